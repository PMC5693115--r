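test_that("measurement validation enforces the schema", {
  m <- toy_measurements()
  expect_silent(validate_measurements(m))
  expect_error(validate_measurements(m[, -3]), "genotype")
  bad <- m
  bad$phh3_count[1] <- 200
  expect_error(validate_measurements(bad), "exceed")
  bad2 <- m
  bad2$genotype[1] <- "mutant"
  expect_error(validate_measurements(bad2), "genotype")
  bad3 <- m
  bad3$size_pixels[1] <- 0
  expect_error(validate_measurements(bad3), "size_pixels")
})

test_that("ratio of averages is litter-matched", {
  m <- toy_measurements()
  rs <- ratio_of_averages(m, "size")
  # litter A: control embryo A1 mean 100; A2 mean 59 -> 0.59
  expect_equal(rs$ratio[rs$embryo_id == "A2"], 0.59)
  expect_equal(rs$ratio[rs$embryo_id == "A1"], 1)
  # litter B: control mean 100, B2 mean 100 -> 1
  expect_equal(rs$ratio[rs$embryo_id == "B2"], 1)

  rp <- ratio_of_averages(m, "proliferation")
  expect_equal(rp$ratio[rp$embryo_id == "A2"], 0.5)

  # a litter without controls is an error
  orphan <- m
  orphan$genotype[orphan$litter_id == "B"] <- "shh_ko"
  expect_error(ratio_of_averages(orphan, "size"), "no control")
})

test_that("posterior summaries report median, 50% box, and P(<1)", {
  draws <- cbind(normal = rep(1, 400),
                 shh_ko = seq(0.4, 0.8, length.out = 400))
  s <- posterior_summary(draws)
  expect_equal(s$p_less_than_1, c(0, 1))
  expect_equal(s$median[2], 0.6, tolerance = 1e-3)
  expect_lte(s$lower_50[2], s$median[2])
  expect_gte(s$upper_50[2], s$median[2])

  sym <- cbind(g = c(seq(0.5, 1.5, length.out = 401)))
  expect_equal(posterior_summary(sym)$p_less_than_1, 0.5, tolerance = 0.01)

  expect_error(posterior_summary(draws[1:50, ]), "100")
})

test_that("the size model recovers a known ratio and matches lme4", {
  truth <- ground_truth(size_ratio = c(normal = 1, shh_ko = 0.6),
                        prolif_ratio = c(normal = 1, shh_ko = 1))
  des <- measurement_design(n_litters = 4, embryos_per_litter = 6,
                            somite_range = c(6, 6),
                            genotypes = c("normal", "shh_ko"))
  m <- generate_measurements(truth, des, seed = 314)
  fit <- suppressWarnings(
    fit_measurement_model(m, "size", draws = 4000, seed = 314)
  )
  s <- posterior_summary(fit)
  expect_identical(s$genotype, c("normal", "shh_ko"))
  # the reference ratio is 1 in every draw by construction
  expect_true(all(fit$ratio_draws[, "normal"] == 1))
  expect_gt(s$median[2], 0.5)
  expect_lt(s$median[2], 0.7)

  # independent route: REML fit of the same hierarchy
  skip_if_not_installed("lme4")
  lm <- lme4::lmer(log(size_pixels) ~ genotype + (1 | litter_id), data = m)
  expect_equal(s$median[2], exp(unname(lme4::fixef(lm)["genotypeshh_ko"])),
               tolerance = 0.03)
})

test_that("size ratios are invariant to the measurement scale", {
  truth <- ground_truth(size_ratio = c(normal = 1, apaf1_ko = 0.8),
                        prolif_ratio = c(normal = 1, apaf1_ko = 1))
  des <- measurement_design(genotypes = c("normal", "apaf1_ko"),
                            somite_range = c(6, 6))
  m <- generate_measurements(truth, des, seed = 5)
  m10 <- m
  m10$size_pixels <- m10$size_pixels * 10
  f1 <- suppressWarnings(fit_measurement_model(m, "size", seed = 5))
  f2 <- suppressWarnings(fit_measurement_model(m10, "size", seed = 5))
  expect_equal(posterior_summary(f1)$median, posterior_summary(f2)$median,
               tolerance = 0.02)
})

test_that("the proliferation model targets the proportion ratio", {
  truth <- ground_truth(prolif_ratio = c(normal = 1, shh_apaf1_dko = 0.4),
                        size_ratio = c(normal = 1, shh_apaf1_dko = 1))
  des <- measurement_design(n_litters = 4, embryos_per_litter = 6,
                            somite_range = c(6, 6),
                            genotypes = c("normal", "shh_apaf1_dko"))
  m <- generate_measurements(truth, des, seed = 2718)
  fit <- suppressWarnings(
    fit_measurement_model(m, "proliferation", draws = 4000, seed = 2718)
  )
  s <- posterior_summary(fit)
  expect_gt(s$median[2], 0.3)
  expect_lt(s$median[2], 0.5)
  expect_equal(s$p_less_than_1[2], 1)
})

test_that("degenerate measurement sets are rejected informatively", {
  m <- toy_measurements()
  only_normal <- m[m$genotype == "normal", ]
  expect_error(fit_measurement_model(only_normal, "size"), "two genotypes")
  no_ref <- m[m$genotype != "normal", ]
  expect_error(fit_measurement_model(no_ref, "size"), "reference")
})
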