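test_that("fate fractions partition the field", {
  st <- make_state(1:4, rep(0, 4),
                   c("proximal", "proximal", "proximal", "distal"))
  ff <- fate_fractions(st)
  expect_equal(ff, list(f_undecided = 0, f_proximal = 0.75, f_distal = 0.25))

  st2 <- make_state(1:3, rep(0, 3), rep("proximal", 3))
  expect_equal(fate_fractions(st2)$f_proximal, 1)

  empty <- st
  empty$agents <- st$agents[0, ]
  expect_error(fate_fractions(empty), "empty")

  # fractions always sum to one on simulated fields
  r <- run_simulation(quick_params(nticks = 6), seed = 12)
  expect_equal(Reduce(`+`, fate_fractions(r)), 1)
})

test_that("boundary profile bins proximal fractions by x", {
  st <- make_state(seq(0.2, 9.8, length.out = 60), rep(0, 60),
                   rep(c("proximal", "distal"), c(30, 30)))
  prof <- boundary_profile(st, bin_width = 1)
  expect_true(all(diff(prof$x) > 0))
  expect_true(all(prof$f_proximal[prof$x < 4.8] == 1))
  expect_true(all(prof$f_proximal[prof$x > 5.2] == 0))
  expect_identical(sum(prof$n_decided), 60L)

  # bins with only undecided agents are flagged as NA
  stu <- make_state(c(0.5, 5.5), c(0, 0), c("proximal", "undecided"))
  profu <- boundary_profile(stu, bin_width = 1)
  expect_true(is.na(profu$f_proximal[profu$x == 5.5]))

  # uniformly random colors give near-0.5 fractions per bin
  set.seed(8)
  n <- 4000
  str <- make_state(runif(n, 0, 10), runif(n, -3, 3),
                    sample(c("proximal", "distal"), n, replace = TRUE))
  profr <- boundary_profile(str, bin_width = 1)
  se <- sqrt(0.25 / profr$n_decided)
  expect_true(all(abs(profr$f_proximal - 0.5) < 4 * se))

  expect_error(boundary_profile(st, bin_width = 0), "bin_width")
})

test_that("boundary sharpness measures the 0.75/0.25 crossing width", {
  # perfect step: width no wider than one bin
  step_prof <- data.frame(x = 1:10 - 0.5,
                          f_proximal = rep(c(1, 0), each = 5),
                          n_decided = 50L)
  expect_lte(boundary_sharpness(step_prof), 1)

  # linear ramp from 1 to 0 over 10 columns crosses at width 5
  ramp <- data.frame(x = 0:10, f_proximal = seq(1, 0, by = -0.1),
                     n_decided = 50L)
  expect_equal(boundary_sharpness(ramp), 5)

  # single-color profiles have no boundary
  flat <- data.frame(x = 1:6, f_proximal = rep(0, 6), n_decided = 10L)
  expect_error(boundary_sharpness(flat), "boundary")
  flat1 <- data.frame(x = 1:6, f_proximal = rep(1, 6), n_decided = 10L)
  expect_error(boundary_sharpness(flat1), "boundary")

  # isotonic smoothing tolerates single-bin noise
  noisy <- data.frame(x = 0:10,
                      f_proximal = c(1, 1, 0.95, 1, 0.8, 0.5, 0.2, 0, 0.05,
                                     0, 0),
                      n_decided = 50L)
  expect_lt(boundary_sharpness(noisy), 5)
})
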