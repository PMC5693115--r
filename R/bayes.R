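#' Validate a somite measurement table
#'
#' Checks the measurement schema shared by the synthetic generator, the
#' descriptive statistic and the hierarchical model: one row per measured
#' somite with columns `litter_id`, `embryo_id`, `genotype`,
#' `somite_index`, `size_pixels` (ROI pixel count, positive),
#' `phh3_count` (mitotic nuclei, nonnegative) and `nuclei_count` (total
#' nuclei, positive, `>= phh3_count`).
#'
#' @param measurements A data.frame in the schema above.
#' @return The validated data.frame (invisibly usable in a pipe).
#' @export
validate_measurements <- function(measurements) {
  req <- c("litter_id", "embryo_id", "genotype", "somite_index",
           "size_pixels", "phh3_count", "nuclei_count")
  if (!is.data.frame(measurements)) stop("measurements must be a data.frame")
  missing <- setdiff(req, names(measurements))
  if (length(missing) > 0) {
    stop("measurement table lacks column(s): ", paste(missing, collapse = ", "))
  }
  m <- measurements
  if (nrow(m) == 0) stop("measurement table is empty")
  if (!all(m$genotype %in% GENOTYPES)) {
    stop("genotype must be one of: ", paste(GENOTYPES, collapse = ", "))
  }
  if (any(m$size_pixels <= 0)) stop("size_pixels must be positive")
  if (any(m$phh3_count < 0)) stop("phh3_count must be nonnegative")
  if (any(m$nuclei_count <= 0)) stop("nuclei_count must be positive")
  if (any(m$phh3_count > m$nuclei_count)) {
    stop("phh3_count cannot exceed nuclei_count")
  }
  m
}

#' Read a somite measurement table from delimited text
#'
#' Adapter for measurement tables with header
#' `litter_id,embryo_id,genotype,somite_index,size_pixels,phh3_count,nuclei_count`.
#' Embryos recorded as heterozygous controls should be labeled `normal`
#' before or during import; a `genotype_map` can rename arbitrary labels.
#'
#' @param file Path to a CSV file.
#' @param genotype_map Optional named character vector mapping file labels
#'   to the canonical genotypes (e.g. `c(het_control = "normal")`).
#' @return A validated measurement data.frame.
#' @export
read_measurements <- function(file, genotype_map = NULL) {
  m <- read.csv(file, stringsAsFactors = FALSE)
  if (!is.null(genotype_map)) {
    hit <- m$genotype %in% names(genotype_map)
    m$genotype[hit] <- unname(genotype_map[m$genotype[hit]])
  }
  validate_measurements(m)
}

embryo_value <- function(m, quantity) {
  switch(quantity,
         size = m$size_pixels,
         proliferation = m$phh3_count / m$nuclei_count,
         stop("quantity must be 'size' or 'proliferation'"))
}

#' Per-embryo ratio of averages against litter-matched controls
#'
#' The descriptive statistic plotted alongside the Bayesian estimates:
#' each embryo's somite average divided by the average over all somites of
#' the `normal` (control) embryos in the same litter. For `quantity =
#' "size"` the somite value is the ROI pixel count; for `"proliferation"`
#' it is the pHH3-positive fraction `phh3_count / nuclei_count`.
#'
#' @param measurements A validated measurement table.
#' @param quantity `"size"` or `"proliferation"`.
#' @return A data.frame `litter_id, embryo_id, genotype, ratio`, one row
#'   per embryo.
#' @export
ratio_of_averages <- function(measurements, quantity = c("size", "proliferation")) {
  quantity <- match.arg(quantity)
  m <- validate_measurements(measurements)
  m$value <- embryo_value(m, quantity)
  out <- list()
  for (lit in unique(m$litter_id)) {
    ml <- m[m$litter_id == lit, ]
    ctrl <- ml$value[ml$genotype == "normal"]
    if (length(ctrl) == 0) {
      stop("litter '", lit, "' has no control (normal) embryo; ",
           "ratios are litter-matched and need at least one")
    }
    ctrl_mean <- mean(ctrl)
    for (emb in unique(ml$embryo_id)) {
      me <- ml[ml$embryo_id == emb, ]
      out[[length(out) + 1]] <- data.frame(
        litter_id = lit, embryo_id = emb, genotype = me$genotype[1],
        ratio = mean(me$value) / ctrl_mean
      )
    }
  }
  do.call(rbind, out)
}

# centered (hierarchical-mean) parameterizations: the litter means carry
# the grand mean, which mixes far better under Gibbs than the offset form
size_model_string <- function() {
  "model {
    for (i in 1:N) {
      y[i] ~ dnorm(mu_l[litter[i]] + beta[geno[i]], tau_w)
    }
    for (j in 1:L) { mu_l[j] ~ dnorm(mu0, tau_l) }
    beta[1] <- 0
    for (k in 2:G) { beta[k] ~ dnorm(0, prec_effect) }
    mu0 ~ dnorm(0, 1.0E-4)
    grand_mean <- mean(mu_l[1:L])
    sigma_w ~ dnorm(0, prec_sd) T(0,)
    sigma_l ~ dnorm(0, prec_sd) T(0,)
    tau_w <- pow(sigma_w, -2)
    tau_l <- pow(sigma_l, -2)
    for (k in 1:G) { ratio[k] <- exp(beta[k]) }
  }"
}

prolif_model_string <- function() {
  "model {
    for (i in 1:N) {
      phh3[i] ~ dbin(p[i], nuclei[i])
      logit(p[i]) <- theta[embryo[i]]
    }
    for (e in 1:E) {
      theta[e] ~ dnorm(mu_l[litter_of[e]] + gamma[geno_of[e]], tau_e)
    }
    for (j in 1:L) { mu_l[j] ~ dnorm(a0, tau_l) }
    gamma[1] <- 0
    for (k in 2:G) { gamma[k] ~ dnorm(0, prec_effect) }
    a0 ~ dnorm(0, 0.25)
    grand_mean <- mean(mu_l[1:L])
    sigma_l ~ dnorm(0, prec_sd) T(0,)
    sigma_e ~ dnorm(0, prec_sd) T(0,)
    tau_l <- pow(sigma_l, -2)
    tau_e <- pow(sigma_e, -2)
    p0 <- ilogit(grand_mean)
    for (k in 1:G) { ratio[k] <- ilogit(grand_mean + gamma[k]) / p0 }
  }"
}

#' Fit the hierarchical Bayesian measurement model
#'
#' Estimates genotype-relative somite ratios from litter-structured
#' measurements by MCMC. For `quantity = "size"` the model is
#' `log(size_pixels) ~ Normal(mu0 + litter effect + beta_g, sigma_within)`
#' with litter effects `~ Normal(0, sigma_litter)`, `beta_normal = 0`, and
#' the size ratio defined as `exp(beta_g)`. For `"proliferation"` the
#' model is `phh3_count ~ Binomial(nuclei_count, p)` with
#' `logit(p) = a0 + litter effect + embryo effect + gamma_g`,
#' `gamma_normal = 0`, and the proliferation ratio defined as the ratio of
#' the population-level proportions,
#' `invlogit(a0 + gamma_g) / invlogit(a0)`. Priors are weakly
#' informative: Normal(0, 1) on genotype effects, half-Normal(0, 1) on all
#' SDs (both configurable through `priors`).
#'
#' Convergence is checked with the per-parameter potential scale
#' reduction factor over all monitored parameters (scale parameters
#' log-transformed); fits with any point estimate at or above 1.01 carry
#' a warning and `converged = FALSE`. With very few litters the
#' litter-level SD is weakly identified and may need `draws = 4000` or
#' more to settle; the genotype ratios converge much faster.
#'
#' @param measurements A validated measurement table containing the
#'   `normal` reference genotype and at least one other genotype.
#' @param quantity `"size"` or `"proliferation"`.
#' @param chains Number of MCMC chains (default 4).
#' @param draws Total iterations per chain; the first half is warm-up
#'   (adaptation + burn-in), the second half is kept (default 2000).
#' @param seed Integer seed; chain RNGs are derived from it, so fits are
#'   reproducible.
#' @param priors Named list: `sd_effect` (prior SD of genotype effects,
#'   default 1) and `sd_scale` (half-Normal scale of the SD priors,
#'   default 1).
#' @return A `rib_fit` object: `ratio_draws` (matrix, one column per
#'   genotype, kept draws pooled over chains), `samples` (the underlying
#'   `coda::mcmc.list`), `genotypes`, `quantity`, `psrf` (per-parameter
#'   point estimates), `converged`, `seed`.
#' @seealso [posterior_summary()], [generate_measurements()]
#' @export
fit_measurement_model <- function(measurements,
                                  quantity = c("size", "proliferation"),
                                  chains = 4, draws = 2000, seed = 1,
                                  priors = list()) {
  quantity <- match.arg(quantity)
  m <- validate_measurements(measurements)
  stopifnot(chains >= 1, draws >= 20)
  genos <- c("normal", setdiff(GENOTYPES, "normal"))
  genos <- genos[genos %in% unique(m$genotype)]
  if (!"normal" %in% genos) {
    stop("measurements contain no reference (normal) embryos")
  }
  if (length(genos) < 2) {
    stop("need at least two genotypes including the reference")
  }
  for (g in genos) {
    if (sum(m$genotype == g) == 0) stop("empty genotype cell: ", g)
  }
  sd_effect <- if (is.null(priors$sd_effect)) 1 else priors$sd_effect
  sd_scale <- if (is.null(priors$sd_scale)) 1 else priors$sd_scale

  litter <- match(m$litter_id, unique(m$litter_id))
  embryo <- match(paste(m$litter_id, m$embryo_id),
                  unique(paste(m$litter_id, m$embryo_id)))
  geno <- match(m$genotype, genos)
  common <- list(N = nrow(m), L = max(litter), G = length(genos),
                 litter = litter, geno = geno,
                 prec_effect = 1 / sd_effect^2, prec_sd = 1 / sd_scale^2)
  if (quantity == "size") {
    data <- c(common, list(y = log(m$size_pixels)))
    model_str <- size_model_string()
  } else {
    first <- match(seq_len(max(embryo)), embryo)
    litter_of <- litter[first]
    geno_of <- geno[first]
    common$litter <- NULL  # litters enter through the embryo-litter map
    common$geno <- NULL    # genotype enters through the embryo-level mean
    data <- c(common, list(phh3 = m$phh3_count, nuclei = m$nuclei_count,
                           E = max(embryo), embryo = embryo,
                           litter_of = litter_of, geno_of = geno_of))
    model_str <- prolif_model_string()
  }
  warmup <- floor(draws / 2)
  keep <- draws - warmup
  inits <- lapply(seq_len(chains), function(ch) {
    # derive per-chain RNG seeds in double precision to dodge 32-bit overflow
    derived <- (abs(as.numeric(seed)) * 1009 + ch * 101) %% 2147483 + 1
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = as.integer(derived))
  })
  monitors <- if (quantity == "size") {
    c("ratio", "grand_mean", "sigma_w", "sigma_l")
  } else {
    c("ratio", "grand_mean", "sigma_l", "sigma_e")
  }
  jm <- rjags::jags.model(textConnection(model_str), data = data,
                          inits = inits, n.chains = chains,
                          n.adapt = max(100, floor(warmup / 2)),
                          quiet = TRUE)
  update(jm, n.iter = warmup - max(100, floor(warmup / 2)),
         progress.bar = "none")
  samples <- rjags::coda.samples(jm, variable.names = monitors,
                                 n.iter = keep, progress.bar = "none")
  mat <- as.matrix(samples)
  ratio_cols <- paste0("ratio[", seq_along(genos), "]")
  ratio_draws <- mat[, ratio_cols, drop = FALSE]
  colnames(ratio_draws) <- genos

  psrf <- rep(1, ncol(mat))
  if (chains >= 2) {
    # the reference ratio is the constant 1; drop it before gelman.diag
    keep_cols <- setdiff(colnames(mat), "ratio[1]")
    gd <- try(coda::gelman.diag(samples[, keep_cols, drop = FALSE],
                                autoburnin = FALSE, multivariate = FALSE,
                                transform = TRUE),
              silent = TRUE)
    if (!inherits(gd, "try-error")) psrf <- gd$psrf[, 1]
  }
  converged <- all(is.finite(psrf)) && max(psrf) < 1.01
  if (!converged) {
    warning("MCMC convergence diagnostic failed: max potential scale ",
            "reduction factor = ", signif(max(psrf), 4),
            " (threshold 1.01); consider more draws")
  }
  structure(list(ratio_draws = ratio_draws, samples = samples,
                 genotypes = genos, quantity = quantity,
                 psrf = psrf, converged = converged,
                 chains = chains, draws = draws, seed = as.integer(seed)),
            class = "rib_fit")
}

#' @export
print.rib_fit <- function(x, ...) {
  cat(sprintf("<rib_fit> %s model: %d chains x %d draws, %s\n",
              x$quantity, x$chains, x$draws,
              if (x$converged) "converged" else "NOT converged"))
  print(posterior_summary(x))
  invisible(x)
}

#' Posterior summary of genotype-relative ratios
#'
#' Summarizes a fitted measurement model the way the ratio estimates are
#' reported: posterior median, central 50% interval, and the posterior
#' probability that the ratio is below 1. The reference genotype's ratio
#' is identically 1 by construction (degenerate interval,
#' `p_less_than_1 = 0`).
#'
#' @param fit A `rib_fit` from [fit_measurement_model()], or a numeric
#'   matrix of ratio draws with one named column per genotype.
#' @param genotype Optional subset of genotypes to report.
#' @return A data.frame `genotype, quantity, median, lower_50, upper_50,
#'   p_less_than_1`.
#' @export
posterior_summary <- function(fit, genotype = NULL) {
  if (inherits(fit, "rib_fit")) {
    draws <- fit$ratio_draws
    quantity <- paste0(fit$quantity, "_ratio")
  } else {
    draws <- as.matrix(fit)
    quantity <- "ratio"
  }
  if (nrow(draws) < 100) {
    stop("need at least 100 posterior draws to summarize")
  }
  genos <- colnames(draws)
  if (!is.null(genotype)) {
    bad <- setdiff(genotype, genos)
    if (length(bad) > 0) stop("no draws for genotype(s): ",
                              paste(bad, collapse = ", "))
    genos <- genotype
  }
  rows <- lapply(genos, function(g) {
    d <- draws[, g]
    data.frame(genotype = g, quantity = quantity,
               median = median(d),
               lower_50 = unname(quantile(d, 0.25)),
               upper_50 = unname(quantile(d, 0.75)),
               p_less_than_1 = mean(d < 1))
  })
  do.call(rbind, rows)
}
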