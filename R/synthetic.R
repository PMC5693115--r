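#' Ground truth for synthetic somite measurements
#'
#' Defines the generative parameters of [generate_measurements()]. The
#' default ratios are the calibrated genotype effects of the measurement
#' study (size 1 / 0.92 / 0.59 / 0.57; proliferation 1 / 0.71 / 1.1 /
#' 0.32 for normal / Apaf1 KO / Shh KO / Shh;Apaf1 DKO); baseline scales
#' and variance components are set to plausible magnitudes for E9.0 somite
#' sections (ROI of ~50,000 pixels, ~10% mitotic index, ~10-15%
#' multiplicative between-litter and within-embryo variation).
#'
#' @param size_ratio Named numeric, per-genotype multiplicative size
#'   effect relative to normal (all > 0).
#' @param prolif_ratio Named numeric, per-genotype proliferation-fraction
#'   ratio relative to normal (all > 0).
#' @param baseline_size Mean control somite ROI size, pixels.
#' @param baseline_phh3 Control pHH3-positive proportion, in (0, 1).
#' @param sigma_litter SD of litter effects (log-size and logit-proportion
#'   scales).
#' @param sigma_within Within-embryo SD of log somite size.
#' @param sigma_embryo SD of embryo effects on the logit-proportion scale.
#' @return A `rib_truth` list.
#' @export
ground_truth <- function(size_ratio = c(normal = 1, apaf1_ko = 0.92,
                                        shh_ko = 0.59, shh_apaf1_dko = 0.57),
                         prolif_ratio = c(normal = 1, apaf1_ko = 0.71,
                                          shh_ko = 1.1, shh_apaf1_dko = 0.32),
                         baseline_size = 50000,
                         baseline_phh3 = 0.1,
                         sigma_litter = 0.1,
                         sigma_within = 0.15,
                         sigma_embryo = 0.1) {
  stopifnot(all(size_ratio > 0), all(prolif_ratio > 0),
            baseline_size > 0, baseline_phh3 > 0, baseline_phh3 < 1,
            sigma_litter >= 0, sigma_within >= 0, sigma_embryo >= 0,
            all(prolif_ratio * baseline_phh3 < 1))
  structure(list(size_ratio = size_ratio, prolif_ratio = prolif_ratio,
                 baseline_size = baseline_size, baseline_phh3 = baseline_phh3,
                 sigma_litter = sigma_litter, sigma_within = sigma_within,
                 sigma_embryo = sigma_embryo),
            class = "rib_truth")
}

#' Study design for synthetic somite measurements
#'
#' @param n_litters Number of litters.
#' @param embryos_per_litter Embryos per litter.
#' @param somite_range Length-2 integer range of measured somites per
#'   embryo (default 6-8, the typical study yield; a wider range like
#'   `c(2, 8)` emulates partially recovered embryos).
#' @param nuclei_range Length-2 range of DAPI nuclei counted per somite.
#' @param genotype_scheme `"balanced"` cycles genotypes within each litter
#'   (first embryo always normal, so every litter has a control);
#'   `"mendelian"` samples genotypes from the `genotype_freq` frequencies,
#'   forcing the first embryo of each litter to normal.
#' @param genotypes Genotypes present in the study.
#' @param genotype_freq Named nonnegative frequencies per genotype
#'   (normalized internally), e.g. built from
#'   [expected_genotype_frequency()]; required for the mendelian scheme.
#' @return A `rib_design` list.
#' @export
measurement_design <- function(n_litters = 4, embryos_per_litter = 6,
                               somite_range = c(6, 8),
                               nuclei_range = c(200, 1000),
                               genotype_scheme = c("balanced", "mendelian"),
                               genotypes = GENOTYPES,
                               genotype_freq = NULL) {
  genotype_scheme <- match.arg(genotype_scheme)
  stopifnot(n_litters >= 1, embryos_per_litter >= 1,
            length(somite_range) == 2, somite_range[1] >= 1,
            somite_range[1] <= somite_range[2],
            length(nuclei_range) == 2, nuclei_range[1] >= 1,
            nuclei_range[1] <= nuclei_range[2],
            all(genotypes %in% GENOTYPES), "normal" %in% genotypes)
  if (genotype_scheme == "mendelian") {
    if (is.null(genotype_freq) || is.null(names(genotype_freq)) ||
        !all(genotypes %in% names(genotype_freq))) {
      stop("mendelian scheme needs named genotype_freq covering all genotypes")
    }
    stopifnot(all(genotype_freq >= 0), sum(genotype_freq) > 0)
  }
  structure(list(n_litters = as.integer(n_litters),
                 embryos_per_litter = as.integer(embryos_per_litter),
                 somite_range = as.integer(somite_range),
                 nuclei_range = as.integer(nuclei_range),
                 genotype_scheme = genotype_scheme,
                 genotypes = genotypes, genotype_freq = genotype_freq),
            class = "rib_design")
}

#' Generate litter-structured synthetic somite measurements
#'
#' Emulates the statistical structure of the measurement study with known
#' ground truth: somite sizes are log-normal with litter and genotype
#' effects (`log size = log baseline + litter effect + log size_ratio +
#' Normal(0, sigma_within)`), pHH3 counts are binomial with litter, embryo
#' and genotype effects on the logit scale (the genotype effect chosen so
#' the population-level proportion ratio equals `prolif_ratio`), and
#' nuclei counts are uniform over `nuclei_range`. Deterministic under a
#' fixed seed.
#'
#' @param truth A [ground_truth()] object.
#' @param design A [measurement_design()] object.
#' @param seed Integer seed.
#' @return A validated measurement data.frame (schema of
#'   [validate_measurements()]).
#' @examples
#' m <- generate_measurements(ground_truth(), measurement_design(), seed = 1)
#' head(m)
#' @export
generate_measurements <- function(truth = ground_truth(),
                                  design = measurement_design(),
                                  seed = 1) {
  stopifnot(inherits(truth, "rib_truth"), inherits(design, "rib_design"))
  set.seed(as.integer(seed))
  genos <- design$genotypes
  missing <- setdiff(genos, names(truth$size_ratio))
  if (length(missing) > 0) stop("truth lacks ratios for: ",
                                paste(missing, collapse = ", "))
  # genotype effect on the logit scale giving the target proportion ratio
  gamma <- qlogis(truth$prolif_ratio[genos] * truth$baseline_phh3) -
    qlogis(truth$baseline_phh3)
  pick_int <- function(rng) {        # avoid sample()'s scalar expansion
    rng[1] + sample.int(rng[2] - rng[1] + 1L, 1L) - 1L
  }
  rows <- list()
  for (lit in seq_len(design$n_litters)) {
    u_size <- rnorm(1, 0, truth$sigma_litter)
    u_prolif <- rnorm(1, 0, truth$sigma_litter)
    geno_assign <- if (design$genotype_scheme == "balanced") {
      rep(genos, length.out = design$embryos_per_litter)
    } else {
      freqs <- design$genotype_freq[genos]
      extra <- if (design$embryos_per_litter > 1) {
        sample(genos, design$embryos_per_litter - 1, replace = TRUE,
               prob = freqs / sum(freqs))
      } else {
        character(0)
      }
      c("normal", extra)
    }
    for (emb in seq_len(design$embryos_per_litter)) {
      g <- geno_assign[emb]
      v <- rnorm(1, 0, truth$sigma_embryo)
      n_som <- pick_int(design$somite_range)
      for (s in seq_len(n_som)) {
        size <- exp(log(truth$baseline_size) + u_size +
                      log(truth$size_ratio[[g]]) +
                      rnorm(1, 0, truth$sigma_within))
        nuclei <- pick_int(design$nuclei_range)
        p <- plogis(qlogis(truth$baseline_phh3) + u_prolif + v + gamma[[g]])
        rows[[length(rows) + 1]] <- data.frame(
          litter_id = sprintf("L%02d", lit),
          embryo_id = sprintf("L%02d_E%02d", lit, emb),
          genotype = g, somite_index = s,
          size_pixels = max(1, round(size)),
          phh3_count = rbinom(1, nuclei, p),
          nuclei_count = nuclei
        )
      }
    }
  }
  validate_measurements(do.call(rbind, rows))
}
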