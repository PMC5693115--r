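#' Simulation parameters for the rib-patterning agent-based model
#'
#' Builds and validates the full parameter set driving [run_simulation()].
#' The first nine arguments are the genotype-level dials (see
#' [genotype_presets()] for the four calibrated presets); the remainder are
#' model constants and design constants of the simulator itself.
#'
#' @param initsizemult Dimensionless scale on the initial progenitor pool;
#'   the pool is `round(base_pool * initsizemult)` cells.
#' @param shh_xport Spatial extent of the Hedgehog (Hh) signal in patch
#'   units: the standard deviation of the Gaussian concentration profile.
#' @param shh_intensity_log log10 of the Hh peak concentration
#'   (dimensionless); 0.6 gives a peak of about 3.98, -2 gives 0.01.
#' @param nticks Maximum simulation duration in ticks.
#' @param p_red1 Fate-conversion coefficient toward the proximal (red)
#'   fate, a probability in `[0, 1]`.
#' @param p_blue1 Fate-conversion coefficient toward the distal (blue)
#'   fate, a probability in `[0, 1]`.
#' @param celldeathmult Peak-death-rate multiplier (>= 0); 0 disables death
#'   entirely (Apaf1-null conditions).
#' @param proliferatemult Proliferation-rate multiplier (>= 0) on the base
#'   per-tick division probability.
#' @param cdduration Duration of the transient cell-death epoch, in ticks;
#'   the death curve is a half-Gaussian in time with SD `cdduration / 2`.
#' @param base_event_rate Per-tick base probability shared by division and
#'   death. Model constant, 0.05.
#' @param hh_peak_x x-position of the Hh peak in patch units. Model
#'   constant, -10.
#' @param base_pool Reference progenitor count. Model constant, 1200.
#' @param block_coeff Side coefficient of the initial square block, patch
#'   units. Model constant, 14: a pool of 1200 starts in a 14 x 14 block.
#' @param world_x_min,world_x_max,world_y_min,world_y_max Bounds of the
#'   rectangular patch field.
#' @param density_max Crowding threshold in cells per patch: agents whose
#'   local density (cells within radius 1, self included, divided by the
#'   disc area) exceeds this move during redistribution. Default 6, the
#'   upper end of the 4-6 cells/patch working density.
#' @param spread_sweeps Maximum redistribution sweeps per tick; caps how
#'   fast the field can decompress in one tick.
#' @param community_radius Neighborhood radius (patch units) of the
#'   community effect.
#' @param community_threshold Supermajority fraction of opposite-fate
#'   neighbors required to flip a decided cell; set above 1 to disable the
#'   community effect.
#' @param community_min_neighbors Minimum number of decided neighbors
#'   before the community rule applies.
#' @param fate_half_saturation Hh concentration at which the fate bias is
#'   balanced (the half-saturation constant of the dose-response).
#'
#' @return An object of class `rib_params` (a validated named list).
#' @seealso [load_preset()], [run_simulation()]
#' @examples
#' p <- sim_params()
#' p$nticks
#' @export
sim_params <- function(initsizemult = 1,
                       shh_xport = 12,
                       shh_intensity_log = 0.6,
                       nticks = 46L,
                       p_red1 = 0.4,
                       p_blue1 = 0.4,
                       celldeathmult = 0.3,
                       proliferatemult = 1,
                       cdduration = 30L,
                       base_event_rate = 0.05,
                       hh_peak_x = -10,
                       base_pool = 1200L,
                       block_coeff = 14,
                       world_x_min = -16,
                       world_x_max = 40,
                       world_y_min = -16,
                       world_y_max = 16,
                       density_max = 6L,
                       spread_sweeps = 3L,
                       community_radius = 1.5,
                       community_threshold = 0.75,
                       community_min_neighbors = 3L,
                       fate_half_saturation = 1) {
  p <- list(
    initsizemult = initsizemult, shh_xport = shh_xport,
    shh_intensity_log = shh_intensity_log, nticks = as.integer(nticks),
    p_red1 = p_red1, p_blue1 = p_blue1, celldeathmult = celldeathmult,
    proliferatemult = proliferatemult, cdduration = as.integer(cdduration),
    base_event_rate = base_event_rate, hh_peak_x = hh_peak_x,
    base_pool = as.integer(base_pool), block_coeff = block_coeff,
    world_x_min = world_x_min, world_x_max = world_x_max,
    world_y_min = world_y_min, world_y_max = world_y_max,
    density_max = as.integer(density_max),
    spread_sweeps = as.integer(spread_sweeps),
    community_radius = community_radius,
    community_threshold = community_threshold,
    community_min_neighbors = as.integer(community_min_neighbors),
    fate_half_saturation = fate_half_saturation
  )
  class(p) <- "rib_params"
  validate_params(p)
}

#' @export
print.rib_params <- function(x, ...) {
  cat("<rib_params>\n")
  for (nm in names(x)) cat(sprintf("  %-24s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

validate_params <- function(p) {
  stopifnot(inherits(p, "rib_params"))
  num1 <- function(v) is.numeric(v) && length(v) == 1 && is.finite(v)
  for (nm in names(p)) {
    if (!num1(p[[nm]])) stop("parameter '", nm, "' must be a finite scalar")
  }
  if (p$p_red1 < 0 || p$p_red1 > 1) stop("p_red1 must be in [0, 1]")
  if (p$p_blue1 < 0 || p$p_blue1 > 1) stop("p_blue1 must be in [0, 1]")
  if (p$p_red1 + p$p_blue1 > 1) {
    stop("p_red1 + p_blue1 must not exceed 1 (they compete in one draw)")
  }
  if (p$base_event_rate < 0 || p$base_event_rate > 1) {
    stop("base_event_rate must be in [0, 1]")
  }
  if (p$celldeathmult < 0) stop("celldeathmult must be >= 0")
  if (p$proliferatemult < 0) stop("proliferatemult must be >= 0")
  if (p$nticks < 1) stop("nticks must be a positive integer")
  if (p$cdduration < 1) stop("cdduration must be a positive integer")
  if (p$initsizemult <= 0) stop("initsizemult must be positive")
  if (p$shh_xport <= 0) stop("shh_xport must be positive")
  if (!(p$world_x_min < 0 && 0 < p$world_x_max)) {
    stop("world bounds must satisfy world_x_min < 0 < world_x_max")
  }
  if (p$world_y_min >= p$world_y_max) stop("world_y_min must be < world_y_max")
  if (p$density_max < 1) stop("density_max must be >= 1")
  if (p$spread_sweeps < 1) stop("spread_sweeps must be >= 1")
  if (p$community_radius <= 0) stop("community_radius must be positive")
  if (p$community_min_neighbors < 1) {
    stop("community_min_neighbors must be >= 1")
  }
  if (p$fate_half_saturation <= 0) {
    stop("fate_half_saturation must be positive")
  }
  if (round(p$base_pool * p$initsizemult) < 1) {
    stop("initial pool would be empty: base_pool * initsizemult < 0.5")
  }
  p
}

# update a rib_params with named overrides, revalidating
modify_params <- function(p, overrides) {
  if (length(overrides) == 0) return(p)
  if (is.null(names(overrides)) || any(names(overrides) == "")) {
    stop("parameter overrides must be named")
  }
  unknown <- setdiff(names(overrides), names(p))
  if (length(unknown) > 0) {
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  }
  for (nm in names(overrides)) p[[nm]] <- overrides[[nm]]
  int_fields <- c("nticks", "cdduration", "base_pool", "density_max",
                  "spread_sweeps", "community_min_neighbors")
  for (nm in intersect(int_fields, names(overrides))) {
    p[[nm]] <- as.integer(p[[nm]])
  }
  validate_params(p)
}
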