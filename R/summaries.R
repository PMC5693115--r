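#' Fate-state fractions of a simulated field
#'
#' @param state A `rib_state` (or `rib_result`, in which case the final
#'   state is used) with at least one agent.
#' @return A named list `f_undecided`, `f_proximal`, `f_distal`, summing
#'   to 1.
#' @examples
#' res <- run_simulation(load_preset("normal", nticks = 5), seed = 1)
#' fate_fractions(res)
#' @export
fate_fractions <- function(state) {
  if (inherits(state, "rib_result")) state <- state$final_state
  stopifnot(inherits(state, "rib_state"))
  n <- nrow(state$agents)
  if (n == 0) stop("cannot compute fate fractions of an empty field")
  list(f_undecided = sum(state$agents$state == FATE_UNDECIDED) / n,
       f_proximal = sum(state$agents$state == FATE_PROXIMAL) / n,
       f_distal = sum(state$agents$state == FATE_DISTAL) / n)
}

#' Local cell density at each agent
#'
#' Density as the redistribution rule sees it: the number of agents within
#' radius 1 patch of each agent (itself included) divided by the disc area
#' `pi`, in cells per patch.
#'
#' @param state A `rib_state` or `rib_result`.
#' @return Numeric vector, one density per agent.
#' @export
local_density <- function(state) {
  if (inherits(state, "rib_result")) state <- state$final_state
  stopifnot(inherits(state, "rib_state"))
  a <- state$agents
  if (nrow(a) == 0) return(numeric(0))
  count_points_within(a$x, a$y, a$x, a$y, 1.0) / pi
}

#' Proximal-fraction profile along the outgrowth axis
#'
#' Bins agents by x and reports, per bin, the proximal fraction among
#' decided (proximal or distal) agents. This turns the visual
#' proximal-then-distal band layout into a curve whose steepness measures
#' how distinct the boundary between the two prospective elements is.
#'
#' @param state A `rib_state` or `rib_result`.
#' @param bin_width Positive bin width in patch units (default 1, one
#'   patch column).
#' @return A data.frame with columns `x` (bin center), `f_proximal`
#'   (proximal fraction among decided agents; `NA` where a bin holds no
#'   decided agents), and `n_decided`.
#' @export
boundary_profile <- function(state, bin_width = 1) {
  if (inherits(state, "rib_result")) state <- state$final_state
  stopifnot(inherits(state, "rib_state"))
  if (!is.numeric(bin_width) || length(bin_width) != 1 || bin_width <= 0) {
    stop("bin_width must be a positive number")
  }
  a <- state$agents
  if (nrow(a) == 0) stop("cannot profile an empty field")
  bin <- floor(a$x / bin_width)
  bins <- sort(unique(bin))
  prox <- tapply(a$state == FATE_PROXIMAL, bin, sum)[as.character(bins)]
  dist <- tapply(a$state == FATE_DISTAL, bin, sum)[as.character(bins)]
  n_dec <- as.integer(prox + dist)
  data.frame(
    x = (bins + 0.5) * bin_width,
    f_proximal = ifelse(n_dec > 0, as.numeric(prox) / pmax(n_dec, 1L), NA),
    n_decided = n_dec
  )
}

#' Boundary sharpness of a proximal-distal profile
#'
#' Operationalizes how distinct the border between the proximal and distal
#' domains is: after isotonic (antitonic, decreasing-in-x) smoothing of
#' the per-bin proximal fraction, returns the x-distance between the point
#' where the smoothed fraction first drops below 0.75 and where it first
#' drops below 0.25 (linear interpolation between bin centers). Smaller is
#' sharper; a perfect step has width at most one bin.
#'
#' @param profile A data.frame from [boundary_profile()].
#' @return Boundary width in patch units (nonnegative).
#' @export
boundary_sharpness <- function(profile) {
  stopifnot(is.data.frame(profile),
            all(c("x", "f_proximal", "n_decided") %in% names(profile)))
  keep <- profile$n_decided > 0 & !is.na(profile$f_proximal)
  x <- profile$x[keep]
  f <- profile$f_proximal[keep]
  if (length(x) < 2) stop("no proximal-distal boundary: profile too short")
  # antitonic fit: isoreg fits nondecreasing, so fit on reversed order
  ord <- order(x)
  x <- x[ord]; f <- f[ord]
  smoothed <- rev(isoreg(seq_along(f), rev(f))$yf)
  if (max(smoothed) < 0.75 || min(smoothed) >= 0.25) {
    stop("no proximal-distal boundary: profile does not cross both ",
         "0.75 and 0.25")
  }
  x75 <- threshold_crossing(x, smoothed, 0.75)
  x25 <- threshold_crossing(x, smoothed, 0.25)
  if (is.na(x75) || is.na(x25)) {
    stop("no proximal-distal boundary: profile does not cross both ",
         "0.75 and 0.25")
  }
  max(x25 - x75, 0)
}

# first x at which a nonincreasing curve drops below `level`, linearly
# interpolated between bin centers; NA if it never does (or starts below)
threshold_crossing <- function(x, f, level) {
  below <- which(f < level)
  if (length(below) == 0) return(NA_real_)
  i <- below[1]
  if (i == 1) return(x[1])
  # interpolate between the last point at/above and the first below
  x0 <- x[i - 1]; x1 <- x[i]; f0 <- f[i - 1]; f1 <- f[i]
  if (f0 == f1) return(x1)
  x0 + (f0 - level) / (f0 - f1) * (x1 - x0)
}
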