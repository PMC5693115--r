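#' Hedgehog concentration profile
#'
#' Static Gaussian concentration of secreted Hh over the patch field:
#' `A * exp(-(x - hh_peak_x)^2 / (2 * sigma^2))` with amplitude
#' `A = 10^shh_intensity_log` and width `sigma = shh_xport`. The peak sits
#' at `hh_peak_x` (default -10), to the left of the progenitor block, so
#' cells nearer the axial midline see more signal. At the normal preset
#' (amplitude `10^0.6`, `shh_xport = 12`) the concentration crosses the
#' fate half-saturation constant near x = 10, inside the progenitor
#' field, which is what lets a balanced proximal/distal pattern form.
#'
#' @param x Numeric vector of patch x-coordinates.
#' @param params A [sim_params()] object.
#' @return Concentrations (dimensionless, >= 0), same length as `x`.
#' @examples
#' hh_concentration(-10, sim_params())  # peak value, 10^0.6
#' @export
hh_concentration <- function(x, params) {
  stopifnot(is.numeric(x), inherits(params, "rib_params"))
  sigma <- params$shh_xport
  10^params$shh_intensity_log *
    exp(-(x - params$hh_peak_x)^2 / (2 * sigma^2))
}

#' Time-varying per-tick death probability
#'
#' Early transient apoptosis: the base event rate is scaled by
#' `celldeathmult` and by a half-Gaussian in time with SD `cdduration / 2`,
#' so death peaks at tick 0 and is effectively over after about
#' `cdduration` ticks.
#'
#' @param tick Integer tick(s), `0 <= tick <= nticks`.
#' @param params A [sim_params()] object.
#' @return Per-agent death probability at that tick.
#' @examples
#' death_rate(0, sim_params(celldeathmult = 1))   # 0.05
#' death_rate(30, sim_params(celldeathmult = 1))  # 0.05 * exp(-2)
#' @export
death_rate <- function(tick, params) {
  stopifnot(is.numeric(tick), all(tick >= 0), inherits(params, "rib_params"))
  params$base_event_rate * params$celldeathmult *
    exp(-0.5 * (tick / (params$cdduration / 2))^2)
}

#' Hh-dose-dependent fate conversion probabilities
#'
#' At division an undecided cell reads the local Hh concentration `C` and
#' converts with probabilities governed by the saturating bias
#' `g = C / (C + K)` (`K` = `fate_half_saturation`):
#' proximal with `p_red1 * g`, distal with `p_blue1 * (1 - g)`, otherwise
#' staying undecided. High Hh favors the proximal (vertebral) fate, low Hh
#' the distal (sternal) fate.
#'
#' @param concentration Nonnegative Hh concentration(s).
#' @param params A [sim_params()] object.
#' @return A matrix with columns `p_proximal` and `p_distal`, one row per
#'   concentration.
#' @examples
#' fate_probabilities(c(0, 1, 1e6), sim_params())
#' @export
fate_probabilities <- function(concentration, params) {
  stopifnot(is.numeric(concentration), inherits(params, "rib_params"))
  if (any(concentration < 0)) stop("concentration must be >= 0")
  g <- concentration / (concentration + params$fate_half_saturation)
  cbind(p_proximal = params$p_red1 * g,
        p_distal = params$p_blue1 * (1 - g))
}

new_state <- function(agents, tick, stopped, next_id, history) {
  structure(list(agents = agents, tick = tick, stopped = stopped,
                 next_id = next_id, history = history),
            class = "rib_state")
}

history_row <- function(tick, agents, births, deaths) {
  data.frame(
    tick = tick, count = nrow(agents), births = births, deaths = deaths,
    n_undecided = sum(agents$state == FATE_UNDECIDED),
    n_proximal = sum(agents$state == FATE_PROXIMAL),
    n_distal = sum(agents$state == FATE_DISTAL),
    max_x = if (nrow(agents) > 0) max(agents$x) else NA_real_
  )
}

#' Create the initial progenitor field
#'
#' Places `N0 = round(base_pool * initsizemult)` undecided agents uniformly
#' at random in a square block with `x` in `[0, s]` and `y` in
#' `[-s/2, s/2]`, where `s = sqrt(N0 / base_pool) * block_coeff`. The
#' square-root scaling keeps the starting density near 6 cells per patch
#' for any pool size.
#'
#' @param params A [sim_params()] object.
#' @param seed Integer seed; the field is identical for identical
#'   `(params, seed)`.
#' @return A `rib_state` at tick 0.
#' @examples
#' s <- initialize_field(sim_params(), seed = 1)
#' nrow(s$agents)  # 1200
#' @export
initialize_field <- function(params, seed) {
  validate_params(params)
  stopifnot(is.numeric(seed), length(seed) == 1)
  n0 <- round(params$base_pool * params$initsizemult)
  if (n0 < 1) stop("invalid parameters: initial pool size is below 1")
  set.seed(as.integer(seed))
  side <- sqrt(n0 / params$base_pool) * params$block_coeff
  agents <- data.frame(
    id = seq_len(n0),
    x = runif(n0, 0, side),
    y = runif(n0, -side / 2, side / 2),
    state = rep(FATE_UNDECIDED, n0)
  )
  st <- new_state(agents, tick = 0L, stopped = FALSE,
                  next_id = n0 + 1L,
                  history = history_row(0L, agents, 0L, 0L))
  st
}

#' @export
print.rib_state <- function(x, ...) {
  cat(sprintf("<rib_state> tick %d, %d agents (%d undecided, %d proximal, %d distal)%s\n",
              x$tick, nrow(x$agents),
              sum(x$agents$state == FATE_UNDECIDED),
              sum(x$agents$state == FATE_PROXIMAL),
              sum(x$agents$state == FATE_DISTAL),
              if (x$stopped) ", stopped" else ""))
  invisible(x)
}

clamp <- function(v, lo, hi) pmin(pmax(v, lo), hi)

#' Death phase: remove agents stochastically
#'
#' Each agent dies independently with probability
#' [death_rate()]`(tick, params)`. The number removed is recorded on the
#' state for the tick's history record.
#'
#' @param state A `rib_state` (not stopped).
#' @param params A [sim_params()] object.
#' @return The updated `rib_state`.
#' @export
death_phase <- function(state, params) {
  stopifnot(inherits(state, "rib_state"))
  if (state$stopped) stop("cannot advance a stopped simulation")
  n <- nrow(state$agents)
  p <- death_rate(state$tick, params)
  if (n == 0 || p <= 0) {
    state$last_deaths <- 0L
    return(state)
  }
  die <- runif(n) < p
  state$agents <- state$agents[!die, , drop = FALSE]
  state$last_deaths <- sum(die)
  state
}

#' Division phase: proliferation with fate decisions at division
#'
#' Each agent divides with probability
#' `base_event_rate * proliferatemult`. An undecided divider first samples
#' a fate from [fate_probabilities()] at its local Hh concentration (one
#' categorical draw among proximal / distal / stay undecided); the daughter
#' inherits the parent's post-decision state and is placed at the parent
#' position plus uniform jitter of at most 0.5 patch per axis, clamped to
#' the world bounds.
#'
#' @inheritParams death_phase
#' @return The updated `rib_state`.
#' @export
division_phase <- function(state, params) {
  stopifnot(inherits(state, "rib_state"))
  if (state$stopped) stop("cannot advance a stopped simulation")
  a <- state$agents
  n <- nrow(a)
  p_div <- min(1, params$base_event_rate * params$proliferatemult)
  if (n == 0 || p_div <= 0) {
    state$last_births <- 0L
    return(state)
  }
  divides <- runif(n) < p_div
  idx <- which(divides)
  nb <- length(idx)
  if (nb > 0) {
    # fate decision for undecided dividers, a single categorical draw
    und <- idx[a$state[idx] == FATE_UNDECIDED]
    if (length(und) > 0) {
      pr <- fate_probabilities(hh_concentration(a$x[und], params), params)
      u <- runif(length(und))
      new_fate <- ifelse(u < pr[, "p_proximal"], FATE_PROXIMAL,
                         ifelse(u < pr[, "p_proximal"] + pr[, "p_distal"],
                                FATE_DISTAL, FATE_UNDECIDED))
      a$state[und] <- new_fate
    }
    daughters <- data.frame(
      id = seq.int(state$next_id, length.out = nb),
      x = clamp(a$x[idx] + runif(nb, -0.5, 0.5),
                params$world_x_min, params$world_x_max),
      y = clamp(a$y[idx] + runif(nb, -0.5, 0.5),
                params$world_y_min, params$world_y_max),
      state = a$state[idx]
    )
    a <- rbind(a, daughters)
    state$next_id <- state$next_id + nb
  }
  state$agents <- a
  state$last_births <- nb
  state
}

#' Community-effect phase: supermajority fate conversion
#'
#' Every decided agent inspects the decided agents within
#' `community_radius` (excluding itself). If at least
#' `community_min_neighbors` are decided and the fraction holding the
#' opposite fate reaches `community_threshold`, the agent flips to that
#' fate. All flips are computed synchronously from the pre-phase state;
#' undecided agents are unaffected. Setting `community_threshold` above 1
#' disables the rule.
#'
#' @inheritParams death_phase
#' @return The updated `rib_state`.
#' @export
community_phase <- function(state, params) {
  stopifnot(inherits(state, "rib_state"))
  a <- state$agents
  if (nrow(a) == 0 || params$community_threshold > 1) return(state)
  decided <- a$state != FATE_UNDECIDED
  if (!any(decided)) return(state)
  counts <- count_neighbor_states(a$x, a$y, a$state, 3L,
                                  params$community_radius)
  n_prox <- counts[, FATE_PROXIMAL]
  n_dist <- counts[, FATE_DISTAL]
  n_dec <- n_prox + n_dist
  opp <- ifelse(a$state == FATE_PROXIMAL, n_dist, n_prox)
  flip <- decided & n_dec >= params$community_min_neighbors &
    opp / pmax(n_dec, 1L) >= params$community_threshold
  if (any(flip)) {
    a$state[flip] <- ifelse(a$state[flip] == FATE_PROXIMAL,
                            FATE_DISTAL, FATE_PROXIMAL)
    state$agents <- a
  }
  state
}

#' Redistribution phase: density-driven spreading
#'
#' Local density at a point is estimated as the number of cells within
#' radius 1 patch (self included) divided by the disc area `pi`, in cells
#' per patch. Agents whose density exceeds `density_max` (default 6
#' cells/patch, the upper end of the working density the tissue maintains)
#' take one unit step toward the adjacent patch-direction with the lowest
#' local density, ties broken uniformly at random; agents at or below the
#' threshold stay put. Positions are clamped to the world bounds, so
#' crowding can never push an agent through the boundary. The sweep
#' repeats up to `spread_sweeps` times per tick; the net effect is a
#' field that expands as the cells divide while local density stays in
#' the 4-6 cells/patch band.
#'
#' @inheritParams death_phase
#' @return The updated `rib_state`.
#' @export
redistribution_phase <- function(state, params) {
  stopifnot(inherits(state, "rib_state"))
  a <- state$agents
  if (nrow(a) == 0) return(state)
  max_count <- params$density_max * pi  # cells/patch -> count in unit disc
  moved <- redistribute_crowded(a$x, a$y, max_count,
                                params$world_x_min, params$world_x_max,
                                params$world_y_min, params$world_y_max,
                                params$spread_sweeps)
  a$x <- moved[, 1]
  a$y <- moved[, 2]
  state$agents <- a
  state
}

#' Advance the simulation by one tick
#'
#' Applies, in order: [death_phase()], [division_phase()] (with fate
#' decisions), [community_phase()], [redistribution_phase()]; increments
#' the tick; appends a history record; and stops the clock when outgrowth
#' reaches the farthest patch column (any agent at
#' `x >= world_x_max - 1`) or when `nticks` is reached.
#'
#' @inheritParams death_phase
#' @return The updated `rib_state`.
#' @export
step_simulation <- function(state, params) {
  stopifnot(inherits(state, "rib_state"))
  if (state$stopped) stop("cannot step a stopped simulation")
  validate_params(params)
  state <- death_phase(state, params)
  state <- division_phase(state, params)
  state <- community_phase(state, params)
  state <- redistribution_phase(state, params)
  state$tick <- state$tick + 1L
  hit_boundary <- nrow(state$agents) > 0 &&
    max(state$agents$x) >= params$world_x_max - 1
  if (hit_boundary) {
    state$stop_reason <- "boundary"
  } else if (state$tick >= params$nticks) {
    state$stop_reason <- "max_ticks"
  }
  state$stopped <- hit_boundary || state$tick >= params$nticks
  state$history <- rbind(
    state$history,
    history_row(state$tick, state$agents,
                state$last_births, state$last_deaths)
  )
  state
}

#' Run a full rib-outgrowth simulation
#'
#' Initializes the progenitor field and advances tick by tick until the
#' outgrowth boundary is hit or `nticks` elapse. The run is fully
#' reproducible: identical `(params, seed)` give bit-identical histories.
#'
#' @param params A [sim_params()] object (e.g. from [load_preset()]).
#' @param seed Integer seed for the single per-run random generator.
#' @return A `rib_result` list: `final_state` (`rib_state`), `history`
#'   (one row per tick: `tick, count, births, deaths, n_undecided,
#'   n_proximal, n_distal, max_x`), `params_used`, `seed`, `stop_reason`
#'   (`"boundary"` or `"max_ticks"`).
#' @examples
#' res <- run_simulation(load_preset("normal", nticks = 5), seed = 1)
#' res$history
#' @export
run_simulation <- function(params, seed) {
  validate_params(params)
  state <- initialize_field(params, seed)
  while (!state$stopped) {
    state <- step_simulation(state, params)
  }
  structure(list(final_state = state,
                 history = state$history,
                 params_used = params,
                 seed = as.integer(seed),
                 stop_reason = state$stop_reason),
            class = "rib_result")
}

#' @export
print.rib_result <- function(x, ...) {
  h <- x$history[nrow(x$history), ]
  cat(sprintf(paste0("<rib_result> stopped at tick %d (%s): %d cells, ",
                     "%d proximal / %d distal / %d undecided\n"),
              h$tick, x$stop_reason, h$count,
              h$n_proximal, h$n_distal, h$n_undecided))
  invisible(x)
}
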