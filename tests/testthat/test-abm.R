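test_that("Hh concentration is a Gaussian peaking at hh_peak_x", {
  p <- sim_params()
  expect_equal(hh_concentration(-10, p), 10^0.6, tolerance = 1e-3)
  expect_equal(hh_concentration(-10, sim_params(shh_intensity_log = -2)),
               0.01)
  # symmetry about the peak
  d <- c(0.5, 1, 3, 7, 15)
  expect_equal(hh_concentration(-10 + d, p), hh_concentration(-10 - d, p))
  # strictly decreasing away from the peak
  vals <- hh_concentration(seq(-10, 30, by = 1), p)
  expect_true(all(diff(vals) < 0))
})

test_that("death rate follows the early transient curve", {
  expect_identical(death_rate(0:40, sim_params(celldeathmult = 0)),
                   rep(0, 41))
  p1 <- sim_params(celldeathmult = 1)
  expect_equal(death_rate(0, p1), 0.05)
  expect_equal(death_rate(30, p1), 0.05 * exp(-2))
  # nonincreasing in time, scaled by the multiplier
  expect_true(all(diff(death_rate(0:46, p1)) <= 0))
  expect_equal(death_rate(7, sim_params(celldeathmult = 0.3)),
               0.3 * death_rate(7, p1))
})

test_that("fate probabilities saturate with Hh dose", {
  p <- sim_params()  # p_red1 = p_blue1 = 0.4, K = 1
  expect_equal(unname(fate_probabilities(0, p)), matrix(c(0, 0.4), 1))
  expect_equal(unname(fate_probabilities(1, p)), matrix(c(0.2, 0.2), 1))
  expect_equal(unname(fate_probabilities(1e9, p)),
               matrix(c(0.4, 0), 1), tolerance = 1e-8)
  cc <- seq(0, 50, by = 0.5)
  pr <- fate_probabilities(cc, p)
  expect_true(all(diff(pr[, "p_proximal"]) >= 0))
  expect_true(all(diff(pr[, "p_distal"]) <= 0))
  expect_true(all(rowSums(pr) <= 0.4 + 0.4 + 1e-12))
  expect_error(fate_probabilities(-1, p), "concentration")
})

test_that("initial field matches the square-block placement rule", {
  p <- sim_params()
  st <- initialize_field(p, seed = 11)
  expect_equal(nrow(st$agents), 1200)
  expect_true(all(st$agents$x >= 0 & st$agents$x <= 14))
  expect_true(all(abs(st$agents$y) <= 7))
  expect_true(all(st$agents$state == 1L))
  expect_identical(st$tick, 0L)
  expect_false(st$stopped)

  st2 <- initialize_field(sim_params(initsizemult = 0.57), seed = 11)
  expect_equal(nrow(st2$agents), 684)
  s <- sqrt(684 / 1200) * 14
  expect_equal(s, 10.568, tolerance = 1e-3)
  expect_true(all(st2$agents$x <= s) && all(abs(st2$agents$y) <= s / 2))

  # determinism of placement
  expect_identical(initialize_field(p, seed = 3)$agents,
                   initialize_field(p, seed = 3)$agents)
})

test_that("death phase removals match the binomial law", {
  p <- quick_params(celldeathmult = 1)  # rate 0.05 at tick 0
  st <- make_state(runif(1000, 0, 10), runif(1000, -5, 5),
                   rep("undecided", 1000), p)
  set.seed(99)
  deaths <- replicate(30, death_phase(st, p)$last_deaths)
  # each draw within 3 sd of Binomial(1000, 0.05)
  expect_true(all(abs(deaths - 50) <= 3 * sqrt(1000 * 0.05 * 0.95)))

  # null control: no multiplier, no deaths
  p0 <- quick_params(celldeathmult = 0)
  expect_identical(death_phase(st, p0)$agents, st$agents)

  # vacuous case: empty field stays empty
  empty <- st
  empty$agents <- st$agents[0, ]
  expect_equal(nrow(death_phase(empty, p)$agents), 0)
})

test_that("division phase divides, decides fates, and respects nulls", {
  p <- quick_params(proliferatemult = 0)
  st <- initialize_field(p, seed = 5)
  expect_identical(division_phase(st, p)$last_births, 0L)

  # DKO-like multiplier scales the division probability
  pd <- quick_params(initsizemult = 1, proliferatemult = 0.32)
  std <- initialize_field(pd, seed = 5)
  set.seed(21)
  births <- replicate(30, division_phase(std, pd)$last_births)
  expect_equal(mean(births) / 1200, 0.016, tolerance = 0.15)

  # zero conversion coefficients: everyone stays undecided
  pz <- quick_params(p_red1 = 0, p_blue1 = 0)
  stz <- initialize_field(pz, seed = 5)
  set.seed(1)
  for (i in 1:5) stz <- division_phase(stz, pz)
  expect_true(all(stz$agents$state == 1L))

  # daughters inherit a decided parent's fate and land within 0.5 patch
  pp <- quick_params(proliferatemult = 20)  # divide with probability 1
  stp <- make_state(rep(5, 40), seq(-4, 4, length.out = 40),
                    rep("proximal", 40), pp)
  set.seed(2)
  out <- division_phase(stp, pp)
  expect_identical(out$last_births, 40L)
  expect_true(all(out$agents$state == 2L))
  expect_true(all(abs(out$agents$x - 5) <= 0.5))
})

test_that("community effect flips supermajority-surrounded cells only", {
  p <- quick_params()
  # focal proximal cell ringed by 8 distal neighbors: flips
  ang <- seq(0, 2 * pi, length.out = 9)[-9]
  st <- make_state(c(0, cos(ang)), c(0, sin(ang)),
                   c("proximal", rep("distal", 8)), p)
  out <- community_phase(st, p)
  expect_identical(fate_labels(out)[1], "distal")

  # 5 proximal + 5 distal neighbors: no supermajority, no flip
  ang10 <- seq(0, 2 * pi, length.out = 11)[-11]
  st2 <- make_state(c(0, cos(ang10)), c(0, sin(ang10)),
                    c("proximal", rep(c("proximal", "distal"), 5)), p)
  expect_identical(fate_labels(community_phase(st2, p)),
                   fate_labels(st2))

  # uniform color is a fixed point
  st3 <- make_state(runif(50, 0, 5), runif(50, -2, 2),
                    rep("proximal", 50), p)
  expect_identical(community_phase(st3, p)$agents, st3$agents)

  # undecided cells are not converted
  st4 <- make_state(c(0, cos(ang)), c(0, sin(ang)),
                    c("undecided", rep("distal", 8)), p)
  expect_identical(fate_labels(community_phase(st4, p))[1], "undecided")

  # threshold above 1 disables the rule
  poff <- quick_params(community_threshold = 1.01)
  expect_identical(community_phase(st, poff)$agents, st$agents)
})

test_that("redistribution spreads crowds and respects bounds", {
  p <- quick_params()
  # a lone agent never moves
  st1 <- make_state(3, 0, "undecided", p)
  expect_identical(redistribution_phase(st1, p)$agents, st1$agents)

  # a stack of 30 agents on one spot decompresses
  st2 <- make_state(rep(1, 30) + runif(30, -0.01, 0.01),
                    rep(0, 30) + runif(30, -0.01, 0.01),
                    rep("undecided", 30), p)
  before <- max(local_density(st2))
  set.seed(4)
  out <- redistribution_phase(st2, p)
  expect_lt(max(local_density(out)), before)

  # crowding at the boundary cannot push agents through it
  st3 <- make_state(rep(p$world_x_max, 25) - runif(25, 0, 0.01),
                    runif(25, -0.05, 0.05), rep("undecided", 25), p)
  set.seed(5)
  out3 <- redistribution_phase(st3, p)
  expect_true(all(out3$agents$x <= p$world_x_max))
  expect_true(all(out3$agents$y >= p$world_y_min &
                    out3$agents$y <= p$world_y_max))
})

test_that("step applies the phase order and the stop rules", {
  p <- quick_params()
  st <- initialize_field(p, seed = 9)
  out <- step_simulation(st, p)
  expect_identical(out$tick, 1L)
  h <- out$history
  expect_equal(h$count[2], h$count[1] + h$births[2] - h$deaths[2])

  # an agent at the farthest patch column stops the clock
  stb <- make_state(c(p$world_x_max - 0.5, 1), c(0, 0),
                    c("undecided", "undecided"), p)
  outb <- step_simulation(stb, p)
  expect_true(outb$stopped)
  expect_identical(outb$stop_reason, "boundary")
  expect_error(step_simulation(outb, p), "stopped")

  # the clock also stops at nticks
  pq <- quick_params(nticks = 2)
  r <- run_simulation(pq, seed = 1)
  expect_identical(r$stop_reason, "max_ticks")
  expect_identical(r$final_state$tick, 2L)
})

test_that("runs conserve counts, stay in bounds, and never un-decide", {
  p <- quick_params(nticks = 12, celldeathmult = 1)
  st <- initialize_field(p, seed = 31)
  seen <- list()
  while (!st$stopped) {
    prev <- st$agents
    st <- step_simulation(st, p)
    # containment every tick
    expect_true(all(st$agents$x >= p$world_x_min &
                      st$agents$x <= p$world_x_max))
    expect_true(all(st$agents$y >= p$world_y_min &
                      st$agents$y <= p$world_y_max))
    # irreversibility: an id decided before never returns to undecided
    common <- intersect(prev$id, st$agents$id)
    was <- prev$state[match(common, prev$id)]
    now <- st$agents$state[match(common, st$agents$id)]
    expect_false(any(was != 1L & now == 1L))
  }
  h <- st$history
  expect_equal(h$count[-1], head(h$count, -1) + h$births[-1] - h$deaths[-1])
  expect_equal(h$n_undecided + h$n_proximal + h$n_distal, h$count)

  # null controls over a whole run
  r0 <- run_simulation(quick_params(celldeathmult = 0, nticks = 8), seed = 2)
  expect_identical(sum(r0$history$deaths), 0L)
  rb <- run_simulation(quick_params(proliferatemult = 0, nticks = 8), seed = 2)
  expect_identical(sum(rb$history$births), 0L)
})

test_that("identical parameters and seed give bit-identical runs", {
  p <- quick_params(nticks = 8, celldeathmult = 0.5)
  r1 <- run_simulation(p, seed = 77)
  r2 <- run_simulation(p, seed = 77)
  expect_identical(r1$history, r2$history)
  expect_identical(r1$final_state$agents, r2$final_state$agents)
  r3 <- run_simulation(p, seed = 78)
  expect_false(identical(r1$history, r3$history))
})
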