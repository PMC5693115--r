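# small, fast simulator configuration for unit tests: ~120-cell pool on a
# compact field, short clock
quick_params <- function(...) {
  defaults <- list(initsizemult = 0.1, nticks = 10L,
                   world_x_min = -10, world_x_max = 20,
                   world_y_min = -10, world_y_max = 10)
  args <- list(...)
  defaults[names(args)] <- args
  do.call(sim_params, defaults)
}

# build a rib_state directly from agent coordinates and fate labels
make_state <- function(x, y, state, params = quick_params(), tick = 0L) {
  st <- initialize_field(params, seed = 1)
  code <- match(state, c("undecided", "proximal", "distal"))
  stopifnot(!anyNA(code))
  st$agents <- data.frame(id = seq_along(x), x = x, y = y, state = code)
  st$next_id <- length(x) + 1L
  st$tick <- tick
  st
}

fate_labels <- function(state) {
  c("undecided", "proximal", "distal")[state$agents$state]
}

# tiny measurement table with two litters; embryo means chosen by hand
toy_measurements <- function() {
  data.frame(
    litter_id = rep(c("A", "B"), each = 4),
    embryo_id = rep(c("A1", "A2", "B1", "B2"), each = 2),
    genotype = rep(c("normal", "shh_ko", "normal", "apaf1_ko"), each = 2),
    somite_index = rep(1:2, 4),
    size_pixels = c(90, 110, 50, 68, 100, 100, 100, 100),
    phh3_count = c(10, 10, 5, 5, 8, 12, 10, 10),
    nuclei_count = rep(100, 8)
  )
}
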