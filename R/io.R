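#' Write and read simulation parameter files
#'
#' Parameters round-trip through a human-readable key-value (YAML) file
#' using the simulator's variable names. Unknown keys are rejected loudly
#' on read.
#'
#' @param params A [sim_params()] object.
#' @param file Path to the parameter file.
#' @return `write_params` returns `file` invisibly; `read_params` returns
#'   a validated `rib_params`.
#' @export
write_params <- function(params, file) {
  validate_params(params)
  yaml::write_yaml(unclass(params), file)
  invisible(file)
}

#' @rdname write_params
#' @export
read_params <- function(file) {
  vals <- yaml::read_yaml(file)
  if (!is.list(vals) || is.null(names(vals))) {
    stop("parameter file must hold named key-value pairs")
  }
  modify_params(sim_params(), vals)
}

#' Write an agent snapshot as delimited text
#'
#' One row per agent with header `tick,id,x,y,state`; states are written
#' as labels (`undecided`, `proximal`, `distal`).
#'
#' @param state A `rib_state` or `rib_result`.
#' @param file Output CSV path.
#' @return `file`, invisibly.
#' @export
write_agent_snapshot <- function(state, file) {
  if (inherits(state, "rib_result")) state <- state$final_state
  stopifnot(inherits(state, "rib_state"))
  a <- state$agents
  out <- data.frame(tick = state$tick, id = a$id, x = a$x, y = a$y,
                    state = FATE_LEVELS[a$state])
  write.csv(out, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Read an agent snapshot written by [write_agent_snapshot()]
#'
#' @param file Snapshot CSV path.
#' @return A `rib_state` usable with the pattern summaries.
#' @export
read_agent_snapshot <- function(file) {
  d <- read.csv(file, stringsAsFactors = FALSE)
  req <- c("tick", "id", "x", "y", "state")
  if (!all(req %in% names(d))) {
    stop("snapshot must have columns: ", paste(req, collapse = ", "))
  }
  code <- match(d$state, FATE_LEVELS)
  if (anyNA(code)) stop("unknown agent state in snapshot")
  agents <- data.frame(id = d$id, x = d$x, y = d$y, state = code)
  new_state(agents, tick = if (nrow(d) > 0) d$tick[1] else 0L,
            stopped = TRUE, next_id = max(c(0L, d$id)) + 1L,
            history = history_row(if (nrow(d) > 0) d$tick[1] else 0L,
                                  agents, 0L, 0L))
}

#' Write the per-tick history of a run
#'
#' Delimited text with header
#' `tick,count,births,deaths,n_undecided,n_proximal,n_distal,max_x`.
#'
#' @param result A `rib_result`.
#' @param file Output CSV path.
#' @return `file`, invisibly.
#' @export
write_history <- function(result, file) {
  stopifnot(inherits(result, "rib_result"))
  write.csv(result$history, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Build a reproducibility manifest for a completed run
#'
#' Records everything needed to reproduce and audit a run: the full
#' parameter set, the seed, the stop reason, the package version, and MD5
#' hashes of any output files. Manifests round-trip losslessly through
#' [write_manifest()] / [read_manifest()].
#'
#' @param result A `rib_result`.
#' @param files Character vector of output files to hash (optional).
#' @return A `rib_manifest` list.
#' @export
run_manifest <- function(result, files = character(0)) {
  stopifnot(inherits(result, "rib_result"))
  hashes <- if (length(files) > 0) {
    h <- tools::md5sum(files)
    as.list(stats::setNames(unname(h), basename(files)))
  } else {
    list()
  }
  structure(list(
    params = result$params_used,
    seed = result$seed,
    stop_reason = result$stop_reason,
    final_tick = result$final_state$tick,
    final_count = nrow(result$final_state$agents),
    version = as.character(packageVersion("ribsim")),
    file_hashes = hashes
  ), class = "rib_manifest")
}

#' @rdname run_manifest
#' @param manifest A `rib_manifest`.
#' @param file Manifest file path (YAML).
#' @export
write_manifest <- function(manifest, file) {
  stopifnot(inherits(manifest, "rib_manifest"))
  out <- unclass(manifest)
  out$params <- unclass(out$params)
  yaml::write_yaml(out, file)
  invisible(file)
}

#' @rdname run_manifest
#' @export
read_manifest <- function(file) {
  m <- yaml::read_yaml(file)
  m$params <- modify_params(sim_params(), m$params)
  class(m) <- "rib_manifest"
  m
}
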