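#' Genotype presets for the rib-patterning simulator
#'
#' The four calibrated parameter columns used for the genotype simulations.
#' Initial size and proliferation multipliers are the posterior medians of
#' the hierarchical measurement model ([fit_measurement_model()]); Hh
#' intensity, death and timing dials encode the genetics: Shh-null
#' conditions collapse the Hh peak (log10 intensity -2), Apaf1-null
#' conditions switch apoptosis off (`celldeathmult = 0`).
#'
#' @return A named list of four `rib_params` objects:
#'   `normal`, `apaf1_ko`, `shh_ko`, `shh_apaf1_dko`.
#' @seealso [load_preset()]
#' @export
genotype_presets <- function() {
  list(
    normal = sim_params(
      initsizemult = 1, shh_xport = 12, shh_intensity_log = 0.6,
      nticks = 46L, p_red1 = 0.4, p_blue1 = 0.4,
      celldeathmult = 0.3, proliferatemult = 1, cdduration = 30L
    ),
    apaf1_ko = sim_params(
      initsizemult = 0.92, shh_xport = 12, shh_intensity_log = 0.6,
      nticks = 46L, p_red1 = 0.4, p_blue1 = 0.4,
      celldeathmult = 0, proliferatemult = 0.71, cdduration = 30L
    ),
    shh_ko = sim_params(
      initsizemult = 0.59, shh_xport = 12, shh_intensity_log = -2,
      nticks = 46L, p_red1 = 0.4, p_blue1 = 0.4,
      celldeathmult = 1, proliferatemult = 1.1, cdduration = 30L
    ),
    shh_apaf1_dko = sim_params(
      initsizemult = 0.57, shh_xport = 12, shh_intensity_log = -2,
      nticks = 46L, p_red1 = 0.4, p_blue1 = 0.4,
      celldeathmult = 0, proliferatemult = 0.32, cdduration = 30L
    )
  )
}

#' Load a genotype preset, optionally overriding parameters
#'
#' @param name One of `"normal"`, `"apaf1_ko"`, `"shh_ko"`,
#'   `"shh_apaf1_dko"`.
#' @param ... Named parameter overrides applied after the preset (any field
#'   of [sim_params()]).
#' @return A `rib_params` object.
#' @examples
#' p <- load_preset("shh_ko")
#' p$shh_intensity_log
#' load_preset("normal", nticks = 10)$nticks
#' @export
load_preset <- function(name, ...) {
  presets <- genotype_presets()
  if (length(name) != 1 || !is.character(name) || !name %in% names(presets)) {
    stop("unknown preset '", paste(name, collapse = ","),
         "'; valid presets: ", paste(names(presets), collapse = ", "))
  }
  modify_params(presets[[name]], list(...))
}
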