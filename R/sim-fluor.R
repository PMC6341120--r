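#' Simulate two-channel chamber fluorescence
#'
#' Chambers holding a stained cell read `signal + N(0, noise)` in each
#' stained channel and `background + N(0, noise)` in the other; empty
#' chambers read background in both. Intensities are truncated at zero.
#'
#' @param config a [sim_config()] object.
#' @param cells chamber table from [simulate_cells()] (carries the true
#'   color code and curation status).
#' @return data.frame with columns `run`, `chamber`, `cell_id`, `green`,
#'   `red`, `curation`.
#' @export
simulate_fluorescence <- function(config, cells) {
  validate_config(config)
  set.seed(stage_seed(config$seed, "fluorescence"))
  n <- nrow(cells)
  stained <- cells$curation != "empty"
  g_on <- stained & cells$code %in% c("G", "GR")
  r_on <- stained & cells$code %in% c("R", "GR")
  green <- ifelse(g_on, config$fluor_signal_mean,
                  config$fluor_background_mean) +
    stats::rnorm(n, 0, config$fluor_noise_sd)
  red <- ifelse(r_on, config$fluor_signal_mean,
                config$fluor_background_mean) +
    stats::rnorm(n, 0, config$fluor_noise_sd)
  data.frame(
    run = cells$run, chamber = cells$chamber, cell_id = cells$cell_id,
    green = pmax(green, 0), red = pmax(red, 0),
    curation = cells$curation, stringsAsFactors = FALSE
  )
}
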