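FLUOR_CODES <- c("G", "R", "GR")

#' Permuted two-color staining design
#'
#' Assigns each (run, timepoint) pair a Calcein color code in
#' `{G, R, GR}`. Within a run the code-to-timepoint mapping is a bijection;
#' across runs the mapping is rotated Latin-square style (run r uses the
#' base order shifted by r - 1), so no two consecutive runs share a
#' mapping, stain color is never collinear with timepoint, and a run-level
#' batch effect remains separable from biology.
#'
#' @param config a [sim_config()] object.
#' @return data.frame with columns `run`, `code`, `timepoint`.
#' @export
make_color_design <- function(config) {
  validate_config(config)
  set.seed(stage_seed(config$seed, "color_design"))
  ntp <- length(config$timepoints)
  codes <- sample(FLUOR_CODES[seq_len(ntp)])
  do.call(rbind, lapply(seq_len(config$n_runs), function(r) {
    shift <- (r - 1L) %% ntp
    data.frame(run = sprintf("run%d", r),
               code = codes[((seq_len(ntp) - 1L + shift) %% ntp) + 1L],
               timepoint = config$timepoints,
               stringsAsFactors = FALSE)
  }))
}

#' Simulate the chamber/cell layout of an experiment
#'
#' One record per capture chamber: its run, true timepoint, true color code
#' (via the staining design) and curation status. A configurable fraction of
#' chambers is empty or holds a doublet.
#'
#' @param config a [sim_config()] object.
#' @param design staining design from [make_color_design()].
#' @return data.frame with columns `cell_id`, `run`, `chamber`, `timepoint`,
#'   `code`, `curation` (`single`/`empty`/`doublet`).
#' @export
simulate_cells <- function(config, design = make_color_design(config)) {
  validate_config(config)
  set.seed(stage_seed(config$seed, "cells"))
  grid <- expand.grid(
    tp = config$timepoints,
    run = sprintf("run%d", seq_len(config$n_runs)),
    idx = seq_len(config$cells_per_run_per_timepoint),
    stringsAsFactors = FALSE
  )
  grid <- grid[order(grid$run, grid$tp, grid$idx), , drop = FALSE]
  n <- nrow(grid)
  key <- paste(design$run, design$timepoint)
  code <- design$code[match(paste(grid$run, grid$tp), key)]
  if (anyNA(code))
    stop("staining design is missing a (run, timepoint) combination",
         call. = FALSE)
  u <- stats::runif(n)
  curation <- ifelse(u < config$empty_rate, "empty",
                     ifelse(u < config$empty_rate + config$doublet_rate,
                            "doublet", "single"))
  cells <- data.frame(
    cell_id = sprintf("%s_c%03d", grid$run,
                      stats::ave(seq_len(n), grid$run, FUN = seq_along)),
    run = grid$run,
    chamber = sprintf("ch%03d",
                      stats::ave(seq_len(n), grid$run, FUN = seq_along)),
    timepoint = grid$tp,
    code = code,
    curation = curation,
    stringsAsFactors = FALSE
  )
  rownames(cells) <- NULL
  cells
}
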