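#' Simulate a complete synthetic single-cell CAGE experiment
#'
#' Runs every generator stage under seeds derived from the master seed:
#' toy genome and annotation, spike design and references, staining design,
#' chamber layout, true molecules, tag pairs (with planted artifacts) and
#' fluorescence. The returned object carries the full ground truth, so
#' every downstream processing stage can be benchmarked against it.
#'
#' @param config a [sim_config()] object.
#' @return An object of class `sccage_sim`: a list with `config`, `genome`,
#'   `regions`, `invasion_sites`, `spike_design`, `spike_refs`,
#'   `color_design`, `truth` (list of `cells`, `molecules`, `spikes`),
#'   `tags` and `chambers`.
#' @examples
#' sim <- simulate_experiment(sim_config(
#'   seed = 7, cells_per_run_per_timepoint = 2, n_promoters = 10,
#'   n_enhancers = 4, n_mito = 2, n_mask = 2, chrom_count = 1,
#'   chrom_length = 60000, spike_dilution = 0.05))
#' nrow(sim$truth$cells)
#' @export
simulate_experiment <- function(config = sim_config()) {
  validate_config(config)
  ga <- make_toy_genome_annotation(config)
  spike_design <- make_spike_design(config)
  spike_refs <- make_spike_references(config, spike_design)
  color_design <- make_color_design(config)
  cells <- simulate_cells(config, color_design)
  molecules <- simulate_feature_molecules(config, cells, ga$regions)
  spikes <- simulate_spike_molecules(config, cells, spike_design)
  truth <- list(cells = cells, molecules = molecules, spikes = spikes)
  tags <- emit_tag_pairs(truth, ga$genome, config,
                         invasion_sites = ga$invasion_sites)
  chambers <- simulate_fluorescence(config, cells)
  out <- list(
    config = config,
    genome = ga$genome,
    regions = ga$regions,
    invasion_sites = ga$invasion_sites,
    spike_design = spike_design,
    spike_refs = spike_refs,
    color_design = color_design,
    truth = truth,
    tags = tags,
    chambers = chambers
  )
  class(out) <- "sccage_sim"
  out
}

#' @export
print.sccage_sim <- function(x, ...) {
  cat("Synthetic single-cell CAGE experiment\n")
  cat(sprintf("  %d chambers (%d runs x %d timepoints), %d annotated regions\n",
              nrow(x$truth$cells), x$config$n_runs,
              length(x$config$timepoints), nrow(x$regions)))
  cat(sprintf("  %d tag pairs (%d flagged artifacts), %d spike species\n",
              nrow(x$tags), sum(x$tags$artifact), nrow(x$spike_design)))
  invisible(x)
}
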