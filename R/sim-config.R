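#' Configuration for a synthetic single-cell CAGE experiment
#'
#' Bundles every tunable parameter of the synthetic-data generator. The
#' defaults describe a three-replicate, three-timepoint microfluidic run with
#' 30 chambers per run and timepoint, 500 endogenous features, bursty
#' expression, two-allele strand-exclusive enhancer transcription, ERCC-style
#' spike-ins captured binomially, a sharp first-base mode for 5' ends,
#' planted strand-invasion artifacts, run-level batch shifts and a permuted
#' two-color fluorescence design.
#'
#' @param seed integer master seed; every stochastic stage derives its own
#'   seed from it (see [stage_seed()]).
#' @param n_runs number of runs (replicates / microfluidic chips).
#' @param timepoints character vector of timepoint labels. With two-color
#'   staining the design supports up to three codes (`G`, `R`, `GR`), so at
#'   most three timepoints per run.
#' @param cells_per_run_per_timepoint chambers loaded per run and timepoint.
#' @param n_promoters,n_enhancers,n_mito,n_mask numbers of annotated regions
#'   of each class on the toy genome.
#' @param chrom_count,chrom_length toy genome shape (bases).
#' @param burst_prob probability that a feature (per allele, for enhancers)
#'   fires a transcriptional burst in a given cell. Scalar, or a matrix with
#'   one row per feature and one column per timepoint.
#' @param burst_size_mean mean molecules per burst (negative binomial mean).
#' @param burst_size_dispersion negative binomial dispersion (variance =
#'   mu + dispersion * mu^2).
#' @param timepoint_effect_sd standard deviation of per-feature,
#'   per-timepoint log-odds shifts applied to `burst_prob`, giving features a
#'   reproducible biological timepoint signal. Set to 0 for a null design.
#' @param allele_count alleles per enhancer locus; each allele independently
#'   commits all its molecules to one strand.
#' @param enhancer_strand_prob probability that an allele picks the plus
#'   strand.
#' @param capture_prob probability that a transcribed molecule is captured
#'   and emits a tag pair.
#' @param first_base_prob probability that a tag's 5' end falls exactly on
#'   the feature's first base; otherwise it is shifted downstream by a
#'   geometric offset.
#' @param offset_mean mean of the geometric downstream offset (bases) for
#'   non-first-base tags.
#' @param invasion_rate probability that a captured molecule is emitted as a
#'   strand-invasion artifact at a planted GGG-context site instead of at its
#'   feature.
#' @param invasion_sites_per_chrom number of artifact sites planted per
#'   chromosome (half per strand).
#' @param invasion_exact if `TRUE` (default) planted sites carry an exact
#'   GGG upstream context; if `FALSE` one base is mismatched, for testing
#'   mismatch-tolerant filtering.
#' @param run_batch_shift numeric vector (recycled to `n_runs`) of per-run
#'   additive log2-scale shifts applied to burst sizes; emulates a strong
#'   run-level batch effect.
#' @param empty_rate,doublet_rate fraction of chambers that are empty or
#'   contain two cells.
#' @param fluor_signal_mean,fluor_background_mean,fluor_noise_sd fluorescence
#'   model (arbitrary units): stained channels read
#'   `signal + N(0, noise)`, unstained ones `background + N(0, noise)`.
#' @param spike_dilution factor converting spike-in design concentrations to
#'   molecules per chamber (molecules = round(concentration * dilution)).
#' @param spike_mix which spike mix is loaded into the chambers
#'   (`"mix1"` or `"mix2"`).
#' @param spike_length length of each synthetic spike reference sequence.
#'
#' @return An object of class `sccage_config` (a validated list).
#' @examples
#' cfg <- sim_config(seed = 1, cells_per_run_per_timepoint = 5,
#'                   n_promoters = 10, n_enhancers = 4)
#' cfg$n_runs
#' @export
sim_config <- function(seed = 1L,
                       n_runs = 3L,
                       timepoints = c("0h", "6h", "24h"),
                       cells_per_run_per_timepoint = 30L,
                       n_promoters = 350L,
                       n_enhancers = 100L,
                       n_mito = 10L,
                       n_mask = 40L,
                       chrom_count = 4L,
                       chrom_length = 200000L,
                       burst_prob = 0.3,
                       burst_size_mean = 20,
                       burst_size_dispersion = 0.5,
                       timepoint_effect_sd = 0.5,
                       allele_count = 2L,
                       enhancer_strand_prob = 0.5,
                       capture_prob = 0.5,
                       first_base_prob = 0.8,
                       offset_mean = 10,
                       invasion_rate = 0.1,
                       invasion_sites_per_chrom = 30L,
                       invasion_exact = TRUE,
                       run_batch_shift = c(0, 0.75, -0.75),
                       empty_rate = 0.04,
                       doublet_rate = 0.03,
                       fluor_signal_mean = 1000,
                       fluor_background_mean = 100,
                       fluor_noise_sd = 50,
                       spike_dilution = 1,
                       spike_mix = c("mix1", "mix2"),
                       spike_length = 1000L) {
  spike_mix <- match.arg(spike_mix)
  cfg <- list(
    seed = as.integer(seed),
    n_runs = as.integer(n_runs),
    timepoints = as.character(timepoints),
    cells_per_run_per_timepoint = as.integer(cells_per_run_per_timepoint),
    n_promoters = as.integer(n_promoters),
    n_enhancers = as.integer(n_enhancers),
    n_mito = as.integer(n_mito),
    n_mask = as.integer(n_mask),
    chrom_count = as.integer(chrom_count),
    chrom_length = as.integer(chrom_length),
    burst_prob = burst_prob,
    burst_size_mean = burst_size_mean,
    burst_size_dispersion = burst_size_dispersion,
    timepoint_effect_sd = timepoint_effect_sd,
    allele_count = as.integer(allele_count),
    enhancer_strand_prob = enhancer_strand_prob,
    capture_prob = capture_prob,
    first_base_prob = first_base_prob,
    offset_mean = offset_mean,
    invasion_rate = invasion_rate,
    invasion_sites_per_chrom = as.integer(invasion_sites_per_chrom),
    invasion_exact = isTRUE(invasion_exact),
    run_batch_shift = rep_len(run_batch_shift, as.integer(n_runs)),
    empty_rate = empty_rate,
    doublet_rate = doublet_rate,
    fluor_signal_mean = fluor_signal_mean,
    fluor_background_mean = fluor_background_mean,
    fluor_noise_sd = fluor_noise_sd,
    spike_dilution = spike_dilution,
    spike_mix = spike_mix,
    spike_length = as.integer(spike_length)
  )
  class(cfg) <- "sccage_config"
  validate_config(cfg)
  cfg
}

#' @keywords internal
validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "sccage_config"))
  chk_prob <- function(x, nm, allow_zero = TRUE, allow_one = TRUE) {
    lo <- if (allow_zero) 0 else .Machine$double.eps
    if (any(!is.finite(x)) || any(x < lo) || any(x > 1) ||
        (!allow_one && any(x == 1)))
      stop(sprintf("'%s' must be a probability in the stated range", nm),
           call. = FALSE)
  }
  if (cfg$n_runs < 1L || cfg$cells_per_run_per_timepoint < 1L)
    stop("n_runs and cells_per_run_per_timepoint must be positive",
         call. = FALSE)
  if (length(cfg$timepoints) < 1L || length(cfg$timepoints) > 3L ||
      anyDuplicated(cfg$timepoints))
    stop("timepoints must be 1-3 distinct labels (two-color design)",
         call. = FALSE)
  chk_prob(cfg$burst_prob, "burst_prob")
  chk_prob(cfg$enhancer_strand_prob, "enhancer_strand_prob")
  chk_prob(cfg$first_base_prob, "first_base_prob")
  if (cfg$capture_prob < 0 || cfg$capture_prob > 1)
    stop("capture_prob must lie in [0, 1]", call. = FALSE)
  if (cfg$invasion_rate < 0 || cfg$invasion_rate >= 1)
    stop("invasion_rate must lie in [0, 1)", call. = FALSE)
  chk_prob(cfg$empty_rate, "empty_rate")
  chk_prob(cfg$doublet_rate, "doublet_rate")
  if (cfg$burst_size_mean <= 0) stop("burst_size_mean must be > 0",
                                     call. = FALSE)
  if (cfg$burst_size_dispersion < 0)
    stop("burst_size_dispersion must be >= 0", call. = FALSE)
  if (cfg$allele_count < 1L) stop("allele_count must be >= 1", call. = FALSE)
  if (cfg$spike_dilution <= 0) stop("spike_dilution must be > 0",
                                    call. = FALSE)
  invisible(cfg)
}

#' @export
print.sccage_config <- function(x, ...) {
  n_cells <- x$n_runs * length(x$timepoints) * x$cells_per_run_per_timepoint
  cat("Synthetic single-cell CAGE experiment configuration\n")
  cat(sprintf("  %d runs x %d timepoints x %d chambers = %d chambers\n",
              x$n_runs, length(x$timepoints),
              x$cells_per_run_per_timepoint, n_cells))
  cat(sprintf("  features: %d promoters, %d enhancers, %d mito, %d mask\n",
              x$n_promoters, x$n_enhancers, x$n_mito, x$n_mask))
  cat(sprintf("  capture p = %g, first-base q = %g, invasion rate = %g\n",
              x$capture_prob, x$first_base_prob, x$invasion_rate))
  invisible(x)
}
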