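#' Simulate true molecule counts per cell, feature and strand
#'
#' Expression follows a two-stage bursting model: in a given cell a feature
#' fires with probability `burst_prob` (a Bernoulli burst gate, modulated
#' per feature and timepoint); if it fires, the molecule count is negative
#' binomial with mean `burst_size_mean` (shifted on the log2 scale by the
#' run's batch effect) and dispersion `burst_size_dispersion`. Promoter and
#' mitochondrial features transcribe on their annotated strand. Each
#' enhancer locus carries `allele_count` alleles; every allele gates and
#' bursts independently and commits all of its molecules to a single strand
#' chosen with probability `enhancer_strand_prob` for plus — transcription
#' is strand-exclusive per allele. Doublet chambers sum two independent
#' cells; empty chambers get nothing.
#'
#' @param config a [sim_config()] object.
#' @param cells chamber table from [simulate_cells()].
#' @param regions annotation from [make_toy_genome_annotation()].
#' @return data.frame with one row per (cell, feature-strand) with positive
#'   molecules: columns `cell_id`, `feature` (enhancers as `id:+` / `id:-`),
#'   `id`, `class`, `chrom`, `strand`, `tss`, `molecules`.
#' @export
simulate_feature_molecules <- function(config, cells, regions) {
  validate_config(config)
  set.seed(stage_seed(config$seed, "molecules"))

  tss <- feature_tss_table(regions)
  ids <- unique(tss$id)
  ntp <- length(config$timepoints)

  # per-feature, per-timepoint burst probability (logit-normal modulation)
  if (is.matrix(config$burst_prob)) {
    pi_mat <- config$burst_prob
    if (nrow(pi_mat) != length(ids) || ncol(pi_mat) != ntp)
      stop("burst_prob matrix must be features x timepoints", call. = FALSE)
  } else {
    base <- stats::qlogis(min(max(config$burst_prob, 1e-6), 1 - 1e-6))
    pi_mat <- matrix(
      stats::plogis(base + stats::rnorm(length(ids) * ntp, 0,
                                        config$timepoint_effect_sd)),
      nrow = length(ids), ncol = ntp
    )
    if (config$burst_prob == 0) pi_mat[] <- 0
    if (config$burst_prob == 1) pi_mat[] <- 1
  }
  rownames(pi_mat) <- ids
  colnames(pi_mat) <- config$timepoints

  tp_idx <- match(cells$timepoint, config$timepoints)
  run_idx <- as.integer(sub("^run", "", cells$run))
  mu_cell <- config$burst_size_mean * 2^config$run_batch_shift[run_idx]
  copies <- ifelse(cells$curation == "empty", 0L,
                   ifelse(cells$curation == "doublet", 2L, 1L))
  nc <- nrow(cells)

  draw_block <- function(feat_ids, active) {
    # gate x NB molecules for features x active cells; returns count matrix
    nf <- length(feat_ids)
    na <- sum(active)
    if (nf == 0L || na == 0L)
      return(matrix(0L, nf, nc, dimnames = list(feat_ids, cells$cell_id)))
    p <- pi_mat[feat_ids, tp_idx[active], drop = FALSE]
    gate <- stats::rbinom(nf * na, 1L, as.vector(p))
    mu <- rep(mu_cell[active], each = nf)
    mol <- if (config$burst_size_dispersion > 0) {
      stats::rnbinom(nf * na, size = 1 / config$burst_size_dispersion,
                     mu = mu)
    } else {
      stats::rpois(nf * na, mu)
    }
    out <- matrix(0L, nf, nc, dimnames = list(feat_ids, cells$cell_id))
    out[, active] <- matrix(as.integer(gate * mol), nf, na)
    out
  }

  pm_ids <- tss$id[tss$class %in% c("promoter", "mito") &
                     !duplicated(tss$id)]
  pm_ids <- intersect(ids, pm_ids)
  enh_ids <- unique(tss$id[tss$class == "enhancer"])

  pm_counts <- matrix(0L, length(pm_ids), nc,
                      dimnames = list(pm_ids, cells$cell_id))
  enh_plus <- matrix(0L, length(enh_ids), nc,
                     dimnames = list(enh_ids, cells$cell_id))
  enh_minus <- enh_plus

  for (cp in 1:2) {
    active <- copies >= cp
    if (!any(active)) next
    pm_counts <- pm_counts + draw_block(pm_ids, active)
    for (a in seq_len(config$allele_count)) {
      mol <- draw_block(enh_ids, active)
      to_plus <- matrix(stats::rbinom(length(enh_ids) * nc, 1L,
                                      config$enhancer_strand_prob),
                        length(enh_ids), nc)
      enh_plus <- enh_plus + mol * to_plus
      enh_minus <- enh_minus + mol * (1L - to_plus)
    }
  }

  melt_counts <- function(m, feature_suffix = NULL) {
    pos <- which(m > 0L, arr.ind = TRUE)
    if (nrow(pos) == 0L) return(NULL)
    feat <- rownames(m)[pos[, 1]]
    if (!is.null(feature_suffix)) feat <- paste0(feat, ":", feature_suffix)
    data.frame(cell_id = colnames(m)[pos[, 2]], feature = feat,
               molecules = as.integer(m[pos]), stringsAsFactors = FALSE)
  }
  long <- rbind(
    melt_counts(pm_counts),
    melt_counts(enh_plus, "+"),
    melt_counts(enh_minus, "-")
  )
  if (is.null(long)) {
    long <- data.frame(cell_id = character(), feature = character(),
                       molecules = integer(), stringsAsFactors = FALSE)
  }
  j <- match(long$feature, tss$feature)
  out <- data.frame(
    cell_id = long$cell_id, feature = long$feature,
    id = tss$id[j], class = tss$class[j], chrom = tss$chrom[j],
    strand = tss$strand[j], tss = tss$tss[j],
    molecules = long$molecules, stringsAsFactors = FALSE
  )
  out <- out[order(out$cell_id, out$feature), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Spike-in molecules per chamber
#'
#' Every chamber — including empty ones, since the spike mix is part of the
#' reagents — receives the designed number of molecules of each species for
#' the loaded mix.
#'
#' @param config a [sim_config()] object.
#' @param cells chamber table from [simulate_cells()].
#' @param design spike design from [make_spike_design()].
#' @return data.frame with columns `cell_id`, `feature` (species id),
#'   `molecules`.
#' @export
simulate_spike_molecules <- function(config, cells, design) {
  mol_col <- paste0("molecules_", config$spike_mix)
  out <- expand.grid(feature = design$id, cell_id = cells$cell_id,
                     stringsAsFactors = FALSE)[, c(2, 1)]
  out$molecules <- design[[mol_col]][match(out$feature, design$id)]
  out[out$molecules > 0L, , drop = FALSE]
}
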