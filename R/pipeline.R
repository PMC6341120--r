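#' Annotation rows for spike-in references
#'
#' One region per species covering its whole reference, class `spike`,
#' plus strand, so spike tags are counted by the same 5'-end rule as
#' genomic features.
#'
#' @param design spike design from [make_spike_design()].
#' @param spike_length reference length (bases).
#' @return annotation data.frame rows.
#' @export
spike_region_table <- function(design, spike_length) {
  data.frame(id = design$id, chrom = design$id, start = 0L,
             end = as.integer(spike_length), strand = "+",
             class = "spike", stringsAsFactors = FALSE)
}

#' Run the full synthetic-experiment pipeline
#'
#' Executes, in order: simulation, tag processing (deduplication,
#' strand-invader filtering, masking, strand-resolved counting), timepoint
#' demultiplexing, cell QC and feature filtering, normalization with batch
#' detrending, spike-in performance metrics, and the enhancer
#' bidirectionality / Gini analysis. Every stage draws its seed from the
#' master seed in the configuration, so a rerun with the same configuration
#' reproduces every table.
#'
#' @param config a [sim_config()] object.
#' @param outdir optional directory; when given, all interchange tables
#'   plus a JSON run manifest are written there.
#' @return list of class `sccage_run` with elements `sim`, `processed`
#'   (counts/tally), `demux`, `qc` (metrics with pass flags), `filtered`
#'   (feature-filtered endogenous counts), `norm` (batch-corrected
#'   normalized matrix), `hvf` (high-variance features), `spike`
#'   (accuracy, detection, first-base, fold change), `enhancer` (locus
#'   table, per-cell scores, downsampling references, Gini/KS, strata,
#'   expression summary) and `manifest`.
#' @export
run_pipeline <- function(config = sim_config(), outdir = NULL) {
  validate_config(config)
  warnings_log <- character(0)
  note <- function(...) {
    warnings_log <<- c(warnings_log, sprintf(...))
  }

  ## 1. simulate
  sim <- simulate_experiment(config)
  regions_all <- rbind(sim$regions,
                       spike_region_table(sim$spike_design,
                                          config$spike_length))

  ## 2. tag processing
  proc <- count_tags(sim$tags, c(sim$genome, sim$spike_refs), regions_all,
                     cells = sim$truth$cells$cell_id)

  ## 3. demultiplex timepoints
  demux <- assign_timepoints(sim$chambers, sim$color_design)
  assigned <- demux$cell_id[!is.na(demux$timepoint)]

  ## 4. cell QC on assigned cells
  counts_assigned <- proc$counts[, assigned, drop = FALSE]
  metrics <- compute_cell_metrics(counts_assigned, regions_all,
                                  spike_ids = sim$spike_design$id)
  qc <- qc_filter_cells(metrics)
  pass_cells <- qc$cell_id[qc$pass]
  note("cells: %d chambers, %d assigned, %d pass QC",
       nrow(sim$truth$cells), length(assigned), length(pass_cells))

  ## 5. endogenous feature filtering + normalization + batch detrending
  cls <- feature_classes(rownames(proc$counts), regions_all,
                         spike_ids = sim$spike_design$id)
  endo <- proc$counts[cls %in% c("promoter", "enhancer"), pass_cells,
                      drop = FALSE]
  filtered <- filter_low_abundance(endo)
  norm <- normalize_counts(filtered)
  meta <- sim$truth$cells[match(pass_cells, sim$truth$cells$cell_id), ]
  norm <- remove_batch_effects(norm, batch = meta$run, batch2 = meta$code,
                               protected = meta$timepoint)
  hvf <- tryCatch(select_high_variance_features(norm),
                  error = function(e) {
                    note("high-variance selection skipped: %s",
                         conditionMessage(e))
                    character(0)
                  })

  ## 6. spike-in metrics
  spike_counts <- proc$counts[rownames(proc$counts) %in%
                                sim$spike_design$id, pass_cells,
                              drop = FALSE]
  accuracy <- spike_accuracy(spike_counts, sim$spike_design,
                             mix = config$spike_mix)
  detection <- fit_detection_limit(
    t(spike_counts[sim$spike_design$id, , drop = FALSE] > 0),
    sim$spike_design[[paste0("molecules_", config$spike_mix)]])
  fbf <- first_base_fraction(proc$pairs, sim$spike_design$id)
  pair <- simulate_spike_pair(sim$spike_design, config$capture_prob,
                              seed = stage_seed(config$seed, "spike_pair"))
  foldchange <- fold_change_analysis(pair$mix1, pair$mix2,
                                     sim$spike_design)

  ## 7. enhancer analysis
  qc_counts <- proc$counts[cls %in% c("promoter", "enhancer"), pass_cells,
                           drop = FALSE]
  loci_tab <- select_robust_bidirectional(qc_counts)
  selected <- loci_tab$locus[loci_tab$selected]
  pcs <- if (length(selected)) per_cell_scores(qc_counts, selected)
         else list(scores = NULL, summary = NULL)
  downsampled <- NULL
  if (length(selected)) {
    downsampled <- do.call(rbind, lapply(selected, function(l) {
      row <- loci_tab[loci_tab$locus == l, ]
      depths <- pcs$scores$plus[pcs$scores$locus == l] +
        pcs$scores$minus[pcs$scores$locus == l]
      d <- downsample_pooled_scores(row$plus, row$minus, depths,
                                    seed = stage_seed(config$seed,
                                                      paste0("ds_", l)))
      d$locus <- l
      d
    }))
  }
  prom_rows <- rownames(qc_counts)[feature_classes(rownames(qc_counts),
                                                   regions_all) ==
                                     "promoter"]
  esc <- enhancer_strand_counts(qc_counts)
  enh_locus_counts <- esc$plus + esc$minus
  gini <- rbind(
    data.frame(feature = prom_rows, class = "promoter",
               gini = apply(qc_counts[prom_rows, , drop = FALSE], 1,
                            gini_log), stringsAsFactors = FALSE),
    data.frame(feature = esc$loci, class = "enhancer",
               gini = apply(enh_locus_counts, 1, gini_log),
               stringsAsFactors = FALSE)
  )
  ks <- tryCatch(
    compare_gini_distributions(gini$gini[gini$class == "promoter"],
                               gini$gini[gini$class == "enhancer"]),
    error = function(e) list(D = NA_real_, p_value = NA_real_))
  locus_level <- rbind(qc_counts[prom_rows, , drop = FALSE],
                       enh_locus_counts)
  bulk <- rowSums(locus_level)
  classes <- stats::setNames(
    c(rep("promoter", length(prom_rows)), rep("enhancer", nrow(enh_locus_counts))),
    rownames(locus_level))
  strata <- detection_by_stratum(locus_level, bulk, classes)
  norm_classes <- stats::setNames(
    feature_classes(rownames(norm$values), regions_all),
    rownames(norm$values))
  expr_summary <- feature_expression_summary(norm$values, norm_classes)

  manifest <- list(
    seed = config$seed,
    n_chambers = nrow(sim$truth$cells),
    n_tags = nrow(sim$tags),
    n_assigned = length(assigned),
    n_pass_qc = length(pass_cells),
    n_features_filtered = nrow(filtered),
    n_selected_enhancers = length(selected),
    median_accuracy = stats::median(accuracy, na.rm = TRUE),
    median_limit50 = stats::median(detection$limit50, na.rm = TRUE),
    first_base_fraction = fbf,
    warnings = warnings_log
  )
  out <- list(
    sim = sim, processed = proc, demux = demux, qc = qc,
    filtered = filtered, norm = norm, hvf = hvf,
    spike = list(accuracy = accuracy, detection = detection,
                 first_base_fraction = fbf, foldchange = foldchange),
    enhancer = list(loci = loci_tab, per_cell = pcs,
                    downsampled = downsampled, gini = gini, ks = ks,
                    strata = strata, expression = expr_summary),
    manifest = manifest
  )
  class(out) <- "sccage_run"
  if (!is.null(outdir)) write_run_outputs(out, outdir)
  out
}

#' @export
print.sccage_run <- function(x, ...) {
  m <- x$manifest
  cat("Single-cell CAGE pipeline run\n")
  cat(sprintf("  chambers %d | assigned %d | pass QC %d\n",
              m$n_chambers, m$n_assigned, m$n_pass_qc))
  cat(sprintf("  filtered features %d | selected enhancers %d\n",
              m$n_features_filtered, m$n_selected_enhancers))
  cat(sprintf("  median spike accuracy %.3f | median limit50 %.1f | first-base %.3f\n",
              m$median_accuracy, m$median_limit50,
              m$first_base_fraction))
  invisible(x)
}

#' Write every pipeline table plus a JSON manifest to a directory
#'
#' @param run a `sccage_run` object.
#' @param outdir output directory (created if missing).
#' @return invisibly, the manifest path.
#' @export
write_run_outputs <- function(run, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outdir, f)
  write_fasta(run$sim$genome, p("genome.fa"))
  write_fasta(run$sim$spike_refs, p("spike_refs.fa"))
  write_spike_design(run$sim$spike_design, p("spike_design.tsv"))
  utils::write.csv(run$sim$color_design, p("color_design.csv"),
                   row.names = FALSE)
  utils::write.csv(run$demux, p("demux.csv"), row.names = FALSE)
  write_matrix_tsv(run$processed$counts, p("counts.tsv"))
  utils::write.table(run$processed$tally, p("tally.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(run$qc, p("qc_metrics.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_matrix_tsv(run$norm$values, p("normalized.tsv"))
  utils::write.table(run$enhancer$loci, p("enhancer_loci.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(run$enhancer$per_cell$scores))
    utils::write.table(run$enhancer$per_cell$scores,
                       p("enhancer_cell_scores.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  utils::write.table(run$enhancer$gini, p("gini.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(run$enhancer$strata, p("detection_strata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    write_regions_bed(run$sim$regions, p("regions.bed"))
    write_tags_bed12(run$sim$tags, p("tags.bed"))
  }
  jsonlite::write_json(run$manifest, p("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(p("manifest.json"))
}
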