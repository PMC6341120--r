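#' Class of each count-matrix row
#'
#' Enhancer rows are named `locus:+` / `locus:-`; other rows carry the
#' region (or spike species) id directly.
#'
#' @param row_ids rownames of a strand-resolved count matrix.
#' @param regions annotation data.frame; spike rows may instead be listed
#'   via `spike_ids`.
#' @param spike_ids optional character vector of spike species ids.
#' @return character vector of classes (`NA` for unknown rows).
#' @export
feature_classes <- function(row_ids, regions, spike_ids = NULL) {
  base_id <- sub(":[+-]$", "", row_ids)
  cls <- regions$class[match(base_id, regions$id)]
  if (!is.null(spike_ids)) cls[base_id %in% spike_ids] <- "spike"
  cls
}

#' Per-cell quality-control metrics
#'
#' Library size (counted tags), feature count (rows with nonzero counts),
#' and the proportions of counts on mitochondrial and spike-in rows.
#'
#' @param counts strand-resolved count matrix (features x cells).
#' @param regions annotation data.frame used to classify rows.
#' @param spike_ids optional spike species ids (see [feature_classes()]).
#' @return data.frame with columns `cell_id`, `library_size`,
#'   `feature_count`, `mito_prop`, `spike_prop`.
#' @export
compute_cell_metrics <- function(counts, regions, spike_ids = NULL) {
  cls <- feature_classes(rownames(counts), regions, spike_ids)
  lib <- colSums(counts)
  feats <- colSums(counts > 0)
  mito <- colSums(counts[which(cls == "mito"), , drop = FALSE])
  spike <- colSums(counts[which(cls == "spike"), , drop = FALSE])
  data.frame(
    cell_id = colnames(counts),
    library_size = as.numeric(lib),
    feature_count = as.integer(feats),
    mito_prop = ifelse(lib > 0, mito / lib, 0),
    spike_prop = ifelse(lib > 0, spike / lib, 0),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Median-absolute-deviation outlier filter for cells
#'
#' A cell fails when `log2(library_size)` or `log2(feature_count + 1)`
#' falls more than `nmads` MADs below its median, or when the
#' mitochondrial or spike proportion rises more than `nmads` MADs above its
#' median. The MAD uses the 1.4826 normal-consistency constant. The
#' inequality is strict: a cell exactly at the boundary passes. A metric
#' with zero MAD filters nothing (noted via a message).
#'
#' @param metrics data.frame from [compute_cell_metrics()].
#' @param nmads number of MADs (default 3).
#' @return `metrics` with added logical `pass` and character `reasons`
#'   (comma-separated reason codes, empty for passing cells).
#' @export
qc_filter_cells <- function(metrics, nmads = 3) {
  if (nrow(metrics) < 5L)
    stop("need at least 5 cells for a MAD filter", call. = FALSE)
  low_fail <- function(x, code) {
    m <- stats::median(x)
    s <- stats::mad(x)       # constant = 1.4826
    if (s == 0 || !is.finite(s)) {
      message("MAD is zero for '", code, "'; metric filters nothing")
      return(rep(FALSE, length(x)))
    }
    x < m - nmads * s
  }
  high_fail <- function(x, code) {
    m <- stats::median(x)
    s <- stats::mad(x)
    if (s == 0 || !is.finite(s)) {
      message("MAD is zero for '", code, "'; metric filters nothing")
      return(rep(FALSE, length(x)))
    }
    x > m + nmads * s
  }
  f1 <- low_fail(log2(metrics$library_size), "library_size")
  f2 <- low_fail(log2(metrics$feature_count + 1), "feature_count")
  f3 <- high_fail(metrics$mito_prop, "mito_prop")
  f4 <- high_fail(metrics$spike_prop, "spike_prop")
  reasons <- apply(cbind(low_lib = f1, low_features = f2,
                         high_mito = f3, high_spike = f4), 1,
                   function(z) paste(names(z)[z], collapse = ","))
  metrics$pass <- !(f1 | f2 | f3 | f4)
  metrics$reasons <- reasons
  metrics
}

#' Remove low-abundance features
#'
#' A feature is removed iff it is expressed (count > 0) in fewer than
#' `min_cells` cells, or its average count across the retained cells is
#' strictly below `min_mean`.
#'
#' @param counts count matrix (features x cells), normally already
#'   restricted to QC-passing cells.
#' @param min_cells minimum expressing cells (default 2).
#' @param min_mean minimum average count (default 0.3).
#' @return the row-filtered matrix.
#' @export
filter_low_abundance <- function(counts, min_cells = 2, min_mean = 0.3) {
  n_expr <- rowSums(counts > 0)
  avg <- rowMeans(counts)
  counts[n_expr >= min_cells & avg >= min_mean, , drop = FALSE]
}
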