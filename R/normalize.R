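#' Depth-normalize a count matrix to log2 scale
#'
#' Size factors are the library sizes divided by their geometric mean,
#' rescaled to mean one; normalized values are
#' `log2(count / size_factor + 1)`.
#'
#' @param counts filtered count matrix (features x cells); no zero-size
#'   cells allowed (remove them with [qc_filter_cells()] first).
#' @return object of class `sccage_norm`: list with `values` (log2 matrix),
#'   `size_factors` (named, mean 1) and `batch_removed` (covariates removed
#'   so far, initially `NULL`).
#' @export
normalize_counts <- function(counts) {
  lib <- colSums(counts)
  if (any(lib == 0))
    stop("zero-count cells must be removed before normalization",
         call. = FALSE)
  sf <- lib / exp(mean(log(lib)))
  sf <- sf / mean(sf)
  values <- log2(sweep(counts, 2, sf, "/") + 1)
  out <- list(values = values,
              size_factors = stats::setNames(sf, colnames(counts)),
              batch_removed = NULL)
  class(out) <- "sccage_norm"
  out
}

#' @export
print.sccage_norm <- function(x, ...) {
  cat(sprintf("Normalized log2 expression: %d features x %d cells\n",
              nrow(x$values), ncol(x$values)))
  if (!is.null(x$batch_removed))
    cat("  batch covariates removed:",
        paste(x$batch_removed, collapse = ", "), "\n")
  invisible(x)
}

#' Remove batch effects by linear detrending
#'
#' Fits, per feature, a least-squares model on batch indicator columns
#' (optionally two batch variables, e.g. run and stain color) while
#' protecting a biological covariate such as timepoint, and subtracts the
#' batch-attributable component. The grand mean is preserved. This is the
#' standard linear batch detrending step as implemented by
#' `limma::removeBatchEffect`.
#'
#' @param norm `sccage_norm` object (or plain matrix).
#' @param batch per-cell batch labels (e.g. run); `NULL` is the identity.
#' @param batch2 optional second batch variable (e.g. stain color).
#' @param protected optional per-cell biological labels to protect
#'   (e.g. timepoint).
#' @return object of the same type with detrended values; the removed
#'   covariates are recorded in `batch_removed`.
#' @export
remove_batch_effects <- function(norm, batch = NULL, batch2 = NULL,
                                 protected = NULL) {
  values <- if (inherits(norm, "sccage_norm")) norm$values else norm
  if (is.null(batch) && is.null(batch2)) return(norm)
  chk <- function(b, nm) {
    b <- factor(b)
    if (any(table(b) < 2L))
      stop("each level of '", nm, "' needs at least 2 cells", call. = FALSE)
    b
  }
  if (!is.null(batch)) batch <- chk(batch, "batch")
  if (!is.null(batch2)) batch2 <- chk(batch2, "batch2")
  design <- matrix(1, ncol(values), 1)
  if (!is.null(protected)) {
    protected <- factor(protected)
    design <- stats::model.matrix(~protected)
    bmat <- cbind(
      if (!is.null(batch)) stats::model.matrix(~batch)[, -1, drop = FALSE],
      if (!is.null(batch2)) stats::model.matrix(~batch2)[, -1, drop = FALSE]
    )
    full <- cbind(design, bmat)
    if (qr(full)$rank < ncol(full))
      stop("batch is confounded with the protected covariate; ",
           "cannot separate batch from biology", call. = FALSE)
  }
  corrected <- limma::removeBatchEffect(values, batch = batch,
                                        batch2 = batch2, design = design)
  removed <- c(if (!is.null(batch)) "batch",
               if (!is.null(batch2)) "batch2")
  if (inherits(norm, "sccage_norm")) {
    norm$values <- corrected
    norm$batch_removed <- c(norm$batch_removed, removed)
    norm
  } else {
    corrected
  }
}

#' Fraction of per-feature variance attributable to a grouping
#'
#' Per-feature R-squared of a one-way fit on the given labels; used to
#' verify that batch detrending removed the run-level signal.
#'
#' @param values numeric matrix (features x cells).
#' @param labels per-cell grouping labels.
#' @return numeric vector of per-feature R-squared values.
#' @export
batch_variance_fraction <- function(values, labels) {
  labels <- factor(labels)
  grand <- rowMeans(values)
  centered <- values - grand
  sst <- rowSums(centered^2)
  ssb <- 0
  for (l in levels(labels)) {
    i <- which(labels == l)
    ssb <- ssb + length(i) * (rowMeans(values[, i, drop = FALSE]) - grand)^2
  }
  out <- ifelse(sst > 0, ssb / sst, 0)
  names(out) <- rownames(values)
  out
}

#' Select high-variance features above a fitted mean-variance trend
#'
#' Fits a running-median trend of per-feature variance against mean on the
#' normalized values; the biological variance is the residual above the
#' trend. Features with positive residual exceeding the 75th percentile of
#' the positive residuals are selected.
#'
#' @param norm `sccage_norm` object or log-scale matrix.
#' @param quantile_cut residual quantile (default 0.75).
#' @return character vector of selected feature ids; attribute `stats` is a
#'   data.frame with per-feature `mean`, `var`, `trend` and `bio_var`.
#' @export
select_high_variance_features <- function(norm, quantile_cut = 0.75) {
  values <- if (inherits(norm, "sccage_norm")) norm$values else norm
  n <- nrow(values)
  if (n < 50L)
    stop("need at least 50 features to fit a variance trend", call. = FALSE)
  mu <- rowMeans(values)
  v <- apply(values, 1, stats::var)
  ord <- order(mu)
  k <- min(2L * floor(n / 20) + 1L, 2L * floor((n - 1) / 2) + 1L)
  k <- max(k, 5L)
  trend_sorted <- stats::runmed(v[ord], k)
  trend <- numeric(n)
  trend[ord] <- trend_sorted
  bio <- v - trend
  pos <- bio[bio > 0]
  sel <- character(0)
  if (length(pos) > 0L) {
    thr <- stats::quantile(pos, quantile_cut)
    sel <- rownames(values)[bio > thr]
  }
  attr(sel, "stats") <- data.frame(
    feature = rownames(values), mean = mu, var = v, trend = trend,
    bio_var = bio, stringsAsFactors = FALSE, row.names = NULL
  )
  sel
}

#' Rarefaction of detected features for one cell
#'
#' Subsamples the cell's counted tags without replacement at each depth and
#' reports the mean number of distinct features detected over replicates.
#' Depths beyond the library size are reported as saturated at full depth.
#'
#' @param features character vector with one entry per counted tag (the
#'   feature it incremented); reconstruct from a count column with
#'   `rep(names(counts), counts)`.
#' @param depth_grid integer depths to subsample to.
#' @param n_reps replicates per depth (default 50).
#' @param seed RNG seed.
#' @return data.frame with `depth`, `mean_detected`, `saturated`.
#' @export
rarefaction_curve <- function(features, depth_grid, n_reps = 50,
                              seed = 1L) {
  set.seed(seed)
  n <- length(features)
  full <- length(unique(features))
  out <- lapply(sort(unique(depth_grid)), function(d) {
    if (d >= n) {
      return(data.frame(depth = d, mean_detected = full,
                        saturated = d > n))
    }
    det <- vapply(seq_len(n_reps), function(i) {
      length(unique(features[sample.int(n, d)]))
    }, numeric(1))
    data.frame(depth = d, mean_detected = mean(det), saturated = FALSE)
  })
  do.call(rbind, out)
}
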