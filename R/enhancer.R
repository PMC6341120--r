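#' Enhancer bidirectionality statistic
#'
#' `|plus - minus| / (plus + minus)`: 0 means perfectly balanced
#' bidirectional transcription, 1 fully unidirectional. Undefined (NA)
#' when the locus has no reads.
#'
#' @param plus,minus nonnegative read counts (vectorized).
#' @return score(s) in `[0, 1]`, `NA` where `plus + minus == 0`.
#' @examples
#' bidirectionality_score(20, 0)   # 1
#' bidirectionality_score(5, 5)    # 0
#' @export
bidirectionality_score <- function(plus, minus) {
  tot <- plus + minus
  ifelse(tot > 0, abs(plus - minus) / tot, NA_real_)
}

#' Per-locus strand count matrices from a strand-resolved count matrix
#'
#' @param counts matrix whose enhancer rows are named `locus:+`/`locus:-`.
#' @return list with `loci`, `plus` and `minus` (loci x cells matrices;
#'   missing strand rows count as zero).
#' @export
enhancer_strand_counts <- function(counts) {
  rows <- grep(":[+-]$", rownames(counts), value = TRUE)
  loci <- sort(unique(sub(":[+-]$", "", rows)))
  get <- function(suffix) {
    m <- matrix(0, length(loci), ncol(counts),
                dimnames = list(loci, colnames(counts)))
    nm <- paste0(loci, ":", suffix)
    here <- nm %in% rownames(counts)
    m[here, ] <- counts[nm[here], , drop = FALSE]
    m
  }
  list(loci = loci, plus = get("+"), minus = get("-"))
}

#' Select robustly detected bidirectional enhancer loci
#'
#' A locus is selected when its pooled (cell-summed) bidirectionality score
#' is at most `max_score` and at least `min_cells` cells each carry at
#' least `min_reads` strand-summed reads at the locus.
#'
#' @param counts strand-resolved count matrix.
#' @param min_reads minimum reads per supporting cell (default 10).
#' @param min_cells minimum supporting cells (default 5).
#' @param max_score pooled-score ceiling (default 0.5).
#' @param strict if `TRUE` require score strictly below `max_score`
#'   (default `FALSE`: `<=`).
#' @return data.frame per locus: `locus`, `plus`, `minus`, `score`,
#'   `n_support`, `selected`.
#' @export
select_robust_bidirectional <- function(counts, min_reads = 10,
                                        min_cells = 5, max_score = 0.5,
                                        strict = FALSE) {
  sc <- enhancer_strand_counts(counts)
  p <- rowSums(sc$plus)
  m <- rowSums(sc$minus)
  score <- bidirectionality_score(p, m)
  support <- rowSums(sc$plus + sc$minus >= min_reads)
  ok_score <- !is.na(score) &
    (if (strict) score < max_score else score <= max_score)
  data.frame(
    locus = sc$loci, plus = p, minus = m, score = score,
    n_support = as.integer(support),
    selected = ok_score & support >= min_cells,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Within-cell bidirectionality scores at selected loci
#'
#' For every cell with at least `min_reads` reads at the locus, the score
#' of that cell's own strand counts; summarized per locus by the unweighted
#' mean and its standard error over scoring cells.
#'
#' @param counts strand-resolved count matrix.
#' @param loci character vector of locus ids to score.
#' @param min_reads minimum locus reads for a cell to be scored
#'   (default 1).
#' @return list with `scores` (long data.frame: `locus`, `cell_id`, `plus`,
#'   `minus`, `score`) and `summary` (`locus`, `n_cells`, `mean_score`,
#'   `se`).
#' @export
per_cell_scores <- function(counts, loci, min_reads = 1) {
  sc <- enhancer_strand_counts(counts)
  keep <- match(loci, sc$loci)
  if (anyNA(keep)) stop("unknown locus id(s)", call. = FALSE)
  long <- do.call(rbind, lapply(seq_along(loci), function(i) {
    p <- sc$plus[keep[i], ]
    m <- sc$minus[keep[i], ]
    use <- (p + m) >= min_reads
    if (!any(use)) return(NULL)
    data.frame(locus = loci[i], cell_id = colnames(counts)[use],
               plus = p[use], minus = m[use],
               score = bidirectionality_score(p[use], m[use]),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  if (is.null(long)) {
    long <- data.frame(locus = character(), cell_id = character(),
                       plus = numeric(), minus = numeric(),
                       score = numeric(), stringsAsFactors = FALSE)
  }
  summ <- do.call(rbind, lapply(loci, function(l) {
    s <- long$score[long$locus == l]
    data.frame(locus = l, n_cells = length(s),
               mean_score = if (length(s)) mean(s) else NA_real_,
               se = if (length(s) > 1) stats::sd(s) / sqrt(length(s))
                    else NA_real_,
               stringsAsFactors = FALSE)
  }))
  list(scores = long, summary = summ)
}

#' Depth-matched downsampling reference for pooled scores
#'
#' Draws `depth` reads without replacement from the pooled strand-labeled
#' read multiset (hypergeometric sampling), scores each draw, and reports
#' the mean and standard error over `n_reps` draws for each requested
#' depth — the expected score of a pseudo-cell at that depth if the pooled
#' strand mixture were homogeneous.
#'
#' @param pooled_plus,pooled_minus pooled strand counts at the locus.
#' @param cell_depths depths to match (typically each scoring cell's locus
#'   reads); zero depths are skipped, depths above the pooled total are
#'   capped with a warning.
#' @param n_reps draws per depth (default 100).
#' @param seed RNG seed.
#' @return data.frame with `depth`, `mean_score`, `se`.
#' @export
downsample_pooled_scores <- function(pooled_plus, pooled_minus,
                                     cell_depths, n_reps = 100, seed = 1L) {
  set.seed(seed)
  total <- pooled_plus + pooled_minus
  stopifnot(total > 0)
  depths <- cell_depths[cell_depths > 0]
  if (any(depths > total)) {
    warning("depths above the pooled total capped at ", total)
    depths <- pmin(depths, total)
  }
  out <- lapply(depths, function(d) {
    x <- stats::rhyper(n_reps, m = pooled_plus, n = pooled_minus, k = d)
    s <- abs(2 * x - d) / d
    data.frame(depth = d, mean_score = mean(s),
               se = stats::sd(s) / sqrt(n_reps))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Gini coefficient of log-transformed expression
#'
#' Gini of `log2(count + 1)` across cells: the mean absolute difference
#' between all (ordered) pairs divided by twice the mean. Computed by the
#' sorted closed form, identical to the O(n^2) pairwise definition.
#'
#' @param counts nonnegative counts across cells (length >= 2).
#' @return Gini coefficient in `[0, 1)`; `NA` for an all-zero vector.
#' @export
gini_log <- function(counts) {
  stopifnot(length(counts) >= 2L)
  v <- sort(log2(counts + 1))
  s <- sum(v)
  if (s == 0) return(NA_real_)
  n <- length(v)
  2 * sum(seq_len(n) * v) / (n * s) - (n + 1) / n
}

#' Compare Gini distributions of two feature classes
#'
#' Two-sample Kolmogorov-Smirnov test between, e.g., promoter and enhancer
#' Gini coefficients. Small samples (either side below 30) use the exact
#' null distribution; larger ones the asymptotic one.
#'
#' @param gini_a,gini_b numeric samples (NAs dropped).
#' @return list with `D` (sup ECDF difference) and `p_value`.
#' @export
compare_gini_distributions <- function(gini_a, gini_b) {
  a <- gini_a[!is.na(gini_a)]
  b <- gini_b[!is.na(gini_b)]
  stopifnot(length(a) > 0, length(b) > 0)
  exact <- min(length(a), length(b)) < 30
  kt <- suppressWarnings(stats::ks.test(a, b, exact = exact))
  list(D = unname(kt$statistic), p_value = kt$p.value)
}

#' Per-cell detected fraction by bulk-expression stratum
#'
#' Features are split, within each class, into `n_strata` quantile bins of
#' their bulk (or pooled) expression; for every cell the fraction of bin
#' members with nonzero counts is reported.
#'
#' @param counts single-cell count matrix.
#' @param bulk_expression named numeric vector covering all rows of
#'   `counts`.
#' @param classes named character vector of feature classes (same rows).
#' @param n_strata number of quantile bins (default 5).
#' @return data.frame: `class`, `stratum` (1 = lowest bulk expression),
#'   `cell_id`, `detected_fraction`.
#' @export
detection_by_stratum <- function(counts, bulk_expression, classes,
                                 n_strata = 5) {
  feats <- rownames(counts)
  if (!all(feats %in% names(bulk_expression)))
    stop("bulk expression missing for some features", call. = FALSE)
  if (!all(feats %in% names(classes)))
    stop("class missing for some features", call. = FALSE)
  bulk <- bulk_expression[feats]
  cls <- classes[feats]
  out <- NULL
  for (cl in unique(cls)) {
    i <- which(cls == cl)
    br <- unique(stats::quantile(bulk[i], probs = seq(0, 1,
                                                      length.out = n_strata + 1)))
    if (length(br) < 2L) next
    bin <- cut(bulk[i], breaks = br, include.lowest = TRUE, labels = FALSE)
    for (s in sort(unique(bin))) {
      rows <- i[bin == s]
      frac <- colMeans(counts[rows, , drop = FALSE] > 0)
      out <- rbind(out, data.frame(
        class = cl, stratum = s, cell_id = colnames(counts),
        detected_fraction = as.numeric(frac),
        stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  out
}

#' Per-feature maximum expression with class labels
#'
#' @param values normalized expression matrix (features x cells).
#' @param classes named character vector of feature classes.
#' @return data.frame: `feature`, `class`, `max_expr`.
#' @export
feature_expression_summary <- function(values, classes) {
  data.frame(
    feature = rownames(values),
    class = unname(classes[rownames(values)]),
    max_expr = apply(values, 1, max),
    stringsAsFactors = FALSE, row.names = NULL
  )
}
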