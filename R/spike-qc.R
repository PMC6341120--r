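#' Spike-in quantification accuracy
#'
#' Pearson correlation between designed input molecules and observed counts
#' for one library (cell). Both sides are `log2(x + 1)`-transformed by
#' default, which compresses the large input dynamic range; the linear
#' option is kept for sensitivity checks.
#'
#' @param cell_counts named numeric vector of observed counts per spike
#'   species, or a species-by-cells matrix (one correlation per column).
#' @param design spike design from [make_spike_design()].
#' @param mix which mix the library was prepared with.
#' @param log_scale correlate on `log2(x + 1)` scale (default `TRUE`).
#' @return numeric correlation(s) in `[-1, 1]`; `NA` where either side has
#'   zero variance.
#' @export
spike_accuracy <- function(cell_counts, design, mix = c("mix1", "mix2"),
                           log_scale = TRUE) {
  mix <- match.arg(mix)
  if (is.matrix(cell_counts)) {
    return(apply(cell_counts, 2, spike_accuracy, design = design,
                 mix = mix, log_scale = log_scale))
  }
  mol <- design[[paste0("molecules_", mix)]][match(names(cell_counts),
                                                   design$id)]
  keep <- !is.na(mol) & mol > 0
  if (sum(keep) < 3L)
    stop("need at least 3 species with positive input", call. = FALSE)
  x <- mol[keep]
  y <- cell_counts[keep]
  if (log_scale) {
    x <- log2(x + 1)
    y <- log2(y + 1)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Molecular detection limit from a per-cell logistic fit
#'
#' For each cell, fits detected/undetected against `log10(molecules)` by
#' binomial-family logistic regression and reports the number of molecules
#' at 50% detection probability, `limit50 = 10^(-b0 / b1)`. Cells whose
#' detections are completely separated by a molecule threshold get the
#' geometric midpoint of the separating gap and a `"separation"` status;
#' cells with all species detected (or none) are censored.
#'
#' @param detections binary matrix, cells in rows and species in columns
#'   (or a single logical/0-1 vector for one cell).
#' @param molecules designed molecules per species (same order as columns).
#' @return data.frame with one row per cell: `cell_id`, `b0`, `b1`,
#'   `limit50`, `status` (`ok`, `separation`, `all_detected`,
#'   `none_detected`, `non_identifiable`).
#' @export
fit_detection_limit <- function(detections, molecules) {
  if (is.null(dim(detections))) {
    detections <- matrix(as.numeric(detections), nrow = 1,
                         dimnames = list("cell", NULL))
  }
  stopifnot(ncol(detections) == length(molecules))
  pos <- molecules > 0
  x_all <- log10(molecules[pos])
  res <- lapply(seq_len(nrow(detections)), function(i) {
    y <- as.numeric(detections[i, pos] > 0)
    if (all(y == 1)) return(list(NA, NA, NA, "all_detected"))
    if (all(y == 0)) return(list(NA, NA, NA, "none_detected"))
    x0 <- x_all[y == 0]
    x1 <- x_all[y == 1]
    if (max(x0) < min(x1)) {
      gap_mid <- (max(x0) + min(x1)) / 2
      return(list(NA, NA, 10^gap_mid, "separation"))
    }
    fit <- suppressWarnings(
      stats::glm(y ~ x_all, family = stats::binomial()))
    b <- stats::coef(fit)
    if (!is.finite(b[2]) || b[2] <= 0)
      return(list(b[1], b[2], NA, "non_identifiable"))
    list(b[1], b[2], 10^(-b[1] / b[2]), "ok")
  })
  out <- data.frame(
    cell_id = rownames(detections) %||% as.character(seq_len(nrow(detections))),
    b0 = vapply(res, function(r) as.numeric(r[[1]]), numeric(1)),
    b1 = vapply(res, function(r) as.numeric(r[[2]]), numeric(1)),
    limit50 = vapply(res, function(r) as.numeric(r[[3]]), numeric(1)),
    status = vapply(res, function(r) r[[4]], character(1)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Fraction of spike tags whose 5' end is at reference position 1
#'
#' Position 1 (1-based) is the reference 5' end, i.e. a 0-based `pos5` of
#' 0. High values indicate specific 5'-end (cap-proximal) capture.
#'
#' @param tags tag-pair data.frame.
#' @param spike_ids character vector of spike reference names; tags whose
#'   `chrom` is in this set are treated as spike tags.
#' @param by_cell return a per-cell named vector instead of one pooled
#'   fraction.
#' @return fraction(s) in `[0, 1]`; `NA` where a library has no spike tags.
#' @export
first_base_fraction <- function(tags, spike_ids, by_cell = FALSE) {
  sp <- tags[tags$chrom %in% spike_ids, , drop = FALSE]
  if (!by_cell) {
    if (nrow(sp) == 0L) return(NA_real_)
    return(mean(sp$pos5 == 0L))
  }
  tapply(sp$pos5 == 0L, sp$cell_id, mean)
}

#' Mix1/mix2 fold-change recovery on spike-ins
#'
#' Scales the two libraries to a common depth, computes per-species
#' observed `log2` ratios with a pseudocount, summarizes each design
#' subgroup by the median of its member ratios, and fits observed on
#' expected `log2` ratios by least squares for an R-squared.
#'
#' @param counts_mix1,counts_mix2 named numeric count vectors over the same
#'   species set.
#' @param design spike design from [make_spike_design()].
#' @param pseudocount zero-guard (default 0.5): added to both scaled counts
#'   of a species when either of its counts is zero, leaving ratios of
#'   fully detected species unshrunken; species undetected in both
#'   libraries are dropped.
#' @return list of class `sccage_foldchange`: `species` (per-species
#'   expected/observed log2 ratios), `subgroups` (per-subgroup median log2
#'   estimate and fold), `r_squared`.
#' @export
fold_change_analysis <- function(counts_mix1, counts_mix2, design,
                                 pseudocount = 0.5) {
  species <- intersect(names(counts_mix1), names(counts_mix2))
  if (length(species) == 0L)
    stop("the two libraries share no species", call. = FALSE)
  c1 <- counts_mix1[species]
  c2 <- counts_mix2[species]
  keep <- c1 > 0 | c2 > 0
  c1 <- c1[keep]
  c2 <- c2[keep]
  species <- species[keep]
  depth <- (sum(c1) + sum(c2)) / 2
  s1 <- c1 * depth / sum(c1)
  s2 <- c2 * depth / sum(c2)
  guard <- ifelse(c1 == 0 | c2 == 0, pseudocount, 0)
  obs <- log2((s1 + guard) / (s2 + guard))
  j <- match(species, design$id)
  expd <- log2(design$ratio[j])
  sub <- design$subgroup[j]
  all_groups <- sort(unique(design$subgroup))
  est <- vapply(all_groups, function(g) {
    v <- obs[sub == g]
    if (length(v) == 0L) NA_real_ else stats::median(v)
  }, numeric(1))
  ratio_of <- design$ratio[match(all_groups, design$subgroup)]
  r2 <- if (stats::sd(obs) == 0 || stats::sd(expd) == 0) {
    NA_real_
  } else {
    # a perfect (noise-free) fit is legitimate here; silence summary.lm
    suppressWarnings(summary(stats::lm(obs ~ expd))$r.squared)
  }
  out <- list(
    species = data.frame(id = species, subgroup = sub,
                         expected_log2 = expd, observed_log2 = as.numeric(obs),
                         stringsAsFactors = FALSE),
    subgroups = data.frame(subgroup = all_groups, ratio = ratio_of,
                           estimate_log2 = est, estimate_fold = 2^est,
                           stringsAsFactors = FALSE),
    r_squared = r2
  )
  class(out) <- "sccage_foldchange"
  out
}

#' @export
print.sccage_foldchange <- function(x, ...) {
  cat("Spike-in fold-change recovery\n")
  print(x$subgroups, row.names = FALSE)
  cat(sprintf("R-squared (observed ~ expected log2 ratio): %.4f\n",
              x$r_squared))
  invisible(x)
}
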