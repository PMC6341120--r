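#' Derive a stage-specific seed from a master seed
#'
#' All stochastic stages of the pipeline draw their seed deterministically
#' from one master seed and the stage name, so that any stage can be rerun
#' in isolation and reproduce the full-pipeline result.
#'
#' @param seed integer master seed.
#' @param stage character scalar naming the stage.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  codes <- utf8ToInt(stage)
  h <- sum(codes * seq_along(codes) * 131)
  as.integer((abs(seed) * 1000003 + h) %% 2147483629 + 1)
}

#' Otsu-style threshold for a bimodal intensity vector
#'
#' Exhaustively maximizes the between-class variance over candidate split
#' points (midpoints between consecutive sorted values).
#'
#' @param x numeric vector of intensities.
#' @return The threshold value; `NA` if fewer than two distinct values.
#' @keywords internal
otsu_split <- function(x) {
  x <- sort(x[is.finite(x)])
  ux <- unique(x)
  if (length(ux) < 2L) return(NA_real_)
  cand <- (ux[-1] + ux[-length(ux)]) / 2
  n <- length(x)
  best <- -Inf
  thr <- cand[1]
  csum <- cumsum(x)
  for (t in cand) {
    k <- sum(x <= t)
    w1 <- k / n
    m1 <- csum[k] / k
    m2 <- (csum[n] - csum[k]) / (n - k)
    v <- w1 * (1 - w1) * (m1 - m2)^2
    if (v > best) {
      best <- v
      thr <- t
    }
  }
  thr
}

# strand-aware reverse complement for plain character vectors
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
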