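#' Estimate per-channel staining thresholds
#'
#' Splits each channel's intensities into two groups with an Otsu-style
#' exhaustive between-class-variance threshold and returns the midpoint of
#' the two group means — a robust decision boundary between background and
#' stain signal.
#'
#' @param records chamber data.frame with `green` and `red` columns.
#' @return named numeric vector `c(green = ..., red = ...)`.
#' @export
estimate_channel_thresholds <- function(records) {
  one <- function(x) {
    t0 <- otsu_split(x)
    if (is.na(t0)) return(NA_real_)
    (mean(x[x <= t0]) + mean(x[x > t0])) / 2
  }
  c(green = one(records$green), red = one(records$red))
}

#' Classify a chamber's color code from its two-channel intensities
#'
#' @param records chamber data.frame with `green` and `red` intensities.
#' @param green_thresh,red_thresh channel thresholds (must be positive);
#'   defaults come from [estimate_channel_thresholds()].
#' @return character vector of codes in `{G, R, GR, none}`.
#' @examples
#' r <- data.frame(green = c(1000, 80, 950), red = c(90, 70, 1100))
#' classify_chamber(r, green_thresh = 500, red_thresh = 500)
#' @export
classify_chamber <- function(records, green_thresh = NULL,
                             red_thresh = NULL) {
  if (is.null(green_thresh) || is.null(red_thresh)) {
    thr <- estimate_channel_thresholds(records)
    green_thresh <- green_thresh %||% thr[["green"]]
    red_thresh <- red_thresh %||% thr[["red"]]
  }
  stopifnot(is.finite(green_thresh), green_thresh > 0,
            is.finite(red_thresh), red_thresh > 0)
  g <- records$green > green_thresh
  r <- records$red > red_thresh
  ifelse(g & r, "GR", ifelse(g, "G", ifelse(r, "R", "none")))
}

#' Assign timepoints to chambers from codes and the staining design
#'
#' Chambers with code `none`, or curated as `empty`, `dead` or `doublet`,
#' are left unassigned (`NA`). All others get the timepoint that their
#' run's design maps their code to.
#'
#' @param records chamber data.frame with `run`, `green`, `red` and
#'   optionally `curation` columns.
#' @param design staining design data.frame (`run`, `code`, `timepoint`).
#' @param green_thresh,red_thresh optional fixed thresholds; by default
#'   estimated from the data per channel.
#' @return `records` with added `code` and `timepoint` columns.
#' @export
assign_timepoints <- function(records, design, green_thresh = NULL,
                              red_thresh = NULL) {
  unknown <- setdiff(unique(records$run), unique(design$run))
  if (length(unknown) > 0L)
    stop("runs absent from the staining design: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  code <- classify_chamber(records, green_thresh, red_thresh)
  key <- paste(design$run, design$code)
  tp <- design$timepoint[match(paste(records$run, code), key)]
  usable <- code != "none"
  if ("curation" %in% names(records)) {
    usable <- usable & !(records$curation %in% c("empty", "dead", "doublet"))
  }
  records$code <- code
  records$timepoint <- ifelse(usable, tp, NA_character_)
  records
}
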