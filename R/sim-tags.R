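MAX_OFFSET <- 50L
FRAG_LEN_MIN <- 80L

# distinct fragment lengths within a (cell, chrom, strand, pos5) group so
# that coordinate-based duplicate collapse never merges distinct molecules
distinct_frag_lengths <- function(n) {
  FRAG_LEN_MIN + sample.int(max(200L, n), n) - 1L
}

#' Emit deduplicatable paired 5'-tag records from true molecules
#'
#' Each true molecule is captured with probability `capture_prob`; a
#' captured molecule emits exactly one tag pair. With probability
#' `first_base_prob` the tag's 5' end sits on the feature's first base,
#' otherwise it is shifted downstream (in strand sense) by a geometric
#' offset with mean `offset_mean`, truncated at 50 nt. With probability
#' `invasion_rate` a captured molecule is emitted instead as a
#' strand-invasion artifact: its 5' end is planted at a genomic site whose
#' three upstream bases (read-strand sense) are the template-switching
#' linker `GGG`, and the tag is flagged in the `artifact` column (the
#' ground-truth label used to benchmark the filter). Fragment ends are
#' drawn so that tags from distinct molecules never share full coordinates.
#'
#' @param truth list with elements `molecules` (from
#'   [simulate_feature_molecules()]) and optionally `spikes` (from
#'   [simulate_spike_molecules()]).
#' @param genome named character vector of chromosome sequences (spike
#'   references are separate; spike tags never land on the genome).
#' @param config a [sim_config()] object.
#' @param invasion_sites planted artifact sites from
#'   [make_toy_genome_annotation()]; `NULL` disables planting (with a
#'   warning if `invasion_rate > 0`).
#' @return data.frame of tag pairs: `cell_id`, `chrom`, `strand`, `pos5`
#'   (0-based 5'-end base), `frag_start`, `frag_end` (0-based half-open
#'   fragment), `origin` (feature id or `"invasion"`), `class`, `artifact`.
#' @export
emit_tag_pairs <- function(truth, genome, config, invasion_sites = NULL) {
  validate_config(config)
  set.seed(stage_seed(config$seed, "tags"))

  mol <- truth$molecules
  src <- data.frame(
    cell_id = mol$cell_id, feature = mol$feature, class = mol$class,
    chrom = mol$chrom, strand = mol$strand, tss = mol$tss,
    molecules = mol$molecules, stringsAsFactors = FALSE
  )
  if (!is.null(truth$spikes) && nrow(truth$spikes) > 0L) {
    sp <- truth$spikes
    src <- rbind(src, data.frame(
      cell_id = sp$cell_id, feature = sp$feature, class = "spike",
      chrom = sp$feature, strand = "+", tss = 0L,
      molecules = sp$molecules, stringsAsFactors = FALSE
    ))
  }
  if (nrow(src) == 0L || config$capture_prob == 0) {
    return(empty_tags())
  }

  captured <- stats::rbinom(nrow(src), src$molecules, config$capture_prob)
  invaded <- stats::rbinom(nrow(src), captured, config$invasion_rate)
  genuine <- captured - invaded

  # genuine tags: 5' end at TSS or a short downstream offset
  gi <- rep.int(seq_len(nrow(src)), genuine)
  gtags <- NULL
  if (length(gi) > 0L) {
    first <- stats::rbinom(length(gi), 1L, config$first_base_prob) == 1L
    off <- integer(length(gi))
    if (any(!first)) {
      off[!first] <- 1L + pmin(
        stats::rgeom(sum(!first), 1 / (1 + config$offset_mean)),
        MAX_OFFSET - 1L)
    }
    sgn <- ifelse(src$strand[gi] == "+", 1L, -1L)
    gtags <- data.frame(
      cell_id = src$cell_id[gi], chrom = src$chrom[gi],
      strand = src$strand[gi],
      pos5 = src$tss[gi] + sgn * off,
      origin = src$feature[gi], class = src$class[gi],
      artifact = FALSE, stringsAsFactors = FALSE
    )
  }

  # artifact tags planted at GGG-context sites
  atags <- NULL
  n_art <- sum(invaded)
  if (n_art > 0L) {
    if (is.null(invasion_sites) || nrow(invasion_sites) == 0L) {
      warning("no linker-context sites available; ",
              "artifact planting skipped (", n_art, " molecules dropped)")
    } else {
      ai <- rep.int(seq_len(nrow(src)), invaded)
      site <- sample.int(nrow(invasion_sites), length(ai), replace = TRUE)
      atags <- data.frame(
        cell_id = src$cell_id[ai],
        chrom = invasion_sites$chrom[site],
        strand = invasion_sites$strand[site],
        pos5 = invasion_sites$pos[site],
        origin = "invasion", class = "invasion",
        artifact = TRUE, stringsAsFactors = FALSE
      )
    }
  }

  tags <- rbind(gtags, atags)
  if (is.null(tags) || nrow(tags) == 0L) return(empty_tags())

  dt <- data.table::as.data.table(tags)
  dt[, len := distinct_frag_lengths(.N),
     by = c("cell_id", "chrom", "strand", "pos5")]
  dt[, frag_start := ifelse(strand == "+", pos5, pos5 - len + 1L)]
  dt[, frag_end := ifelse(strand == "+", pos5 + len, pos5 + 1L)]
  dt[, len := NULL]
  data.table::setorder(dt, cell_id, chrom, frag_start)
  out <- as.data.frame(dt)
  out <- out[, c("cell_id", "chrom", "strand", "pos5",
                 "frag_start", "frag_end", "origin", "class", "artifact")]
  rownames(out) <- NULL
  out
}

empty_tags <- function() {
  data.frame(cell_id = character(), chrom = character(),
             strand = character(), pos5 = integer(),
             frag_start = integer(), frag_end = integer(),
             origin = character(), class = character(),
             artifact = logical(), stringsAsFactors = FALSE)
}
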