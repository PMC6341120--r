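#' Convert a 0-based half-open region table to GRanges
#' @param regions annotation data.frame (`chrom`, `start`, `end`, `strand`).
#' @return a `GRanges` (1-based closed coordinates internally).
#' @keywords internal
regions_to_granges <- function(regions) {
  strand <- ifelse(regions$strand %in% c("+", "-"), regions$strand, "*")
  gr <- GenomicRanges::GRanges(
    seqnames = regions$chrom,
    ranges = IRanges::IRanges(start = regions$start + 1L, end = regions$end),
    strand = strand
  )
  S4Vectors::mcols(gr)$id <- regions$id
  S4Vectors::mcols(gr)$class <- regions$class
  gr
}

#' Collapse coordinate-identical tag pairs
#'
#' Pairs sharing cell identity, chromosome, strand and full fragment
#' coordinates are PCR/optical duplicates of one molecule; exactly one
#' survives (the first occurrence, preserving input order).
#'
#' @param pairs tag-pair data.frame (see [emit_tag_pairs()] for columns).
#' @return the deduplicated data.frame.
#' @examples
#' p <- data.frame(cell_id = "c1", chrom = "chr1", strand = "+",
#'                 pos5 = 10L, frag_start = 10L, frag_end = c(100L, 100L))
#' nrow(collapse_duplicate_pairs(p))   # 1
#' @export
collapse_duplicate_pairs <- function(pairs) {
  if (nrow(pairs) == 0L) return(pairs)
  key <- paste(pairs$cell_id, pairs$chrom, pairs$strand,
               pairs$frag_start, pairs$frag_end, sep = "\r")
  out <- pairs[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Flag strand-invasion artifacts by upstream linker match
#'
#' A tag is called a strand invader when the `nchar(linker)` genomic bases
#' immediately upstream of its 5' end, read in the tag's strand sense
#' (reverse-complemented for minus-strand tags), match the
#' template-switching linker with at most `max_mismatch` mismatches. Tags
#' too close to a chromosome edge to have a full upstream context are left
#' unflagged and counted in the `edge_count` attribute of the result.
#'
#' @param pairs tag-pair data.frame.
#' @param genome named character vector (or `DNAStringSet`) of reference
#'   sequences covering every chromosome present in `pairs`.
#' @param linker linker sequence to match (default `"GGG"`, the terminal
#'   riboguanosines of the template-switching oligo).
#' @param max_mismatch allowed mismatches (default 0, exact match).
#' @return `pairs` with a logical `invader` column; attribute `edge_count`
#'   holds the number of tags lacking upstream context.
#' @export
flag_strand_invaders <- function(pairs, genome, linker = "GGG",
                                 max_mismatch = 0L) {
  if (methods::is(genome, "DNAStringSet")) {
    genome <- stats::setNames(as.character(genome), names(genome))
  }
  stopifnot(is.character(genome), !is.null(names(genome)))
  if (nrow(pairs) == 0L) {
    pairs$invader <- logical(0)
    attr(pairs, "edge_count") <- 0L
    return(pairs)
  }
  missing_chrom <- setdiff(unique(pairs$chrom), names(genome))
  if (length(missing_chrom) > 0L)
    stop("no reference sequence for: ",
         paste(utils::head(missing_chrom, 5), collapse = ", "),
         call. = FALSE)

  k <- nchar(linker)
  len <- nchar(genome)[pairs$chrom]
  plus <- pairs$strand == "+"
  edge <- (plus & pairs$pos5 < k) | (!plus & pairs$pos5 + k >= len)

  ctx <- rep(NA_character_, nrow(pairs))
  ip <- which(plus & !edge)
  if (length(ip) > 0L) {
    # 0-based pos5 - k .. pos5 - 1  ->  1-based pos5 - k + 1 .. pos5
    ctx[ip] <- substring(genome[pairs$chrom[ip]],
                         pairs$pos5[ip] - k + 1L, pairs$pos5[ip])
  }
  im <- which(!plus & !edge)
  if (length(im) > 0L) {
    # 0-based pos5 + 1 .. pos5 + k  ->  1-based pos5 + 2 .. pos5 + k + 1
    raw <- substring(genome[pairs$chrom[im]],
                     pairs$pos5[im] + 2L, pairs$pos5[im] + k + 1L)
    ctx[im] <- revcomp(raw)
  }

  mism <- rep(NA_integer_, nrow(pairs))
  has_ctx <- !is.na(ctx)
  if (any(has_ctx)) {
    m <- integer(sum(has_ctx))
    for (i in seq_len(k)) {
      m <- m + (substr(ctx[has_ctx], i, i) != substr(linker, i, i))
    }
    mism[has_ctx] <- m
  }
  pairs$invader <- !is.na(mism) & mism <= max_mismatch
  attr(pairs, "edge_count") <- sum(edge)
  pairs
}

#' Subtract promoter intervals from enhancer intervals
#'
#' Removes any promoter-overlapped sub-interval from every enhancer locus.
#' Enhancers split by an internal subtraction keep their locus id (one row
#' per piece); enhancers fully covered by promoters are dropped. All other
#' region classes pass through unchanged.
#'
#' @param regions annotation data.frame.
#' @return the modified annotation data.frame.
#' @export
subtract_promoters_from_enhancers <- function(regions) {
  enh <- regions$class == "enhancer"
  prom <- regions$class == "promoter"
  if (!any(enh) || !any(prom)) return(regions)
  enh_gr <- regions_to_granges(regions[enh, , drop = FALSE])
  prom_gr <- GenomicRanges::reduce(
    regions_to_granges(regions[prom, , drop = FALSE]), ignore.strand = TRUE)
  pieces <- GenomicRanges::setdiff(enh_gr, prom_gr, ignore.strand = TRUE)
  if (length(pieces) == 0L) {
    out <- regions[!enh, , drop = FALSE]
    rownames(out) <- NULL
    return(out)
  }
  # map each piece back to the locus it came from, clipped to that locus
  hit <- GenomicRanges::findOverlaps(pieces, enh_gr, ignore.strand = TRUE)
  pieces <- pieces[S4Vectors::queryHits(hit)]
  src_gr <- enh_gr[S4Vectors::subjectHits(hit)]
  src <- regions[enh, , drop = FALSE][S4Vectors::subjectHits(hit), ,
                                      drop = FALSE]
  new_enh <- data.frame(
    id = src$id, chrom = as.character(GenomicRanges::seqnames(pieces)),
    start = pmax(GenomicRanges::start(pieces),
                 GenomicRanges::start(src_gr)) - 1L,
    end = pmin(GenomicRanges::end(pieces), GenomicRanges::end(src_gr)),
    strand = ".", class = "enhancer", stringsAsFactors = FALSE
  )
  out <- rbind(regions[!enh, , drop = FALSE], new_enh)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Remove tags whose 5' base falls in a masked region
#'
#' Masking is strand-insensitive (rRNA/tRNA/small-RNA loci are removed on
#' both strands).
#'
#' @param pairs tag-pair data.frame.
#' @param regions annotation data.frame (only `class == "mask"` rows used).
#' @return the filtered data.frame; attribute `masked_count` has the number
#'   removed, `masked_by_cell` a per-cell table.
#' @export
apply_mask <- function(pairs, regions) {
  mask <- regions[regions$class == "mask", , drop = FALSE]
  if (nrow(pairs) == 0L || nrow(mask) == 0L) {
    attr(pairs, "masked_count") <- 0L
    return(pairs)
  }
  tag_gr <- GenomicRanges::GRanges(
    pairs$chrom, IRanges::IRanges(pairs$pos5 + 1L, width = 1L))
  hit <- IRanges::overlapsAny(
    tag_gr, regions_to_granges(mask), ignore.strand = TRUE)
  out <- pairs[!hit, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "masked_count") <- sum(hit)
  attr(out, "masked_by_cell") <- table(pairs$cell_id[hit])
  out
}

#' Count tag 5' ends into a strand-resolved feature-by-cell matrix
#'
#' A tag increments a promoter, mitochondrial or spike row iff its 5' base
#' lies in the region interval and the strands match. A tag increments an
#' enhancer row `locus:+` or `locus:-` iff its 5' base lies in the
#' (promoter-subtracted) enhancer interval; the row strand is the tag
#' strand. Tags matching no region are tallied per cell as unannotated.
#' Tags hitting several regions are assigned to the first region in sorted
#' (chrom, start) order, with a warning.
#'
#' @param pairs tag-pair data.frame (artifacts already removed, or remove
#'   here with `drop_invaders` if an `invader` column is present).
#' @param regions annotation data.frame; enhancers should already be
#'   promoter-subtracted (see [subtract_promoters_from_enhancers()]).
#' @param cells optional character vector of cell ids fixing the matrix
#'   columns (cells without tags get zero columns).
#' @param drop_invaders remove tags with `invader == TRUE` before counting.
#' @return list with `counts` (integer matrix, features x cells) and
#'   `tally` (data.frame `cell_id`, `counted`, `unannotated`).
#' @export
assign_five_prime_counts <- function(pairs, regions, cells = NULL,
                                     drop_invaders = TRUE) {
  if (drop_invaders && "invader" %in% names(pairs)) {
    pairs <- pairs[!pairs$invader, , drop = FALSE]
  }
  feat <- regions[regions$class %in%
                    c("promoter", "mito", "spike", "enhancer"), ,
                  drop = FALSE]
  feat <- feat[order(feat$chrom, feat$start), , drop = FALSE]
  enh_ids <- unique(feat$id[feat$class == "enhancer"])
  row_ids <- c(feat$id[feat$class != "enhancer"],
               if (length(enh_ids)) paste0(rep(enh_ids, each = 2),
                                           ":", c("+", "-")))
  row_ids <- unique(row_ids)
  if (is.null(cells)) cells <- sort(unique(pairs$cell_id))
  counts <- matrix(0L, length(row_ids), length(cells),
                   dimnames = list(row_ids, cells))
  tally <- data.frame(cell_id = cells, counted = 0L, unannotated = 0L,
                      stringsAsFactors = FALSE)
  if (nrow(pairs) == 0L) return(list(counts = counts, tally = tally))

  tag_gr <- GenomicRanges::GRanges(
    pairs$chrom, IRanges::IRanges(pairs$pos5 + 1L, width = 1L),
    strand = pairs$strand)
  feat_gr <- regions_to_granges(feat)  # enhancers get strand "*"
  hits <- GenomicRanges::findOverlaps(tag_gr, feat_gr)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  if (anyDuplicated(qh)) {
    warning("tags overlapping multiple regions assigned to the first ",
            "region in sorted order")
    keep <- !duplicated(qh)
    qh <- qh[keep]
    sh <- sh[keep]
  }
  feat_class <- feat$class[sh]
  rid <- ifelse(feat_class == "enhancer",
                paste0(feat$id[sh], ":", pairs$strand[qh]),
                feat$id[sh])
  ri <- match(rid, row_ids)
  ci <- match(pairs$cell_id[qh], cells)
  ok <- !is.na(ci)
  if (any(ok)) {
    inc <- table(factor(ri[ok], levels = seq_along(row_ids)),
                 factor(ci[ok], levels = seq_along(cells)))
    counts <- counts + matrix(as.integer(inc), nrow = length(row_ids),
                              dimnames = dimnames(counts))
  }
  counted_by_cell <- table(factor(pairs$cell_id[qh], levels = cells))
  total_by_cell <- table(factor(pairs$cell_id, levels = cells))
  tally$counted <- as.integer(counted_by_cell)
  tally$unannotated <- as.integer(total_by_cell) - tally$counted
  list(counts = counts, tally = tally)
}

#' Full tag-processing stage: deduplicate, filter, mask and count
#'
#' Orchestrates [collapse_duplicate_pairs()], [flag_strand_invaders()],
#' [apply_mask()], [subtract_promoters_from_enhancers()] and
#' [assign_five_prime_counts()], and assembles the per-cell accounting
#' table. Strand invaders are removed before counting by default; set
#' `drop_invaders = FALSE` to keep (flagged) invaders in the counts.
#'
#' @param pairs raw tag-pair data.frame.
#' @param genome named character vector of reference sequences (include
#'   spike references if spike tags are present).
#' @param regions annotation data.frame.
#' @param linker,max_mismatch see [flag_strand_invaders()].
#' @param drop_invaders remove flagged invaders before counting.
#' @param cells optional fixed cell-id set for the matrix columns.
#' @return list with `counts`, `tally` (per cell: `n_input`, `n_duplicate`,
#'   `n_invader`, `n_masked`, `counted`, `unannotated`), `pairs` (the
#'   deduplicated, flagged, masked pairs) and `regions` (with enhancers
#'   promoter-subtracted).
#' @export
count_tags <- function(pairs, genome, regions, linker = "GGG",
                       max_mismatch = 0L, drop_invaders = TRUE,
                       cells = NULL) {
  if (is.null(cells)) cells <- sort(unique(pairs$cell_id))
  cnt <- function(df) as.integer(table(factor(df$cell_id, levels = cells)))
  n_input <- cnt(pairs)
  dedup <- collapse_duplicate_pairs(pairs)
  n_dup <- n_input - cnt(dedup)
  flagged <- flag_strand_invaders(dedup, genome, linker = linker,
                                  max_mismatch = max_mismatch)
  if (drop_invaders) {
    n_inv <- cnt(flagged[flagged$invader, , drop = FALSE])
    work <- flagged[!flagged$invader, , drop = FALSE]
  } else {
    n_inv <- rep(0L, length(cells))
    work <- flagged
  }
  masked <- apply_mask(work, regions)
  n_masked <- cnt(work) - cnt(masked)
  regions2 <- subtract_promoters_from_enhancers(regions)
  asg <- assign_five_prime_counts(masked, regions2, cells = cells,
                                  drop_invaders = FALSE)
  tally <- data.frame(
    cell_id = cells, n_input = n_input, n_duplicate = n_dup,
    n_invader = n_inv, n_masked = n_masked,
    counted = asg$tally$counted, unannotated = asg$tally$unannotated,
    stringsAsFactors = FALSE
  )
  list(counts = asg$counts, tally = tally, pairs = masked,
       regions = regions2)
}
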