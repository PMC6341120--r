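# Interchange formats: FASTA for sequences (Biostrings), BED6 for regions
# and BED12 for tag pairs (rtracklayer), TSV/CSV for tables, JSON for the
# run manifest.

need_rtracklayer <- function() {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("rtracklayer is required for BED import/export", call. = FALSE)
}

#' Write / read reference sequences as FASTA
#' @param seqs named character vector of sequences.
#' @param path file path.
#' @return `read_fasta` returns a named character vector.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write / read an annotation table as BED6
#'
#' The BED name field encodes `class|id`; coordinates are 0-based
#' half-open as in the in-memory representation.
#'
#' @param regions annotation data.frame.
#' @param path file path.
#' @return `read_regions_bed` returns the annotation data.frame.
#' @export
write_regions_bed <- function(regions, path) {
  need_rtracklayer()
  gr <- regions_to_granges(regions)
  names(gr) <- paste(regions$class, regions$id, sep = "|")
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' @rdname write_regions_bed
#' @export
read_regions_bed <- function(path) {
  need_rtracklayer()
  gr <- rtracklayer::import(path, format = "BED")
  nm <- strsplit(gr$name, "|", fixed = TRUE)
  data.frame(
    id = vapply(nm, `[`, character(1), 2),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = sub("\\*", ".", as.character(GenomicRanges::strand(gr))),
    class = vapply(nm, `[`, character(1), 1),
    stringsAsFactors = FALSE
  )
}

#' Write / read tag pairs as BED12
#'
#' One record per (collapsed) pair: the fragment interval with a single
#' block; the name field packs `cell_id|origin|artifact` with `|`
#' separators. The 5' end is `chromStart` on `+` and `chromEnd - 1` on
#' `-`.
#'
#' @param pairs tag-pair data.frame.
#' @param path file path.
#' @return `read_tags_bed12` returns a tag-pair data.frame.
#' @export
write_tags_bed12 <- function(pairs, path) {
  need_rtracklayer()
  gr <- GenomicRanges::GRanges(
    pairs$chrom,
    IRanges::IRanges(pairs$frag_start + 1L, pairs$frag_end),
    strand = pairs$strand
  )
  names(gr) <- paste(pairs$cell_id, pairs$origin,
                     ifelse(pairs$artifact, "artifact", "ok"), sep = "|")
  S4Vectors::mcols(gr)$thick <- IRanges::ranges(gr)
  S4Vectors::mcols(gr)$blocks <- IRanges::IRangesList(
    lapply(GenomicRanges::width(gr), function(w) IRanges::IRanges(1L, w)))
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' @rdname write_tags_bed12
#' @export
read_tags_bed12 <- function(path) {
  need_rtracklayer()
  gr <- rtracklayer::import(path, format = "BED")
  nm <- strsplit(gr$name, "|", fixed = TRUE)
  strand <- as.character(GenomicRanges::strand(gr))
  start0 <- GenomicRanges::start(gr) - 1L
  end0 <- GenomicRanges::end(gr)
  data.frame(
    cell_id = vapply(nm, `[`, character(1), 1),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = strand,
    pos5 = ifelse(strand == "+", start0, end0 - 1L),
    frag_start = start0,
    frag_end = end0,
    origin = vapply(nm, `[`, character(1), 2),
    class = NA_character_,
    artifact = vapply(nm, `[`, character(1), 3) == "artifact",
    stringsAsFactors = FALSE
  )
}

#' Write / read a count (or expression) matrix as TSV
#' @param mat matrix with row and column names.
#' @param path file path.
#' @return `read_matrix_tsv` returns a matrix.
#' @export
write_matrix_tsv <- function(mat, path) {
  df <- data.frame(feature = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
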