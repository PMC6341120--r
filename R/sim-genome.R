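# Region geometry (bases). Features are placed in the first 70% of each
# chromosome, artifact sites in the last 20%, so that genuine tag positions
# (feature start + short downstream offset) can never collide with a planted
# strand-invasion context.
REGION_WIDTH <- c(promoter = 200L, enhancer = 400L, mito = 200L, mask = 300L)
REGION_GAP <- 100L
FEATURE_ZONE_START <- 400L  # headroom so upstream context / fragments fit
FEATURE_ZONE_FRAC <- 0.7
INVASION_ZONE_FRAC <- 0.8

# Random DNA with no GGG or CCC trimer anywhere, so that the only exact
# linker contexts on the genome are the ones planted deliberately.
random_safe_seq <- function(n) {
  s <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
  repeat {
    m <- gregexpr("GGG|CCC", s)[[1]]
    if (m[1] == -1L) break
    for (p in as.integer(m) + 1L) {
      substr(s, p, p) <- sample(c("A", "T"), 1L)
    }
  }
  s
}

#' Generate a toy genome with promoter/enhancer/mask/mito annotation
#'
#' Builds `chrom_count` random chromosomes and places the requested numbers
#' of non-overlapping regions on them: stranded promoters and mitochondrial
#' features, unstranded enhancer loci, and mask intervals. A set of
#' strand-invasion artifact sites is planted in a reserved zone of each
#' chromosome: each site's three upstream bases (in read-strand sense) are
#' set to the template-switching linker `GGG`, and the rest of the genome is
#' guaranteed free of `GGG`/`CCC` trimers, so an upstream-sequence filter
#' can be benchmarked at exact recall and precision.
#'
#' Coordinates are 0-based half-open throughout (BED convention).
#'
#' @param config a [sim_config()] object.
#' @return A list with elements:
#'   \describe{
#'     \item{genome}{named character vector, one DNA string per chromosome.}
#'     \item{regions}{data.frame with columns `id`, `chrom`, `start`, `end`,
#'       `strand` (`+`/`-`/`.`), `class`
#'       (`promoter`/`enhancer`/`mito`/`mask`).}
#'     \item{invasion_sites}{data.frame with columns `chrom`, `pos`
#'       (0-based 5' position), `strand`; the planted artifact sites.}
#'   }
#' @examples
#' cfg <- sim_config(n_promoters = 5, n_enhancers = 3, n_mito = 1,
#'                   n_mask = 2, chrom_count = 1, chrom_length = 50000)
#' ga <- make_toy_genome_annotation(cfg)
#' table(ga$regions$class)
#' @export
make_toy_genome_annotation <- function(config) {
  validate_config(config)
  set.seed(stage_seed(config$seed, "genome"))

  n_req <- c(promoter = config$n_promoters, enhancer = config$n_enhancers,
             mito = config$n_mito, mask = config$n_mask)
  slot <- max(REGION_WIDTH) + REGION_GAP
  zone_end <- as.integer(floor(config$chrom_length * FEATURE_ZONE_FRAC))
  slots_per_chrom <- (zone_end - FEATURE_ZONE_START) %/% slot
  capacity <- slots_per_chrom * config$chrom_count
  if (sum(n_req) > capacity) {
    stop(sprintf(paste0("cannot place %d regions: capacity is %d ",
                        "(increase chrom_length or chrom_count)"),
         sum(n_req), capacity), call. = FALSE)
  }

  chroms <- sprintf("chr%d", seq_len(config$chrom_count))
  genome <- vapply(chroms, function(x) random_safe_seq(config$chrom_length),
                   character(1))

  # one row per region, assigned round-robin to chromosomes, each in its own
  # slot with random jitter -> disjoint by construction
  cls <- rep(names(n_req), n_req)
  ids <- unlist(lapply(names(n_req), function(k) {
    prefix <- c(promoter = "prom", enhancer = "enh",
                mito = "mito", mask = "mask")[[k]]
    sprintf("%s_%03d", prefix, seq_len(n_req[[k]]))
  }), use.names = FALSE)
  n_tot <- length(cls)
  chrom_of <- chroms[((seq_len(n_tot) - 1L) %% config$chrom_count) + 1L]
  slot_of <- integer(n_tot)
  for (ch in chroms) {
    i <- which(chrom_of == ch)
    slot_of[i] <- sample.int(slots_per_chrom, length(i)) - 1L
  }
  width <- REGION_WIDTH[cls]
  jitter <- vapply(slot - REGION_GAP - width,
                   function(m) sample.int(m + 1L, 1L) - 1L, integer(1))
  start <- FEATURE_ZONE_START + slot_of * slot + jitter
  strand <- ifelse(cls %in% c("promoter", "mito"),
                   sample(c("+", "-"), n_tot, replace = TRUE), ".")
  regions <- data.frame(
    id = ids, chrom = chrom_of, start = as.integer(start),
    end = as.integer(start + width), strand = strand, class = cls,
    stringsAsFactors = FALSE, row.names = NULL
  )
  regions <- regions[order(regions$chrom, regions$start), , drop = FALSE]
  rownames(regions) <- NULL

  # planted strand-invasion sites, spaced in the reserved tail zone
  inv <- NULL
  if (config$invasion_sites_per_chrom > 0L) {
    z0 <- as.integer(ceiling(config$chrom_length * INVASION_ZONE_FRAC)) + 10L
    z1 <- config$chrom_length - 400L
    grid <- seq.int(z0, z1, by = 50L)
    if (length(grid) < config$invasion_sites_per_chrom)
      stop("chromosome too short to plant the requested invasion sites",
           call. = FALSE)
    inv <- do.call(rbind, lapply(chroms, function(ch) {
      pos <- sort(sample(grid, config$invasion_sites_per_chrom))
      data.frame(chrom = ch, pos = pos,
                 strand = rep_len(c("+", "-"),
                                  config$invasion_sites_per_chrom),
                 stringsAsFactors = FALSE)
    }))
    # read-sense upstream trimer: GGG exactly, or GAG with one mismatch
    up_plus <- if (config$invasion_exact) "GGG" else "GAG"
    up_minus <- revcomp(up_plus)
    for (i in seq_len(nrow(inv))) {
      ch <- inv$chrom[i]
      p <- inv$pos[i]
      if (inv$strand[i] == "+") {
        substr(genome[[ch]], p - 2L, p) <- up_plus       # 0-based p-3..p-1
      } else {
        substr(genome[[ch]], p + 2L, p + 4L) <- up_minus # 0-based p+1..p+3
      }
    }
  }

  list(genome = genome, regions = regions, invasion_sites = inv)
}

#' Feature 5' start (TSS) positions implied by an annotation
#'
#' Promoters and mitochondrial features start transcription at their
#' 5'-most base (interval start on `+`, `end - 1` on `-`). Enhancer loci
#' transcribe divergently from their midpoint: the plus-strand eRNA starts
#' at the midpoint, the minus-strand eRNA one base to its left.
#'
#' @param regions annotation data.frame as returned by
#'   [make_toy_genome_annotation()].
#' @return data.frame with columns `feature` (for enhancers, `id:+`/`id:-`),
#'   `id`, `class`, `chrom`, `strand`, `tss` (0-based).
#' @export
feature_tss_table <- function(regions) {
  stopifnot(all(c("id", "chrom", "start", "end", "strand", "class")
                %in% names(regions)))
  r <- regions[regions$class %in% c("promoter", "mito"), , drop = FALSE]
  tss_p <- data.frame(
    feature = r$id, id = r$id, class = r$class, chrom = r$chrom,
    strand = r$strand,
    tss = ifelse(r$strand == "+", r$start, r$end - 1L),
    stringsAsFactors = FALSE
  )
  e <- regions[regions$class == "enhancer", , drop = FALSE]
  mid <- as.integer((e$start + e$end) %/% 2L)
  tss_e <- rbind(
    data.frame(feature = paste0(e$id, ":+"), id = e$id, class = "enhancer",
               chrom = e$chrom, strand = "+", tss = mid,
               stringsAsFactors = FALSE),
    data.frame(feature = paste0(e$id, ":-"), id = e$id, class = "enhancer",
               chrom = e$chrom, strand = "-", tss = mid - 1L,
               stringsAsFactors = FALSE)
  )
  out <- rbind(tss_p, tss_e)
  rownames(out) <- NULL
  out
}

#' Synthetic spike-in reference sequences
#'
#' One random reference per spike species (no GGG/CCC trimer, mirroring the
#' toy genome), with position 1 defined as the transcript 5' end.
#'
#' @param config a [sim_config()] object.
#' @param design a spike design, see [make_spike_design()].
#' @return named character vector of reference sequences.
#' @export
make_spike_references <- function(config, design) {
  validate_config(config)
  set.seed(stage_seed(config$seed, "spike_refs"))
  refs <- vapply(design$id, function(x) random_safe_seq(config$spike_length),
                 character(1))
  names(refs) <- design$id
  refs
}
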