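# Reduced-scale configurations used across test files. Kept deliberately
# small so unit tests stay fast; study-scale runs live in the acceptance
# tests.

small_config <- function(seed = 11, ...) {
  args <- list(
    seed = seed,
    n_runs = 2L,
    timepoints = c("0h", "6h"),
    cells_per_run_per_timepoint = 5L,
    n_promoters = 20L,
    n_enhancers = 8L,
    n_mito = 3L,
    n_mask = 4L,
    chrom_count = 2L,
    chrom_length = 60000L,
    spike_dilution = 0.2
  )
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(sim_config, args)
}

# hand-built annotation for matrix-level tests
toy_regions <- function() {
  data.frame(
    id = c("prom_001", "prom_002", "mito_001", "enh_001", "mask_001"),
    chrom = "chr1",
    start = c(100L, 400L, 700L, 1000L, 1600L),
    end = c(300L, 600L, 900L, 1400L, 1900L),
    strand = c("+", "-", "+", ".", "."),
    class = c("promoter", "promoter", "mito", "enhancer", "mask"),
    stringsAsFactors = FALSE
  )
}

make_pair <- function(cell = "c1", chrom = "chr1", strand = "+", pos5 = 0L,
                      len = 100L) {
  if (strand == "+") {
    fs <- pos5
    fe <- pos5 + len
  } else {
    fs <- pos5 - len + 1L
    fe <- pos5 + 1L
  }
  data.frame(cell_id = cell, chrom = chrom, strand = strand,
             pos5 = as.integer(pos5), frag_start = as.integer(fs),
             frag_end = as.integer(fe), origin = "manual", class = "manual",
             artifact = FALSE, stringsAsFactors = FALSE)
}
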