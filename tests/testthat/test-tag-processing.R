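test_that("duplicate collapse keeps one pair per coordinate-cell group", {
  # two identical pairs in one cell -> one survivor
  p <- rbind(make_pair("c1", pos5 = 10), make_pair("c1", pos5 = 10))
  expect_equal(nrow(collapse_duplicate_pairs(p)), 1)
  # identical coordinates in different cells are distinct molecules
  p2 <- rbind(make_pair("c1", pos5 = 10), make_pair("c2", pos5 = 10))
  expect_equal(nrow(collapse_duplicate_pairs(p2)), 2)
  # 7 pairs, 3 coordinate-identical in one cell -> 5 survive
  p7 <- rbind(
    make_pair("c1", pos5 = 10), make_pair("c1", pos5 = 10),
    make_pair("c1", pos5 = 10), make_pair("c1", pos5 = 20),
    make_pair("c2", pos5 = 10), make_pair("c1", pos5 = 10, len = 50),
    make_pair("c1", strand = "-", pos5 = 200)
  )
  out <- collapse_duplicate_pairs(p7)
  expect_equal(nrow(out), 5)
  # brute-force grouping oracle
  key <- paste(p7$cell_id, p7$chrom, p7$strand, p7$frag_start, p7$frag_end)
  expect_equal(nrow(out), length(unique(key)))
  # survivors keep first-occurrence order
  expect_equal(out$pos5[1], 10L)
})

test_that("duplicate collapse is idempotent and never increases size", {
  set.seed(1)
  p <- do.call(rbind, lapply(1:200, function(i) {
    make_pair(sample(c("c1", "c2"), 1), pos5 = sample(10:14, 1),
              len = sample(50:52, 1))
  }))
  once <- collapse_duplicate_pairs(p)
  twice <- collapse_duplicate_pairs(once)
  expect_lte(nrow(once), nrow(p))
  expect_identical(once, twice)
})

test_that("strand-invader flagging matches the upstream linker in strand sense", {
  #          0-based: 0123456789...
  genome <- c(c1 = "AAAAGGGTATCCCTTTAAAA")
  p <- rbind(
    make_pair(pos5 = 7, chrom = "c1"),                  # upstream GGG
    make_pair(pos5 = 10, chrom = "c1"),                 # upstream TAT
    make_pair(strand = "-", pos5 = 9, chrom = "c1", len = 5),   # CCC -> GGG
    make_pair(strand = "-", pos5 = 12, chrom = "c1", len = 5),  # TTT -> AAA
    make_pair(pos5 = 2, chrom = "c1")                   # no upstream context
  )
  out <- flag_strand_invaders(p, genome)
  expect_equal(out$invader, c(TRUE, FALSE, TRUE, FALSE, FALSE))
  expect_equal(attr(out, "edge_count"), 1L)
  # one mismatch tolerated: GGT context at pos5 = 8
  p2 <- make_pair(pos5 = 8, chrom = "c1")
  expect_false(flag_strand_invaders(p2, genome)$invader)
  expect_true(flag_strand_invaders(p2, genome, max_mismatch = 1)$invader)
})

test_that("invader filter has perfect recall and precision on planted artifacts", {
  cfg <- small_config(seed = 17, invasion_rate = 0.15)
  sim <- simulate_experiment(cfg)
  expect_gt(sum(sim$tags$artifact), 50)
  dedup <- collapse_duplicate_pairs(sim$tags)
  out <- flag_strand_invaders(dedup, c(sim$genome, sim$spike_refs))
  expect_identical(out$invader, out$artifact)
})

test_that("mismatched planted contexts are missed at exact matching only", {
  cfg <- small_config(seed = 18, invasion_rate = 0.15, invasion_exact = FALSE)
  sim <- simulate_experiment(cfg)
  out <- flag_strand_invaders(sim$tags, c(sim$genome, sim$spike_refs))
  expect_false(any(out$invader))
  # tolerant matching recovers every planted artifact (genuine tags with a
  # near-linker context may also be flagged; only recall is exact here)
  out1 <- flag_strand_invaders(sim$tags, c(sim$genome, sim$spike_refs),
                               max_mismatch = 1)
  expect_true(all(out1$invader[out1$artifact]))
})

test_that("promoter subtraction trims, splits and drops enhancers correctly", {
  mk <- function(id, start, end, class, strand = ".") {
    data.frame(id = id, chrom = "chr1", start = start, end = end,
               strand = strand, class = class, stringsAsFactors = FALSE)
  }
  # disjoint -> unchanged
  r1 <- rbind(mk("p1", 0, 50, "promoter", "+"), mk("e1", 100, 200, "enhancer"))
  out1 <- subtract_promoters_from_enhancers(r1)
  e <- out1[out1$class == "enhancer", ]
  expect_equal(c(e$start, e$end), c(100, 200))
  # fully covered -> dropped
  r2 <- rbind(mk("p1", 90, 210, "promoter", "+"), mk("e1", 100, 200, "enhancer"))
  expect_equal(sum(subtract_promoters_from_enhancers(r2)$class == "enhancer"), 0)
  # internal subtraction -> two pieces sharing the locus id
  r3 <- rbind(mk("p1", 140, 160, "promoter", "+"), mk("e1", 100, 200, "enhancer"))
  e3 <- subtract_promoters_from_enhancers(r3)
  e3 <- e3[e3$class == "enhancer", ]
  expect_equal(nrow(e3), 2)
  expect_equal(unique(e3$id), "e1")
  expect_equal(sort(e3$start), c(100, 160))
  expect_equal(sort(e3$end), c(140, 200))
})

test_that("masking removes exactly the tags whose 5' base is inside a mask", {
  regions <- toy_regions()   # mask_001 covers [1600, 1900)
  pos <- c(1600, 1700, 1899, 1900, 1599, 100, 250, 1850, 1950, 50)
  p <- do.call(rbind, lapply(pos, function(x) make_pair(pos5 = x)))
  out <- apply_mask(p, regions)
  inside <- pos >= 1600 & pos < 1900   # brute-force membership oracle
  expect_equal(sum(inside), 4)
  expect_equal(nrow(out), 6)
  expect_equal(sort(out$pos5), sort(pos[!inside]))
  expect_equal(attr(out, "masked_count"), 4L)
})

test_that("5' counting respects half-open bounds and strand matching", {
  regions <- toy_regions()
  p <- rbind(
    make_pair("c1", pos5 = 100),               # prom_001 start, + -> counted
    make_pair("c1", pos5 = 300),               # prom_001 end -> excluded
    make_pair("c1", pos5 = 299),               # last base -> counted
    make_pair("c1", strand = "-", pos5 = 200, len = 50),  # wrong strand
    make_pair("c1", strand = "-", pos5 = 500, len = 50),  # prom_002 (-)
    make_pair("c1", pos5 = 1100),              # enhancer, + strand row
    make_pair("c1", strand = "-", pos5 = 1200, len = 50), # enhancer, - row
    make_pair("c2", pos5 = 100)
  )
  asg <- assign_five_prime_counts(p, regions)
  m <- asg$counts
  expect_equal(m["prom_001", "c1"], 2)
  expect_equal(m["prom_001", "c2"], 1)
  expect_equal(m["prom_002", "c1"], 1)
  expect_equal(m["enh_001:+", "c1"], 1)
  expect_equal(m["enh_001:-", "c1"], 1)
  tal <- asg$tally
  expect_equal(tal$unannotated[tal$cell_id == "c1"], 2)  # pos 300 + antisense
  expect_equal(sum(m), 6)
})

test_that("counts equal ground-truth molecules under perfect emission", {
  cfg <- small_config(seed = 19, capture_prob = 1, first_base_prob = 1,
                      invasion_rate = 0)
  sim <- simulate_experiment(cfg)
  regions_all <- rbind(sim$regions,
                       spike_region_table(sim$spike_design,
                                          cfg$spike_length))
  proc <- count_tags(sim$tags, c(sim$genome, sim$spike_refs), regions_all,
                     cells = sim$truth$cells$cell_id)
  truth <- rbind(
    sim$truth$molecules[, c("cell_id", "feature", "molecules")],
    data.frame(cell_id = sim$truth$spikes$cell_id,
               feature = sim$truth$spikes$feature,
               molecules = sim$truth$spikes$molecules)
  )
  obs <- proc$counts[cbind(match(truth$feature, rownames(proc$counts)),
                           match(truth$cell_id, colnames(proc$counts)))]
  expect_equal(obs, truth$molecules)
  expect_equal(sum(proc$counts), sum(truth$molecules))
})

test_that("counting conserves every deduplicated tag", {
  cfg <- small_config(seed = 23, invasion_rate = 0.1)
  sim <- simulate_experiment(cfg)
  regions_all <- rbind(sim$regions,
                       spike_region_table(sim$spike_design,
                                          cfg$spike_length))
  proc <- count_tags(sim$tags, c(sim$genome, sim$spike_refs), regions_all,
                     cells = sim$truth$cells$cell_id)
  tal <- proc$tally
  expect_equal(tal$counted + tal$unannotated + tal$n_masked +
                 tal$n_invader + tal$n_duplicate, tal$n_input)
  # independent recount of the input per cell
  expect_equal(tal$n_input,
               as.integer(table(factor(sim$tags$cell_id,
                                       levels = tal$cell_id))))
})

test_that("counts are invariant under mirror-image strand relabeling", {
  cfg <- small_config(seed = 29, n_mask = 0, spike_dilution = 0.05)
  sim <- simulate_experiment(cfg)
  L <- cfg$chrom_length
  flip_seq <- function(s) chartr("ACGT", "TGCA",
                                 paste(rev(strsplit(s, "")[[1]]),
                                       collapse = ""))
  genome_f <- vapply(sim$genome, flip_seq, character(1))
  reg <- sim$regions
  reg_f <- data.frame(id = reg$id, chrom = reg$chrom,
                      start = L - reg$end, end = L - reg$start,
                      strand = chartr("+-", "-+", reg$strand),
                      class = reg$class, stringsAsFactors = FALSE)
  tg <- sim$tags[sim$tags$class != "spike", ]
  tg_f <- tg
  tg_f$strand <- chartr("+-", "-+", tg$strand)
  tg_f$pos5 <- L - 1L - tg$pos5
  tg_f$frag_start <- L - tg$frag_end
  tg_f$frag_end <- L - tg$frag_start
  a <- count_tags(tg, sim$genome, reg, cells = sim$truth$cells$cell_id)
  b <- count_tags(tg_f, genome_f, reg_f, cells = sim$truth$cells$cell_id)
  # promoter/mito rows identical; enhancer strand rows swap + and -
  rows <- rownames(a$counts)
  swap <- ifelse(grepl(":\\+$", rows), sub(":\\+$", ":-", rows),
                 ifelse(grepl(":-$", rows), sub(":-$", ":+", rows), rows))
  expect_equal(a$counts, b$counts[swap, , drop = FALSE],
               ignore_attr = TRUE)
  expect_equal(a$tally, b$tally)
})
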