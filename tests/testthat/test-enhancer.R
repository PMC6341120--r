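test_that("bidirectionality score hits its definitional values", {
  expect_equal(bidirectionality_score(20, 0), 1)
  expect_equal(bidirectionality_score(5, 5), 0)
  expect_equal(bidirectionality_score(30, 10), 0.5)
  expect_true(is.na(bidirectionality_score(0, 0)))
})

test_that("bidirectionality score is symmetric and scale invariant", {
  set.seed(12)
  for (i in 1:50) {
    a <- sample(0:200, 1)
    b <- sample(0:200, 1)
    if (a + b == 0) next
    expect_equal(bidirectionality_score(a, b), bidirectionality_score(b, a))
    k <- runif(1, 0.1, 9)
    expect_equal(bidirectionality_score(k * a, k * b),
                 bidirectionality_score(a, b), tolerance = 1e-12)
  }
})

test_that("robust-bidirectional selection applies all three thresholds", {
  cells <- paste0("c", 1:8)
  m <- rbind(
    # balanced, well supported -> selected
    "e1:+" = c(6, 6, 6, 6, 6, 6, 0, 0),
    "e1:-" = c(6, 6, 6, 6, 6, 6, 0, 0),
    # fully unidirectional, heavy coverage -> excluded on score
    "e2:+" = rep(25, 8),
    "e2:-" = rep(0, 8),
    # balanced but only 2 supporting cells -> excluded on support
    "e3:+" = c(20, 20, 1, 0, 0, 0, 0, 0),
    "e3:-" = c(20, 20, 1, 0, 0, 0, 0, 0),
    # balanced, exactly at the thresholds -> selected (10 reads, 5 cells)
    "e4:+" = c(5, 5, 5, 5, 5, 0, 0, 0),
    "e4:-" = c(5, 5, 5, 5, 5, 0, 0, 0),
    # score exactly 0.5 -> selected under the <= convention
    "e5:+" = c(15, 15, 15, 15, 15, 0, 0, 0),
    "e5:-" = c(5, 5, 5, 5, 5, 0, 0, 0)
  )
  colnames(m) <- cells
  out <- select_robust_bidirectional(m)
  expect_equal(out$locus[out$selected], c("e1", "e4", "e5"))
  strict <- select_robust_bidirectional(m, strict = TRUE)
  expect_false(strict$selected[strict$locus == "e5"])
  # pooled bookkeeping
  expect_equal(out$score[out$locus == "e2"], 1)
  expect_equal(out$n_support[out$locus == "e3"], 2)
})

test_that("per-cell scores are 1 for strand-pure cells and summarized correctly", {
  m <- rbind(
    "e1:+" = c(4, 0, 3, 0),
    "e1:-" = c(0, 6, 1, 0)
  )
  colnames(m) <- paste0("c", 1:4)
  pcs <- per_cell_scores(m, "e1")
  expect_equal(nrow(pcs$scores), 3)   # c4 has no reads
  expect_equal(pcs$scores$score[pcs$scores$cell_id == "c1"], 1)
  expect_equal(pcs$scores$score[pcs$scores$cell_id == "c3"], 0.5)
  expect_equal(pcs$summary$n_cells, 3)
  expect_equal(pcs$summary$mean_score, mean(c(1, 1, 0.5)))
})

test_that("single-allele simulations give per-cell scores of exactly 1", {
  cfg <- small_config(seed = 41, allele_count = 1, invasion_rate = 0,
                      first_base_prob = 1, capture_prob = 1)
  sim <- simulate_experiment(cfg)
  regions_all <- rbind(sim$regions,
                       spike_region_table(sim$spike_design,
                                          cfg$spike_length))
  proc <- count_tags(sim$tags, c(sim$genome, sim$spike_refs), regions_all)
  esc <- enhancer_strand_counts(proc$counts)
  has_reads <- esc$plus + esc$minus > 0
  scores <- bidirectionality_score(esc$plus[has_reads],
                                   esc$minus[has_reads])
  expect_true(all(scores == 1))
})

test_that("two-allele per-cell scores match a direct allele-mixture oracle", {
  cfg <- small_config(seed = 43, allele_count = 2, n_enhancers = 30,
                      cells_per_run_per_timepoint = 15,
                      timepoint_effect_sd = 0, run_batch_shift = 0,
                      empty_rate = 0, doublet_rate = 0)
  ga <- make_toy_genome_annotation(cfg)
  cells <- simulate_cells(cfg)
  mol <- simulate_feature_molecules(cfg, cells, ga$regions)
  enh <- mol[mol$class == "enhancer", ]
  key <- paste(enh$cell_id, enh$id)
  plus <- tapply(ifelse(enh$strand == "+", enh$molecules, 0), key, sum)
  minus <- tapply(ifelse(enh$strand == "-", enh$molecules, 0), key, sum)
  got <- mean(bidirectionality_score(plus, minus), na.rm = TRUE)

  # independent oracle: simulate the allele mixture directly
  set.seed(999)
  n <- 200000
  pi_ <- cfg$burst_prob
  g <- matrix(stats::rbinom(2 * n, 1, pi_), ncol = 2)
  sz <- matrix(stats::rnbinom(2 * n, size = 1 / cfg$burst_size_dispersion,
                              mu = cfg$burst_size_mean), ncol = 2)
  s <- matrix(stats::rbinom(2 * n, 1, 0.5), ncol = 2)
  pp <- rowSums(g * sz * s)
  mm <- rowSums(g * sz * (1 - s))
  ok <- pp + mm > 0
  oracle <- mean(abs(pp - mm)[ok] / (pp + mm)[ok])
  se <- stats::sd(abs(pp - mm)[ok] / (pp + mm)[ok]) / sqrt(sum(ok))
  n_obs <- sum(!is.na(bidirectionality_score(plus, minus)))
  se_obs <- stats::sd(bidirectionality_score(plus, minus),
                      na.rm = TRUE) / sqrt(n_obs)
  expect_lt(abs(got - oracle), 3 * sqrt(se^2 + se_obs^2))
  # burst-level exclusivity keeps the mixture strongly unidirectional
  expect_gt(oracle, 0.85)
})

test_that("downsampling reproduces the pooled score at full depth", {
  d <- downsample_pooled_scores(30, 10, cell_depths = 40, n_reps = 50,
                                seed = 3)
  expect_equal(d$mean_score, 0.5)
  expect_equal(d$se, 0)
  d2 <- downsample_pooled_scores(1, 1, cell_depths = 1, n_reps = 50,
                                 seed = 3)
  expect_equal(d2$mean_score, 1)
  expect_warning(downsample_pooled_scores(5, 5, cell_depths = 100,
                                          n_reps = 10, seed = 1), "capped")
})

test_that("downsampling mean matches the exact hypergeometric expectation", {
  # X ~ Hypergeom(50 plus, 50 minus, draw 10); score = |2X - 10| / 10
  exact <- sum(stats::dhyper(0:10, 50, 50, 10) * abs(2 * (0:10) - 10) / 10)
  d <- downsample_pooled_scores(50, 50, cell_depths = 10, n_reps = 10000,
                                seed = 7)
  expect_lt(abs(d$mean_score - exact), 3 * d$se)
})

test_that("log-scale Gini matches the definitional values and the O(n^2) oracle", {
  expect_equal(gini_log(rep(7, 10)), 0)
  expect_equal(gini_log(c(1, 0, 0, 0)), 0.75)  # single holder: (n-1)/n
  expect_true(is.na(gini_log(rep(0, 5))))
  gini_brute <- function(counts) {
    v <- log2(counts + 1)
    n <- length(v)
    tot <- 0
    for (i in seq_len(n)) for (j in seq_len(n)) tot <- tot + abs(v[i] - v[j])
    tot / (2 * n^2 * mean(v))
  }
  set.seed(14)
  for (i in 1:5) {
    x <- stats::rpois(20, 3)
    if (sum(x) == 0) next
    expect_equal(gini_log(x), gini_brute(x), tolerance = 1e-12)
  }
})

test_that("KS comparison matches a brute-force ECDF enumeration", {
  same <- compare_gini_distributions(c(0.1, 0.5, 0.9), c(0.1, 0.5, 0.9))
  expect_equal(same$D, 0)
  disj <- compare_gini_distributions(c(0.1, 0.2), c(0.8, 0.9))
  expect_equal(disj$D, 1)
  got <- compare_gini_distributions(c(1, 2, 3), c(2, 3, 4))
  grid <- sort(unique(c(1, 2, 3, 4)))
  e1 <- stats::ecdf(c(1, 2, 3))(grid)
  e2 <- stats::ecdf(c(2, 3, 4))(grid)
  expect_equal(got$D, max(abs(e1 - e2)))
})

test_that("features with rarer bursts have stochastically larger Gini", {
  set.seed(16)
  n_cells <- 60
  gini_class <- function(pi_, mu, n_feat = 60) {
    vapply(seq_len(n_feat), function(i) {
      x <- stats::rbinom(n_cells, 1, pi_) *
        stats::rnbinom(n_cells, size = 2, mu = mu)
      gini_log(x)
    }, numeric(1))
  }
  g_bursty <- gini_class(0.1, 30)   # same mean expression pi * mu = 3
  g_broad <- gini_class(0.9, 10 / 3)
  w <- stats::wilcox.test(g_bursty, g_broad, alternative = "greater")
  expect_lt(w$p.value, 1e-6)
})

test_that("detection by stratum is exact for saturated and empty cells", {
  m <- rbind(f1 = c(1, 0), f2 = c(2, 0), f3 = c(1, 0), f4 = c(5, 0))
  colnames(m) <- c("full", "empty")
  bulk <- c(f1 = 1, f2 = 10, f3 = 100, f4 = 1000)
  cls <- c(f1 = "promoter", f2 = "promoter", f3 = "promoter",
           f4 = "promoter")
  out <- detection_by_stratum(m, bulk, cls, n_strata = 2)
  expect_true(all(out$detected_fraction[out$cell_id == "full"] == 1))
  expect_true(all(out$detected_fraction[out$cell_id == "empty"] == 0))
})

test_that("detected fraction rises with bulk-expression stratum under capture", {
  set.seed(18)
  n_feat <- 100
  n_cells <- 120
  mol <- round(10^seq(0, 2.5, length.out = n_feat))
  counts <- matrix(stats::rbinom(n_feat * n_cells, rep(mol, n_cells), 0.05),
                   n_feat, n_cells,
                   dimnames = list(sprintf("f%03d", 1:n_feat),
                                   sprintf("c%03d", 1:n_cells)))
  cls <- stats::setNames(rep("promoter", n_feat), rownames(counts))
  bulk <- stats::setNames(as.numeric(mol), rownames(counts))
  out <- detection_by_stratum(counts, bulk, cls, n_strata = 4)
  med <- tapply(out$detected_fraction, out$stratum, mean)
  expect_true(all(diff(med) > 0))
})

test_that("feature expression summary reports per-feature maxima", {
  m <- matrix(c(0, 1, 5, 2,
                3, 3, 0, 1,
                0, 0, 0, 0), nrow = 3, byrow = TRUE,
              dimnames = list(c("p1", "p2", "e1"), paste0("c", 1:4)))
  cls <- c(p1 = "promoter", p2 = "promoter", e1 = "enhancer")
  out <- feature_expression_summary(m, cls)
  expect_equal(out$max_expr, c(5, 3, 0))
  expect_equal(out$class, c("promoter", "promoter", "enhancer"))
  one <- feature_expression_summary(m[, 2, drop = FALSE], cls)
  expect_equal(one$max_expr, m[, 2], ignore_attr = TRUE)
})
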