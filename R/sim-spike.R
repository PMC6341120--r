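# Bundled ERCC-like design: 92 species in four equal subgroups whose
# mix1:mix2 input ratios are 4, 1, 2/3 and 1/2. Within a subgroup,
# concentrations span 3.5 decades on a log-uniform grid. Subgroup-level
# scale factors are chosen so that the two mixes have equal total input,
# which keeps per-library depth scaling from biasing fold-change recovery.
SPIKE_SUBGROUPS <- data.frame(
  subgroup = c("A", "B", "C", "D"),
  ratio = c(4, 1, 2 / 3, 1 / 2),
  scale = c(1, 1, 0.5, 0.5),
  stringsAsFactors = FALSE
)
SPIKE_PER_SUBGROUP <- 23L

#' Spike-in design table with ground-truth molecule counts
#'
#' Returns the bundled 92-species spike-in design: each species belongs to
#' one of four subgroups with designed mix1:mix2 input ratios of 4, 1, 2/3
#' and 1/2, and carries a concentration on a log-spaced grid. Molecules per
#' chamber are the concentrations scaled by `config$spike_dilution` and
#' rounded to integers.
#'
#' @param config a [sim_config()] object (only `spike_dilution` is used).
#' @return data.frame with columns `id`, `subgroup`, `ratio`, `conc_mix1`,
#'   `conc_mix2`, `molecules_mix1`, `molecules_mix2`.
#' @examples
#' d <- make_spike_design(sim_config())
#' nrow(d)                      # 92
#' tapply(d$conc_mix1 / d$conc_mix2, d$subgroup, unique)
#' @export
make_spike_design <- function(config = sim_config()) {
  validate_config(config)
  grid <- 10^seq(-1, 2.5, length.out = SPIKE_PER_SUBGROUP)
  rows <- lapply(seq_len(nrow(SPIKE_SUBGROUPS)), function(g) {
    sg <- SPIKE_SUBGROUPS[g, ]
    conc1 <- sg$scale * grid
    data.frame(
      subgroup = sg$subgroup,
      ratio = sg$ratio,
      conc_mix1 = conc1,
      conc_mix2 = conc1 / sg$ratio,
      stringsAsFactors = FALSE
    )
  })
  d <- do.call(rbind, rows)
  d$id <- sprintf("SPK_%03d", seq_len(nrow(d)))
  d$molecules_mix1 <- as.integer(round(d$conc_mix1 * config$spike_dilution))
  d$molecules_mix2 <- as.integer(round(d$conc_mix2 * config$spike_dilution))
  d[, c("id", "subgroup", "ratio", "conc_mix1", "conc_mix2",
        "molecules_mix1", "molecules_mix2")]
}

#' Simulate a mix1/mix2 spike library pair by binomial capture
#'
#' Each species' observed count in each library is a binomial draw from its
#' designed molecules with the given capture probability — the simplest
#' model of molecule-level capture noise, used to exercise fold-change
#' recovery.
#'
#' @param design spike design from [make_spike_design()].
#' @param capture_prob per-molecule capture probability.
#' @param seed RNG seed.
#' @return list with named count vectors `mix1` and `mix2`.
#' @export
simulate_spike_pair <- function(design, capture_prob, seed = 1L) {
  set.seed(seed)
  list(
    mix1 = stats::setNames(
      stats::rbinom(nrow(design), design$molecules_mix1, capture_prob),
      design$id),
    mix2 = stats::setNames(
      stats::rbinom(nrow(design), design$molecules_mix2, capture_prob),
      design$id)
  )
}

#' Read / write a spike design table
#'
#' Tab-separated interchange format with columns `id`, `subgroup`,
#' `conc_mix1`, `conc_mix2` (plus optional `ratio` and molecule columns).
#'
#' @param path file path.
#' @param design a spike design data.frame.
#' @return `read_spike_design` returns the design data.frame.
#' @export
read_spike_design <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "subgroup", "conc_mix1", "conc_mix2")
  if (!all(need %in% names(d)))
    stop("spike design must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  d
}

#' @rdname read_spike_design
#' @export
write_spike_design <- function(design, path) {
  utils::write.table(design, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
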