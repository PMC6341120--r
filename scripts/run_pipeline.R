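#!/usr/bin/env Rscript

# Thin shell entry point over sccage::run_pipeline(): simulate a synthetic
# single-cell CAGE experiment and write every report table plus a JSON
# manifest. Configuration defaults are the package defaults; any
# sim_config() argument can be overridden from a YAML file, e.g.
#
#   seed: 3
#   cells_per_run_per_timepoint: 10
#   invasion_rate: 0.05
#
# Usage: Rscript scripts/run_pipeline.R [--config cfg.yaml] [--seed 1]
#        --outdir out/

suppressPackageStartupMessages({
  library(optparse)
  library(sccage)
})

parser <- OptionParser(option_list = list(
  make_option("--config", type = "character", default = NULL,
              help = "YAML file of sim_config() overrides"),
  make_option("--seed", type = "integer", default = NULL,
              help = "master seed (overrides the config file)"),
  make_option("--outdir", type = "character", default = "sccage_run",
              help = "output directory [default %default]")
))
opt <- parse_args(parser)

args <- list()
if (!is.null(opt$config)) {
  args <- yaml::read_yaml(opt$config)
  bad <- setdiff(names(args), names(formals(sim_config)))
  if (length(bad) > 0)
    stop("unknown configuration keys: ", paste(bad, collapse = ", "))
}
if (!is.null(opt$seed)) args$seed <- opt$seed

cfg <- do.call(sim_config, args)
run <- run_pipeline(cfg, outdir = opt$outdir)
print(run)
cat("outputs written to ", opt$outdir, "\n", sep = "")
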