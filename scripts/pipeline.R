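#!/usr/bin/env Rscript
# Thin shell wrapper over photoinduct::run_pipeline(). Usage:
#   Rscript scripts/pipeline.R --config run.yml
#   Rscript scripts/pipeline.R --n-reps 5 --seed 1 --out-dir results/run1

suppressPackageStartupMessages({
  library(optparse)
  library(photoinduct)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--config", type = "character", default = NULL,
              help = "YAML run configuration (overrides other flags)"),
  make_option("--n-reps", type = "integer", default = 5,
              help = "replicate leaves per genotype x treatment [default %default]"),
  make_option("--seed", type = "integer", default = 1,
              help = "run seed [default %default]"),
  make_option("--out-dir", type = "character", default = NULL,
              help = "output directory for metrics/summary CSVs"))))

cfg <- if (!is.null(opts$config)) opts$config else
  list(n_reps = opts$`n-reps`, seed = opts$seed, out_dir = opts$`out-dir`)
print(run_pipeline(cfg))
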