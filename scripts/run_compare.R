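#!/usr/bin/env Rscript
# Thin command-line wrapper over prostascreen::run_compare():
#
#   Rscript scripts/run_compare.R --n 100000 --seed 1 --out results \
#       [--strategy name1,name2,...] [--scenario scenario1_mri_120]

suppressPackageStartupMessages({
  library(optparse)
  library(prostascreen)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--n", type = "integer", default = 10000L,
              help = "cohort size [default %default]"),
  make_option("--seed", type = "integer", default = 1L,
              help = "master seed [default %default]"),
  make_option("--strategy", type = "character", default = NULL,
              help = "comma-separated strategy presets (default: all ten)"),
  make_option("--scenario", type = "character", default = NULL,
              help = paste("named scenario preset to apply, one of:",
                           paste(names(scenario_presets()), collapse = ", "))),
  make_option("--out", type = "character", default = "results",
              help = "output directory [default %default]")
)))

strategies <- if (is.null(opts$strategy)) list_strategy_presets() else
  strsplit(opts$strategy, ",")[[1]]
config <- run_config(strategies = strategies, n_persons = opts$n,
                     master_seed = opts$seed)
if (!is.null(opts$scenario)) {
  sc <- scenario_presets()[[opts$scenario]]
  if (is.null(sc)) stop("unknown scenario: ", opts$scenario)
  for (p in names(sc$overrides)) {
    config <- set_config_path(config, p, sc$overrides[[p]])
  }
}
run_compare(config, opts$out)
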