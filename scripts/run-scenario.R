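#!/usr/bin/env Rscript
# Convenience runner for the full simulated two-population experiment.
#   Rscript scripts/run-scenario.R --seed 1 --out scenario_out [--small]
#   Rscript scripts/run-scenario.R --goddard --L 30 --Ne 100 --N 1500 --h2 0.5

suppressPackageStartupMessages({
  library(optparse)
  library(jointGBLUP)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--seed", type = "integer", default = 1L),
  make_option("--out", type = "character", default = "scenario_out"),
  make_option("--small", action = "store_true", default = FALSE,
              help = "reduced problem size (seconds instead of hours)"),
  make_option("--goddard", action = "store_true", default = FALSE,
              help = "print the deterministic expected reliability and exit"),
  make_option("--L", type = "double", default = 30),
  make_option("--Ne", type = "double", default = 100),
  make_option("--N", type = "double", default = 1500),
  make_option("--h2", type = "double", default = 0.5)
)))

if (opts$goddard) {
  cat(sprintf("expected reliability: %.4f\n",
              goddardExpectedReliability(opts$L, opts$Ne, opts$N, opts$h2)))
  quit(status = 0)
}

cfg <- if (opts$small) {
  smallScenarioConfig(seed = opts$seed, outDir = opts$out)
} else {
  scenarioConfig(seed = opts$seed, outDir = opts$out)
}
report <- runScenario(cfg)
print(report)
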