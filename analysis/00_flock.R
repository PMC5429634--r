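# Shared study setup for the analysis scripts: a simulated flock of six
# quail-like animals under the default synthetic conditions (full rhythm
# set 24/12/8/6/4.8/4 h, long-range-correlated modulation alpha ~ 0.85,
# power-law immobility bouts S = -1.5 on 1-250 s, mean activity 25%,
# 6.5 days at 0.5 s sampling).  Sourced by the numbered scripts.

library(ultrarhythm)

FLOCK_SEEDS <- 1:6

flock_series <- function(seeds = FLOCK_SEEDS) {
  lapply(seeds, function(s)
    gen_fractal_locomotion(synthetic_spec(seed = s),
                           animal_id = sprintf("quail_%02d", s)))
}

results_dir <- "results"
dir.create(results_dir, showWarnings = FALSE)
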