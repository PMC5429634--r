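#!/usr/bin/env Rscript

# Simulate the study flock and summarize each animal's activity record:
# record length, realized percent of time ambulating, day-night contrast of
# the hourly profile, and the count/mean of immobility events.  The
# realized records reproduce the broad features of home-cage quail
# locomotion: mean hourly ambulation near 25%, hourly values spanning
# roughly 5-45%, and tens of thousands of immobility bouts with means of
# the order of 15-20 s.

source("analysis/00_flock.R")

flock <- flock_series()

summ <- do.call(rbind, lapply(flock, function(ser) {
  h <- percent_ambulating_hourly(ser)
  dur <- extract_events(ser, "immobile")
  data.frame(animal = ser$animal_id,
             n_samples = length(ser$values),
             days = round(length(ser$values) * ser$dt / 86400, 2),
             mean_hourly_pct = round(mean(h), 2),
             min_hourly_pct = round(min(h), 2),
             max_hourly_pct = round(max(h), 2),
             n_immobility_events = length(dur),
             mean_immobility_s = round(mean(dur), 2))
}))

write.csv(summ, file.path(results_dir, "01_flock_summary.csv"),
          row.names = FALSE)
print(summ, row.names = FALSE)
message("median day-night style contrast (max/min hourly %): ",
        round(median(summ$max_hourly_pct / pmax(summ$min_hourly_pct, 1)), 1))
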