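#!/usr/bin/env Rscript

# Rhythm detection per animal with the two periodogram methods.
# Fourier spectra are computed on the full-resolution series; the Enright
# chi-square periodogram on 6-min actograms (both at the 0.001 level).
# For each animal the table records the dominant spectral period, whether
# the circadian (24 h) and main ultradian (12, 8, 6 h) periods are flagged,
# and the harmonics-removed Enright peak list.

source("analysis/00_flock.R")

flock <- flock_series()

near <- function(p, target, tol) any(abs(p - target) <= tol)

rows <- lapply(flock, function(ser) {
  ps <- peak_significance(power_spectrum(ser), alpha_level = 0.001)
  sig <- ps$periods_hours[ps$significant]
  acto <- bin_to_actogram(ser, 360)
  en <- enright_periodogram(acto, alpha_level = 0.001)
  pk <- enright_select_peaks(en)
  data.frame(animal = ser$animal_id,
             fourier_dominant_h = round(ps$periods_hours[which.max(ps$power)], 2),
             fourier_sig_24h = near(sig, 24, 2),
             fourier_sig_12h = near(sig, 12, 0.6),
             fourier_sig_8h = near(sig, 8, 0.4),
             enright_sig_24h = en$significant[en$period_bins == 240],
             enright_sig_12h = en$significant[en$period_bins == 120],
             enright_peaks_h = paste(round(pk$period_hours[pk$significant], 1),
                                     collapse = ";"))
})
tab <- do.call(rbind, rows)
write.csv(tab, file.path(results_dir, "02_rhythm_detection.csv"),
          row.names = FALSE)
print(tab, row.names = FALSE)
message(sprintf(
  "circadian rhythm detected by Fourier in %d/%d animals; significant 12 h Enright peak in %d/%d",
  sum(tab$fourier_sig_24h), nrow(tab), sum(tab$enright_sig_12h), nrow(tab)))
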