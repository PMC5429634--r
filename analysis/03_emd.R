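#!/usr/bin/env Rscript

# Empirical mode decomposition of 30 s-bin actograms: number of intrinsic
# mode functions per animal, reconstruction error, and the pooled
# principal-peak histogram over the slow-mode window (the rule that
# attributes circadian/ultradian periods to IMFs).

source("analysis/00_flock.R")

flock <- flock_series()

peaks <- list()
rows <- lapply(seq_along(flock), function(i) {
  acto <- bin_to_actogram(flock[[i]], 30)
  dec <- emd_decompose(acto)
  sp <- imf_spectra(dec)
  pp <- principal_peaks(sp)
  peaks[[i]] <<- pp
  recon <- Reduce(`+`, dec$imfs) + dec$residual
  data.frame(animal = flock[[i]]$animal_id,
             n_imfs = length(dec$imfs),
             recon_rel_err = max(abs(recon - acto$percents)) /
               diff(range(acto$percents)),
             slow_mode_periods_h = paste(
               round(sort(pp$period_hours[pp$period_hours >= 3]), 1),
               collapse = ";"))
})
tab <- do.call(rbind, rows)
write.csv(tab, file.path(results_dir, "03_emd.csv"), row.names = FALSE)
print(tab, row.names = FALSE)

hist <- peak_histogram(peaks)
write.csv(hist, file.path(results_dir, "03_emd_peak_histogram.csv"),
          row.names = FALSE)
message("principal-peak histogram (period h : count): ",
        paste(sprintf("%g:%d", hist$period_hours, hist$count),
              collapse = "  "))
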