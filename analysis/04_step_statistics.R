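#!/usr/bin/env Rscript

# Fit the missed-step mixture model to the step-size histograms from both
# step finders, convert the fundamental FRET step size to bp with the
# calibration slope, and fit the detection-censored exponential to the
# pause lifetimes. This is the end of the analysis chain: the numbers
# written here are the step-size and kinetics estimates.

library(stepfret)

calib <- study_calibration()

rows <- data.frame()
for (m in c("chisq", "hmm")) {
  h <- read.table(sprintf("results/step_histogram_%s.tsv", m),
                  header = TRUE, sep = "\t")
  hist <- structure(
    list(bin_edges = c(h$bin_center - 0.01, max(h$bin_center) + 0.01),
         counts = h$count, x = h$bin_center, movement_type = "exit",
         construct = "H2A/[end,+6]", n_steps = sum(h$count)),
    class = "step_histogram"
  )
  fit <- fit_eq1(hist)[[1]]
  bp <- convert_step_to_bp(fit$c, fit$c_se, calib)
  cat(sprintf(
    "%-5s c = %.3f +/- %.3f dFRET, f = %.2f, s = %.3f  ->  %.1f +/- %.1f bp\n",
    m, fit$c, fit$c_se, fit$f, fit$s, bp$bp, bp$bp_se
  ))
  rows <- rbind(rows, data.frame(
    method = m, n_steps = sum(h$count), c = fit$c, c_se = fit$c_se,
    f = fit$f, s = fit$s, step_bp = bp$bp, step_bp_se = bp$bp_se
  ))
}

pauses <- read.table("results/pauses.tsv", header = TRUE, sep = "\t")$pause_frames
pf <- fit_pause_lifetimes(pauses, frame_rate = 1, threshold = 5)
cat(sprintf(
  "pause lifetime tau = %.1f +/- %.1f frames; expected missed fraction %.2f (n = %d)\n",
  pf$tau_frames, pf$tau_se_frames, pf$missed_fraction, pf$n
))

rows$tau_frames <- pf$tau_frames
rows$missed_fraction_expected <- pf$missed_fraction
write.table(rows, "results/step_statistics.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat("statistics -> results/step_statistics.tsv\n")
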