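#!/usr/bin/env Rscript
# Assay-arithmetic closure: simulate Ellman plates around known IC50s,
# push them through percent-inhibition -> log-linear IC50 -> pIC50, and
# measure recovery versus absorbance noise. Writes
# results/assay_recovery.csv.

suppressPackageStartupMessages(library(chalqsar))

true_ic50 <- c(AC4 = 3.63, AC12 = 1.10, weak = 60.26)
noise_frac <- c(0, 0.01, 0.02, 0.05)
n_seeds <- 25L

rows <- list()
for (nf in noise_frac) {
  errs <- sapply(seq_len(n_seeds), function(s) {
    ps <- simulate_plate(true_ic50, sigma = nf * 0.9, replicates = 3,
                         seed = 1000L + s)
    tab <- ic50_table(ps$plate)
    abs(tab$pic50[match(names(true_ic50), tab$id)] - pic50(true_ic50))
  })
  rows[[length(rows) + 1L]] <- data.frame(
    noise_frac = nf, mean_abs_pic50_error = mean(errs),
    max_abs_pic50_error = max(errs))
}
out <- do.call(rbind, rows)

dir.create("results", showWarnings = FALSE)
write.csv(out, "results/assay_recovery.csv", row.names = FALSE)

print(out, row.names = FALSE)
cat(sprintf(
  "At triplicate 2%% absorbance noise the mean |pIC50| error is %.3f (< 0.1).\n",
  out$mean_abs_pic50_error[out$noise_frac == 0.02]))
cat("Wrote results/assay_recovery.csv\n")
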