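#!/usr/bin/env Rscript
# Preservation-method comparison: absolute ethanol vs lysis buffer.
#
# Ten simulated engorged mosquitoes (five per preservation agent) are
# profiled at 0 h post-feeding. Per-sample mean peak heights are
# range-standardized (Sneath-Sokal) across the batch and compared by
# one-way ANOVA. The generator's buffer multiplier is its 2.2x calibration,
# so the simulation should recover roughly a 120% height advantage.

suppressPackageStartupMessages(library(bloodmealSTR))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 1L
dir.create("results", showWarnings = FALSE)

panel <- load_panel("bloodmeal")
human <- panel_subset(panel, "human")
cfg <- generator_config(seed = seed)
freqs <- gen_allele_freqs(human, cfg)
hosts <- gen_population(freqs, 10, cfg, id_prefix = "HOST")
method <- rep(c("lysis_buffer", "ethanol"), each = 5)

rows <- list()
for (i in 1:10) {
  bm <- gen_bloodmeal(hosts[i], panel, cfg, time_h = 0,
                      preservation = method[i],
                      sample_id = sprintf("PRES%02d", i), counter = i)
  prof <- calls_to_profile(bin_peaks(bm$peaks, human)$calls, human)
  n_alleles <- sum(sapply(prof$calls, function(df)
    if (nrow(df) == 1) 2 else nrow(df)))
  rows[[i]] <- data.frame(sample_id = prof$sample_id, method = method[i],
                          n_alleles_detected = n_alleles,
                          mean_ph = mean_ph(prof))
}
tab <- do.call(rbind, rows)
tab$std_ph <- standardize_ph(tab$mean_ph)
write.csv(tab, "results/02_preservation.csv", row.names = FALSE)

amp_rate <- tapply(tab$n_alleles_detected, tab$method, mean) / 32
cat(sprintf("Mean allele detection at 0 h: buffer %.1f%%, ethanol %.1f%%\n",
            100 * amp_rate["lysis_buffer"], 100 * amp_rate["ethanol"]))
gain <- 100 * (mean(tab$mean_ph[tab$method == "lysis_buffer"]) /
                 mean(tab$mean_ph[tab$method == "ethanol"]) - 1)
cat(sprintf("Lysis-buffer PH advantage: +%.0f%%\n", gain))

an <- anova_oneway(split(tab$std_ph, tab$method), tukey = FALSE)
cat(sprintf("One-way ANOVA on standardized PH: F(%d, %d) = %.1f, P = %.2g\n",
            an$df_between, an$df_within, an$F, an$p))
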