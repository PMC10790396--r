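#!/usr/bin/env Rscript
# IS-PRM acquisition simulation: replay the trigger logic on clean, jittered
# and decoy-bearing streams; TIC-normalize light quantities; summarize
# replicate precision. Writes results/acquisition_log.tsv and
# results/isprm_summary.tsv.

suppressMessages(library(kipquant))
dir.create("results", showWarnings = FALSE)

clean <- gen_isprm_stream(20, ppm_jitter_sd = 0, decoy_rate = 0, seed = 501)
acq <- run_acquisition(clean)
sens <- sum(acq$log$kind == "light_ms2") / nrow(clean$inclusion)

decoyed <- gen_isprm_stream(20, decoy_rate = 3, seed = 502)
dacq <- run_acquisition(decoyed)
hm <- dacq$log[dacq$log$kind == "heavy_ms2", ]
false_rate <- sum(hm$triggered & grepl("^decoy", hm$precursor_id)) /
  max(1, sum(grepl("^decoy", hm$precursor_id)))

jit <- vapply(1:25, function(s) {
  a <- run_acquisition(gen_isprm_stream(8, ppm_jitter_sd = 5, seed = s))
  sum(a$log$kind == "light_ms2") / 8
}, 0)

cat(sprintf("Trigger sensitivity %.2f on clean streams; decoy false-trigger rate %.4f; sensitivity %.2f under 5 ppm jitter at 3 ppm tolerance.\n",
            sens, false_rate, mean(jit)))

# TIC normalization: run2 is the same sample at double the loading, so its
# raw signal and TIC both double; normalization restores a 1:1 ratio
q <- acq$quantities[!is.na(acq$quantities)]
tic <- c(run1 = 1e9, run2 = 2e9)
qm <- cbind(run1 = q, run2 = 2 * q)
norm <- tic_normalize(qm, tic)
cat(sprintf("After TIC normalization a 2x loading difference leaves a %.2f-fold median ratio.\n",
            median(norm[, "run2"] / norm[, "run1"])))

summary <- data.frame(metric = c("trigger_sensitivity",
                                 "decoy_false_trigger_rate",
                                 "sensitivity_5ppm_jitter"),
                      value = c(sens, false_rate, mean(jit)))
write.table(acq$log, "results/acquisition_log.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
write.table(summary, "results/isprm_summary.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
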