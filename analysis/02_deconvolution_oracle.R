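#!/usr/bin/env Rscript
# Why deconvolve at all? On a noiseless synthetic recording with
# overlapping stimulus, displacement, saccade, blink and gap transients,
# the FIR GLM recovers every injected kernel to machine precision while
# naive event-locked averaging is badly contaminated by the neighboring
# responses.

suppressPackageStartupMessages(library(saccsupp))

dir.create("results", showWarnings = FALSE)

res <- experiment_deconv_oracle(seed = 1)
cat(sprintf("FIR-GLM max |recovered - injected| over all conditions: %.2e\n",
            res$max_recovery_error))
cat(sprintf("Naive displacement-locked average max bias: %.2f baseline SD\n",
            res$naive_bias))
cat("Per-condition recovery error:\n")
print(round(res$per_condition, 12))

tab <- data.frame(condition = names(res$per_condition),
                  recovery_error = as.numeric(res$per_condition))
tab <- rbind(tab, data.frame(condition = "naive_average_bias",
                             recovery_error = res$naive_bias))
saccsupp:::write_tsv_file(tab, "results/deconvolution_oracle.tsv")
cat("Wrote results/deconvolution_oracle.tsv\n")
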