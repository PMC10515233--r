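#!/usr/bin/env Rscript
# Generate the study-like synthetic data set every later step analyzes:
# 793 persons, 14 five-category items in two wording clusters (trait
# correlation 0.5), person distribution N(0.88, 1.57^2). Writes the
# response CSV, item metadata and the generating truth for reference.
suppressPackageStartupMessages(library(pcmeval))

spec <- pss_like_preset(seed = 4201)
rm <- simulate_pcm(spec)

dir.create("results/data", showWarnings = FALSE, recursive = TRUE)
write.csv(cbind(as.data.frame(rm$data), rm$person_meta),
          "results/data/responses.csv", row.names = FALSE, na = "")
write.csv(rm$item_meta, "results/data/item_meta.csv", row.names = FALSE)
jsonlite::write_json(
  list(seed = spec$seed, n = spec$n, rho = spec$rho,
       person_mean = spec$person_mean, person_sd = spec$person_sd,
       thresholds = spec$thresholds),
  "results/data/truth.json", auto_unbox = TRUE, digits = NA, pretty = TRUE)

cat(sprintf("Simulated %d persons x %d items (seed %d).\n",
            nrow(rm$data), ncol(rm$data), spec$seed))
cat("Category totals:",
    paste(tabulate(rm$data + 1L, 5), collapse = " / "), "\n")
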