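#!/usr/bin/env Rscript
# Separate analyses of the negatively and positively worded subscales:
# model fit, item fit and dimensionality within each wording cluster
# (where the partial credit model is correctly specified for this data).
suppressPackageStartupMessages(library(pcmeval))

rm <- read_responses("results/data/responses.csv",
                     meta_path = "results/data/item_meta.csv",
                     person_meta = c("gender", "age"))

for (sub in c("negative7", "positive7")) {
  cat("\n====", sub, "====\n")
  rms <- subset_items(rm, pss_item_subset(sub))
  fit <- fit_cml(rms)
  ft <- flag_misfit(outfit_infit(pcm_residuals(rms, fit)))
  print(ft)
  rep <- dimensionality_report(rms, fit)
  v <- assess_unidimensionality(rep)
  cat("eigenvalue range:", round(min(rep$eigenvalues), 2), "-",
      round(max(rep$eigenvalues), 2), "| verdict:", v$verdict, "\n")
  write.csv(ft, sprintf("results/%s_item_fit.csv", sub), row.names = FALSE)
  write.csv(data.frame(eigenvalue = rep$eigenvalues),
            sprintf("results/%s_eigenvalues.csv", sub), row.names = FALSE)
}
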