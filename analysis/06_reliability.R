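#!/usr/bin/env Rscript
# Targeting and conditional reliability of the negative subscales:
# person/item distributions, test information, the range where the
# person separation index reaches 0.7, and person coverage.
suppressPackageStartupMessages(library(pcmeval))

rm <- read_responses("results/data/responses.csv",
                     meta_path = "results/data/item_meta.csv",
                     person_meta = c("gender", "age"))

for (sub in c("negative7", "negative6")) {
  cat("\n====", sub, "====\n")
  rms <- subset_items(rm, pss_item_subset(sub))
  fit <- fit_cml(rms)
  pe <- estimate_persons(rms, fit)
  print(targeting_summary(pe, fit))
  prof <- reliability_profile(fit, pe)
  print(prof)
  write.csv(prof$profile, sprintf("results/%s_reliability_profile.csv", sub),
            row.names = FALSE)
}
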