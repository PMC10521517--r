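#!/usr/bin/env Rscript
# Stage 1: simulate the crossed thermal-stress experiment (PdC vs PdD,
# 26 vs 32 deg C, 14 days) under the default preset and persist the assay
# tables for the downstream stages.

library(holotherm)

seed <- 42L
a <- generate_assay_set(paper_default_config(seed = seed))
print(a)

dir.create("results", showWarnings = FALSE)
save_assay_set(a, "results/assays")
cat(sprintf("\nWrote results/assays (seed %d): %d fragments, %d PAM records\n",
            seed, nrow(a$design), nrow(a$pam)))
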