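#!/usr/bin/env Rscript
# Stage 7: consolidated report. Re-runs every stage on the assay set,
# screens tank/colony random effects against the temperature/time/genotype
# fixed effects, and ordinates the holobiont-arm-tank units in trait space
# (PCA over the seven standardized traits).

library(holotherm)
suppressPackageStartupMessages(library(dplyr))

a <- load_assay_set("results/assays")
rep <- build_report(a)
print(rep)

# mixed-effects screen on excitation pressure over the stress phase
q <- rep$metrics$qm |> left_join(a$design, by = "fragment_id")
scr <- mixed_effects_screen(q[q$day >= 1, ], "qm",
                            fixed = c("temperature", "day", "holobiont"))
cat("\nFixed effects on Qm:\n")
print(as.data.frame(scr$fixed_effects), digits = 3)
cat("\nRandom-effect verdicts:\n")
print(as.data.frame(scr$random_verdicts), digits = 3)

readr::write_csv(as.data.frame(rep$pca$scores), "results/pca_scores.csv")
readr::write_csv(tibble::as_tibble(rep$pca$loadings, rownames = "trait"),
                 "results/pca_loadings.csv")
cat(sprintf("\nPCA: PC1 %.0f%%, PC2 %.0f%% of trait variance\n",
            100 * rep$pca$variance_explained[1],
            100 * rep$pca$variance_explained[2]))
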