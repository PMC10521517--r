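#!/usr/bin/env Rscript
# Stage 4: areal symbiont densities from hemocytometer counts and bleaching
# rates over the fate-tracked census. Heated PdC should lose ~98% of its
# symbionts by day 14 and bleach progressively (day 7 then day 14); PdD
# should be unaffected.

library(holotherm)
suppressPackageStartupMessages(library(dplyr))

a <- load_assay_set("results/assays")

dens <- areal_density(a$counts) |> left_join(a$design, by = "fragment_id")
readr::write_csv(dens, "results/density.csv")
dens_sum <- dens |>
  group_by(holobiont, temperature, day) |>
  summarise(mean_density = mean(density), .groups = "drop")
print(as.data.frame(dens_sum), digits = 3)

bleach <- bind_rows(lapply(c(0, 7, 14), function(d)
  bleaching_rate(a$census, a$design, d)))
readr::write_csv(bleach, "results/bleaching.csv")
cat("\nBleaching rates (% of remaining fragments):\n")
print(as.data.frame(bleach[bleach$temperature == 32, ]), digits = 3)
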