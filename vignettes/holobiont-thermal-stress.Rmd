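---
title: "Methods: simulating and analyzing holobiont thermal stress"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analyzing holobiont thermal stress}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(holotherm)
```

# The experiment being modeled

Two holobionts of the coral *Pocillopora damicornis* — one dominated by
*Cladocopium* symbionts (PdC), one by *Durusdinium* (PdD) — are compared
under a 14-day thermal challenge. Each holobiont contributes 3 source
colonies; 40 ramets per colony are distributed over 6 tanks, 3 held at
26 °C (control) and 3 ramped to 32 °C (heated). Per tank, fragment roles
are fixed by position: one fragment per colony is fate-tracked for
PAM fluorometry and buoyant weighing, three are sacrificed at days 0, 7
and 14 for cell counts and qPCR, and one enters the day-14 ¹³C
incubation. All fragments are scored in the bleaching census.

The central contrast is a growth-vs-tolerance trade-off: PdC grows
faster at control temperature but collapses under heat
(photoinhibition, calcification decline, symbiont loss, bleaching),
while PdD is thermally stable but slower-growing. Community assays ask
whether heat drives *shuffling* (a change in the C:D balance of an
existing mixed community) rather than wholesale symbiont replacement.

# Generative model

`generate_assay_set(config)` draws every assay from a hierarchical
model whose group-level expectations are set by an *effect table*
(`default_effect_table()`, one row per holobiont × arm) and whose
dispersions are set by a *noise table* (`default_noise()`). The defaults
are the study conditions; they are not fit to data at runtime.

- **PAM yields.** Each fate-tracked fragment has a dusk dark-adapted
  yield Fv/Fm and a midday light-adapted yield ΔF/Fm′, daily from day 0
  to 14. Control Fv/Fm sits at 0.65; heated PdC declines linearly to
  0.23× baseline at day 14 (heated PdD stays flat). Excitation pressure
  Qm = 1 − (ΔF/Fm′)/(Fv/Fm) has a control baseline of 0.10; the heated
  offset steps to its plateau at day 1 (0.17 for PdC, 0.02 for PdD) so
  that the day-1–14 pooled mean equals the plateau. Light yields are
  then ΔF/Fm′ = Fv/Fm · (1 − Qm) plus truncated Gaussian noise
  (sd 0.02), keeping 0 < ΔF/Fm′ < Fv/Fm.
- **Buoyant weights** at days 0, 7, 14 are built by inverting the rate
  equation: a per-fragment interval rate is drawn (CV 0.10) around the
  group mean and multiplied back through the fragment's day-0 area.
  Heated PdC rates carry multipliers 0.60 (days 0–7) and 0.50 (7–14);
  the PdC control baseline is 1.71× the PdD baseline.
- **Cell counts** are Poisson draws in eight 10⁻⁴ mL hemocytometer
  chamber replicates, with dilution and slurry volume recorded per
  sample. Heated PdC density falls to 0.35× control at day 7 and 0.02×
  at day 14 (a 98% loss).
- **Census.** Bleaching is an absorbing per-fragment Bernoulli process:
  once scored bleached, a fragment stays bleached. Per-observation
  probabilities are chosen so that cumulative bleached fractions among
  heated PdC reach 0.267 by day 7 and 0.833 by day 14; a small
  independent removal process (sampling loss) thins the denominator.
- **qPCR.** Genus-specific CT pairs are generated from target log₁₀ D/C
  trajectories (heated PdC −7 → −4; control PdC flat near −7; heated
  PdD 2.5 → 2.7; control PdD drifting to 2.2) via
  ΔCT = −log₁₀(D/C)/log₁₀ 2 around a dominant-target CT near 16, with
  per-replicate CT noise (sd 0.15). CTs past the cycle limit are
  emitted as non-detects.
- **Isotopes.** Labeled fragments incubate 24 h in seawater whose DIC
  pool (2000 µmol L⁻¹, natural δ¹³C −15‰) is spiked with 70 µmol L⁻¹
  NaH¹³CO₃ at 99 atom %. Host and symbiont tissue δ¹³C are produced by
  inverting the uptake equation at the group's target fixation rate
  (PdC control 4.0 × 10⁻³ h⁻¹, heated 1.6 × 10⁻³; PdD 2.5 × 10⁻³ in
  both arms) and translocation fraction (PdC 0.45, PdD 0.30). Unlabeled
  tank controls carry only natural-abundance noise.
- **Clone libraries.** Twenty ITS2 clones per sacrificed sample are
  multinomial draws from the dominant genus's type pool (PdC: C42 0.50,
  C1 0.30, C1b 0.12, C1c 0.08; PdD: D1 0.55, D4 0.30, D6 0.15). The two
  holobionts share no ITS2 types; the trace background genus seen by
  qPCR sits below clone-library detection and is deliberately omitted.

Seeds are honored by saving and restoring `.Random.seed`, so generation
is reproducible and side-effect-free.

# Analysis conventions and numerical choices

- **ΔQm pooling window.** Heated-minus-control Qm is pooled over days
  1–14; day 0 precedes the ramp and is excluded. Standard errors of the
  two arm means combine in quadrature.
- **Pairing.** Yields are averaged over replicates within fragment ×
  day before pairing; days lacking either phase are skipped with a
  warning. Fragments with Fv/Fm ≤ 0 are dropped; Qm < 0 (midday yield
  above dusk yield) is retained but flagged.
- **Initial-area normalization.** All calcification intervals divide by
  the day-0 area, not the interval-start area, so weekly rates are
  additive: rate(0→14) is the day-weighted mean of the two weekly
  rates.
- **Bleaching denominator.** Rates are percentages of *remaining*
  fragments; removed fragments leave the denominator from their removal
  day onward. A day with zero remaining fragments is an error, not 0%.
- **Hemocytometer volume.** Each chamber replicate represents 10⁻⁴ mL
  (Neubauer large square); density = mean count / volume × dilution ×
  slurry volume / blasted area.
- **Non-detects.** A missing CT is imputed at the 40-cycle limit and the
  resulting D/C flagged `censored`; such values are floors/ceilings,
  not point estimates. D/C uses replicate-mean CTs:
  D/C = 2^−(CT_D − CT_C). The shuffling index 2·(D/C)/(1 + D/C) − 1
  maps ratios symmetrically onto [−1, 1].
- **Isotope validity filter.** A labeled sample contributes to uptake
  only if its atom % exceeds its tank-matched unlabeled control
  (falling back to the holobiont-wide control mean when the tank has no
  control); no copy-number or fractionation correction is applied
  beyond the VPDB standard (R = 0.0112372).
- **Zero-adjusted Bray–Curtis.** A dummy column of 1s is appended
  before `vegan::vegdist(method = "bray")` so that all-zero profiles
  remain comparable. NMDS is `vegan::monoMDS` (Kruskal stress-1), best
  of 20 seeded random restarts; grouping is complete linkage cut at
  height 1 − similarity/100 (90% similarity by default).
- **Statistical routing.** Group comparisons run Shapiro–Wilk per group
  and Levene's test across groups at α = 0.05; if both pass, ANOVA with
  Tukey HSD (post-hocs only when the omnibus is significant), otherwise
  Kruskal–Wallis. The mixed screen fits `lmerTest::lmer` with tank and
  colony random intercepts and reports `ranova` verdicts.
- **PCA.** Seven trait means (Fv/Fm, Qm, calcification, density,
  bleaching, log₁₀ D/C, total uptake) are computed per holobiont × arm
  × tank unit, z-scored, and passed to `prcomp`.

# What the generator does and does not emulate

It reproduces group-level means, dispersions, censoring, and the
fate-tracking structure of the design. It does not model tank
micro-environments beyond a shared random intercept scale,
within-colony genetic variation beyond a colony intercept, diel or
ramp-phase dynamics inside a day, symbiont uptake from the environment
(switching), or PCR/sequencing artifacts in clone libraries. Trait
trajectories are piecewise-linear between scheduled sampling days —
adequate for weekly contrasts, not for sub-weekly kinetics.

# Problem sizes

A full assay set is 240 fragments, 3240 PAM rows, and a ~120-row clone
table; generation takes well under a second and the complete pipeline
(`analysis/01`–`07`) a few seconds. Ensemble reproduction
(`scripts/acceptance.R`, 20–50 seeds per quantity) runs in under a
minute.
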