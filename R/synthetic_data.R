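# Seeded generator emulating the two-holobiont x two-temperature thermal
# stress experiment: 3 colonies per holobiont, 40 ramets per colony spread
# over six 80-L tanks (3 control at 26 deg C, 3 heated at 32 deg C), a
# 14-day time course with destructive sampling at days 0/7/14 and daily PAM.

#' Default effect table encoding the study's reported effect sizes
#'
#' One row per holobiont x temperature arm. Trajectories are piecewise
#' linear in day between the stated endpoints. The heated-PdC arm carries
#' the full thermal-stress syndrome: Fv/Fm falling to 0.23x control by day
#' 14 (a 77% decrease), symbiont density falling to 0.02x (98% decline),
#' calcification multipliers 0.60 (interval 0-7) and 0.50 (interval 7-14),
#' cumulative bleaching probabilities 0.267 (day 7) and 0.833 (day 14), and
#' log10 D/C drifting -7 to -4 (a 1000-fold rise of the background
#' Durusdinium). PdD is thermotolerant: all multipliers 1, no bleaching,
#' slight log10 D/C rise under heat and a significant slight decline in its
#' control arm. Control PdC calcifies 1.71x control PdD; control PdD hosts
#' denser symbiont populations than PdC; PdC fixes and translocates more
#' carbon than PdD at control temperature, with PdC rates reduced by heat
#' and PdD rates unchanged.
#'
#' @return Tibble with one row per holobiont-arm parameter block.
#' @keywords internal
default_effect_table <- function() {
  tibble::tribble(
    ~holobiont, ~temperature, ~fvfm_baseline, ~fvfm_day14_multiplier,
      ~qm_baseline, ~qm_offset_peak,
      ~density_baseline, ~density_day7_multiplier, ~density_day14_multiplier,
      ~calc_baseline, ~calc_mult_day7, ~calc_mult_day14,
      ~bleach_prob_day7, ~bleach_prob_day14,
      ~log10_dc_start, ~log10_dc_end,
      ~carbon_fixation_rate, ~translocation_fraction, ~natural_delta13c,
    "PdC", 26, 0.65, 1.00, 0.10, 0.00, 1.5e6, 1.00, 1.00, 0.0684, 1.00, 1.00,
      0.000, 0.000, -7.0, -6.9, 4.0e-3, 0.45, -15,
    "PdC", 32, 0.65, 0.23, 0.10, 0.17, 1.5e6, 0.35, 0.02, 0.0684, 0.60, 0.50,
      0.267, 0.833, -7.0, -4.0, 1.6e-3, 0.45, -15,
    "PdD", 26, 0.65, 1.00, 0.10, 0.00, 2.5e6, 1.00, 1.00, 0.0400, 1.00, 1.00,
      0.000, 0.000,  2.5,  2.2, 2.5e-3, 0.30, -15,
    "PdD", 32, 0.65, 1.00, 0.10, 0.02, 2.5e6, 1.00, 1.00, 0.0400, 1.00, 1.00,
      0.000, 0.000,  2.5,  2.7, 2.5e-3, 0.30, -15
  )
}

# Effect table with no arm differences: both arms of each holobiont follow
# that holobiont's control trajectory, no bleaching, no heat offsets.
null_effect_table <- function() {
  tab <- default_effect_table()
  ctrl <- tab[tab$temperature == 26, ]
  heated <- ctrl
  heated$temperature <- 32
  dplyr::arrange(dplyr::bind_rows(ctrl, heated), .data$holobiont,
                 .data$temperature)
}

default_noise <- function() {
  list(
    yield_sd = 0.02,          # PAM replicate SD, dimensionless yield units
    weight_sd = 5e-4,         # buoyant-weight measurement SD, g
    calc_rate_cv = 0.10,      # per-fragment biological CV of Eq.-2 rate
    density_cv = 0.15,        # per-fragment lognormal CV of areal density
    ct_sd = 0.15,             # qPCR technical-replicate SD, cycles
    log10_dc_sd = 0.15,       # per-fragment biological SD of log10 D/C
    delta13c_sd = 0.3,        # IRMS reproducibility, per mil
    uptake_cv = 0.25,         # per-fragment lognormal CV of total uptake
    translocation_sd = 0.03   # per-fragment SD of the host share
  )
}

#' Generator configuration presets
#'
#' `paper_default_config()` encodes the full reported effect structure (see
#' [default_effect_table()]); `null_effect_config()` removes every arm
#' difference so both temperature arms are exchangeable, for type-I-error
#' calibration. Identical configurations generate identical assay sets.
#'
#' @param seed Integer seed driving all randomness in [generate_assay_set()].
#' @param n_colonies Colonies per holobiont.
#' @param n_tanks_per_arm Tanks per temperature arm per holobiont.
#' @param n_fragments_per_colony Ramets cut per colony.
#' @param duration_days Length of the thermal-stress phase.
#' @return A list of class `generator_config`.
#' @export
paper_default_config <- function(seed = 1L, n_colonies = 3L,
                                 n_tanks_per_arm = 3L,
                                 n_fragments_per_colony = 40L,
                                 duration_days = 14L) {
  new_generator_config("paper_default", default_effect_table(), seed,
                       n_colonies, n_tanks_per_arm, n_fragments_per_colony,
                       duration_days)
}

#' @rdname paper_default_config
#' @export
null_effect_config <- function(seed = 1L, n_colonies = 3L,
                               n_tanks_per_arm = 3L,
                               n_fragments_per_colony = 40L,
                               duration_days = 14L) {
  new_generator_config("null_effect", null_effect_table(), seed,
                       n_colonies, n_tanks_per_arm, n_fragments_per_colony,
                       duration_days)
}

new_generator_config <- function(preset, effect_table, seed, n_colonies,
                                 n_tanks_per_arm, n_fragments_per_colony,
                                 duration_days, noise = default_noise()) {
  stopifnot(n_colonies >= 1, n_tanks_per_arm >= 1,
            n_fragments_per_colony >= 1, duration_days >= 1)
  if (any(unlist(noise) <= 0)) {
    abort("noise standard deviations must be positive",
          class = "holotherm_config_error")
  }
  probs <- c(effect_table$bleach_prob_day7, effect_table$bleach_prob_day14)
  stopifnot(all(probs >= 0 & probs <= 1),
            all(effect_table$bleach_prob_day14 >= effect_table$bleach_prob_day7))
  structure(list(preset = preset, effect_table = effect_table,
                 seed = as.integer(seed), n_colonies = as.integer(n_colonies),
                 n_tanks_per_arm = as.integer(n_tanks_per_arm),
                 n_fragments_per_colony = as.integer(n_fragments_per_colony),
                 duration_days = as.integer(duration_days), noise = noise),
            class = "generator_config")
}

# Linear interpolation between a day-0 and a day-D endpoint.
lin_traj <- function(day, start, end, duration) {
  start + (end - start) * pmin(day, duration) / duration
}

#' Generate a synthetic assay set
#'
#' Simulates all eight assay tables under the configured design:
#' \itemize{
#'   \item PAM: daily dark (Fv/Fm) and light (dF/Fm') yields, in triplicate,
#'     on 3 fate-tracked ramets per colony per arm (n = 9 per arm). The
#'     heated arm's excitation pressure Qm is offset above control from day
#'     1 on (heat ramped 1 deg C/h on day 0); light yields are derived as
#'     Fv/Fm x (1 - Qm) so dark yields exceed paired light yields in
#'     expectation. Yields carry Gaussian replicate noise truncated to [0,1].
#'   \item Buoyant weights at days 0/7/14 on the same ramets, accreted from
#'     per-interval Eq.-2 rates with per-fragment biological variation plus
#'     balance noise.
#'   \item Hemocytometer counts (Poisson, triplicate) and qPCR CTs
#'     (technical triplicates, 2 primers) on 2 destructively sampled ramets
#'     per colony per arm (n = 6) at days 0/7/14; CT pairs are drawn so that
#'     2^-(CT_D - CT_C) follows the arm's log10 D/C trajectory.
#'   \item Fate-tracked census for every fragment: bleaching is an absorbing
#'     per-fragment Bernoulli first-passage process matching the cumulative
#'     probabilities in the effect table; destructively sampled fragments
#'     are flagged "removed" from the following census day so bleaching-rate
#'     denominators ("all the remaining fragments") are exercised.
#'   \item 13C isotope records at day 14: 2 labeled ramets per colony per
#'     arm (n = 6) incubated 24 h at 70 umol/L tracer (99 atom%), host and
#'     symbiont fractions, plus one unlabeled tank control per fraction;
#'     labeled delta13C = natural baseline + enrichment implied by the
#'     arm's fixation rate and translocation fraction.
#'   \item ITS2 clone libraries (multinomial, 20 clones/sample) at the
#'     pretreatment stage and at day 14 for both arms; the dominant genus
#'     holds essentially the whole library (background genus at 1e-5).
#' }
#'
#' @param config A `generator_config` from [paper_default_config()] or
#'   [null_effect_config()].
#' @return A validated [assay_set()].
#' @export
generate_assay_set <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)

  eff <- config$effect_table
  nz <- config$noise
  D <- config$duration_days
  design <- build_design(config)

  pam_frags   <- subset_fragments(design, per_colony_tank = 1L, which = "first")
  dens_frags  <- subset_fragments(design, per_colony_tank = 1L, which = "second",
                                  n_tanks = 2L, n_days = 3L)
  iso_frags   <- subset_fragments(design, per_colony_tank = 1L, which = "third",
                                  n_tanks = 2L, n_days = 1L)

  pam      <- gen_pam(pam_frags$flat, eff, nz, D)
  weights  <- gen_weights(pam_frags$flat, eff, nz, D)
  census   <- gen_census(design, dens_frags, iso_frags, eff, D)
  counts   <- gen_counts(dens_frags, eff, nz, D)
  qpcr     <- gen_qpcr(dens_frags, eff, nz, D)
  isotopes <- gen_isotopes(design, iso_frags, eff, nz)
  clones   <- gen_clones(dens_frags, design)

  assay_set(design = design, pam = pam, weights = weights, counts = counts,
            census = census, qpcr = qpcr, isotopes = isotopes, clones = clones,
            metadata = list(preset = config$preset, seed = config$seed,
                            units = "g, cm2, cells, permil, CT cycles"))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

build_design <- function(config) {
  n_tanks <- 2L * config$n_tanks_per_arm
  grids <- lapply(c("PdC", "PdD"), function(h) {
    per_tank <- rep(config$n_fragments_per_colony %/% n_tanks, n_tanks)
    extra <- config$n_fragments_per_colony %% n_tanks
    if (extra > 0) per_tank[seq_len(extra)] <- per_tank[seq_len(extra)] + 1L
    rows <- lapply(seq_len(config$n_colonies), function(co) {
      tibble::tibble(
        holobiont = h, colony = co,
        tank = rep(seq_len(n_tanks), per_tank),
        index = unlist(lapply(per_tank, seq_len))
      )
    })
    dplyr::bind_rows(rows)
  })
  des <- dplyr::bind_rows(grids)
  des$temperature <- ifelse(des$tank <= config$n_tanks_per_arm, 26, 32)
  des$fragment_id <- fragment_id(des$holobiont, des$colony, des$tank, des$index)
  # index is kept as an extra column: the generator allocates assay roles
  # (PAM vs destructive sampling) by within-tank fragment index
  dplyr::select(des, "fragment_id", "holobiont", "colony", "tank",
                "temperature", "index")
}

# Deterministic assay-role allocation. "first" picks fragment index 1 in
# every tank (PAM + weights, n = n_colonies x n_tanks_per_arm per arm).
# "second"/"third" pick later indices in the first n_tanks tanks per arm,
# one fragment per sampling day, for destructive assays.
subset_fragments <- function(design, per_colony_tank, which,
                             n_tanks = NULL, n_days = 1L) {
  if (which == "first") {
    flat <- design[design$index == 1L, ]
    return(list(flat = flat))
  }
  # density/qPCR fragments occupy indices 2..(1+3 sampling days); isotope
  # fragments come after them so the destructive-assay subsets are disjoint
  offset <- if (which == "second") 1L else 4L
  arms <- dplyr::distinct(design, .data$holobiont, .data$temperature)
  sel <- lapply(seq_len(nrow(arms)), function(i) {
    arm <- design[design$holobiont == arms$holobiont[i] &
                    design$temperature == arms$temperature[i], ]
    tanks <- sort(unique(arm$tank))[seq_len(min(n_tanks, length(unique(arm$tank))))]
    rows <- lapply(seq_len(n_days), function(d) {
      out <- arm[arm$tank %in% tanks & arm$index == offset + d, ]
      out$sample_day_slot <- d
      out
    })
    dplyr::bind_rows(rows)
  })
  list(flat = dplyr::bind_rows(sel))
}

arm_lookup <- function(frags, eff) {
  dplyr::left_join(frags, eff, by = c("holobiont", "temperature"))
}

gen_pam <- function(frags, eff, nz, D) {
  days <- 0:D
  grid <- tidyr::crossing(frags["fragment_id"], day = days)
  grid <- dplyr::left_join(grid, frags, by = "fragment_id")
  grid <- arm_lookup(grid, eff)
  fvfm_true <- lin_traj(grid$day, grid$fvfm_baseline,
                        grid$fvfm_baseline * grid$fvfm_day14_multiplier, D)
  qm_true <- grid$qm_baseline + ifelse(grid$day >= 1, grid$qm_offset_peak, 0)
  light_true <- fvfm_true * (1 - qm_true)
  long <- tidyr::crossing(
    grid[c("fragment_id", "day")] |>
      dplyr::mutate(.dark = fvfm_true, .light = light_true),
    phase = c("dark", "light"), replicate = 1:3)
  mu <- ifelse(long$phase == "dark", long$.dark, long$.light)
  long$yield <- pmin(1, pmax(0, stats::rnorm(nrow(long), mu, nz$yield_sd)))
  dplyr::arrange(
    dplyr::select(long, "fragment_id", "day", "phase", "replicate", "yield"),
    .data$fragment_id, .data$day, .data$phase, .data$replicate)
}

gen_weights <- function(frags, eff, nz, D) {
  fr <- arm_lookup(frags, eff)
  n <- nrow(fr)
  area <- stats::rlnorm(n, log(10), 0.10)           # cm^2, ~2-3 cm ramets
  bw0 <- stats::rlnorm(n, log(1.0), 0.15)           # g
  r1 <- fr$calc_baseline * fr$calc_mult_day7 *
    pmax(0.05, 1 + stats::rnorm(n, 0, nz$calc_rate_cv))
  r2 <- fr$calc_baseline * fr$calc_mult_day14 *
    pmax(0.05, 1 + stats::rnorm(n, 0, nz$calc_rate_cv))
  # invert Eq. 2: mass gain over a 7-day interval = rate x A x 7 / 100
  bw7 <- bw0 + r1 * area * 7 / 100
  bw14 <- bw7 + r2 * area * 7 / 100
  meas <- function(w) w + stats::rnorm(n, 0, nz$weight_sd)
  tibble::tibble(
    fragment_id = rep(fr$fragment_id, 3),
    day = rep(c(0L, 7L, 14L), each = n),
    buoyant_weight_g = c(bw0, meas(bw7), meas(bw14)),
    surface_area_cm2 = rep(area, 3)
  ) |> dplyr::arrange(.data$fragment_id, .data$day)
}

gen_census <- function(design, dens_frags, iso_frags, eff, D) {
  des <- arm_lookup(design, eff)
  n <- nrow(des)
  # absorbing Bernoulli first passage matching cumulative probabilities
  u <- stats::runif(n)
  bleach_day <- ifelse(u < des$bleach_prob_day7, 7L,
                       ifelse(u < des$bleach_prob_day14, 14L, NA_integer_))
  removal_day <- rep(NA_integer_, n)
  df <- dens_frags$flat
  slot_day <- c(0L, 7L, 14L)
  removal_day[match(df$fragment_id, des$fragment_id)] <-
    slot_day[df$sample_day_slot]
  removal_day[match(iso_frags$flat$fragment_id, des$fragment_id)] <- 14L
  days <- c(0L, 7L, 14L)
  grid <- tidyr::crossing(tibble::tibble(
    fragment_id = des$fragment_id, .bleach = bleach_day, .remove = removal_day),
    day = days)
  status <- ifelse(!is.na(grid$.remove) & grid$day > grid$.remove, "removed",
                   ifelse(!is.na(grid$.bleach) & grid$day >= grid$.bleach,
                          "bleached", "healthy"))
  tibble::tibble(fragment_id = grid$fragment_id, day = grid$day,
                 status = status) |>
    dplyr::arrange(.data$fragment_id, .data$day)
}

gen_counts <- function(dens_frags, eff, nz, D) {
  fr <- arm_lookup(dens_frags$flat, eff)
  day <- c(0L, 7L, 14L)[fr$sample_day_slot]
  mult <- ifelse(day == 0L, 1,
                 ifelse(day == 7L, fr$density_day7_multiplier,
                        fr$density_day14_multiplier))
  dens <- fr$density_baseline * mult *
    stats::rlnorm(nrow(fr), -nz$density_cv^2 / 2, nz$density_cv)
  area <- stats::rlnorm(nrow(fr), log(10), 0.10)
  dilution <- 1; slurry <- 5; chamber_vol <- 1e-4
  lambda <- dens * area * chamber_vol / (dilution * slurry)
  long <- tidyr::crossing(
    tibble::tibble(fragment_id = fr$fragment_id, day = day,
                   .lambda = lambda, .area = area),
    replicate = 1:3)
  long$chamber_count <- stats::rpois(nrow(long), long$.lambda)
  tibble::tibble(fragment_id = long$fragment_id, day = long$day,
                 chamber_count = long$chamber_count,
                 dilution_factor = dilution, slurry_volume_ml = slurry,
                 surface_area_cm2 = long$.area, replicate = long$replicate) |>
    dplyr::arrange(.data$fragment_id, .data$day, .data$replicate)
}

gen_qpcr <- function(dens_frags, eff, nz, D) {
  fr <- arm_lookup(dens_frags$flat, eff)
  day <- c(0L, 7L, 14L)[fr$sample_day_slot]
  log10_dc <- lin_traj(day, fr$log10_dc_start, fr$log10_dc_end, D) +
    stats::rnorm(nrow(fr), 0, nz$log10_dc_sd)
  delta_ct <- -log10_dc / log10(2)          # CT_D - CT_C
  base <- stats::rnorm(nrow(fr), 16, 0.5)   # dominant-genus CT
  ct_c <- ifelse(delta_ct >= 0, base, base - delta_ct)
  ct_d <- ifelse(delta_ct >= 0, base + delta_ct, base)
  long <- tidyr::crossing(
    tibble::tibble(fragment_id = fr$fragment_id, day = day,
                   .ct_c = ct_c, .ct_d = ct_d),
    primer = c("C", "D"), replicate = 1:3)
  mu <- ifelse(long$primer == "C", long$.ct_c, long$.ct_d)
  long$ct <- stats::rnorm(nrow(long), mu, nz$ct_sd)
  dplyr::select(long, "fragment_id", "day", "primer", "replicate", "ct") |>
    dplyr::arrange(.data$fragment_id, .data$day, .data$primer, .data$replicate)
}

gen_isotopes <- function(design, iso_frags, eff, nz,
                         incubation_hours = 24, tracer_umol = 70,
                         ambient_dic_umol = 2000) {
  fr <- arm_lookup(iso_frags$flat, eff)
  n <- nrow(fr)
  a_nat <- atom_percent(fr$natural_delta13c)
  a_dic <- (ambient_dic_umol * a_nat + tracer_umol * 99) /
    (ambient_dic_umol + tracer_umol)
  u_tot <- fr$carbon_fixation_rate *
    stats::rlnorm(n, -nz$uptake_cv^2 / 2, nz$uptake_cv)
  f <- pmin(0.95, pmax(0.05, fr$translocation_fraction +
                         stats::rnorm(n, 0, nz$translocation_sd)))
  mk <- function(frac, uptake) {
    a_s <- a_nat + uptake * incubation_hours * (a_dic - a_nat)
    tibble::tibble(fragment_id = fr$fragment_id, fraction = frac, labeled = 1L,
                   delta13c_permil = delta13c_from_atom_percent(a_s) +
                     stats::rnorm(n, 0, nz$delta13c_sd),
                   organic_carbon_ug = stats::rlnorm(n, log(500), 0.2))
  }
  labeled <- dplyr::bind_rows(mk("host", f * u_tot),
                              mk("symbiont", (1 - f) * u_tot))
  # one unlabeled control fragment per tank per holobiont, both fractions
  ctrl_frags <- design |>
    dplyr::anti_join(fr["fragment_id"], by = "fragment_id") |>
    dplyr::group_by(.data$holobiont, .data$tank) |>
    dplyr::slice_max(.data$index, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  eff_ctrl <- arm_lookup(ctrl_frags, eff)
  nat <- tidyr::crossing(
    tibble::tibble(fragment_id = eff_ctrl$fragment_id,
                   .base = eff_ctrl$natural_delta13c),
    fraction = c("host", "symbiont"))
  nat$labeled <- 0L
  nat$delta13c_permil <- nat$.base + stats::rnorm(nrow(nat), 0, nz$delta13c_sd)
  nat$organic_carbon_ug <- stats::rlnorm(nrow(nat), log(500), 0.2)
  dplyr::bind_rows(labeled,
                   dplyr::select(nat, "fragment_id", "fraction", "labeled",
                                 "delta13c_permil", "organic_carbon_ug")) |>
    dplyr::arrange(.data$fragment_id, .data$fraction, .data$labeled)
}

# ITS2 clone libraries: dominant-genus metahaplotypes only, 20 clones per
# library. The non-dominant genus sits at ~1e-5 of the community or below,
# far under the detection floor of a 20-clone Sanger library, so cross-genus
# types never appear in clone data (they are visible only to qPCR).
gen_clones <- function(dens_frags, design, clones_per_sample = 20L) {
  fr <- dens_frags$flat
  fr$day <- c(0L, 7L, 14L)[fr$sample_day_slot]
  pre <- fr[fr$day == 0L & fr$temperature == 26, ]
  pre$stage <- "pretreatment"
  end <- fr[fr$day == 14L, ]
  end$stage <- "end"
  samp <- dplyr::bind_rows(pre, end)
  type_profiles <- list(
    PdC = c(C42 = 0.50, C1 = 0.30, C1b = 0.12, C1c = 0.08),
    PdD = c(D1 = 0.55, D4 = 0.30, D6 = 0.15))
  rows <- lapply(seq_len(nrow(samp)), function(i) {
    h <- samp$holobiont[i]
    p <- type_profiles[[h]]
    counts <- as.vector(stats::rmultinom(1, clones_per_sample, p))
    keep <- counts > 0
    tibble::tibble(fragment_id = samp$fragment_id[i], stage = samp$stage[i],
                   its2_type = names(p)[keep], clone_count = counts[keep])
  })
  dplyr::bind_rows(rows)
}

#' Tiny deterministic worked example
#'
#' A two-fragment, no-noise fixture whose downstream metrics are
#' hand-computable: Fv/Fm = 0.60 with dF/Fm' = 0.30 gives Qm = 0.5;
#' buoyant weight 1.000 g growing to 1.014 g over 7 days on 10 cm^2 gives a
#' calcification rate of 0.02; qPCR CT_C = 20 with CT_D = 30 gives
#' D/C = 2^-10.
#'
#' @return An [assay_set()] with two fragments and two sampling days.
#' @export
generate_worked_microexample <- function() {
  design <- tibble::tibble(
    fragment_id = c("PdC-1-1-1", "PdC-1-4-1"),
    holobiont = "PdC", colony = 1L, tank = c(1L, 4L),
    temperature = c(26, 32))
  pam <- tidyr::crossing(fragment_id = design$fragment_id, day = c(0L, 7L),
                         phase = c("dark", "light"), replicate = 1L)
  pam$yield <- ifelse(pam$phase == "dark", 0.60, 0.30)
  weights <- tidyr::crossing(fragment_id = design$fragment_id,
                             day = c(0L, 7L))
  weights$buoyant_weight_g <- ifelse(weights$day == 0L, 1.000, 1.014)
  weights$surface_area_cm2 <- 10
  counts <- tidyr::crossing(fragment_id = design$fragment_id, day = 0L,
                            replicate = 1:3)
  counts$chamber_count <- c(50L, 48L, 52L)[counts$replicate]
  counts$dilution_factor <- 10
  counts$slurry_volume_ml <- 5
  counts$surface_area_cm2 <- 5
  counts <- dplyr::select(counts, "fragment_id", "day", "chamber_count",
                          "dilution_factor", "slurry_volume_ml",
                          "surface_area_cm2", "replicate")
  census <- tidyr::crossing(fragment_id = design$fragment_id, day = c(0L, 7L))
  census$status <- "healthy"
  qpcr <- tidyr::crossing(fragment_id = design$fragment_id, day = 0L,
                          primer = c("C", "D"), replicate = 1L)
  qpcr$ct <- ifelse(qpcr$primer == "C", 20, 30)
  assay_set(design = design, pam = pam, weights = weights, counts = counts,
            census = census, qpcr = qpcr,
            metadata = list(preset = "microexample"))
}
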