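# Quantum-yield metrics: maximum excitation pressure over PSII and its
# thermal-adjustment contrast between heated and control arms.

#' Pair dark- and light-phase PAM yields
#'
#' Replicate yields are averaged per fragment-day-phase at the measurement
#' level (triplicate readings exist to minimize instrument variation, so the
#' mean is taken before any derived quantity). A pair is emitted only when
#' both phases were measured that day; unpaired fragment-days are returned
#' in a skip list attribute and signalled as a warning.
#'
#' @param pam Tibble of PAM records (fragment_id, day, phase, replicate,
#'   yield) with phase "dark" (Fv/Fm) or "light" (dF/Fm').
#' @return Tibble with columns fragment_id, day, fv_fm, df_fm_prime and an
#'   attribute `skipped` listing unpaired fragment-days.
#' @export
pair_yields <- function(pam) {
  if (nrow(pam) == 0) {
    out <- tibble::tibble(fragment_id = character(0), day = integer(0),
                          fv_fm = numeric(0), df_fm_prime = numeric(0))
    attr(out, "skipped") <- out[c("fragment_id", "day")]
    return(out)
  }
  means <- pam |>
    dplyr::group_by(.data$fragment_id, .data$day, .data$phase) |>
    dplyr::summarise(yield = mean(.data$yield, na.rm = TRUE),
                     .groups = "drop")
  wide <- tidyr::pivot_wider(means, names_from = "phase",
                             values_from = "yield")
  if (!"dark" %in% names(wide)) wide$dark <- NA_real_
  if (!"light" %in% names(wide)) wide$light <- NA_real_
  skipped <- wide[is.na(wide$dark) | is.na(wide$light),
                  c("fragment_id", "day")]
  if (nrow(skipped) > 0) {
    warn(sprintf("%d fragment-day(s) lacked a dark/light pair and were skipped",
                 nrow(skipped)))
  }
  out <- wide[!is.na(wide$dark) & !is.na(wide$light), ]
  out <- tibble::tibble(fragment_id = out$fragment_id, day = out$day,
                        fv_fm = out$dark, df_fm_prime = out$light)
  attr(out, "skipped") <- skipped
  out
}

#' Maximum excitation pressure over PSII
#'
#' Qm = 1 - (dF/Fm') / (Fv/Fm), the fraction of PSII reaction centres closed
#' under ambient light. Qm is scale-invariant in the yield pair and lies in
#' [0, 1] whenever the light yield does not exceed the dark yield; negative
#' values (light above dark) are retained and flagged rather than truncated,
#' to avoid biasing group means.
#'
#' @param pairs Tibble from [pair_yields()] (or any tibble with fv_fm and
#'   df_fm_prime columns).
#' @return Input with columns `qm` and logical `flagged_negative`; pairs
#'   with Fv/Fm = 0 are dropped with a warning (Qm undefined).
#' @export
compute_qm <- function(pairs) {
  undef <- pairs$fv_fm <= 0
  if (any(undef)) {
    warn(sprintf("%d pair(s) with Fv/Fm = 0 excluded (Qm undefined)",
                 sum(undef)))
    pairs <- pairs[!undef, ]
  }
  pairs$qm <- 1 - pairs$df_fm_prime / pairs$fv_fm
  pairs$flagged_negative <- pairs$qm < 0
  pairs
}

#' Thermal adjustment of excitation pressure (delta Qm)
#'
#' For each holobiont, the mean Qm over heated fragments minus the mean Qm
#' over control fragments: per day, or pooled over the stress phase (days 1
#' through the end) when `pooling = "overall"`. The standard error is
#' propagated from the two group standard errors in quadrature.
#'
#' @param qm Tibble from [compute_qm()] (fragment_id, day, qm).
#' @param design Design tibble with fragment_id, holobiont, temperature.
#' @param pooling `"per_day"` or `"overall"`.
#' @return Tibble with holobiont, day (`"overall"` when pooled), delta_qm,
#'   se, and the two group means.
#' @export
compute_delta_qm <- function(qm, design, pooling = c("overall", "per_day")) {
  pooling <- match.arg(pooling)
  dat <- join_design(qm, design)
  if (pooling == "overall") {
    dat <- dat[dat$day >= 1, ]
    dat$day_group <- "overall"
  } else {
    dat$day_group <- as.character(dat$day)
  }
  grp <- dat |>
    dplyr::group_by(.data$holobiont, .data$day_group, .data$temperature) |>
    dplyr::summarise(mean_qm = mean(.data$qm),
                     se_qm = stats::sd(.data$qm) / sqrt(dplyr::n()),
                     .groups = "drop")
  wide <- tidyr::pivot_wider(grp, names_from = "temperature",
                             values_from = c("mean_qm", "se_qm"))
  if (!all(c("mean_qm_26", "mean_qm_32") %in% names(wide))) {
    missing_arm <- setdiff(c("26", "32"),
                           unique(as.character(grp$temperature)))
    abort(sprintf("missing temperature arm(s) %s for delta-Qm",
                  paste(missing_arm, collapse = ", ")),
          class = "holotherm_integrity_error")
  }
  incomplete <- is.na(wide$mean_qm_26) | is.na(wide$mean_qm_32)
  if (any(incomplete)) {
    bad <- unique(wide$holobiont[incomplete])
    abort(sprintf("holobiont %s lacks one temperature arm",
                  paste(bad, collapse = ", ")),
          class = "holotherm_integrity_error")
  }
  tibble::tibble(
    holobiont = wide$holobiont, day = wide$day_group,
    delta_qm = wide$mean_qm_32 - wide$mean_qm_26,
    se = sqrt(wide$se_qm_32^2 + wide$se_qm_26^2),
    mean_qm_heated = wide$mean_qm_32, mean_qm_control = wide$mean_qm_26)
}
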