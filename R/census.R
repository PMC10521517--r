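# Areal Symbiodiniaceae density from hemocytometer counts and bleaching
# rates over the fate-tracked fragment census.

#' Areal Symbiodiniaceae density
#'
#' Replicate chamber counts are averaged per fragment-day, converted to a
#' cell concentration via the chamber volume (default 1e-4 mL, the standard
#' Neubauer large-square volume; configurable for other counting rules),
#' scaled by dilution and slurry volume, and normalized to fragment surface
#' area:
#' density = mean(count) / chamber_volume x dilution x slurry / area.
#'
#' @param counts Tibble (fragment_id, day, chamber_count, dilution_factor,
#'   slurry_volume_ml, surface_area_cm2, replicate).
#' @param chamber_volume_ml Counting-chamber volume per replicate count, mL.
#' @return Tibble with fragment_id, day, density (cells cm^-2).
#' @export
areal_density <- function(counts, chamber_volume_ml = 1e-4) {
  if (nrow(counts) == 0) {
    return(tibble::tibble(fragment_id = character(0), day = integer(0),
                          density = numeric(0)))
  }
  meta_check <- counts |>
    dplyr::group_by(.data$fragment_id, .data$day) |>
    dplyr::summarise(
      n_meta = dplyr::n_distinct(.data$dilution_factor, .data$slurry_volume_ml,
                                 .data$surface_area_cm2),
      .groups = "drop")
  if (any(meta_check$n_meta > 1)) {
    abort("replicate counts disagree on dilution/slurry/area metadata",
          class = "holotherm_integrity_error")
  }
  counts |>
    dplyr::group_by(.data$fragment_id, .data$day) |>
    dplyr::summarise(
      density = mean(.data$chamber_count) / chamber_volume_ml *
        .data$dilution_factor[1] * .data$slurry_volume_ml[1] /
        .data$surface_area_cm2[1],
      .groups = "drop")
}

#' Bleaching rate among remaining fragments
#'
#' The percentage of bleached fragments among all remaining fragments of a
#' group at a given day. "Remaining" excludes fragments removed
#' (destructively sampled) before that day and includes currently bleached
#' ones: rate = 100 x #bleached / (#total - #removed).
#'
#' @param census Tibble (fragment_id, day, status) with status healthy /
#'   bleached / removed.
#' @param design Design tibble (fragment_id, holobiont, temperature).
#' @param day Census day at which to evaluate.
#' @return Tibble with holobiont, temperature, n_remaining, n_bleached,
#'   bleaching_rate (percent).
#' @export
bleaching_rate <- function(census, design, day) {
  snap <- census[census$day == day, ]
  snap <- join_design(snap, design)
  out <- snap |>
    dplyr::group_by(.data$holobiont, .data$temperature) |>
    dplyr::summarise(
      n_remaining = sum(.data$status != "removed"),
      n_bleached = sum(.data$status == "bleached"),
      .groups = "drop")
  if (any(out$n_remaining == 0)) {
    abort("no remaining fragments in at least one group: rate undefined",
          class = "holotherm_domain_error")
  }
  out$bleaching_rate <- 100 * out$n_bleached / out$n_remaining
  out$day <- day
  out
}
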