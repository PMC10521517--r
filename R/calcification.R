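# Buoyant-weight calcification: daily skeletal mass increase normalized to
# initial surface area, rate = (BW_final - BW_initial) / A_initial x
# (1 / days) x 100. The x100 factor is reproduced literally, so the unit is
# (g cm^-2 d^-1) x 100; negative rates (dissolution) are allowed.

#' Calcification rate from a weight pair
#'
#' @param bw_initial,bw_final Buoyant weights (g) at the interval endpoints.
#' @param a_initial Initial (day-0) skeletal surface area, cm^2.
#' @param days Interval length in days.
#' @return Rate in (g cm^-2 d^-1) x 100.
#' @export
calcification_rate <- function(bw_initial, bw_final, a_initial, days) {
  if (any(a_initial <= 0)) {
    abort("a_initial must be positive", class = "holotherm_domain_error")
  }
  if (any(days <= 0)) {
    abort("days must be positive", class = "holotherm_domain_error")
  }
  (bw_final - bw_initial) / a_initial * (1 / days) * 100
}

#' Per-fragment calcification rates over weighing intervals
#'
#' Uses the day-0 surface area (A_initial) for every interval; later-day
#' areas, if recorded, are ignored. Fragments missing a weight at either
#' endpoint of an interval are skipped for that interval with a warning.
#'
#' @param weights Tibble (fragment_id, day, buoyant_weight_g,
#'   surface_area_cm2).
#' @param intervals List of 2-vectors `c(start, end)` in days; default the
#'   weekly intervals 0-7 and 7-14.
#' @return Tibble with fragment_id, day_start, day_end, rate.
#' @export
interval_rates <- function(weights, intervals = list(c(0, 7), c(7, 14))) {
  a0 <- weights[weights$day == 0, c("fragment_id", "surface_area_cm2")]
  names(a0)[2] <- "a_initial"
  rows <- lapply(intervals, function(iv) {
    w1 <- weights[weights$day == iv[1], c("fragment_id", "buoyant_weight_g")]
    w2 <- weights[weights$day == iv[2], c("fragment_id", "buoyant_weight_g")]
    names(w1)[2] <- "bw_initial"; names(w2)[2] <- "bw_final"
    d <- dplyr::inner_join(w1, w2, by = "fragment_id")
    d <- dplyr::inner_join(d, a0, by = "fragment_id")
    n_skipped <- dplyr::n_distinct(weights$fragment_id) - nrow(d)
    if (n_skipped > 0) {
      warn(sprintf("%d fragment(s) missing an endpoint weight for interval %d-%d",
                   n_skipped, iv[1], iv[2]))
    }
    tibble::tibble(
      fragment_id = d$fragment_id, day_start = iv[1], day_end = iv[2],
      rate = calcification_rate(d$bw_initial, d$bw_final, d$a_initial,
                                iv[2] - iv[1]))
  })
  dplyr::bind_rows(rows)
}
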