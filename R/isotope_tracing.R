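# 13C tracer uptake: natural-abundance correction, validity filtering and
# host/symbiont translocation partitioning. Uptake follows the classical
# atom-percent-excess form: the tracer carbon incorporated per unit tissue
# carbon over the incubation, normalized per hour.

R_VPDB <- 0.0112372  # 13C/12C of the VPDB standard

#' Convert delta-13C to atom percent 13C
#'
#' R = R_VPDB x (1 + delta/1000); atom% = 100 x R / (1 + R).
#'
#' @param delta13c Per-mil deviation from VPDB. Must exceed -1000 (the
#'   physical lower bound where the isotope ratio reaches zero).
#' @return Atom percent 13C.
#' @export
atom_percent <- function(delta13c) {
  if (any(delta13c <= -1000, na.rm = TRUE)) {
    abort("delta13c must be > -1000 permil", class = "holotherm_domain_error")
  }
  r <- R_VPDB * (1 + delta13c / 1000)
  100 * r / (1 + r)
}

#' Convert atom percent 13C back to delta-13C
#'
#' Inverse of [atom_percent()].
#'
#' @param ap Atom percent 13C, in (0, 100).
#' @return Per-mil deviation from VPDB.
#' @export
delta13c_from_atom_percent <- function(ap) {
  r <- ap / (100 - ap)
  (r / R_VPDB - 1) * 1000
}

#' Atom percent of the incubation-medium DIC after tracer addition
#'
#' Mixes the labeled bicarbonate spike (default 70 umol/L at 99 atom% 13C)
#' into the ambient dissolved inorganic carbon pool (default 2000 umol/L at
#' the natural atom percent).
#'
#' @param natural_atom_percent Atom percent of the ambient DIC.
#' @param tracer_umol Tracer concentration, umol/L.
#' @param tracer_atom_percent Isotopic purity of the tracer, atom percent.
#' @param ambient_dic_umol Ambient DIC concentration, umol/L.
#' @return Atom percent 13C of the mixed DIC pool.
#' @export
dic_atom_percent <- function(natural_atom_percent, tracer_umol = 70,
                             tracer_atom_percent = 99,
                             ambient_dic_umol = 2000) {
  (ambient_dic_umol * natural_atom_percent + tracer_umol * tracer_atom_percent) /
    (ambient_dic_umol + tracer_umol)
}

#' Tracer uptake rates with validity filtering
#'
#' For each labeled sample, uptake = [(a_s - a_n) / (a_DIC - a_n)] x
#' (1 / incubation_hours) where a_s, a_n and a_DIC are the atom percents of
#' the labeled sample, its natural (unlabeled) control and the incubation
#' medium DIC. The result is tracer carbon per tissue carbon per hour
#' (C_tracer / C_tissue normalization). A sample is valid only when its
#' isotopic ratio exceeds the natural baseline (a_s > a_n); invalid samples
#' carry no uptake value. The natural baseline is the tank-matched unlabeled
#' control of the same holobiont and fraction, falling back to the
#' holobiont-wide unlabeled mean when no tank control exists.
#'
#' @param isotopes Isotope tibble (fragment_id, fraction, labeled,
#'   delta13c_permil, organic_carbon_ug).
#' @param design Design tibble.
#' @param incubation_hours Incubation length, h.
#' @param tracer_umol,ambient_dic_umol Tracer and ambient DIC
#'   concentrations, umol/L, defining a_DIC via [dic_atom_percent()].
#' @return Tibble with fragment_id, fraction, holobiont, temperature,
#'   uptake (h^-1, NA when invalid) and logical valid.
#' @export
tracer_uptake <- function(isotopes, design, incubation_hours = 24,
                          tracer_umol = 70, ambient_dic_umol = 2000) {
  iso <- join_design(isotopes, design)
  iso$ap <- atom_percent(iso$delta13c_permil)
  nat <- iso[iso$labeled == 0, ]
  nat_tank <- nat |>
    dplyr::group_by(.data$holobiont, .data$tank, .data$fraction) |>
    dplyr::summarise(a_n_tank = mean(.data$ap), .groups = "drop")
  nat_holo <- nat |>
    dplyr::group_by(.data$holobiont, .data$fraction) |>
    dplyr::summarise(a_n_holo = mean(.data$ap), .groups = "drop")
  lab <- iso[iso$labeled == 1, ]
  lab <- dplyr::left_join(lab, nat_tank,
                          by = c("holobiont", "tank", "fraction"))
  lab <- dplyr::left_join(lab, nat_holo, by = c("holobiont", "fraction"))
  lab$a_n <- ifelse(is.na(lab$a_n_tank), lab$a_n_holo, lab$a_n_tank)
  if (any(is.na(lab$a_n))) {
    abort("no unlabeled control available for at least one holobiont/fraction",
          class = "holotherm_integrity_error")
  }
  a_dic <- dic_atom_percent(mean(nat$ap), tracer_umol = tracer_umol,
                            ambient_dic_umol = ambient_dic_umol)
  if (any(a_dic <= lab$a_n)) {
    abort("DIC atom percent does not exceed the natural baseline",
          class = "holotherm_config_error")
  }
  lab$valid <- lab$ap > lab$a_n
  lab$uptake <- ifelse(
    lab$valid,
    (lab$ap - lab$a_n) / (a_dic - lab$a_n) / incubation_hours,
    NA_real_)
  dplyr::select(lab, "fragment_id", "fraction", "holobiont", "temperature",
                "uptake", "valid")
}

#' Group-level translocation summary
#'
#' Per holobiont x temperature arm: mean host and symbiont uptake, the
#' fragment-level translocation fraction host / (host + symbiont) averaged
#' over fragments, and per holobiont the ordinary least-squares slope of
#' host uptake against total uptake with its 95% CI (the partitioning
#' efficiency; a temperature term tests whether the slope shifts with arm).
#'
#' @param uptakes Tibble from [tracer_uptake()].
#' @return List with `groups` (per-arm means and fractions) and `slopes`
#'   (per-holobiont slope, CI, and the p-value of the slope-by-temperature
#'   interaction; NA where fewer than 2 valid pairs exist).
#' @export
summarize_translocation <- function(uptakes) {
  wide <- uptakes[uptakes$valid %in% TRUE, ] |>
    dplyr::select("fragment_id", "fraction", "holobiont", "temperature",
                  "uptake") |>
    tidyr::pivot_wider(names_from = "fraction", values_from = "uptake")
  if (!"host" %in% names(wide)) wide$host <- NA_real_
  if (!"symbiont" %in% names(wide)) wide$symbiont <- NA_real_
  wide <- wide[!is.na(wide$host) & !is.na(wide$symbiont), ]
  wide$total <- wide$host + wide$symbiont
  wide$translocation_fraction <- ifelse(wide$total > 0,
                                        wide$host / wide$total, NA_real_)
  groups <- wide |>
    dplyr::group_by(.data$holobiont, .data$temperature) |>
    dplyr::summarise(host_uptake = mean(.data$host),
                     symbiont_uptake = mean(.data$symbiont),
                     translocation_fraction = mean(.data$translocation_fraction),
                     n = dplyr::n(), .groups = "drop")
  slopes <- lapply(unique(wide$holobiont), function(h) {
    d <- wide[wide$holobiont == h, ]
    if (nrow(d) < 2) {
      return(tibble::tibble(holobiont = h, slope = NA_real_,
                            ci_lo = NA_real_, ci_hi = NA_real_,
                            p_temperature_interaction = NA_real_))
    }
    fit <- stats::lm(host ~ total, data = d)
    ci <- stats::confint(fit)["total", ]
    p_int <- NA_real_
    if (dplyr::n_distinct(d$temperature) > 1 && nrow(d) >= 4) {
      fit2 <- stats::lm(host ~ total * factor(temperature), data = d)
      cf <- summary(fit2)$coefficients
      int_row <- grep("total:", rownames(cf))
      if (length(int_row) == 1) p_int <- cf[int_row, 4]
    }
    tibble::tibble(holobiont = h, slope = unname(stats::coef(fit)["total"]),
                   ci_lo = ci[1], ci_hi = ci[2],
                   p_temperature_interaction = p_int)
  })
  list(groups = groups, slopes = dplyr::bind_rows(slopes),
       fragments = wide)
}
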