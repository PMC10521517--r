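# Expected atom percents frozen from direct evaluation of the two-step
# closed form at R_VPDB = 0.0112372 (see atom_percent docs).
test_that("delta-13C to atom percent follows the VPDB closed form", {
  expect_equal(atom_percent(0), 1.11123, tolerance = 1e-5)
  expect_equal(atom_percent(1000), 2.19804, tolerance = 1e-5)
  expect_error(atom_percent(-1000), class = "holotherm_domain_error")
  # strictly monotone transform
  deltas <- seq(-900, 900, by = 90)
  expect_true(all(diff(atom_percent(deltas)) > 0))
  # round-trip with the inverse
  expect_equal(delta13c_from_atom_percent(atom_percent(deltas)), deltas,
               tolerance = 1e-9)
})

test_that("DIC atom percent mixes tracer into the ambient pool", {
  a_nat <- atom_percent(-15)
  a_dic <- dic_atom_percent(a_nat)
  expect_equal(a_dic, (2000 * a_nat + 70 * 99) / 2070, tolerance = 1e-12)
  expect_gt(a_dic, a_nat)
})

# Build a minimal labeled/control isotope table with known atom percents.
iso_fixture <- function(a_s_host, a_s_symb, a_n = atom_percent(-15)) {
  design <- tiny_design()
  d_n <- delta13c_from_atom_percent(a_n)
  labeled <- tidyr::crossing(fragment_id = design$fragment_id[c(2, 4)],
                             fraction = c("host", "symbiont"))
  labeled$labeled <- 1L
  labeled$delta13c_permil <- delta13c_from_atom_percent(
    ifelse(labeled$fraction == "host", a_s_host, a_s_symb))
  labeled$organic_carbon_ug <- 500
  controls <- tidyr::crossing(fragment_id = design$fragment_id[c(1, 3)],
                              fraction = c("host", "symbiont"))
  controls$labeled <- 0L
  controls$delta13c_permil <- d_n
  controls$organic_carbon_ug <- 500
  list(iso = dplyr::bind_rows(labeled, controls), design = design)
}

test_that("uptake reproduces the hand-evaluated ratio formula", {
  # a_n = 1.112, a_DIC = 2.300, a_s = 1.231, 24 h -> (0.119/1.188)/24
  fx <- iso_fixture(a_s_host = 1.231, a_s_symb = 1.231, a_n = 1.112)
  # choose ambient/tracer so the mixed DIC pool sits at 2.300 atom%
  tracer <- 2000 * (2.300 - 1.112) / (99 - 2.300)
  up <- tracer_uptake(fx$iso, fx$design, incubation_hours = 24,
                      tracer_umol = tracer, ambient_dic_umol = 2000)
  expect_true(all(up$valid))
  expect_equal(unique(round(up$uptake, 7)), 4.173681e-3, tolerance = 1e-4)
})

test_that("full-equilibration and boundary cases behave algebraically", {
  a_n <- atom_percent(-15)
  a_dic <- dic_atom_percent(a_n)
  fx <- iso_fixture(a_s_host = a_dic, a_s_symb = a_n)
  up <- tracer_uptake(fx$iso, fx$design, incubation_hours = 24)
  host <- up[up$fraction == "host", ]
  symb <- up[up$fraction == "symbiont", ]
  expect_equal(host$uptake, rep(1 / 24, 2), tolerance = 1e-6)
  # a_s == a_n sits on the filter boundary: invalid, no uptake value
  expect_true(all(!symb$valid | abs(symb$uptake) < 1e-9))
})

test_that("the validity filter is sound: no valid sample at or below baseline", {
  set.seed(99)
  a_n <- atom_percent(-15)
  for (i in 1:20) {
    a_host <- a_n + runif(1, -0.05, 0.2)
    a_symb <- a_n + runif(1, -0.05, 0.2)
    fx <- iso_fixture(a_host, a_symb)
    up <- tracer_uptake(fx$iso, fx$design)
    expect_true(all(is.na(up$uptake[!up$valid])))
    expect_true(all(up$uptake[up$valid] > 0))
  }
})

test_that("a DIC pool below the baseline is a configuration error", {
  fx <- iso_fixture(a_s_host = 1.2, a_s_symb = 1.2)
  expect_error(tracer_uptake(fx$iso, fx$design, tracer_umol = 0),
               class = "holotherm_config_error")
})

test_that("translocation fractions are bounded and symmetric inputs give 0.5", {
  a_n <- atom_percent(-15)
  a_dic <- dic_atom_percent(a_n)
  a_s <- a_n + 0.4 * (a_dic - a_n)
  fx <- iso_fixture(a_s, a_s)
  up <- tracer_uptake(fx$iso, fx$design)
  s <- summarize_translocation(up)
  expect_true(all(s$groups$translocation_fraction == 0.5))
  expect_true(all(s$fragments$translocation_fraction >= 0 &
                    s$fragments$translocation_fraction <= 1))
})

test_that("degenerate single-observation groups report means but no slope", {
  a_n <- atom_percent(-15)
  a_dic <- dic_atom_percent(a_n)
  fx <- iso_fixture(a_n + 0.3 * (a_dic - a_n), a_n + 0.2 * (a_dic - a_n))
  up <- tracer_uptake(fx$iso, fx$design)
  one <- up[up$fragment_id == up$fragment_id[1], ]
  s <- summarize_translocation(one)
  expect_equal(nrow(s$groups), 1)
  expect_true(is.na(s$slopes$slope))
})

test_that("synthetic isotopes recover fixation and translocation parameters", {
  runs <- lapply(1:8, function(s) {
    a <- generate_assay_set(paper_default_config(seed = s))
    tr <- summarize_translocation(tracer_uptake(a$isotopes, a$design))
    g <- tr$groups
    tot <- g$host_uptake + g$symbiont_uptake
    tibble::tibble(
      holobiont = g$holobiont, temperature = g$temperature,
      total = tot, frac = g$translocation_fraction,
      slope_pdc = tr$slopes$slope[tr$slopes$holobiont == "PdC"],
      slope_pdd = tr$slopes$slope[tr$slopes$holobiont == "PdD"],
      p_int_pdc = tr$slopes$p_temperature_interaction[
        tr$slopes$holobiont == "PdC"])
  })
  runs <- dplyr::bind_rows(runs)
  m <- function(h, t, col) mean(runs[[col]][runs$holobiont == h &
                                              runs$temperature == t])
  se <- function(h, t, col) {
    x <- runs[[col]][runs$holobiont == h & runs$temperature == t]
    stats::sd(x) / sqrt(length(x))
  }
  expect_lt(abs(m("PdC", 26, "total") - 4.0e-3),
            3 * se("PdC", 26, "total") + 2e-4)
  expect_lt(abs(m("PdC", 32, "total") - 1.6e-3),
            3 * se("PdC", 32, "total") + 2e-4)
  expect_lt(abs(m("PdD", 26, "frac") - 0.30), 3 * se("PdD", 26, "frac") + 0.02)
  expect_lt(abs(m("PdC", 26, "frac") - 0.45), 3 * se("PdC", 26, "frac") + 0.02)
  # PdC partitions more efficiently; its slope does not shift with arm
  expect_gt(mean(runs$slope_pdc), mean(runs$slope_pdd))
  expect_gt(mean(runs$p_int_pdc > 0.05), 0.7)
})
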