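test_that("assumption checks route clean data parametric, heavy tails nonparametric", {
  set.seed(21)
  vals <- rnorm(60)
  grp <- rep(c("a", "b"), each = 30)
  ch <- assumption_checks(vals, grp)
  expect_equal(ch$route, "parametric")
  heavy <- rcauchy(60)
  ch2 <- assumption_checks(heavy, grp)
  expect_equal(ch2$route, "kruskal")
  # groups below n = 3 are 'insufficient' and routed nonparametric
  ch3 <- suppressWarnings(assumption_checks(rnorm(4), rep(c("a", "b"), 2)))
  expect_true(all(ch3$shapiro$verdict == "insufficient"))
  expect_equal(ch3$route, "kruskal")
  # constant group: homogeneity undefined, flagged
  ch4 <- assumption_checks(c(1, 1, 1, rnorm(3)), rep(c("a", "b"), each = 3))
  expect_true(is.na(ch4$levene_p))
  expect_false(ch4$homogeneous)
})

test_that("omnibus with Tukey runs post hoc only when significant", {
  set.seed(33)
  d <- data.frame(y = c(rnorm(20, 0), rnorm(20, 3)),
                  g = rep(c("a", "b"), each = 20))
  res <- omnibus_and_posthoc(d, "y", "g", route = "parametric")
  expect_true(res$significant)
  expect_false(is.null(res$posthoc))
  d2 <- data.frame(y = rep(c(1.0, 1.1, 0.9, 1.05), 2),
                   g = rep(c("a", "b"), each = 4))
  res2 <- omnibus_and_posthoc(d2, "y", "g", route = "parametric")
  expect_gt(res2$p_value, 0.9)
  expect_null(res2$posthoc)
  res3 <- omnibus_and_posthoc(d, "y", "g", route = "kruskal")
  expect_equal(res3$test, "kruskal-wallis")
})

test_that("an empty three-way cell is an error naming the cell", {
  set.seed(8)
  d <- expand.grid(t = c(26, 32), day = c(7, 14), h = c("PdC", "PdD"))
  d <- d[rep(1:8, 3), ]
  d$y <- rnorm(nrow(d))
  d <- d[!(d$t == 32 & d$day == 14 & d$h == "PdD"), ]
  expect_error(omnibus_and_posthoc(d, "y", c("t", "day", "h")),
               regexp = "empty design cell",
               class = "holotherm_domain_error")
})

test_that("paper-default data flag PdC heat contrasts but not PdD", {
  flags <- lapply(1:6, function(s) {
    a <- generate_assay_set(paper_default_config(seed = s))
    d <- dplyr::left_join(areal_density(a$counts), a$design,
                          by = "fragment_id")
    d14 <- d[d$day == 14, ]
    q <- compute_qm(pair_yields(a$pam))
    q14 <- dplyr::left_join(q[q$day == 14, ], a$design, by = "fragment_id")
    get_p <- function(dd, resp) {
      vapply(c("PdC", "PdD"), function(h) {
        omnibus_and_posthoc(dd[dd$holobiont == h, ], resp, "temperature",
                            route = "parametric")$p_value
      }, numeric(1))
    }
    c(dens = get_p(d14, "density"), fvfm = get_p(q14, "fv_fm"))
  })
  flags <- do.call(rbind, flags)
  expect_true(all(flags[, "dens.PdC"] < 0.05))
  expect_true(all(flags[, "fvfm.PdC"] < 0.05))
  expect_gt(mean(flags[, "dens.PdD"] >= 0.05), 0.5)
  expect_gt(mean(flags[, "fvfm.PdD"] >= 0.05), 0.5)
})

test_that("mixed-effects screen recovers injected variance components", {
  set.seed(55)
  base <- expand.grid(tank = 1:6, colony = 1:3, rep = 1:4)
  base$temperature <- ifelse(base$tank <= 3, 26, 32)
  # zero tank variance, zero colony variance
  d0 <- base
  d0$y <- 0.5 * (d0$temperature == 32) + rnorm(nrow(d0), sd = 1)
  s0 <- mixed_effects_screen(d0, "y", fixed = "temperature")
  tank_share <- s0$variance_shares$share[s0$variance_shares$component == "tank"]
  expect_lt(tank_share, 0.15)
  # large colony effect dominates
  d1 <- base
  colony_fx <- c(-3, 0, 3)
  d1$y <- colony_fx[d1$colony] + rnorm(nrow(d1), sd = 0.5)
  s1 <- mixed_effects_screen(d1, "y", fixed = "temperature")
  shares <- s1$variance_shares
  expect_gt(shares$share[shares$component == "colony"], 0.5)
  expect_equal(
    s1$random_verdicts$verdict[grepl("colony", s1$random_verdicts$term)],
    "substantial")
  # fewer than 2 levels in a random factor is an error
  expect_error(mixed_effects_screen(d0[d0$tank == 1, ], "y", "temperature"),
               class = "holotherm_domain_error")
})

test_that("paper-default mixed screen flags genotype/temperature, not tank/colony", {
  a <- generate_assay_set(paper_default_config(seed = 9))
  q <- compute_qm(pair_yields(a$pam))
  q14 <- dplyr::left_join(q[q$day >= 7, ], a$design, by = "fragment_id")
  s <- mixed_effects_screen(q14, "qm",
                            fixed = c("temperature", "day", "holobiont"))
  fe <- s$fixed_effects
  expect_true(fe$significant[fe$term == "temperature"])
  expect_true(fe$significant[fe$term == "holobiont"])
  expect_true(all(s$random_verdicts$verdict == "negligible"))
})

test_that("the consolidated report is complete and flags omitted stages", {
  a <- generate_assay_set(paper_default_config(seed = 6))
  rep_full <- build_report(a)
  expect_s3_class(rep_full, "metrics_report")
  expect_true(all(c("qm", "delta_qm", "calcification", "density",
                    "bleaching", "dc", "dc_trajectory", "uptake",
                    "translocation", "dominance") %in%
                    names(rep_full$metrics)))
  expect_length(rep_full$gaps, 0)
  expect_false(is.null(rep_full$pca))
  expect_gte(ncol(rep_full$pca$loadings), 2)
  expect_equal(nrow(rep_full$pca$loadings), 7)  # seven traits
  # omitting photochemistry leaves an explicit gap
  b <- assay_set(design = a$design, weights = a$weights, counts = a$counts,
                 census = a$census, qpcr = a$qpcr, isotopes = a$isotopes,
                 clones = a$clones)
  rep_gap <- build_report(b)
  expect_true("photochemistry" %in% rep_gap$gaps)
})

test_that("PCA separates holobionts when arms are exchangeable", {
  a <- generate_assay_set(null_effect_config(seed = 12))
  rep0 <- build_report(a)
  sc <- rep0$pca$scores
  # the dominant axis splits PdC from PdD, not 26 from 32
  pc1 <- sc$PC1
  holo_gap <- abs(mean(pc1[sc$holobiont == "PdC"]) -
                    mean(pc1[sc$holobiont == "PdD"]))
  arm_gap <- abs(mean(pc1[sc$temperature == 26]) -
                   mean(pc1[sc$temperature == 32]))
  expect_gt(holo_gap, arm_gap)
})
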