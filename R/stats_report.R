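# Supporting inference layer: assumption checks with parametric vs
# nonparametric routing, omnibus ANOVA with Tukey post hoc, mixed-effects
# screening of tank/colony effects, and the consolidated metrics report.
# Standard fitting routines (stats, car, lme4/lmerTest) are used throughout;
# the bespoke assay metrics live in the upstream modules.

#' Normality and homogeneity checks with routing
#'
#' Shapiro-Wilk per group and Levene's test across groups at alpha; groups
#' smaller than 3 yield the verdict "insufficient" and nonparametric
#' routing. A group with zero variance makes homogeneity undefined and is
#' flagged.
#'
#' @param values Numeric response.
#' @param group Grouping factor.
#' @param alpha Significance level for the verdicts.
#' @return List with `shapiro` (per-group tibble), `levene_p`, `normal`,
#'   `homogeneous`, and `route` ("parametric" or "kruskal").
#' @export
assumption_checks <- function(values, group, alpha = 0.05) {
  group <- factor(group)
  sizes <- table(group)
  shapiro <- lapply(levels(group), function(g) {
    x <- values[group == g]
    if (length(x) < 3 || stats::sd(x) == 0) {
      tibble::tibble(group = g, p = NA_real_, verdict = "insufficient")
    } else {
      p <- stats::shapiro.test(x)$p.value
      tibble::tibble(group = g, p = p,
                     verdict = ifelse(p >= alpha, "normal", "non-normal"))
    }
  })
  shapiro <- dplyr::bind_rows(shapiro)
  constant <- tapply(values, group, stats::sd) == 0
  levene_p <- if (any(sizes < 2) || any(constant, na.rm = TRUE)) {
    NA_real_
  } else {
    car::leveneTest(values ~ group)[1, "Pr(>F)"]
  }
  normal <- all(shapiro$verdict == "normal")
  homogeneous <- !is.na(levene_p) && levene_p >= alpha
  route <- if (normal && homogeneous) "parametric" else "kruskal"
  list(shapiro = shapiro, levene_p = levene_p, normal = normal,
       homogeneous = homogeneous, route = route)
}

#' Omnibus test with Tukey post hoc
#'
#' One-way (single factor) or multi-way ANOVA over the supplied factors;
#' Tukey HSD pairwise comparisons are run only when the omnibus test is
#' significant at alpha, mirroring the sequential testing order. When
#' `route = "auto"`, assumption checks on the first factor decide between
#' ANOVA and Kruskal-Wallis (single-factor only; multi-way designs always
#' use ANOVA, with the routing verdict recorded).
#'
#' @param data Data frame holding the response and factors.
#' @param response Response column name.
#' @param factors Character vector of factor column names.
#' @param alpha Significance level.
#' @param route "auto", "parametric" or "kruskal".
#' @return List with `test`, `statistic`, `p_value`, `significant`,
#'   `posthoc` (Tukey table or NULL) and the `assumptions` verdicts.
#' @export
omnibus_and_posthoc <- function(data, response, factors, alpha = 0.05,
                                route = "auto") {
  stopifnot(length(factors) >= 1)
  for (f in factors) data[[f]] <- factor(data[[f]])
  if (length(factors) > 1) {
    cells <- table(data[factors])
    if (any(cells == 0)) {
      empty <- which(cells == 0, arr.ind = TRUE)[1, ]
      abort(sprintf("empty design cell: %s",
                    paste(names(dimnames(cells)),
                          mapply(function(d, i) dimnames(cells)[[d]][i],
                                 seq_along(empty), empty),
                          sep = "=", collapse = ", ")),
            class = "holotherm_domain_error")
    }
  }
  checks <- assumption_checks(data[[response]], data[[factors[1]]], alpha)
  use_kruskal <- (route == "kruskal") ||
    (route == "auto" && checks$route == "kruskal" && length(factors) == 1)
  if (use_kruskal) {
    kt <- stats::kruskal.test(data[[response]], data[[factors[1]]])
    return(list(test = "kruskal-wallis", statistic = unname(kt$statistic),
                p_value = kt$p.value, significant = kt$p.value < alpha,
                posthoc = NULL, assumptions = checks))
  }
  fml <- stats::as.formula(paste(response, "~", paste(factors, collapse = "*")))
  fit <- stats::aov(fml, data = data)
  tab <- summary(fit)[[1]]
  p_main <- tab[1, "Pr(>F)"]
  significant <- any(tab[-nrow(tab), "Pr(>F)"] < alpha, na.rm = TRUE)
  posthoc <- NULL
  if (significant) {
    posthoc <- stats::TukeyHSD(fit)
  }
  list(test = if (length(factors) == 1) "one-way anova" else
         sprintf("%d-way anova", length(factors)),
       statistic = unname(tab[1, "F value"]), p_value = p_main,
       anova_table = tab, significant = significant, posthoc = posthoc,
       assumptions = checks)
}

#' Mixed-effects screen of fixed and random factors
#'
#' Fits a Gaussian identity-link mixed model of the response on the fixed
#' factors (temperature, time, genotype as available) with random
#' intercepts for tank and colony, via lmerTest. Reports fixed-effect tests,
#' random-effect variance shares, and a per-random-factor verdict
#' ("negligible" when the likelihood-ratio test of that component is
#' non-significant). Singular fits are reported as boundary (zero-variance)
#' estimates, not failures.
#'
#' @param data Data frame with the response, fixed and random factor
#'   columns.
#' @param response Response column name.
#' @param fixed Character vector of fixed-effect column names.
#' @param random Character vector of random-intercept column names (each
#'   needs >= 2 levels).
#' @param alpha Significance level for verdicts.
#' @return List with `fixed_effects`, `variance_shares`, `random_verdicts`,
#'   `singular`.
#' @export
mixed_effects_screen <- function(data, response, fixed,
                                 random = c("tank", "colony"),
                                 alpha = 0.05) {
  for (r in random) {
    if (dplyr::n_distinct(data[[r]]) < 2) {
      abort(sprintf("random factor '%s' needs >= 2 levels", r),
            class = "holotherm_domain_error")
    }
    data[[r]] <- factor(data[[r]])
  }
  fixed <- fixed[vapply(fixed, function(f) dplyr::n_distinct(data[[f]]) > 1,
                        logical(1))]
  fml <- stats::as.formula(paste(
    response, "~", paste(fixed, collapse = " + "), "+",
    paste(sprintf("(1 | %s)", random), collapse = " + ")))
  fit <- suppressMessages(lmerTest::lmer(fml, data = data))
  vc <- as.data.frame(lme4::VarCorr(fit))
  shares <- tibble::tibble(component = vc$grp,
                           variance = vc$vcov,
                           share = vc$vcov / sum(vc$vcov))
  an <- stats::anova(fit)
  fixed_effects <- tibble::tibble(term = rownames(an),
                                  f_value = an$`F value`,
                                  p_value = an$`Pr(>F)`,
                                  significant = an$`Pr(>F)` < alpha)
  rv <- suppressMessages(lmerTest::ranova(fit))
  rv_terms <- rownames(rv)[-1]
  random_verdicts <- tibble::tibble(
    term = rv_terms, p_value = rv$`Pr(>Chisq)`[-1],
    verdict = ifelse(rv$`Pr(>Chisq)`[-1] < alpha, "substantial",
                     "negligible"))
  list(fixed_effects = fixed_effects, variance_shares = shares,
       random_verdicts = random_verdicts,
       singular = lme4::isSingular(fit), fit = fit)
}

#' Consolidated metrics report
#'
#' Runs every derived-metric stage on an assay set and assembles the result:
#' per-stage metric tables, group comparisons, and a PCA over the z-scored
#' trait means (Fv/Fm, dF/Fm', symbiont density, calcification rate, carbon
#' fixation, carbon translocation, symbiont relative abundance) aggregated
#' per holobiont x arm x tank. Stages whose input table is empty are
#' reported as gaps rather than errors.
#'
#' @param x An [assay_set()].
#' @param alpha Significance level for the comparisons.
#' @return List of class `metrics_report` with elements `metrics`,
#'   `comparisons`, `pca`, `gaps`.
#' @export
build_report <- function(x, alpha = 0.05) {
  validate_assay_set(x)
  design <- x$design
  gaps <- character(0)
  metrics <- list()
  comparisons <- list()

  if (nrow(x$pam) > 0) {
    qm <- compute_qm(pair_yields(x$pam))
    metrics$qm <- qm
    metrics$delta_qm <- compute_delta_qm(qm, design, pooling = "overall")
    last_day <- max(qm$day)
    d14 <- join_design(qm[qm$day == last_day, ], design)
    for (h in unique(d14$holobiont)) {
      dh <- d14[d14$holobiont == h, ]
      if (dplyr::n_distinct(dh$temperature) > 1) {
        comparisons[[paste0("qm_day", last_day, "_", h)]] <-
          omnibus_and_posthoc(dh, "qm", "temperature", alpha)
      }
    }
  } else gaps <- c(gaps, "photochemistry")

  if (nrow(x$weights) > 0) {
    metrics$calcification <- interval_rates(x$weights)
  } else gaps <- c(gaps, "calcification")

  if (nrow(x$counts) > 0) {
    metrics$density <- areal_density(x$counts)
  } else gaps <- c(gaps, "density")

  if (nrow(x$census) > 0) {
    days <- sort(unique(x$census$day))
    metrics$bleaching <- dplyr::bind_rows(
      lapply(days, function(d) bleaching_rate(x$census, design, d)))
  } else gaps <- c(gaps, "census")

  if (nrow(x$qpcr) > 0) {
    ratios <- dc_ratio(x$qpcr)
    metrics$dc <- shuffling_index(ratios)
    metrics$dc_trajectory <- dc_trajectory(ratios, design)
  } else gaps <- c(gaps, "community_qpcr")

  if (nrow(x$isotopes) > 0) {
    up <- tracer_uptake(x$isotopes, design)
    metrics$uptake <- up
    metrics$translocation <- summarize_translocation(up)
  } else gaps <- c(gaps, "isotopes")

  if (nrow(x$clones) > 0) {
    metrics$dominance <- dominance_share(x$clones)
  } else gaps <- c(gaps, "clones")

  pca <- tryCatch(report_pca(metrics, design), error = function(e) NULL)
  if (is.null(pca) && length(gaps) == 0) gaps <- c(gaps, "pca")

  structure(list(metrics = metrics, comparisons = comparisons, pca = pca,
                 gaps = gaps, alpha = alpha), class = "metrics_report")
}

# Trait means per holobiont x temperature x tank, z-scored, then PCA.
report_pca <- function(metrics, design) {
  unit <- function(tab, value, name) {
    need <- setdiff(c("holobiont", "temperature", "tank"), names(tab))
    if (length(need) > 0) {
      tab <- dplyr::left_join(
        tab, design[c("fragment_id", need)], by = "fragment_id")
    }
    tab |>
      dplyr::group_by(.data$holobiont, .data$temperature, .data$tank) |>
      dplyr::summarise("{name}" := mean(.data[[value]], na.rm = TRUE),
                       .groups = "drop")
  }
  traits <- list()
  if (!is.null(metrics$qm)) {
    pam_last <- metrics$qm[metrics$qm$day == max(metrics$qm$day), ]
    traits$fvfm <- unit(pam_last, "fv_fm", "fv_fm")
    traits$dffm <- unit(pam_last, "df_fm_prime", "df_fm_prime")
  }
  if (!is.null(metrics$density)) {
    dl <- metrics$density[metrics$density$day == max(metrics$density$day), ]
    traits$density <- unit(dl, "density", "density")
  }
  if (!is.null(metrics$calcification)) {
    traits$calc <- unit(metrics$calcification, "rate", "calcification")
  }
  if (!is.null(metrics$uptake)) {
    up <- metrics$uptake[metrics$uptake$valid %in% TRUE, ]
    traits$fix <- unit(up[up$fraction == "symbiont", ], "uptake",
                       "carbon_fixation")
    traits$trans <- unit(up[up$fraction == "host", ], "uptake",
                         "carbon_translocation")
  }
  if (!is.null(metrics$dc)) {
    dcl <- metrics$dc[metrics$dc$day == max(metrics$dc$day), ]
    traits$dc <- unit(dcl, "log10_dc", "log10_dc")
  }
  if (length(traits) < 2) stop("not enough traits for PCA")
  tab <- Reduce(function(a, b) dplyr::full_join(
    a, b, by = c("holobiont", "temperature", "tank")), traits)
  mat <- as.matrix(tab[, -(1:3), drop = FALSE])
  keep <- stats::complete.cases(mat)
  mat <- mat[keep, , drop = FALSE]
  if (nrow(mat) < 3) stop("not enough complete units for PCA")
  fit <- stats::prcomp(mat, center = TRUE, scale. = TRUE)
  list(scores = cbind(tab[keep, 1:3], as.data.frame(fit$x)),
       loadings = fit$rotation,
       variance_explained = fit$sdev^2 / sum(fit$sdev^2))
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report>\n")
  cat("  metric tables:", paste(names(x$metrics), collapse = ", "), "\n")
  cat("  comparisons:", length(x$comparisons), "\n")
  if (!is.null(x$pca)) {
    cat(sprintf("  PCA: %d traits, PC1 %.0f%% of variance\n",
                ncol(x$pca$loadings), 100 * x$pca$variance_explained[1]))
  }
  if (length(x$gaps)) cat("  gaps:", paste(x$gaps, collapse = ", "), "\n")
  invisible(x)
}

#' @importFrom rlang :=
NULL
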