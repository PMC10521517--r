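# Symbiont community metrics: genus-specific qPCR ratio (D/C = 2^-dCT),
# shuffling index, log-ratio trajectories, clone-library community
# matrices, zero-adjusted Bray-Curtis dissimilarity, NMDS ordination and
# complete-linkage grouping.

#' Durusdinium-to-Cladocopium ratio from qPCR threshold cycles
#'
#' Per fragment-day: the CT of each primer is the mean of its detected
#' technical replicates, and D/C = 2^-(CT_D - CT_C). A primer with no
#' detected replicate is substituted with the detection-limit CT (default
#' 40 cycles) and the record flagged censored; a fragment-day where both
#' primers are fully non-detect is skipped with a warning.
#'
#' @param qpcr Tibble (fragment_id, day, primer, replicate, ct); non-detect
#'   replicates encoded as NA ct.
#' @param ct_limit Detection-limit CT substituted for a non-detect primer.
#' @return Tibble with fragment_id, day, ct_c, ct_d, dc, log10_dc, censored.
#' @export
dc_ratio <- function(qpcr, ct_limit = 40) {
  means <- qpcr |>
    dplyr::group_by(.data$fragment_id, .data$day, .data$primer) |>
    dplyr::summarise(ct = mean(.data$ct, na.rm = TRUE), .groups = "drop")
  means$ct[is.nan(means$ct)] <- NA_real_
  wide <- tidyr::pivot_wider(means, names_from = "primer",
                             values_from = "ct")
  if (!"C" %in% names(wide)) wide$C <- NA_real_
  if (!"D" %in% names(wide)) wide$D <- NA_real_
  both_nd <- is.na(wide$C) & is.na(wide$D)
  if (any(both_nd)) {
    warn(sprintf("%d fragment-day(s) non-detect for both primers; skipped",
                 sum(both_nd)))
    wide <- wide[!both_nd, ]
  }
  censored <- is.na(wide$C) | is.na(wide$D)
  ct_c <- ifelse(is.na(wide$C), ct_limit, wide$C)
  ct_d <- ifelse(is.na(wide$D), ct_limit, wide$D)
  dc <- 2^(-(ct_d - ct_c))
  tibble::tibble(fragment_id = wide$fragment_id, day = wide$day,
                 ct_c = ct_c, ct_d = ct_d, dc = dc, log10_dc = log10(dc),
                 censored = censored)
}

#' Symbiont shuffling index
#'
#' The Durusdinium proportion p_D = dc / (1 + dc) mapped affinely onto
#' [-1, +1]: index = 2 p_D - 1. The bounds are attained only at complete
#' dominance (-1: all Cladocopium; +1: all Durusdinium); the index is
#' strictly increasing in the D/C ratio.
#'
#' @param dc Non-negative D/C ratio(s) (vector or the tibble from
#'   [dc_ratio()], whose `dc` column is used).
#' @return Numeric index in [-1, 1], or the input tibble with an `index`
#'   column added.
#' @export
shuffling_index <- function(dc) {
  if (is.data.frame(dc)) {
    dc$index <- shuffling_index(dc$dc)
    return(dc)
  }
  if (any(dc < 0, na.rm = TRUE)) {
    abort("dc must be non-negative", class = "holotherm_domain_error")
  }
  p_d <- dc / (1 + dc)
  2 * p_d - 1
}

#' Trajectory of log10 D/C over time
#'
#' Ordinary least-squares regression of log10(D/C) on day within each
#' holobiont x temperature arm, with the 95% confidence interval of the
#' slope and its p-value.
#'
#' @param ratios Tibble from [dc_ratio()].
#' @param design Design tibble.
#' @return Tibble with holobiont, temperature, slope (log10 units per day),
#'   ci_lo, ci_hi, p_value, n.
#' @export
dc_trajectory <- function(ratios, design) {
  dat <- join_design(ratios, design)
  fits <- dat |>
    dplyr::group_by(.data$holobiont, .data$temperature) |>
    dplyr::group_map(function(d, key) {
      if (dplyr::n_distinct(d$day) < 2) {
        abort(sprintf("fewer than 2 time points for %s at %s",
                      key$holobiont, key$temperature),
              class = "holotherm_domain_error")
      }
      fit <- stats::lm(log10_dc ~ day, data = d)
      ci <- stats::confint(fit)["day", ]
      tibble::tibble(holobiont = key$holobiont,
                     temperature = key$temperature,
                     slope = unname(stats::coef(fit)["day"]),
                     ci_lo = ci[1], ci_hi = ci[2],
                     p_value = summary(fit)$coefficients["day", 4],
                     n = nrow(d))
    })
  dplyr::bind_rows(fits)
}

#' Build a samples-by-types community matrix from clone counts
#'
#' @param clones Tibble (fragment_id, stage, its2_type, clone_count).
#' @return Numeric matrix, rows named `"<fragment_id>:<stage>"`.
#' @export
community_matrix <- function(clones) {
  clones$sample <- paste(clones$fragment_id, clones$stage, sep = ":")
  wide <- clones |>
    dplyr::group_by(.data$sample, .data$its2_type) |>
    dplyr::summarise(clone_count = sum(.data$clone_count), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "its2_type", values_from = "clone_count",
                       values_fill = 0)
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$sample
  m
}

#' Zero-adjusted Bray-Curtis dissimilarity
#'
#' Appends a constant "dummy species" column (value 1 for every sample) to
#' the abundance matrix and computes Bray-Curtis over all columns including
#' the dummy: d(i,j) = sum |x_ik - x_jk| / sum (x_ik + x_jk). The dummy
#' keeps comparisons involving empty samples defined (two all-zero samples
#' have dissimilarity 0) and bounds d strictly below 1.
#'
#' @param m Non-negative abundance matrix (samples x types).
#' @return A `dist` object.
#' @export
zero_adjusted_bray_curtis <- function(m) {
  m <- as.matrix(m)
  if (any(m < 0)) {
    abort("abundances must be non-negative", class = "holotherm_domain_error")
  }
  adj <- cbind(m, dummy = rep(1, nrow(m)))
  vegan::vegdist(adj, method = "bray")
}

#' Non-metric multidimensional scaling
#'
#' Global NMDS minimizing Kruskal stress-1 by isotonic regression, taking
#' the best of `restarts` random starts under a fixed seed (so coordinates
#' are reproducible).
#'
#' @param d Symmetric dissimilarity (`dist` or square matrix, zero
#'   diagonal).
#' @param dims Number of ordination axes.
#' @param restarts Random starts; the lowest-stress solution is kept.
#' @param seed Integer seed for the random starts.
#' @return List with `points` (samples x dims), `stress` (Kruskal stress-1,
#'   as a proportion) and the winning start index.
#' @export
nmds <- function(d, dims = 2, restarts = 20, seed = 1) {
  if (!inherits(d, "dist")) {
    d <- as.matrix(d)
    if (!isSymmetric(unname(d), tol = 1e-8)) {
      abort("dissimilarity matrix must be symmetric",
            class = "holotherm_domain_error")
    }
    d <- stats::as.dist(d)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  best <- NULL
  best_start <- NA_integer_
  for (i in seq_len(restarts)) {
    init <- matrix(stats::rnorm(attr(d, "Size") * dims), ncol = dims)
    fit <- vegan::monoMDS(d, y = init, k = dims, model = "global",
                          maxit = 500)
    if (is.null(best) || fit$stress < best$stress) {
      best <- fit
      best_start <- i
    }
  }
  pts <- best$points
  rownames(pts) <- attr(d, "Labels")
  list(points = pts, stress = best$stress, start = best_start)
}

#' Complete-linkage grouping at a similarity threshold
#'
#' Agglomerative complete-linkage clustering cut at dissimilarity
#' 1 - cut/100, i.e. every pair within a group is at least `similarity_cut`
#' percent similar.
#'
#' @param d Dissimilarity (`dist` or square matrix).
#' @param similarity_cut Similarity threshold in percent, in (0, 100).
#' @return Integer group label per sample.
#' @export
complete_linkage_groups <- function(d, similarity_cut = 90) {
  if (similarity_cut <= 0 || similarity_cut >= 100) {
    abort("similarity_cut must lie in (0, 100)",
          class = "holotherm_domain_error")
  }
  if (!inherits(d, "dist")) d <- stats::as.dist(as.matrix(d))
  hc <- stats::hclust(d, method = "complete")
  stats::cutree(hc, h = 1 - similarity_cut / 100)
}

#' Dominant-genus clone share per sample
#'
#' The first character of an ITS2 type label gives its genus (C or D); the
#' dominant genus of a sample is the one with the larger clone total.
#'
#' @param clones Tibble (fragment_id, stage, its2_type, clone_count).
#' @return Tibble with fragment_id, stage, dominant_genus and
#'   dominance_share (percent of clones belonging to the dominant genus).
#' @export
dominance_share <- function(clones) {
  clones$genus <- substr(clones$its2_type, 1, 1)
  clones |>
    dplyr::group_by(.data$fragment_id, .data$stage, .data$genus) |>
    dplyr::summarise(count = sum(.data$clone_count), .groups = "drop_last") |>
    dplyr::summarise(
      dominant_genus = .data$genus[which.max(.data$count)],
      dominance_share = 100 * max(.data$count) / sum(.data$count),
      .groups = "drop")
}
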