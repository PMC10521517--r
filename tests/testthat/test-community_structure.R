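qpcr_row <- function(ct_c, ct_d, id = "f", day = 0L) {
  tibble::tibble(fragment_id = id, day = day,
                 primer = rep(c("C", "D"), each = length(ct_c)),
                 replicate = c(seq_along(ct_c), seq_along(ct_d)),
                 ct = c(ct_c, ct_d))
}

test_that("D/C follows 2^-(CT_D - CT_C) on replicate means", {
  expect_equal(dc_ratio(qpcr_row(20, 30))$dc, 2^-10)
  expect_equal(dc_ratio(qpcr_row(25, 25))$dc, 1)
  expect_equal(dc_ratio(qpcr_row(30, 20))$dc, 1024)
  # replicate means first: CTs {19,20,21} behave as 20
  expect_equal(dc_ratio(qpcr_row(c(19, 20, 21), c(29, 30, 31)))$dc, 2^-10)
})

test_that("non-detect primers get the CT limit and are flagged censored", {
  q <- qpcr_row(20, NA_real_)
  r <- dc_ratio(q, ct_limit = 40)
  expect_true(r$censored)
  expect_equal(r$dc, 2^-(40 - 20))
  both <- qpcr_row(NA_real_, NA_real_)
  expect_warning(r2 <- dc_ratio(both), regexp = "non-detect")
  expect_equal(nrow(r2), 0)
})

test_that("log10 D/C is linear in delta-CT", {
  r1 <- dc_ratio(qpcr_row(20, 25))
  r2 <- dc_ratio(qpcr_row(20, 30))
  expect_equal(r1$log10_dc, -5 * log10(2))
  expect_equal(r2$log10_dc / r1$log10_dc, 2)  # doubling dCT doubles |log10|
})

test_that("shuffling index maps proportion onto [-1, 1] monotonically", {
  expect_equal(shuffling_index(0), -1)
  expect_equal(shuffling_index(1), 0)
  expect_gt(shuffling_index(1e12), 1 - 1e-11)
  dc <- sort(stats::runif(50, 0, 100))
  idx <- shuffling_index(dc)
  expect_true(all(diff(idx) > 0))
  expect_true(all(idx > -1 & idx < 1))
  expect_error(shuffling_index(-0.1), class = "holotherm_domain_error")
})

test_that("D/C trajectory slopes recover the arm drifts", {
  const <- dc_ratio(dplyr::bind_rows(lapply(c(0L, 7L, 14L), function(d)
    qpcr_row(20, 30, id = paste0("PdC-1-1-", d), day = d))))
  design <- tibble::tibble(fragment_id = unique(const$fragment_id),
                           holobiont = "PdC", colony = 1L, tank = 1L,
                           temperature = 26)
  tr <- suppressWarnings(dc_trajectory(const, design))  # perfect-fit warning
  expect_equal(tr$slope, 0, tolerance = 1e-12)
  single_day <- const[const$day == 0, ]
  expect_error(dc_trajectory(single_day, design),
               class = "holotherm_domain_error")
  # synthetic heated PdC rises ~3 log10 units over 14 days; PdD control falls
  a <- generate_assay_set(paper_default_config(seed = 2))
  tr2 <- dc_trajectory(dc_ratio(a$qpcr), a$design)
  pdc_heat <- tr2[tr2$holobiont == "PdC" & tr2$temperature == 32, ]
  expect_equal(pdc_heat$slope * 14, 3, tolerance = 0.5)
  pdd_ctrl <- tr2[tr2$holobiont == "PdD" & tr2$temperature == 26, ]
  expect_lt(pdd_ctrl$slope, 0)
})

test_that("zero-adjusted Bray-Curtis matches hand-summed cases", {
  m <- rbind(a = c(10, 0), b = c(0, 10), c = c(0, 0), d = c(0, 0),
             e = c(10, 0))
  d <- as.matrix(zero_adjusted_bray_curtis(m))
  expect_equal(d["a", "b"], 20 / 22)  # (10+10+0)/(10+10+2)
  expect_equal(d["c", "d"], 0)        # dummy prevents 0/0 for empty samples
  expect_equal(d["a", "e"], 0)        # identical rows
  expect_true(isSymmetric(d))
  expect_true(all(diag(d) == 0))
  expect_true(all(d >= 0 & d < 1))
  expect_error(zero_adjusted_bray_curtis(rbind(c(-1, 2), c(0, 1))),
               class = "holotherm_domain_error")
})

test_that("NMDS is seed-deterministic and embeds exact configurations", {
  m <- matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), nrow = 3)
  fit1 <- nmds(m, restarts = 5, seed = 7)
  fit2 <- nmds(m, restarts = 5, seed = 7)
  expect_identical(fit1$points, fit2$points)
  # three equidistant samples embed exactly: stress ~ 0
  expect_lt(fit1$stress, 1e-3)
  # rank-preserving perturbation of a planar configuration stays near 0
  set.seed(5)
  pts <- matrix(rnorm(12), ncol = 2)
  d0 <- dist(pts)
  d_pert <- d0^1.3  # monotone transform preserves ranks
  fit3 <- nmds(d_pert, restarts = 10, seed = 3)
  expect_lt(fit3$stress, 0.05)
  asym <- matrix(c(0, 1, 2, 0), nrow = 2)
  expect_error(nmds(asym), class = "holotherm_domain_error")
})

test_that("complete-linkage grouping matches a brute-force oracle", {
  d4 <- matrix(0.5, 4, 4)
  d4[1, 2] <- d4[2, 1] <- 0.05
  d4[3, 4] <- d4[4, 3] <- 0.05
  diag(d4) <- 0
  g <- complete_linkage_groups(d4, similarity_cut = 90)
  expect_equal(unname(g[1]), unname(g[2]))
  expect_equal(unname(g[3]), unname(g[4]))
  expect_false(g[1] == g[3])
  # all-zero dissimilarity collapses to one group
  expect_equal(dplyr::n_distinct(complete_linkage_groups(matrix(0, 3, 3))), 1)
  expect_error(complete_linkage_groups(d4, similarity_cut = 100),
               class = "holotherm_domain_error")
  # random <= 5-sample instances agree with the exhaustive oracle
  set.seed(31)
  for (i in 1:25) {
    n <- sample(3:5, 1)
    m <- matrix(runif(n * n, 0.01, 1), n, n)
    m <- (m + t(m)) / 2
    diag(m) <- 0
    cut <- runif(1, 50, 95)
    ours <- complete_linkage_groups(m, cut)
    oracle <- brute_complete_linkage(m, h = 1 - cut / 100)
    # same partition up to label permutation
    expect_equal(length(unique(ours)), length(unique(oracle)))
    expect_true(all(outer(ours, ours, "==") == outer(oracle, oracle, "==")))
  }
})

test_that("synthetic clone libraries group by genus regardless of treatment", {
  a <- generate_assay_set(paper_default_config(seed = 4))
  m <- community_matrix(a$clones)
  d <- zero_adjusted_bray_curtis(m)
  groups <- complete_linkage_groups(d, similarity_cut = 90)
  holo <- substr(rownames(m), 1, 3)
  # genus blocks never mix at the 90%-similarity cut
  cross <- outer(groups, groups, "==") & outer(holo, holo, "!=")
  expect_false(any(cross))
  # and the ordination separates them on the first axis
  ord <- nmds(d, restarts = 10, seed = 1)
  expect_identical(nmds(d, restarts = 10, seed = 1)$points, ord$points)
  pdc <- ord$points[holo == "PdC", 1]
  pdd <- ord$points[holo == "PdD", 1]
  expect_true(max(min(pdc), min(pdd)) > min(max(pdc), max(pdd)) ||
                !any(range(pdc)[1] < pdd & pdd < range(pdc)[2]))
})

test_that("dominance of the initial genus stays above 99% of clone counts", {
  shares <- vapply(1:5, function(s) {
    a <- generate_assay_set(paper_default_config(seed = s))
    min(dominance_share(a$clones)$dominance_share)
  }, numeric(1))
  expect_true(all(shares > 99))
})
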