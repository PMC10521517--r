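# Shared fixtures built in code.

tiny_design <- function() {
  tibble::tibble(
    fragment_id = c("PdC-1-1-1", "PdC-1-4-1", "PdD-1-1-1", "PdD-1-4-1"),
    holobiont = rep(c("PdC", "PdD"), each = 2),
    colony = 1L, tank = rep(c(1L, 4L), 2),
    temperature = rep(c(26, 32), 2))
}

# Independent brute-force complete-linkage clustering for small instances:
# agglomerate the pair of clusters with the smallest maximum inter-point
# dissimilarity until that minimum exceeds the cut height.
brute_complete_linkage <- function(d, h) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  repeat {
    if (length(clusters) == 1) break
    best <- c(NA, NA); best_val <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i >= j) next
        val <- max(d[clusters[[i]], clusters[[j]]])
        if (val < best_val) { best_val <- val; best <- c(i, j) }
      }
    }
    if (best_val > h) break
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  labels <- integer(n)
  for (k in seq_along(clusters)) labels[clusters[[k]]] <- k
  labels
}

# Group means joined to the design, for recovery checks.
group_mean <- function(tab, design, value, holo, temp, at_day = NULL) {
  dat <- dplyr::left_join(tab, design, by = "fragment_id")
  dat <- dat[dat$holobiont == holo & dat$temperature == temp, ]
  if (!is.null(at_day)) dat <- dat[dat$day == at_day, ]
  mean(dat[[value]])
}
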