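# Shared statistical primitives: vectorized Spearman correlation against a
# reference vector, and a tie-aware Mann-Whitney U test with an exact
# enumeration path for small groups.

# Spearman correlation of every row of `x` against `y`, with two-sided
# p-values: t approximation for n > 10, stats::cor.test for small n (exact
# when tie-free). Constant rows give NA.
spearman_rows <- function(x, y) {
  n <- length(y)
  stopifnot(ncol(x) == n, n >= 3)
  if (sd(y) == 0) abort("reference vector is constant; Spearman correlation undefined.")
  ry <- rank(y)
  rx <- t(apply(x, 1, rank))
  rxc <- rx - rowMeans(rx)
  ryc <- ry - mean(ry)
  denom <- unname(sqrt(rowSums(rxc^2) * sum(ryc^2)))
  r <- as.vector(rxc %*% ryc) / denom
  r[denom == 0] <- NA_real_
  if (n > 10) {
    tval <- r * sqrt((n - 2) / pmax(1 - r^2, 0))
    p <- 2 * pt(-abs(tval), df = n - 2)
    p[abs(r) >= 1] <- 0
  } else {
    p <- vapply(seq_len(nrow(x)), function(i) {
      if (is.na(r[i])) return(NA_real_)
      suppressWarnings(
        cor.test(x[i, ], y, method = "spearman", exact = TRUE)$p.value
      )
    }, numeric(1))
  }
  tibble(spearman_r = r, p_value = p, n_obs = n)
}

# scalar Spearman with the same p-value policy
spearman_test <- function(x, y) {
  res <- spearman_rows(matrix(x, nrow = 1), y)
  list(estimate = res$spearman_r, p.value = res$p_value, n = res$n_obs)
}

# Two-sided Mann-Whitney U. Exact path (default when both groups <= 8):
# full enumeration of group assignments over the tie-averaged pooled
# ranks, so ties are handled exactly. Otherwise the tie-corrected normal
# approximation of stats::wilcox.test (with continuity correction).
mann_whitney <- function(x, y, exact = NULL) {
  n1 <- length(x)
  n2 <- length(y)
  if (n1 < 1 || n2 < 1) abort("both groups must be non-empty.")
  if (is.null(exact)) exact <- n1 <= 8 && n2 <= 8
  pooled_ranks <- rank(c(x, y))
  u_obs <- sum(pooled_ranks[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (exact) {
    mu <- n1 * n2 / 2
    picks <- combn(n1 + n2, n1)
    us <- colSums(matrix(pooled_ranks[picks], nrow = n1)) - n1 * (n1 + 1) / 2
    # >= with a tolerance so tied statistics count as at-least-as-extreme
    p <- mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
  } else {
    p <- suppressWarnings(
      stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
    )
  }
  list(statistic = u_obs, p.value = min(p, 1), exact = exact)
}
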