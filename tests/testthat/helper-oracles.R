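# Independent brute-force oracles. Each reimplements a statistic from its
# definition, by enumeration or direct evaluation, sharing no code with the
# package implementation.

# ssGSEA running sum, written as an explicit walk over the expression-sorted
# gene list (no shared helpers with the package).
oracle_ssgsea_raw <- function(values, gene_names, set_genes, alpha = 0.25) {
  r <- rank(values)
  ord <- gene_names[order(values, decreasing = TRUE)]
  r_by_gene <- setNames(r, gene_names)
  in_set <- ord %in% set_genes
  pin_total <- sum(abs(r_by_gene[ord[in_set]])^alpha)
  running <- 0
  total <- 0
  for (g in ord) {
    if (g %in% set_genes) {
      running <- running + abs(r_by_gene[[g]])^alpha / pin_total
    } else {
      running <- running - 1 / sum(!in_set)
    }
    total <- total + running
  }
  total
}

# AUC by direct pair counting: concordant + half ties over all pos x neg pairs
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == "NR"]
  neg <- scores[labels == "R"]
  conc <- 0
  for (p in pos) for (n in neg) {
    conc <- conc + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  conc / (length(pos) * length(neg))
}

# one-sided Fisher enrichment p by explicit hypergeometric summation
oracle_fisher_greater <- function(k, n_top, n_universe, n_sig) {
  i <- k:min(n_top, n_sig)
  sum(choose(n_top, i) * choose(n_universe - n_top, n_sig - i)) /
    choose(n_universe, n_sig)
}

# Efron partial log-likelihood for a single binary covariate, maximized by
# 1-D golden-section search: the Cox coefficient oracle
oracle_cox_efron <- function(time, event, x, interval = c(-10, 10)) {
  loglik <- function(beta) {
    eta <- beta * x
    ll <- 0
    for (t in sort(unique(time[event == 1]))) {
      died <- which(time == t & event == 1)
      risk <- which(time >= t)
      d <- length(died)
      ll <- ll + sum(eta[died])
      sum_risk <- sum(exp(eta[risk]))
      sum_died <- sum(exp(eta[died]))
      for (l in seq_len(d) - 1) {
        ll <- ll - log(sum_risk - l / d * sum_died)
      }
    }
    ll
  }
  optimize(loglik, interval = interval, maximum = TRUE, tol = 1e-9)$maximum
}

# exact two-sided Spearman p by full permutation enumeration (tie-free, small n)
oracle_spearman_exact_p <- function(x, y) {
  n <- length(x)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  r_obs <- cor(x, y, method = "spearman")
  rs <- vapply(perms(seq_len(n)), function(p) {
    cor(x[p], y, method = "spearman")
  }, numeric(1))
  mean(abs(rs) >= abs(r_obs) - 1e-12)
}

# Gaussian-kernel class-conditional naive Bayes posterior, evaluated longhand
oracle_nb_kernel_posterior <- function(train_by_class, priors, x_new, adjust = 1) {
  dens <- vapply(seq_along(train_by_class), function(ci) {
    obs <- train_by_class[[ci]]
    h <- bw.nrd0(obs) * adjust
    mean(dnorm(x_new, mean = obs, sd = h))
  }, numeric(1))
  num <- priors * dens
  num / sum(num)
}
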