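# Small deterministic fixtures, built in code at test time.

tiny_expr <- function(values, genes = NULL, obs = NULL, layer = "lognorm") {
  m <- as.matrix(values)
  if (is.null(genes)) {
    genes <- if (is.null(rownames(m))) sprintf("G%03d", seq_len(nrow(m))) else rownames(m)
  }
  if (is.null(obs)) {
    obs <- if (is.null(colnames(m))) sprintf("s%02d", seq_len(ncol(m))) else colnames(m)
  }
  dimnames(m) <- list(genes, obs)
  expr_matrix(m, layer = layer)
}

random_lognorm <- function(n_genes, n_obs, seed = 1) {
  set.seed(seed)
  tiny_expr(matrix(rnorm(n_genes * n_obs, mean = 2, sd = 1), n_genes, n_obs))
}

# clinical table with survival, deterministic
toy_clinical <- function(n, n_r = floor(n / 2), cohort = "K1", seed = 1) {
  set.seed(seed)
  tibble::tibble(
    sample_id = sprintf("%s_s%03d", cohort, seq_len(n)),
    cohort = cohort,
    response = c(rep("R", n_r), rep("NR", n - n_r)),
    os_months = round(rexp(n, 1 / 20), 2),
    event = rbinom(n, 1, 0.7),
    tmb = round(rlnorm(n, 1.5, 0.8), 2),
    ith = round(runif(n), 3)
  )
}
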