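#' Empirical-Bayes location/scale batch adjustment (ComBat)
#'
#' Merges cohorts measured in batches by removing per-batch, per-gene
#' systematic location and scale differences, on log-scale expression.
#' Each gene is standardized by its grand mean (batch-size weighted) and
#' pooled variance; per-batch location (`gamma`) and scale (`delta^2`)
#' effects are estimated gene-wise and -- when `eb = TRUE` -- shrunk
#' toward common batch-level priors by the standard parametric
#' empirical-Bayes fixed-point iteration (normal prior on gamma,
#' inverse-gamma prior on delta^2, method-of-moments hyperpriors,
#' tolerance 1e-6, at most 500 iterations); the data are then
#' back-transformed with the batch effects removed. With `eb = FALSE`
#' the raw per-batch estimates are used, which exactly equalizes every
#' batch's per-gene mean and variance to the grand statistics (a useful
#' diagnostic mode). No biological covariates are modelled.
#'
#' A single-batch input is returned unchanged. Genes with zero pooled
#' variance are passed through untouched with a warning.
#'
#' @param m An [expr_matrix] (log-scale values expected) or plain matrix,
#'   genes x samples.
#' @param batch Vector of batch labels along samples (>= 2 samples per
#'   batch).
#' @param eb Apply empirical-Bayes shrinkage (default `TRUE`).
#' @param tol,max_iter Fixed-point iteration controls.
#' @return A list with `adjusted` (an [expr_matrix], layer `adjusted`) and
#'   `model` (a `batch_model`: per-batch gamma/delta2 matrices before and
#'   after shrinkage, grand mean, pooled variance, hyperprior estimates).
#' @export
combat_adjust <- function(m, batch, eb = TRUE, tol = 1e-6, max_iter = 500) {
  x <- unclass(as_expr_matrix(m, layer = if (is_expr_matrix(m)) expr_layer(m) else "lognorm"))
  if (any(!is.finite(x))) abort("non-finite values in expression matrix.")
  batch <- as.character(batch)
  stopifnot(length(batch) == ncol(x))
  batches <- sort(unique(batch))
  n_b <- table(factor(batch, levels = batches))
  if (any(n_b < 2)) {
    abort(paste0("batch(es) with < 2 samples: ",
                 paste(names(n_b)[n_b < 2], collapse = ", ")))
  }
  if (length(batches) == 1) {
    return(list(
      adjusted = expr_matrix(x, layer = "adjusted"),
      model = structure(list(batches = batches, eb_enabled = eb, identity = TRUE),
                        class = "batch_model")
    ))
  }
  n <- ncol(x)
  G <- nrow(x)

  # per-batch gene means and the batch-size weighted grand mean
  batch_mean <- vapply(batches, function(b) rowMeans(x[, batch == b, drop = FALSE]),
                       numeric(G))
  grand_mean <- as.vector(batch_mean %*% (as.numeric(n_b) / n))
  resid <- x - batch_mean[, match(batch, batches), drop = FALSE]
  # unbiased pooled variance (residual SS over n - B), consistent with the
  # n_b - 1 per-batch scale estimates below: this makes the eb = FALSE
  # adjustment exactly idempotent
  pooled_var <- rowSums(resid^2) / (n - length(batches))

  zero_var <- pooled_var <= 0
  if (any(zero_var)) {
    warn(sprintf("%d gene(s) with zero pooled variance passed through untouched.",
                 sum(zero_var)))
  }
  adj <- x
  use <- which(!zero_var)
  if (length(use) > 0) {
    xs <- x[use, , drop = FALSE]
    gm <- grand_mean[use]
    pv <- pooled_var[use]
    z <- (xs - gm) / sqrt(pv)

    gamma_hat <- vapply(batches, function(b) rowMeans(z[, batch == b, drop = FALSE]),
                        numeric(length(use)))
    delta2_hat <- vapply(batches, function(b) {
      apply(z[, batch == b, drop = FALSE], 1, var)
    }, numeric(length(use)))
    gamma_hat <- matrix(gamma_hat, ncol = length(batches),
                        dimnames = list(NULL, batches))
    delta2_hat <- matrix(delta2_hat, ncol = length(batches),
                         dimnames = list(NULL, batches))

    if (eb) {
      gamma_bar <- colMeans(gamma_hat)
      tau2 <- apply(gamma_hat, 2, var)
      # inverse-gamma hyperpriors by method of moments
      d_mean <- colMeans(delta2_hat)
      d_var <- apply(delta2_hat, 2, var)
      lambda <- (d_mean^2 + 2 * d_var) / d_var
      theta <- (d_mean^3 + d_mean * d_var) / d_var

      gamma_star <- gamma_hat
      delta2_star <- delta2_hat
      for (bi in seq_along(batches)) {
        b <- batches[[bi]]
        zb <- z[, batch == b, drop = FALSE]
        nb <- ncol(zb)
        g_old <- gamma_hat[, bi]
        d_old <- delta2_hat[, bi]
        sum_z <- rowSums(zb)
        for (it in seq_len(max_iter)) {
          g_new <- (nb * tau2[bi] * (sum_z / nb) + d_old * gamma_bar[bi]) /
            (nb * tau2[bi] + d_old)
          ss <- rowSums((zb - g_new)^2)
          d_new <- (theta[bi] + 0.5 * ss) / (nb / 2 + lambda[bi] - 1)
          change <- max(abs(g_new - g_old) / (abs(g_old) + 1e-12),
                        abs(d_new - d_old) / (abs(d_old) + 1e-12))
          g_old <- g_new
          d_old <- d_new
          if (change < tol) break
        }
        gamma_star[, bi] <- g_old
        delta2_star[, bi] <- d_old
      }
    } else {
      gamma_bar <- tau2 <- lambda <- theta <- NULL
      gamma_star <- gamma_hat
      delta2_star <- delta2_hat
    }

    bidx <- match(batch, batches)
    z_adj <- (z - gamma_star[, bidx, drop = FALSE]) /
      sqrt(delta2_star)[, bidx, drop = FALSE]
    adj[use, ] <- z_adj * sqrt(pv) + gm
  } else {
    gamma_hat <- delta2_hat <- gamma_star <- delta2_star <- NULL
    gamma_bar <- tau2 <- lambda <- theta <- NULL
  }

  model <- structure(
    list(
      batches = batches, n_per_batch = as.integer(n_b), eb_enabled = eb,
      grand_mean = grand_mean, pooled_var = pooled_var,
      gamma_hat = gamma_hat, delta2_hat = delta2_hat,
      gamma_star = gamma_star, delta2_star = delta2_star,
      prior = list(gamma_bar = gamma_bar, tau2 = tau2,
                   lambda = lambda, theta = theta),
      zero_variance_genes = rownames(x)[zero_var],
      identity = FALSE
    ),
    class = "batch_model"
  )
  list(adjusted = expr_matrix(adj, layer = "adjusted"), model = model)
}

#' @export
print.batch_model <- function(x, ...) {
  if (isTRUE(x$identity)) {
    cat("<batch_model> single batch (identity adjustment)\n")
  } else {
    cat(sprintf("<batch_model> %d batches, empirical Bayes %s\n",
                length(x$batches), if (x$eb_enabled) "on" else "off"))
  }
  invisible(x)
}

#' Merge per-cohort expression matrices into one matrix
#'
#' Column-binds cohort matrices over their shared genes and returns the
#' merged matrix together with the batch label vector, ready for
#' [combat_adjust()].
#'
#' @param expr_list Named list of [expr_matrix] objects (names are batch
#'   labels).
#' @return A list with `expr` (merged [expr_matrix]) and `batch`
#'   (character vector along samples).
#' @export
merge_cohorts <- function(expr_list) {
  stopifnot(length(expr_list) >= 1, !is.null(names(expr_list)))
  shared <- Reduce(intersect, lapply(expr_list, rownames))
  if (length(shared) == 0) abort("cohorts share no genes.")
  mats <- lapply(expr_list, function(m) unclass(m)[shared, , drop = FALSE])
  merged <- do.call(cbind, mats)
  batch <- rep(names(expr_list), vapply(mats, ncol, integer(1)))
  layer <- expr_layer(expr_list[[1]])
  list(expr = expr_matrix(merged, layer = layer), batch = batch)
}
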