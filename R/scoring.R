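#' Quality-control thresholds for single-cell filtering
#'
#' Defaults mirror the strict filters used throughout single-cell ICI
#' cohort processing: drop a cell when detected genes exceed 7,500 or fall
#' below 200, total reads exceed 75,000, or the mitochondrial read
#' fraction exceeds 20%. All comparisons are strict, so a cell sitting
#' exactly on a boundary is retained.
#'
#' @param max_genes,min_genes Detected-gene bounds (count of genes with
#'   nonzero counts).
#' @param max_reads Total-read upper bound.
#' @param max_mito_frac Mitochondrial read-fraction upper bound, in [0, 1].
#' @return A `qc_thresholds` list.
#' @export
qc_thresholds <- function(max_genes = 7500, min_genes = 200,
                          max_reads = 75000, max_mito_frac = 0.20) {
  stopifnot(min_genes < max_genes, max_mito_frac >= 0, max_mito_frac <= 1)
  structure(
    list(max_genes = max_genes, min_genes = min_genes,
         max_reads = max_reads, max_mito_frac = max_mito_frac),
    class = "qc_thresholds"
  )
}

#' Filter low-quality cells from a counts matrix
#'
#' @param m An [expr_matrix] with the counts layer.
#' @param mito_genes A [gene_set] of mitochondrial genes, or `NULL` to use
#'   every gene whose symbol starts with `"MT-"`.
#' @param thresholds A [qc_thresholds()].
#' @return The filtered [expr_matrix] (genes unchanged). The number of
#'   cells failing each criterion is attached as attribute `qc_removed`
#'   (a named integer vector; a cell can fail several criteria).
#' @export
qc_filter_cells <- function(m, mito_genes = NULL, thresholds = qc_thresholds()) {
  m <- as_expr_matrix(m)
  if (expr_layer(m) != "counts") abort("qc_filter_cells() requires the counts layer.")
  if (is.null(mito_genes)) {
    mito <- rownames(m)[startsWith(rownames(m), "MT-")]
  } else {
    mito <- intersect(as_gene_set(mito_genes, "MITO")$genes, rownames(m))
  }
  detected <- colSums(m > 0)
  total <- colSums(m)
  mito_frac <- if (length(mito) > 0) {
    colSums(m[mito, , drop = FALSE]) / pmax(total, 1)
  } else {
    rep(0, ncol(m))
  }
  fail <- cbind(
    too_many_genes = detected > thresholds$max_genes,
    too_few_genes = detected < thresholds$min_genes,
    too_many_reads = total > thresholds$max_reads,
    high_mito = mito_frac > thresholds$max_mito_frac
  )
  keep <- rowSums(fail) == 0
  if (!any(keep)) abort("all cells removed by QC filtering.")
  out <- rewrap(unclass(m)[, keep, drop = FALSE], m, layer = "counts")
  attr(out, "qc_removed") <- colSums(fail)
  out
}

#' Log-normalize a counts matrix
#'
#' Per cell, `count -> ln(1 + scale * count / cell_total)` -- the standard
#' library-size normalization followed by log1p, applied column-wise.
#'
#' @param m An [expr_matrix] with the counts layer.
#' @param scale Scale factor (default 10,000).
#' @return An [expr_matrix] with layer `lognorm`.
#' @export
#' @examples
#' m <- expr_matrix(matrix(c(1, 1, 2, 0, 2, 2), 3,
#'   dimnames = list(c("A", "B", "C"), c("c1", "c2"))
#' ))
#' log_normalize(m)["A", "c1"] # log(1 + 10000 * 1/4)
log_normalize <- function(m, scale = 10000) {
  m <- as_expr_matrix(m)
  if (expr_layer(m) != "counts") abort("log_normalize() requires the counts layer.")
  totals <- colSums(m)
  zero <- which(totals == 0)
  if (length(zero) > 0) {
    abort(paste0("cell(s) with zero total counts: ",
                 paste(head(colnames(m)[zero], 5), collapse = ", ")))
  }
  vals <- log1p(sweep(unclass(m), 2, totals / scale, "/"))
  rewrap(vals, m, layer = "lognorm")
}

# internal: ssGSEA running-sum score for one observation given precomputed
# average-tie ranks (higher expression -> larger rank)
.ssgsea_one <- function(ranks, in_set, alpha) {
  ord <- order(ranks, decreasing = TRUE)
  in_ord <- in_set[ord]
  w <- abs(ranks[ord])^alpha
  step_in <- ifelse(in_ord, w, 0)
  step_in <- step_in / sum(step_in)
  step_out <- ifelse(in_ord, 0, 1 / sum(!in_ord))
  sum(cumsum(step_in - step_out))
}

#' Single-sample gene-set enrichment scores
#'
#' The default `ssgsea` method is the single-sample rank statistic: within
#' each observation genes are ranked by expression (average ranks on
#' ties); a random walk down the ranking accrues `|rank|^alpha` (normalized
#' to total 1) at in-set genes and `1/(G - |S|)` at out-of-set genes; the
#' score is the sum of the running sum (the area between the in-set and
#' out-of-set empirical CDFs). Raw scores are then min-max rescaled across
#' the observations of the matrix to span [-1, 1], so scores are
#' matrix-relative and must never be compared across matrices. Being
#' rank-based, the score is invariant to any strictly monotone
#' per-observation transform of expression.
#'
#' The `zmean` fallback is the mean, over set genes, of gene-wise z-scored
#' expression.
#'
#' @param m An [expr_matrix] (lognorm layer expected).
#' @param sets A [gene_set], or a (named) list of them.
#' @param method `"ssgsea"` or `"zmean"`.
#' @param alpha Rank-weight exponent for ssgsea.
#' @return An `enrichment_scores` object: a numeric matrix (sets x
#'   observations) with class attribute, convertible with [tidy()].
#' @export
score_gene_set <- function(m, sets, method = c("ssgsea", "zmean"), alpha = 0.25) {
  method <- match.arg(method)
  m <- as_expr_matrix(m, layer = "lognorm")
  if (inherits(sets, "gene_set")) sets <- list(sets)
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    names(sets) <- vapply(sets, function(s) as_gene_set(s)$name, character(1))
  }
  x <- unclass(m)
  scores <- matrix(NA_real_, nrow = length(sets), ncol = ncol(x),
                   dimnames = list(names(sets), colnames(x)))
  if (method == "ssgsea") {
    ranks <- apply(x, 2, rank) # average ranks on ties
    for (i in seq_along(sets)) {
      s <- as_gene_set(sets[[i]])
      present <- intersect(s$genes, rownames(x))
      if (length(present) < length(s$genes)) {
        warn(sprintf("set '%s': %d gene(s) absent from the matrix, dropped.",
                     s$name, length(s$genes) - length(present)))
      }
      if (length(present) < 2) {
        abort(sprintf("set '%s': fewer than 2 genes present in the matrix.", s$name))
      }
      if (length(present) >= nrow(x)) {
        abort(sprintf("set '%s' covers the whole matrix; no out-of-set genes.", s$name))
      }
      in_set <- rownames(x) %in% present
      raw <- vapply(seq_len(ncol(x)), function(j) {
        .ssgsea_one(ranks[, j], in_set, alpha)
      }, numeric(1))
      rng <- range(raw)
      scores[i, ] <- if (diff(rng) == 0) 0 else 2 * (raw - rng[1]) / diff(rng) - 1
    }
  } else {
    for (i in seq_along(sets)) {
      s <- as_gene_set(sets[[i]])
      present <- intersect(s$genes, rownames(x))
      if (length(present) < 2) {
        abort(sprintf("set '%s': fewer than 2 genes present in the matrix.", s$name))
      }
      sub <- x[present, , drop = FALSE]
      sds <- apply(sub, 1, sd)
      if (any(sds == 0)) {
        warn(sprintf("set '%s': %d zero-variance gene(s) skipped.", s$name, sum(sds == 0)))
        sub <- sub[sds > 0, , drop = FALSE]
        sds <- sds[sds > 0]
      }
      if (nrow(sub) == 0) {
        scores[i, ] <- 0
        next
      }
      z <- (sub - rowMeans(sub)) / sds
      scores[i, ] <- colMeans(z)
    }
  }
  structure(scores, class = c("enrichment_scores", class(matrix())))
}

#' @export
print.enrichment_scores <- function(x, ...) {
  cat(sprintf("<enrichment_scores> %d set(s) x %d observations\n", nrow(x), ncol(x)))
  invisible(x)
}

#' @rdname score_gene_set
#' @param x An `enrichment_scores` object.
#' @param ... Unused.
#' @method tidy enrichment_scores
#' @export
tidy.enrichment_scores <- function(x, ...) {
  as_tibble(unclass(x), rownames = "set") |>
    tidyr::pivot_longer(-"set", names_to = "obs_id", values_to = "score")
}
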