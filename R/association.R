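#' Correlate a signature score with per-sample features
#'
#' Spearman correlation of a per-sample score against every feature row
#' (gene expression or other per-sample scores), with two-sided p-values
#' and Benjamini-Hochberg FDR across features.
#'
#' @param score Named numeric vector of per-sample scores.
#' @param features An [expr_matrix], `enrichment_scores` matrix, or plain
#'   numeric matrix (features x samples) covering the score's samples.
#' @return A tibble: feature, spearman_r, p_value, fdr, n_obs.
#' @export
correlate_score_with_features <- function(score, features) {
  if (is.null(names(score))) abort("`score` must be named by sample id.")
  x <- unclass(features)
  if (!is.matrix(x)) abort("`features` must be a matrix (features x samples).")
  common <- intersect(names(score), colnames(x))
  if (length(common) < 3) abort("need at least 3 shared samples.")
  s <- score[common]
  if (sd(s) == 0) abort("score vector is constant; correlation undefined.")
  res <- spearman_rows(x[, common, drop = FALSE], s)
  out <- tibble(feature = rownames(x)) |> dplyr::bind_cols(res)
  out$fdr <- NA_real_
  ok <- !is.na(out$p_value)
  out$fdr[ok] <- p.adjust(out$p_value[ok], method = "BH")
  out[, c("feature", "spearman_r", "p_value", "fdr", "n_obs")]
}

#' Marker-based immune infiltration scores
#'
#' Relative abundance of immune/stromal populations from bulk expression:
#' each population's score per sample is the arithmetic mean of its marker
#' genes' expression. Marker sets are user-supplied (e.g. a GMT of
#' population markers); markers absent from the matrix are dropped with a
#' warning, and a population with no present markers is skipped.
#'
#' @param m An [expr_matrix] (lognorm layer).
#' @param marker_sets A list of [gene_set]s, one per population.
#' @return An `enrichment_scores` matrix (populations x samples).
#' @export
marker_infiltration <- function(m, marker_sets) {
  m <- as_expr_matrix(m, layer = "lognorm")
  if (inherits(marker_sets, "gene_set")) marker_sets <- list(marker_sets)
  x <- unclass(m)
  rows <- list()
  for (s in marker_sets) {
    s <- as_gene_set(s)
    present <- intersect(s$genes, rownames(x))
    if (length(present) == 0) {
      warn(sprintf("population '%s': no marker genes present, skipped.", s$name))
      next
    }
    if (length(present) < length(s$genes)) {
      warn(sprintf("population '%s': %d marker(s) absent, dropped.",
                   s$name, length(s$genes) - length(present)))
    }
    rows[[s$name]] <- colMeans(x[present, , drop = FALSE])
  }
  if (length(rows) == 0) abort("no population had any marker genes present.")
  scores <- do.call(rbind, rows)
  dimnames(scores) <- list(names(rows), colnames(x))
  structure(scores, class = c("enrichment_scores", class(matrix())))
}

#' Median-split quadrant labels from signature score and TMB
#'
#' Samples are split at the median on each axis -- high means strictly
#' greater than the median, low means less than or equal (ties go to
#' low) -- and labelled HGHT, HGLT, LGHT or LGLT (high/low Glyc
#' signature x high/low TMB).
#'
#' @param sig_scores Named numeric vector of signature scores.
#' @param tmb Named numeric vector of tumour mutational burden, same
#'   samples.
#' @return A tibble: sample_id, label (factor with the four levels).
#' @export
#' @examples
#' median_quadrants(c(a = 1, b = 2, c = 3, d = 4), c(a = 4, b = 3, c = 2, d = 1))
median_quadrants <- function(sig_scores, tmb) {
  if (is.null(names(sig_scores)) || is.null(names(tmb))) {
    abort("both vectors must be named by sample id.")
  }
  common <- intersect(names(sig_scores), names(tmb))
  if (length(common) < 4) abort("need at least 4 shared samples.")
  s <- sig_scores[common]
  t <- tmb[common]
  if (length(unique(s)) == 1 || length(unique(t)) == 1) {
    abort("median split undefined for an all-equal vector.")
  }
  high_g <- s > median(s)
  high_t <- t > median(t)
  label <- paste0(ifelse(high_g, "HG", "LG"), ifelse(high_t, "HT", "LT"))
  tibble(
    sample_id = common,
    label = factor(label, levels = c("HGHT", "HGLT", "LGHT", "LGLT"))
  )
}

#' Pairwise group comparisons by Mann-Whitney U
#'
#' Two-sided Mann-Whitney tests between every pair of groups (exact
#' enumeration when both groups have <= 8 samples, tie-corrected normal
#' approximation otherwise), with Benjamini-Hochberg adjustment across the
#' pairs. Pairs involving a group with fewer than 2 samples are skipped
#' with a warning.
#'
#' @param values Numeric vector.
#' @param group_labels Vector of group labels, same length.
#' @return A tibble: group1, group2, n1, n2, statistic (U for group1),
#'   p_value, fdr.
#' @export
compare_groups <- function(values, group_labels) {
  stopifnot(length(values) == length(group_labels))
  keep <- !is.na(values) & !is.na(group_labels)
  values <- values[keep]
  group_labels <- as.character(group_labels[keep])
  groups <- sort(unique(group_labels))
  if (length(groups) < 2) abort("need at least 2 groups.")
  sizes <- table(group_labels)
  small <- names(sizes)[sizes < 2]
  if (length(small) > 0) {
    warn(paste0("group(s) with < 2 samples skipped: ", paste(small, collapse = ", ")))
  }
  eligible <- setdiff(groups, small)
  if (length(eligible) < 2) abort("no testable group pair.")
  pairs <- combn(eligible, 2, simplify = FALSE)
  out <- purrr::map_dfr(pairs, function(pr) {
    x <- values[group_labels == pr[1]]
    y <- values[group_labels == pr[2]]
    mw <- mann_whitney(x, y)
    tibble(group1 = pr[1], group2 = pr[2], n1 = length(x), n2 = length(y),
           statistic = mw$statistic, p_value = mw$p.value)
  })
  out$fdr <- p.adjust(out$p_value, method = "BH")
  out
}
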