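#' Correlate gene expression with glycolysis scores in malignant cells
#'
#' Per gene, Spearman correlation (average ranks on ties) between
#' expression and a per-cell glycolysis score, restricted to the masked
#' (malignant) observations; two-sided p-values (t approximation for
#' n > 10) and Benjamini-Hochberg FDR across all non-constant genes of the
#' dataset. FDR is computed within each dataset separately, never pooled
#' across datasets.
#'
#' @param m An [expr_matrix] (lognorm layer).
#' @param glyc Named numeric vector of per-observation glycolysis scores
#'   covering the observations of `m`, or a 1-set `enrichment_scores`
#'   matrix.
#' @param obs_mask Logical vector along observations, or character vector
#'   of observation ids, selecting the (malignant) cells to use; `NULL`
#'   uses all.
#' @return A tibble: gene, spearman_r, p_value, fdr, n_obs. Constant genes
#'   have NA statistics and are excluded from the FDR adjustment.
#' @export
correlate_with_glycolysis <- function(m, glyc, obs_mask = NULL) {
  m <- as_expr_matrix(m, layer = "lognorm")
  if (inherits(glyc, "enrichment_scores")) {
    stopifnot(nrow(glyc) == 1)
    glyc <- setNames(as.vector(glyc[1, ]), colnames(glyc))
  }
  if (is.null(names(glyc))) abort("`glyc` must be named by observation id.")
  missing_obs <- setdiff(colnames(m), names(glyc))
  if (length(missing_obs) > 0) abort("glycolysis scores missing for some observations.")
  glyc <- glyc[colnames(m)]
  if (!is.null(obs_mask)) {
    if (is.character(obs_mask)) obs_mask <- colnames(m) %in% obs_mask
    stopifnot(length(obs_mask) == ncol(m))
    m <- rewrap(unclass(m)[, obs_mask, drop = FALSE], m)
    glyc <- glyc[obs_mask]
  }
  if (ncol(m) < 3) abort("need at least 3 masked observations.")
  res <- spearman_rows(unclass(m), glyc)
  out <- tibble(gene = rownames(m)) |> dplyr::bind_cols(res)
  out$fdr <- NA_real_
  ok <- !is.na(out$p_value)
  out$fdr[ok] <- p.adjust(out$p_value[ok], method = "BH")
  out[, c("gene", "spearman_r", "p_value", "fdr", "n_obs")]
}

#' Select the glycolysis-correlated gene set (Gx)
#'
#' Genes with a strictly positive correlation with glycolysis-intensity
#' scores: `spearman_r > r_min` and `fdr < fdr_max`, both strict.
#'
#' @param corrs Tibble from [correlate_with_glycolysis()].
#' @param r_min Correlation floor (default 0).
#' @param fdr_max FDR ceiling (default 1e-5).
#' @return A [gene_set] (possibly empty) named `"GX"`, with the selected
#'   rows of `corrs` attached as attribute `stats`.
#' @export
select_gx <- function(corrs, r_min = 0, fdr_max = 1e-5) {
  keep <- !is.na(corrs$spearman_r) & !is.na(corrs$fdr) &
    corrs$spearman_r > r_min & corrs$fdr < fdr_max
  out <- gene_set("GX", corrs$gene[keep], allow_empty = TRUE)
  attr(out, "stats") <- corrs[keep, ]
  out
}

#' Select malignant-overexpressed genes (Gy)
#'
#' Per gene, a two-sided Wilcoxon rank-sum test of malignant versus all
#' other cells (exact enumeration when both groups have <= 8 cells,
#' tie-corrected normal approximation otherwise) and the log-scale fold
#' change `mean(malignant) - mean(rest)`. Gy keeps genes with
#' `fdr < fdr_max` and `logfc > min_logfc` (BH across all tested genes).
#'
#' @param m An [expr_matrix] (lognorm layer).
#' @param malignant_mask Logical vector along observations (or character
#'   ids) marking malignant cells.
#' @param fdr_max,min_logfc Selection thresholds.
#' @return A [gene_set] named `"GY"` with per-gene statistics (gene,
#'   logfc, p_value, fdr) in attribute `stats`.
#' @export
select_gy <- function(m, malignant_mask, fdr_max = 0.05, min_logfc = 0.25) {
  m <- as_expr_matrix(m, layer = "lognorm")
  if (is.character(malignant_mask)) malignant_mask <- colnames(m) %in% malignant_mask
  stopifnot(length(malignant_mask) == ncol(m))
  if (!any(malignant_mask) || all(malignant_mask)) {
    abort("both malignant and non-malignant observations are required.")
  }
  x <- unclass(m)
  mal <- x[, malignant_mask, drop = FALSE]
  rest <- x[, !malignant_mask, drop = FALSE]
  logfc <- unname(rowMeans(mal) - rowMeans(rest))
  p <- vapply(seq_len(nrow(x)), function(i) {
    mann_whitney(mal[i, ], rest[i, ])$p.value
  }, numeric(1))
  fdr <- p.adjust(p, method = "BH")
  stats <- tibble(gene = rownames(x), logfc = logfc, p_value = p, fdr = fdr)
  keep <- fdr < fdr_max & logfc > min_logfc
  out <- gene_set("GY", rownames(x)[keep], allow_empty = TRUE)
  attr(out, "stats") <- stats[keep, ]
  out
}

#' Derive the per-dataset candidate gene sets (Gx, Gy, Gn)
#'
#' Runs the full per-dataset leg of signature derivation: score every cell
#' for glycolysis intensity with [score_gene_set()], correlate gene
#' expression with that score across malignant cells, select Gx
#' (glycolysis-correlated) and Gy (malignant-overexpressed), and intersect
#' them into Gn -- the dataset's tumour-specific, glycolysis-coupled
#' candidate genes.
#'
#' @param dataset_id Identifier for this dataset.
#' @param m An [expr_matrix] (lognorm layer).
#' @param annotations Tibble with columns `cell_id` and logical
#'   `malignant` covering the observations of `m`.
#' @param glyc_set [gene_set] of glycolysis-intensity genes to score with.
#' @param method,alpha Passed to [score_gene_set()].
#' @param gx_r_min,gx_fdr_max,gy_fdr_max,gy_min_logfc Selection thresholds
#'   passed to [select_gx()] / [select_gy()].
#' @return A `dataset_gene_sets` list: dataset_id, gx, gy, gn (gene_sets),
#'   correlations (tibble), n_malignant.
#' @export
derive_dataset_sets <- function(dataset_id, m, annotations, glyc_set,
                                method = "ssgsea", alpha = 0.25,
                                gx_r_min = 0, gx_fdr_max = 1e-5,
                                gy_fdr_max = 0.05, gy_min_logfc = 0.25) {
  m <- as_expr_matrix(m, layer = "lognorm")
  stopifnot(all(c("cell_id", "malignant") %in% names(annotations)))
  ann <- annotations[match(colnames(m), annotations$cell_id), ]
  if (any(is.na(ann$cell_id))) abort("annotations do not cover all observations.")
  if (!any(ann$malignant)) abort("no malignant cells in annotations.")
  scores <- score_gene_set(m, glyc_set, method = method, alpha = alpha)
  corrs <- correlate_with_glycolysis(m, scores, obs_mask = ann$malignant)
  gx <- select_gx(corrs, r_min = gx_r_min, fdr_max = gx_fdr_max)
  gy <- select_gy(m, ann$malignant, fdr_max = gy_fdr_max, min_logfc = gy_min_logfc)
  gn <- gene_set("GN", intersect(gx$genes, gy$genes), allow_empty = TRUE)
  structure(
    list(dataset_id = dataset_id, gx = gx, gy = gy, gn = gn,
         correlations = corrs, n_malignant = sum(ann$malignant)),
    class = "dataset_gene_sets"
  )
}

#' @export
print.dataset_gene_sets <- function(x, ...) {
  cat(sprintf("<dataset_gene_sets> %s: |Gx| = %d, |Gy| = %d, |Gn| = %d\n",
              x$dataset_id, length(x$gx$genes), length(x$gy$genes), length(x$gn$genes)))
  invisible(x)
}

#' Aggregate per-dataset gene sets into the glycolytic signature
#'
#' For every gene appearing in any dataset's Gn, collect its Spearman R
#' from each dataset whose Gn contains it (these are positive by
#' construction), take the geometric mean, and admit the gene to the
#' signature when the geometric mean strictly exceeds `r_threshold` and
#' the gene was supported by at least `min_datasets` datasets.
#'
#' @param sets List of `dataset_gene_sets` from [derive_dataset_sets()].
#' @param r_threshold Geometric-mean correlation cut (default 0.3, strict).
#' @param min_datasets Minimum dataset support (default 1).
#' @param name Name for the returned signature gene set.
#' @return A `signature_aggregate` list with `signature` (a [gene_set])
#'   and `aggregates`: a tibble (gene, n_datasets, geo_mean_r,
#'   in_signature, per_dataset_r list-column) sorted by decreasing
#'   geo_mean_r. The result is independent of the order of `sets`.
#' @export
aggregate_signature <- function(sets, r_threshold = 0.3, min_datasets = 1,
                                name = "GLYC_SIGNATURE") {
  if (length(sets) < 1) abort("at least one dataset is required.")
  per_gene <- purrr::map_dfr(sets, function(ds) {
    genes <- ds$gn$genes
    if (length(genes) == 0) return(tibble())
    r <- ds$correlations$spearman_r[match(genes, ds$correlations$gene)]
    tibble(gene = genes, dataset_id = ds$dataset_id, spearman_r = r)
  })
  if (nrow(per_gene) == 0) {
    return(structure(
      list(signature = gene_set(name, character(0), allow_empty = TRUE),
           aggregates = tibble(gene = character(0), n_datasets = integer(0),
                               geo_mean_r = numeric(0), in_signature = logical(0),
                               per_dataset_r = list()),
           r_threshold = r_threshold, min_datasets = min_datasets),
      class = "signature_aggregate"
    ))
  }
  if (any(per_gene$spearman_r <= 0, na.rm = TRUE)) {
    abort("internal invariant violated: Gn gene with non-positive Spearman R.")
  }
  agg <- per_gene |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(
      n_datasets = dplyr::n(),
      geo_mean_r = exp(mean(log(.data$spearman_r))),
      per_dataset_r = list(setNames(.data$spearman_r, .data$dataset_id)),
      .groups = "drop"
    ) |>
    # strict threshold with a guard against floating-point noise in the
    # log-mean-exp geometric mean, so boundary cases stay excluded
    dplyr::mutate(in_signature = .data$geo_mean_r > r_threshold + 1e-12 &
                    .data$n_datasets >= min_datasets) |>
    dplyr::arrange(dplyr::desc(.data$geo_mean_r), .data$gene) |>
    dplyr::relocate("gene", "n_datasets", "geo_mean_r", "in_signature")
  structure(
    list(signature = gene_set(name, agg$gene[agg$in_signature], allow_empty = TRUE),
         aggregates = agg,
         r_threshold = r_threshold, min_datasets = min_datasets),
    class = "signature_aggregate"
  )
}

#' @export
print.signature_aggregate <- function(x, ...) {
  cat(sprintf("<signature_aggregate> %d candidate gene(s), %d in signature\n",
              nrow(x$aggregates), length(x$signature$genes)))
  invisible(x)
}

#' @rdname aggregate_signature
#' @param x A `signature_aggregate`.
#' @param ... Unused.
#' @method tidy signature_aggregate
#' @export
tidy.signature_aggregate <- function(x, ...) {
  dplyr::select(x$aggregates, -"per_dataset_r")
}

#' @rdname aggregate_signature
#' @method glance signature_aggregate
#' @export
glance.signature_aggregate <- function(x, ...) {
  tibble(
    n_candidates = nrow(x$aggregates),
    n_signature = length(x$signature$genes),
    max_geo_mean_r = if (nrow(x$aggregates)) max(x$aggregates$geo_mean_r) else NA_real_
  )
}
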