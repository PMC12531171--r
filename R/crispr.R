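#' Collapse guide-level log-fold changes to gene level
#'
#' A gene's log-fold change is the arithmetic mean of its sgRNAs'
#' log-fold changes within a screen.
#'
#' @param screen Tibble with columns `gene` and `lfc` (one row per sgRNA);
#'   a `dataset` column, if present, is carried through (one value per
#'   screen expected).
#' @return A tibble: (dataset,) gene, lfc, n_sgrna.
#' @export
gene_level_lfc <- function(screen) {
  stopifnot(all(c("gene", "lfc") %in% names(screen)))
  grp <- intersect(c("dataset", "gene"), names(screen))
  screen |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(n_sgrna = dplyr::n(), lfc = mean(.data$lfc), .groups = "drop") |>
    dplyr::relocate(dplyr::all_of(grp), "lfc", "n_sgrna")
}

#' Z-score normalize gene-level log-fold changes within a dataset
#'
#' `z = (lfc - mean) / sd` with the sample standard deviation (n - 1
#' denominator), so z-scores are comparable across screens of different
#' depth and dynamic range.
#'
#' @param gene_lfc Tibble with columns `gene` and `lfc` for one dataset
#'   (e.g. one group of [gene_level_lfc()] output).
#' @param dataset_id Dataset identifier; defaults to the `dataset` column
#'   if present.
#' @return A `screen_z_table` tibble: dataset, gene, z (mean 0, sd 1 over
#'   recorded genes).
#' @export
zscore_normalize <- function(gene_lfc, dataset_id = NULL) {
  stopifnot(all(c("gene", "lfc") %in% names(gene_lfc)))
  if (is.null(dataset_id)) {
    dataset_id <- if ("dataset" %in% names(gene_lfc)) unique(gene_lfc$dataset) else "D01"
  }
  stopifnot(length(dataset_id) == 1)
  if (nrow(gene_lfc) < 2) abort("need at least 2 genes to z-normalize.")
  s <- sd(gene_lfc$lfc)
  if (s == 0) abort("constant log-fold changes; z-normalization undefined.")
  tibble(
    dataset = as.character(dataset_id),
    gene = toupper(gene_lfc$gene),
    z = (gene_lfc$lfc - mean(gene_lfc$lfc)) / s
  )
}

#' Rank genes by average Z across CRISPR screens
#'
#' Per gene, the mean z over the datasets in which it is recorded
#' (missing (gene, dataset) pairs are simply skipped); genes present in
#' fewer than `min_presence` datasets are excluded. Genes are ranked
#' ascending by mean z -- rank 1 is the most negative, i.e. the strongest
#' immune-resistance candidate -- with ties broken lexicographically by
#' symbol for determinism. The result is invariant to dataset order.
#'
#' @param tables List of `screen_z_table` tibbles from
#'   [zscore_normalize()] (or one combined tibble).
#' @param min_presence Minimum number of datasets a gene must appear in.
#' @return A tibble: gene, mean_z, n_datasets_present, rank, percentile
#'   (= rank / N).
#' @export
aggregate_rank <- function(tables, min_presence = 1) {
  if (is.data.frame(tables)) tables <- list(tables)
  if (length(tables) < 1) abort("at least one z-table is required.")
  combined <- dplyr::bind_rows(tables)
  if (nrow(combined) == 0) abort("no genes recorded in any dataset.")
  out <- combined |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(mean_z = mean(.data$z),
                     n_datasets_present = dplyr::n_distinct(.data$dataset),
                     .groups = "drop") |>
    dplyr::filter(.data$n_datasets_present >= min_presence) |>
    dplyr::arrange(.data$mean_z, .data$gene)
  if (nrow(out) == 0) abort("no gene meets the presence threshold.")
  out |> dplyr::mutate(rank = dplyr::row_number(),
                       percentile = .data$rank / dplyr::n())
}

#' Top fraction of an immune-resistance ranking
#'
#' The first `floor(frac * N)` genes of the ascending mean-z ranking (on
#' 22,505 ranked genes the 5%, 10% and 20% cuts contain 1,125, 2,250 and
#' 4,501 genes).
#'
#' @param ranked Tibble from [aggregate_rank()].
#' @param frac Fraction in (0, 1).
#' @param name Name for the returned gene set.
#' @return A [gene_set] of the top-ranked genes, in rank order.
#' @export
top_fraction <- function(ranked, frac, name = NULL) {
  stopifnot(frac > 0, frac < 1)
  k <- floor(frac * nrow(ranked))
  if (k == 0) abort("floor(frac * N) is zero; fraction too small for this ranking.")
  if (is.null(name)) name <- sprintf("TOP_%g_PCT", 100 * frac)
  gene_set(name, ranked$gene[seq_len(k)])
}

#' Enrichment of a signature among top-ranked genes
#'
#' Fisher's exact test of the 2x2 table (in signature x in top set) over
#' the ranking universe: by default the one-sided enrichment p-value, i.e.
#' the hypergeometric upper tail of the overlap. The signature is first
#' restricted to the universe (its restricted size is reported).
#'
#' @param signature [gene_set] under test.
#' @param top [gene_set] of top-ranked genes (must be within the
#'   universe).
#' @param universe [gene_set] of all ranked genes.
#' @param sided `"greater"` (enrichment, default) or `"two.sided"`.
#' @return A one-row tibble: overlap (k), n_signature_in_universe,
#'   n_top, n_universe, proportion (k over signature-in-universe),
#'   fisher_p.
#' @export
enrichment_test <- function(signature, top, universe, sided = c("greater", "two.sided")) {
  sided <- match.arg(sided)
  sig <- as_gene_set(signature, "SIGNATURE")$genes
  top_g <- as_gene_set(top, "TOP")$genes
  uni <- as_gene_set(universe, "UNIVERSE")$genes
  if (!all(top_g %in% uni)) abort("top set must be a subset of the universe.")
  sig_u <- intersect(sig, uni)
  if (length(sig_u) == 0) abort("signature does not intersect the universe.")
  k <- length(intersect(sig_u, top_g))
  m <- length(top_g)
  n_uni <- length(uni)
  s <- length(sig_u)
  p <- if (sided == "greater") {
    phyper(k - 1, m, n_uni - m, s, lower.tail = FALSE)
  } else {
    stats::fisher.test(
      matrix(c(k, s - k, m - k, n_uni - m - s + k), nrow = 2),
      alternative = "two.sided"
    )$p.value
  }
  tibble(
    overlap = k,
    n_signature_in_universe = s,
    n_top = m,
    n_universe = n_uni,
    proportion = k / s,
    fisher_p = p
  )
}
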