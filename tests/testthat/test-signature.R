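# fabricate a dataset_gene_sets object directly (for aggregation tests)
fake_ds <- function(id, genes, r) {
  corr <- tibble::tibble(gene = genes, spearman_r = r,
                         p_value = 1e-8, fdr = 1e-7, n_obs = 100L)
  structure(
    list(dataset_id = id,
         gx = gene_set("GX", genes, allow_empty = TRUE),
         gy = gene_set("GY", genes, allow_empty = TRUE),
         gn = gene_set("GN", genes, allow_empty = TRUE),
         correlations = corr, n_malignant = 100L),
    class = "dataset_gene_sets"
  )
}

test_that("gene-glycolysis correlation matches hand-computed Spearman values", {
  m <- tiny_expr(rbind(c(1, 2, 3, 4, 5),
                       c(2, 1, 4, 3, 5),
                       c(5, 4, 3, 2, 1),
                       c(7, 7, 7, 7, 7)))
  glyc <- setNames(c(10, 20, 30, 40, 50), colnames(m))
  res <- correlate_with_glycolysis(m, glyc)
  expect_equal(res$spearman_r[1], 1)
  expect_equal(res$spearman_r[2], 0.8)  # 1 - 6*4 / (5*24)
  expect_equal(res$spearman_r[3], -1)
  expect_true(is.na(res$spearman_r[4])) # constant gene
  expect_true(is.na(res$fdr[4]))
  expect_true(all(res$fdr >= res$p_value, na.rm = TRUE))
  expect_error(correlate_with_glycolysis(m, setNames(rep(1, 5), colnames(m))),
               "constant")
})

test_that("small-n Spearman p-values agree with permutation enumeration", {
  x <- c(2, 1, 4, 3, 5)
  y <- c(1, 2, 3, 4, 5)
  m <- tiny_expr(matrix(x, 1, dimnames = list("G001", paste0("s", 1:5))))
  res <- correlate_with_glycolysis(m, setNames(y, colnames(m)))
  expect_equal(res$p_value[1], oracle_spearman_exact_p(x, y), tolerance = 1e-9)
})

test_that("Gx selection applies strict thresholds", {
  corrs <- tibble::tibble(
    gene = c("A", "B", "C", "D"),
    spearman_r = c(0.5, 0.5, -0.2, 0.4),
    p_value = c(1e-7, 1e-5, 1e-10, 1e-6),
    fdr = c(1e-6, 1e-4, 1e-9, 1e-5),
    n_obs = 50L
  )
  gx <- select_gx(corrs)
  expect_identical(gx$genes, "A")        # B fails FDR, C fails sign
  # D sits exactly at FDR = 1e-5: excluded by strictness
  expect_false("D" %in% gx$genes)
  expect_length(select_gx(corrs[0, ])$genes, 0)
})

test_that("Gy small-group test is an exact enumeration", {
  m <- tiny_expr(matrix(c(5, 6, 7, 1, 2, 3), 1, 6,
                        dimnames = list("A", paste0("c", 1:6))))
  mask <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  # fully separated 3 vs 3: exact two-sided p = 2 / choose(6,3) * 1 = 0.1
  gy_default <- select_gy(m, mask)            # 0.1 > 0.05: excluded
  expect_length(gy_default$genes, 0)
  gy_relaxed <- select_gy(m, mask, fdr_max = 0.2)
  expect_identical(gy_relaxed$genes, "A")
  expect_equal(attr(gy_relaxed, "stats")$p_value, 0.1, tolerance = 1e-12)
  expect_equal(attr(gy_relaxed, "stats")$logfc, 4)

  # identical distributions: excluded
  m0 <- tiny_expr(matrix(rep(c(1, 2, 3), 2), 1, 6,
                         dimnames = list("A", paste0("c", 1:6))))
  expect_length(select_gy(m0, mask, fdr_max = 0.9)$genes, 0)

  # higher in rest: excluded regardless of p (sign of logfc)
  m_neg <- tiny_expr(matrix(c(1, 2, 3, 5, 6, 7), 1, 6,
                            dimnames = list("A", paste0("c", 1:6))))
  expect_length(select_gy(m_neg, mask, fdr_max = 0.9)$genes, 0)

  expect_error(select_gy(m, rep(TRUE, 6)), "non-malignant")
})

test_that("per-dataset derivation recovers planted genes and handles edge cases", {
  planted <- sprintf("G%04d", 31:80)
  sim <- simulate_sc_dataset(
    n_genes = 1000, n_cells = 800,
    truth = sc_sim_truth(gene_set("P", planted), seed = 31)
  )
  ln <- log_normalize(sim$expr)
  ds <- derive_dataset_sets("D1", ln, sim$annotations, sim$glyc_set)
  expect_identical(ds$gn$genes, intersect(ds$gx$genes, ds$gy$genes))
  expect_gte(mean(planted %in% ds$gn$genes), 0.8)
  # the glycolysis reference genes are correlated but not malignant-specific
  expect_length(intersect(sim$glyc_set$genes, ds$gn$genes), 0)
  # every Gn gene has a positive recorded correlation
  r_gn <- ds$correlations$spearman_r[match(ds$gn$genes, ds$correlations$gene)]
  expect_true(all(r_gn > 0))

  ann_none <- dplyr::mutate(sim$annotations, malignant = FALSE)
  expect_error(derive_dataset_sets("D1", ln, ann_none, sim$glyc_set), "malignant")
})

test_that("aggregation applies the geometric-mean rule with strict threshold", {
  sets <- list(
    fake_ds("D1", c("A", "B", "C"), c(0.4, 0.9, 0.35)),
    fake_ds("D2", c("A", "B"), c(0.4, 0.1))
  )
  agg <- aggregate_signature(sets, r_threshold = 0.3, min_datasets = 1)
  tab <- agg$aggregates
  expect_equal(tab$geo_mean_r[tab$gene == "A"], 0.4)           # constant case
  expect_equal(tab$geo_mean_r[tab$gene == "B"], 0.3)           # sqrt(0.09)
  expect_false(tab$in_signature[tab$gene == "B"])              # strict >
  expect_true(all(c("A", "C") %in% agg$signature$genes))

  # dataset-support floor
  agg2 <- aggregate_signature(sets, min_datasets = 2)
  expect_identical(agg2$signature$genes, "A")                  # C seen once
})

test_that("aggregation is order-invariant and geo-mean is bounded by extremes", {
  set.seed(8)
  sets <- lapply(1:4, function(i) {
    genes <- sample(LETTERS[1:15], 8)
    fake_ds(paste0("D", i), genes, runif(8, 0.05, 0.95))
  })
  a1 <- aggregate_signature(sets)
  a2 <- aggregate_signature(rev(sets))
  expect_identical(a1$aggregates$gene, a2$aggregates$gene)
  expect_equal(a1$aggregates$geo_mean_r, a2$aggregates$geo_mean_r)
  for (i in seq_len(nrow(a1$aggregates))) {
    rs <- a1$aggregates$per_dataset_r[[i]]
    expect_gte(a1$aggregates$geo_mean_r[i], min(rs) - 1e-12)
    expect_lte(a1$aggregates$geo_mean_r[i], max(rs) + 1e-12)
  }
})

test_that("empty Gn intersections give a valid empty result", {
  sets <- list(fake_ds("D1", character(0), numeric(0)))
  agg <- aggregate_signature(sets)
  expect_length(agg$signature$genes, 0)
  expect_equal(nrow(agg$aggregates), 0)
})
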