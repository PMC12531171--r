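test_that("single-cell generator couples planted genes to latent activity", {
  planted <- sprintf("G%04d", 31:80)
  sim <- simulate_sc_dataset(
    n_genes = 2000, n_cells = 1500,
    truth = sc_sim_truth(gene_set("P", planted), malignant_logfc = 1,
                         corr_strength = 1, seed = 42)
  )
  expect_identical(expr_layer(sim$expr), "counts")
  expect_identical(colnames(sim$expr), sim$annotations$cell_id)
  mal <- sim$annotations$malignant
  mean_planted <- colMeans(unclass(sim$expr)[planted, mal])
  r <- cor(mean_planted, sim$glyc_activity[mal], method = "spearman")
  expect_gt(r, 0.5)
})

test_that("decoupled null: planted genes show no malignant enrichment", {
  planted <- sprintf("G%04d", 31:80)
  sim <- simulate_sc_dataset(
    n_genes = 500, n_cells = 400,
    truth = sc_sim_truth(gene_set("P", planted), malignant_logfc = 0,
                         corr_strength = 0.01, seed = 9)
  )
  ln <- log_normalize(sim$expr)
  mal <- sim$annotations$malignant
  mean_planted_mal <- colMeans(unclass(ln)[planted, mal])
  mean_planted_rest <- colMeans(unclass(ln)[planted, !mal])
  p <- stats::wilcox.test(mean_planted_mal, mean_planted_rest)$p.value
  expect_gt(p, 0.001)
})

test_that("generators are bit-reproducible and return their truth untouched", {
  tr <- sc_sim_truth(gene_set("P", sprintf("G%04d", 31:40)), seed = 5)
  s1 <- simulate_sc_dataset(n_genes = 200, n_cells = 100, truth = tr)
  s2 <- simulate_sc_dataset(n_genes = 200, n_cells = 100, truth = tr)
  expect_identical(unclass(s1$expr), unclass(s2$expr))
  expect_identical(s1$glyc_activity, s2$glyc_activity)
  expect_identical(s1$truth, tr)

  ctr <- cohort_sim_truth(seed = 5)
  sig <- gene_set("S", sprintf("G%04d", 1:20))
  c1 <- simulate_ici_cohorts(2, 20, sig, ctr, n_genes = 100)
  c2 <- simulate_ici_cohorts(2, 20, sig, ctr, n_genes = 100)
  expect_identical(c1$expr, c2$expr)
  expect_identical(c1$clinical, c2$clinical)

  str_ <- screen_sim_truth(gene_set("R", sprintf("G%04d", 1:10)), seed = 5)
  k1 <- simulate_crispr_screens(200, str_)
  k2 <- simulate_crispr_screens(200, str_)
  expect_identical(k1$screens, k2$screens)
})

test_that("cohort generator reproduces the planted response effect", {
  sig <- gene_set("S", sprintf("G%04d", 1:50))
  sim <- simulate_ici_cohorts(
    n_cohorts = 4, n_per_cohort = 150, signature = sig,
    truth = cohort_sim_truth(signature_effect = 1, batch_loc_sd = 0,
                             batch_scale_sd = 0, true_hr = 2, seed = 21),
    n_genes = 300
  )
  merged <- merge_cohorts(sim$expr)
  x <- unclass(merged$expr)[sig$genes, ]
  resp <- setNames(sim$clinical$response, sim$clinical$sample_id)[colnames(x)]
  diff <- mean(x[, resp == "NR"]) - mean(x[, resp == "R"])
  expect_equal(diff, 1, tolerance = 0.1) # Monte-Carlo error at n = 600
  # survival fields are complete and censoring is present but not total
  expect_true(all(!is.na(sim$clinical$os_months)))
  expect_true(all(sim$clinical$event %in% 0:1))
  expect_gt(mean(sim$clinical$event), 0.4)
  expect_lt(mean(sim$clinical$event), 1)
})

test_that("hazard-neutral cohorts give uniform-ish survival p-values", {
  sig <- gene_set("S", sprintf("G%04d", 1:10))
  pvals <- vapply(1:8, function(i) {
    sim <- simulate_ici_cohorts(
      n_cohorts = 1, n_per_cohort = 60, signature = sig,
      truth = cohort_sim_truth(true_hr = 1, signature_effect = 0, seed = 100 + i),
      n_genes = 50
    )
    sv <- survival_compare(sim$clinical,
                           setNames(sim$clinical$response, sim$clinical$sample_id))
    sv$p_value
  }, numeric(1))
  expect_lte(sum(pvals < 0.05), 2) # ~0.4 expected under the null
})

test_that("screen generator plants negative shifts and drops pairs at the missing rate", {
  planted <- sprintf("G%04d", 1:25)
  tr <- screen_sim_truth(gene_set("R", planted), lfc_shift = -2,
                         n_datasets = 10, missing_rate = 0.3, seed = 13)
  sim <- simulate_crispr_screens(n_genes = 500, truth = tr)
  expect_length(sim$screens, 10)
  n_pairs <- sum(vapply(sim$screens, function(s) dplyr::n_distinct(s$gene), integer(1)))
  expect_equal(n_pairs / (500 * 10), 0.7, tolerance = 0.03)

  # planted genes rank low with no missingness and a strong shift
  tr0 <- screen_sim_truth(gene_set("R", planted), lfc_shift = -2,
                          n_datasets = 10, missing_rate = 0, seed = 13)
  sim0 <- simulate_crispr_screens(n_genes = 500, truth = tr0)
  ranked <- aggregate_rank(lapply(sim0$screens, function(s) zscore_normalize(gene_level_lfc(s))))
  planted_pct <- ranked$percentile[ranked$gene %in% planted]
  expect_true(all(planted_pct <= 0.1))

  # null shift: planted ranks scatter across the ranking
  trn <- screen_sim_truth(gene_set("R", planted), lfc_shift = 0,
                          n_datasets = 10, missing_rate = 0, seed = 13) |>
    suppressWarnings()
  simn <- simulate_crispr_screens(n_genes = 500, truth = trn)
  rankedn <- aggregate_rank(lapply(simn$screens, function(s) zscore_normalize(gene_level_lfc(s))))
  pctn <- rankedn$percentile[rankedn$gene %in% planted]
  expect_gt(mean(pctn), 0.25)
  expect_lt(mean(pctn), 0.75)
})

test_that("degenerate truth inputs are rejected", {
  expect_error(
    simulate_sc_dataset(n_genes = 50, n_cells = 20,
      truth = sc_sim_truth(gene_set("P", c("G0001", "ZZZZ")), seed = 1)),
    "universe"
  )
  expect_error(
    simulate_ici_cohorts(2, 20, gene_set("S", "NOPE"),
                         cohort_sim_truth(seed = 1), n_genes = 50),
    "disjoint"
  )
  expect_warning(screen_sim_truth(gene_set("R", "G0001"), lfc_shift = 1), "rank low")
  expect_error(simulate_sc_dataset(n_genes = 10, n_cells = 5,
    cell_type_props = c(tumor = 1), malignant_type = "other"), "malignant")
})
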