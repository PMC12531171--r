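test_that("stratified split reproduces the 618/154 partition on 772 samples", {
  clin <- tibble::tibble(
    sample_id = sprintf("s%03d", 1:772),
    cohort = rep(c("C1", "C2", "C3", "C4", "C5"), length.out = 772),
    response = rep(c("R", "NR"), times = c(300, 472))
  )
  sp <- make_split(clin, train_frac = 0.8, seed = 3)
  expect_length(sp$train_ids, 618)      # round-half-up of 617.6
  expect_length(sp$validation_ids, 154)
  # stratification: class balance preserved within one sample
  train_resp <- clin$response[clin$sample_id %in% sp$train_ids]
  expect_equal(sum(train_resp == "R"), 240)
  expect_equal(sum(train_resp == "NR"), 378)
})

test_that("splits are exactly stratified, deterministic, and validated", {
  clin <- toy_clinical(10, n_r = 5)
  sp <- make_split(clin, 0.8, seed = 1)
  expect_length(sp$train_ids, 8)
  train_resp <- clin$response[clin$sample_id %in% sp$train_ids]
  expect_equal(unname(table(train_resp)["R"]), 4)
  expect_identical(make_split(clin, 0.8, seed = 9)$train_ids,
                   make_split(clin, 0.8, seed = 9)$train_ids)
  expect_false(identical(make_split(clin, 0.8, seed = 9)$train_ids,
                         make_split(clin, 0.8, seed = 10)$train_ids))

  # held-out cohorts stay untouched
  clin2 <- dplyr::bind_rows(toy_clinical(20, cohort = "K1"),
                            toy_clinical(12, cohort = "K9"))
  sp2 <- make_split(clin2, 0.8, seed = 1, test_cohorts = "K9")
  expect_length(sp2$test_ids, 12)
  expect_length(intersect(sp2$test_ids, c(sp2$train_ids, sp2$validation_ids)), 0)

  # a class that cannot reach the training set errors
  clin3 <- toy_clinical(10, n_r = 9)
  expect_error(make_split(clin3, 0.1, seed = 1), "absent from the training set")
})

test_that("gaussian naive Bayes posterior is symmetric between balanced classes", {
  x <- matrix(c(-1, 0, 1, 1, 2, 3), ncol = 1)   # class means 0 and 2, sd 1
  y <- factor(rep(c("R", "NR"), each = 3), levels = c("R", "NR"))
  clf <- glycoscore:::.clf_fit("nb", x, y, list(usekernel = FALSE, fL = 0))
  p_mid <- glycoscore:::.clf_prob(clf, matrix(1, ncol = 1))
  expect_equal(p_mid, 0.5, tolerance = 1e-12)
  p_low <- glycoscore:::.clf_prob(clf, matrix(0, ncol = 1))
  expect_lt(p_low, 0.5) # labelled R
})

test_that("kernel naive Bayes matches a hand-evaluated KDE posterior", {
  set.seed(10)
  r_obs <- c(rnorm(8, -1, 0.3), rnorm(8, 3, 0.3)) # bimodal R class
  nr_obs <- rnorm(16, 1, 0.5)
  x <- matrix(c(r_obs, nr_obs), ncol = 1)
  y <- factor(rep(c("R", "NR"), each = 16), levels = c("R", "NR"))
  clf <- glycoscore:::.clf_fit("nb", x, y, list(usekernel = TRUE, fL = 0, adjust = 1))
  for (t in c(-1, 1, 3)) {
    got <- glycoscore:::.clf_prob(clf, matrix(t, ncol = 1))
    want <- oracle_nb_kernel_posterior(list(R = r_obs, NR = nr_obs),
                                       priors = c(0.5, 0.5), x_new = t)[2]
    expect_equal(got, unname(want), tolerance = 1e-9)
  }
  # the bandwidth multiplier changes the posterior (adjust is honoured)
  clf2 <- glycoscore:::.clf_fit("nb", x, y, list(usekernel = TRUE, fL = 0, adjust = 3))
  expect_false(isTRUE(all.equal(glycoscore:::.clf_prob(clf2, matrix(3, ncol = 1)),
                                glycoscore:::.clf_prob(clf, matrix(3, ncol = 1)))))
})

test_that("AUC matches pair-counting oracle, with exact complement symmetry", {
  scores <- c(0.9, 0.8, 0.7, 0.85)
  labels <- c("NR", "NR", "R", "R")
  r <- roc_auc(scores, labels)
  expect_equal(r$auc, 0.75) # 3 of 4 pairs concordant
  expect_equal(r$n_pos, 2); expect_equal(r$n_neg, 2)
  expect_true(r$ci_low <= r$auc && r$auc <= r$ci_high)

  set.seed(12)
  for (i in 1:4) {
    s <- round(runif(30), 2) # ties likely
    l <- sample(c("R", "NR"), 30, replace = TRUE)
    if (length(unique(l)) < 2) next
    expect_equal(roc_auc(s, l)$auc, oracle_auc(s, l), tolerance = 1e-12)
    expect_equal(roc_auc(s, l)$auc + roc_auc(-s, l)$auc, 1, tolerance = 1e-12)
  }

  expect_equal(roc_auc(c(1, 1, 0, 0), c("NR", "NR", "R", "R"))$auc, 1)
  expect_equal(roc_auc(rep(0.5, 6), rep(c("NR", "R"), 3))$auc, 0.5)
  expect_error(roc_auc(c(0.1, 0.9), c("R", "R")), "both classes")
})

test_that("Cox comparison matches the Efron partial-likelihood oracle", {
  # identical survival in both groups: HR = 1
  clin_same <- tibble::tibble(
    sample_id = paste0("s", 1:8), cohort = "K",
    response = NA_character_,
    os_months = rep(c(3, 6, 9, 12), 2),
    event = rep(c(1, 1, 0, 1), 2)
  )
  labels <- setNames(rep(c("R", "NR"), each = 4), clin_same$sample_id)
  sv_same <- survival_compare(clin_same, labels)
  expect_equal(sv_same$hr, 1, tolerance = 1e-6)

  # 6-subject toy against the grid-search oracle
  clin6 <- tibble::tibble(
    sample_id = paste0("s", 1:6), cohort = "K", response = NA_character_,
    os_months = c(2, 4, 5, 7, 9, 12),
    event = c(1, 1, 0, 1, 1, 1)
  )
  lab6 <- setNames(c("NR", "R", "NR", "R", "NR", "R"), clin6$sample_id)
  sv6 <- survival_compare(clin6, lab6)
  beta_oracle <- oracle_cox_efron(clin6$os_months, clin6$event,
                                  as.numeric(lab6 == "NR"))
  expect_equal(log(sv6$hr), beta_oracle, tolerance = 1e-4)
  expect_true(sv6$ci_low <= sv6$hr && sv6$hr <= sv6$ci_high)
  expect_equal(sort(tidy(sv6)$group), c("NR", "R"))
})

test_that("Cox recovery: simulated hazard ratio of 2 is estimated near 2", {
  sig <- gene_set("S", sprintf("G%04d", 1:10))
  sim <- simulate_ici_cohorts(
    n_cohorts = 1, n_per_cohort = 500, signature = sig,
    truth = cohort_sim_truth(true_hr = 2, signature_effect = 0, seed = 19),
    n_genes = 30
  )
  sv <- survival_compare(sim$clinical,
                         setNames(sim$clinical$response, sim$clinical$sample_id))
  expect_gt(sv$hr, 1.7)
  expect_lt(sv$hr, 2.4)
  km <- tidy(sv)
  expect_lt(km$median_os[km$group == "NR"], km$median_os[km$group == "R"])
})

test_that("model training is seed-deterministic and separates a strong signal", {
  sig <- gene_set("S", sprintf("G%04d", 1:30))
  sim <- simulate_ici_cohorts(
    n_cohorts = 2, n_per_cohort = 60, signature = sig,
    truth = cohort_sim_truth(signature_effect = 2, batch_loc_sd = 0,
                             batch_scale_sd = 0, seed = 23),
    n_genes = 100
  )
  mg <- merge_cohorts(sim$expr)
  args <- list(mg$expr, sim$clinical, sig, algorithms = c("nb", "cancerclass"),
               cv_repeats = 2, seed = 4)
  m1 <- do.call(train_select, args)
  m2 <- do.call(train_select, args)
  expect_identical(tidy(m1), tidy(m2)) # identical configs, identical CV stats
  expect_gte(m1$summary$validation_auc[m1$summary$algorithm == "nb"], 0.85)
  expect_s3_class(glance(m1), "tbl_df")
})

test_that("null signal yields chance-level validation AUC", {
  sig <- gene_set("S", sprintf("G%04d", 1:30))
  aucs <- vapply(1:5, function(i) {
    sim <- simulate_ici_cohorts(
      n_cohorts = 2, n_per_cohort = 60, signature = sig,
      truth = cohort_sim_truth(signature_effect = 0, batch_loc_sd = 0,
                               batch_scale_sd = 0, seed = 300 + i),
      n_genes = 100
    )
    mg <- merge_cohorts(sim$expr)
    m <- train_select(mg$expr, sim$clinical, sig, algorithms = "nb",
                      cv_repeats = 1, seed = i)
    m$summary$validation_auc[1]
  }, numeric(1))
  expect_gte(mean(aucs), 0.4)
  expect_lte(mean(aucs), 0.6)
})

test_that("prediction imputes missing features and applies the 0.5 threshold", {
  sig <- gene_set("S", sprintf("G%04d", 1:20))
  sim <- simulate_ici_cohorts(
    n_cohorts = 2, n_per_cohort = 50, signature = sig,
    truth = cohort_sim_truth(signature_effect = 2, seed = 29), n_genes = 60
  )
  mg <- merge_cohorts(sim$expr)
  model <- train_select(mg$expr, sim$clinical, sig, algorithms = "nb",
                        cv_repeats = 1, seed = 2)
  pred <- predict_response(model, mg$expr)
  expect_identical(pred$label, ifelse(pred$score > 0.5, "NR", "R"))
  truth_resp <- setNames(sim$clinical$response, sim$clinical$sample_id)
  expect_gt(mean(pred$label == truth_resp[pred$sample_id]), 0.8)

  # drop half the features: prediction still works, with a warning
  keep <- sprintf("G%04d", 1:10)
  sub <- expr_matrix(unclass(mg$expr)[keep, ], layer = "lognorm")
  expect_warning(pred2 <- predict_response(model, sub), "imputed")
  expect_equal(nrow(pred2), ncol(mg$expr))

  none <- expr_matrix(unclass(mg$expr)[sprintf("G%04d", 31:40), ], layer = "lognorm")
  expect_error(predict_response(model, none), "no model features")
})

test_that("Kaplan-Meier medians are invariant to sample order", {
  clin <- toy_clinical(40, seed = 55)
  labels <- setNames(rep(c("R", "NR"), 20), clin$sample_id)
  sv1 <- survival_compare(clin, labels)
  perm <- sample(nrow(clin))
  sv2 <- survival_compare(clin[perm, ], labels)
  expect_equal(dplyr::arrange(tidy(sv1), group), dplyr::arrange(tidy(sv2), group))
  expect_equal(sv1$hr, sv2$hr, tolerance = 1e-9)
})
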