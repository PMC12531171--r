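#' Stratified train/validation/test split
#'
#' Splits samples into a training set of size `round(train_frac * n)`
#' (round half up; on 772 samples at 0.8 this gives 618 train / 154
#' validation), stratified by response so class balance is preserved;
#' the remainder is the validation set. Samples from cohorts named in
#' `test_cohorts` are held out untouched as the test set, and samples
#' without a response label are excluded from train/validation.
#'
#' @param clinical Clinical tibble (sample_id, cohort, response, ...).
#' @param train_frac Training fraction (default 0.8).
#' @param seed Integer seed; identical seeds give identical splits.
#' @param test_cohorts Character vector of cohort labels held out as test.
#' @return A `split_plan`: list(train_ids, validation_ids, test_ids,
#'   train_frac, seed).
#' @export
make_split <- function(clinical, train_frac = 0.8, seed = 1L, test_cohorts = NULL) {
  stopifnot(train_frac > 0, train_frac < 1)
  test_ids <- clinical$sample_id[clinical$cohort %in% test_cohorts]
  pool <- clinical[!clinical$sample_id %in% test_ids & !is.na(clinical$response), ]
  if (nrow(pool) < 2) abort("too few labelled samples to split.")
  n <- nrow(pool)
  round_half_up <- function(x) floor(x + 0.5)
  target <- round_half_up(train_frac * n)

  classes <- split(pool$sample_id, pool$response)
  take <- vapply(classes, function(ids) round_half_up(train_frac * length(ids)), numeric(1))
  # per-class rounding can miss the overall target by one; adjust in the
  # largest classes, never emptying a class
  while (sum(take) > target) {
    i <- which.max(take)
    take[i] <- take[i] - 1
  }
  while (sum(take) < target) {
    room <- vapply(classes, length, integer(1)) - take
    i <- which.max(room)
    take[i] <- take[i] + 1
  }
  set.seed(seed)
  train_ids <- unlist(lapply(seq_along(classes), function(i) {
    ids <- classes[[i]]
    ids[sample.int(length(ids), take[i])]
  }), use.names = FALSE)
  validation_ids <- setdiff(pool$sample_id, train_ids)
  train_resp <- pool$response[pool$sample_id %in% train_ids]
  if (length(unique(train_resp)) < length(classes)) {
    abort("a response class is absent from the training set after splitting.")
  }
  structure(
    list(train_ids = train_ids, validation_ids = validation_ids,
         test_ids = test_ids, train_frac = train_frac, seed = as.integer(seed)),
    class = "split_plan"
  )
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan> train %d / validation %d / test %d (frac = %g)\n",
              length(x$train_ids), length(x$validation_ids), length(x$test_ids),
              x$train_frac))
  invisible(x)
}

# internal: stratified fold assignment
.make_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    fold[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
  }
  fold
}

#' Train candidate classifiers and select the best by validation AUC
#'
#' Restricts the merged expression matrix to the signature genes, splits
#' samples with [make_split()], tunes each candidate algorithm by
#' stratified `cv_folds`-fold cross-validation repeated `cv_repeats` times
#' (each repeat on a distinct derived seed; candidates with a single
#' hyperparameter configuration still report their cross-validated AUC),
#' refits each algorithm on the full training set, and selects the
#' algorithm with the highest validation-set AUC. The nearest-centroid
#' (`cancerclass`) candidate is parameter-free and is fit on the entire
#' training set without cross-validation.
#'
#' @param expr An [expr_matrix] (adjusted or lognorm layer), genes x
#'   samples, covering the split's samples.
#' @param clinical Clinical tibble with response labels.
#' @param signature [gene_set] restricting the features.
#' @param algorithms Subset of
#'   `c("nb", "knn", "rf", "svm", "logitboost", "adaboost", "cancerclass")`.
#' @param cv_folds,cv_repeats Cross-validation protocol (defaults 5 and 10).
#' @param seed Integer seed driving the split, fold assignment and every
#'   stochastic fit.
#' @param split An existing `split_plan` to reuse; `NULL` builds one.
#' @param train_frac,test_cohorts Passed to [make_split()] when `split` is
#'   `NULL`.
#' @return A `glyc_model`: per-algorithm summary (see [tidy()]), the
#'   fitted best classifier, features, training means (for imputation at
#'   prediction time) and the split plan.
#' @export
train_select <- function(expr, clinical, signature,
                         algorithms = .clf_algorithms,
                         cv_folds = 5, cv_repeats = 10, seed = 1L,
                         split = NULL, train_frac = 0.8, test_cohorts = NULL) {
  stopifnot(cv_folds >= 2, cv_repeats >= 1)
  algorithms <- match.arg(algorithms, .clf_algorithms, several.ok = TRUE)
  expr <- as_expr_matrix(expr, layer = "lognorm")
  signature <- as_gene_set(signature, "SIGNATURE")
  features <- intersect(signature$genes, rownames(expr))
  if (length(features) == 0) abort("no signature genes present in the expression matrix.")
  if (is.null(split)) {
    split <- make_split(clinical, train_frac = train_frac, seed = seed,
                        test_cohorts = test_cohorts)
  }
  x_all <- t(unclass(expr)[features, , drop = FALSE])
  resp <- setNames(clinical$response, clinical$sample_id)

  get_xy <- function(ids) {
    ids <- intersect(ids, rownames(x_all))
    list(x = x_all[ids, , drop = FALSE],
         y = factor(resp[ids], levels = c("R", "NR")))
  }
  tr <- get_xy(split$train_ids)
  va <- get_xy(split$validation_ids)
  if (length(unique(tr$y)) < 2) abort("fewer than 2 response classes in training data.")

  results <- list()
  fits <- list()
  for (ai in seq_along(algorithms)) {
    alg <- algorithms[[ai]]
    grid <- .clf_grid(alg, length(features))
    if (alg == "cancerclass" || nrow(grid) == 0) {
      set.seed(seed + 1000L * ai)
      fit <- .clf_fit(alg, tr$x, tr$y)
      cv_auc <- NA_real_
      best_params <- list()
    } else {
      grid_auc <- vapply(seq_len(nrow(grid)), function(gi) {
        params <- as.list(grid[gi, ])
        rep_auc <- vapply(seq_len(cv_repeats), function(r) {
          set.seed(seed + 1000L * ai + 17L * r)
          folds <- .make_folds(tr$y, cv_folds)
          oof <- rep(NA_real_, length(tr$y))
          for (f in seq_len(cv_folds)) {
            set.seed(seed + 1000L * ai + 17L * r + f)
            fit_f <- .clf_fit(alg, tr$x[folds != f, , drop = FALSE],
                              tr$y[folds != f], params)
            oof[folds == f] <- .clf_prob(fit_f, tr$x[folds == f, , drop = FALSE])
          }
          roc_auc(oof, tr$y)$auc
        }, numeric(1))
        mean(rep_auc)
      }, numeric(1))
      best_i <- which.max(grid_auc)
      best_params <- as.list(grid[best_i, ])
      cv_auc <- grid_auc[best_i]
      set.seed(seed + 1000L * ai)
      fit <- .clf_fit(alg, tr$x, tr$y, best_params)
    }
    val_scores <- .clf_prob(fit, va$x)
    val_auc <- roc_auc(val_scores, va$y)$auc
    results[[alg]] <- tibble(
      algorithm = alg,
      cv_auc = cv_auc,
      validation_auc = val_auc,
      params = list(best_params)
    )
    fits[[alg]] <- fit
  }
  summary_tbl <- dplyr::bind_rows(results) |>
    dplyr::arrange(dplyr::desc(.data$validation_auc))
  best_alg <- summary_tbl$algorithm[[1]]
  structure(
    list(
      summary = summary_tbl,
      best_algorithm = best_alg,
      best_fit = fits[[best_alg]],
      fits = fits,
      features = features,
      feature_means = colMeans(tr$x),
      split = split,
      cv_folds = cv_folds, cv_repeats = cv_repeats, seed = as.integer(seed)
    ),
    class = "glyc_model"
  )
}

#' @export
print.glyc_model <- function(x, ...) {
  cat(sprintf("<glyc_model> best: %s (validation AUC %.3f), %d feature(s)\n",
              x$best_algorithm, x$summary$validation_auc[[1]], length(x$features)))
  invisible(x)
}

#' @rdname train_select
#' @param x A `glyc_model`.
#' @param ... Unused.
#' @method tidy glyc_model
#' @export
tidy.glyc_model <- function(x, ...) {
  dplyr::select(x$summary, -"params")
}

#' @rdname train_select
#' @method glance glyc_model
#' @export
glance.glyc_model <- function(x, ...) {
  tibble(
    best_algorithm = x$best_algorithm,
    validation_auc = x$summary$validation_auc[[1]],
    n_features = length(x$features),
    n_train = length(x$split$train_ids),
    n_validation = length(x$split$validation_ids),
    n_test = length(x$split$test_ids)
  )
}

#' Predict ICI response from expression
#'
#' Scores samples with a fitted model: the score is the predicted
#' probability of non-response, and the label is `NR` when the score
#' exceeds 0.5, `R` otherwise. Model features absent from the matrix are
#' imputed with their training means (with a warning).
#'
#' @param model A `glyc_model` from [train_select()] (the selected
#'   classifier is used).
#' @param expr An [expr_matrix], genes x samples.
#' @return A tibble: sample_id, score (probability of NR), label.
#' @export
predict_response <- function(model, expr) {
  stopifnot(inherits(model, "glyc_model"))
  expr <- as_expr_matrix(expr, layer = "lognorm")
  present <- intersect(model$features, rownames(expr))
  if (length(present) == 0) abort("no model features present in the expression matrix.")
  x <- matrix(rep(model$feature_means, each = ncol(expr)),
              nrow = ncol(expr),
              dimnames = list(colnames(expr), model$features))
  x[, present] <- t(unclass(expr)[present, , drop = FALSE])
  missing <- setdiff(model$features, present)
  if (length(missing) > 0) {
    warn(sprintf("%d model feature(s) absent; imputed with training means.",
                 length(missing)))
  }
  score <- .clf_prob(model$best_fit, x)
  tibble(
    sample_id = colnames(expr),
    score = as.numeric(score),
    label = ifelse(score > 0.5, "NR", "R")
  )
}

#' ROC curve area with confidence interval
#'
#' AUC as the tie-corrected Mann-Whitney concordance probability
#' (concordant pairs plus half the tied pairs over `n_pos * n_neg`), with
#' a DeLong 95% confidence interval by default (stratified bootstrap
#' optional). The positive class is `NR` and higher scores must indicate
#' non-response, so `roc_auc(scores) + roc_auc(-scores) = 1` exactly.
#'
#' @param scores Numeric scores (probability of NR).
#' @param labels Response labels (`R`/`NR`, factor or character).
#' @param ci_method `"delong"` or `"bootstrap"`.
#' @return A `glyc_roc`: list(auc, ci_low, ci_high, n_pos, n_neg, roc)
#'   where `roc` is the underlying pROC object.
#' @export
roc_auc <- function(scores, labels, ci_method = c("delong", "bootstrap")) {
  ci_method <- match.arg(ci_method)
  labels <- as.character(labels)
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]
  labels <- labels[keep]
  if (length(unique(labels)) < 2) abort("both classes must be present.")
  r <- pROC::roc(response = labels, predictor = scores,
                 levels = c("R", "NR"), direction = "<", quiet = TRUE)
  auc <- as.numeric(pROC::auc(r))
  ci <- tryCatch(
    suppressWarnings(as.numeric(pROC::ci.auc(
      r,
      method = if (ci_method == "delong") "delong" else "bootstrap",
      boot.n = 500, progress = "none"
    ))),
    error = function(e) c(auc, auc, auc)
  )
  ci_low <- max(0, min(ci[1], auc, na.rm = TRUE))
  ci_high <- min(1, max(ci[3], auc, na.rm = TRUE))
  structure(
    list(auc = auc, ci_low = ci_low, ci_high = ci_high,
         n_pos = sum(labels == "NR"), n_neg = sum(labels == "R"), roc = r),
    class = "glyc_roc"
  )
}

#' @export
print.glyc_roc <- function(x, ...) {
  cat(sprintf("<glyc_roc> AUC %.3f (95%% CI %.3f-%.3f), %d NR / %d R\n",
              x$auc, x$ci_low, x$ci_high, x$n_pos, x$n_neg))
  invisible(x)
}

#' @rdname roc_auc
#' @param x A `glyc_roc`.
#' @param ... Unused.
#' @method glance glyc_roc
#' @export
glance.glyc_roc <- function(x, ...) {
  tibble(auc = x$auc, ci_low = x$ci_low, ci_high = x$ci_high,
         n_pos = x$n_pos, n_neg = x$n_neg)
}

#' Compare survival between predicted risk groups
#'
#' Univariate Cox proportional-hazards regression of overall survival on
#' the predicted label (NR versus R, Efron tie handling), with a Wald 95%
#' confidence interval and p-value, plus Kaplan-Meier per-group median
#' survival.
#'
#' @param clinical Clinical tibble with `sample_id`, `os_months`, `event`.
#' @param labels Predicted labels: a tibble from [predict_response()] or a
#'   named character vector of `R`/`NR`.
#' @return A `glyc_survcmp`: list(hr, ci_low, ci_high, p_value, medians,
#'   cox, km, data).
#' @export
survival_compare <- function(clinical, labels) {
  if (is.data.frame(labels)) {
    labels <- setNames(labels$label, labels$sample_id)
  }
  if (is.null(names(labels))) abort("`labels` must be named by sample id.")
  dat <- clinical |>
    dplyr::filter(.data$sample_id %in% names(labels),
                  !is.na(.data$os_months), !is.na(.data$event)) |>
    dplyr::mutate(group = factor(labels[.data$sample_id], levels = c("R", "NR")))
  counts <- table(dat$group)
  if (length(counts) < 2 || any(counts < 2)) {
    abort("need >= 2 samples with survival data in each predicted group.")
  }
  events <- tapply(dat$event, dat$group, sum)
  if (any(events == 0)) {
    warn("a group has no events; the hazard ratio is unstable.")
  }
  cox <- survival::coxph(
    survival::Surv(os_months, event) ~ group,
    data = dat, ties = "efron"
  )
  sm <- summary(cox)
  km <- survival::survfit(survival::Surv(os_months, event) ~ group, data = dat)
  km_tab <- summary(km)$table
  medians <- tibble(
    group = sub("^group=", "", rownames(km_tab)),
    n = as.integer(km_tab[, "records"]),
    events = as.integer(km_tab[, "events"]),
    median_os = as.numeric(km_tab[, "median"])
  )
  structure(
    list(
      hr = unname(sm$conf.int[1, "exp(coef)"]),
      ci_low = unname(sm$conf.int[1, "lower .95"]),
      ci_high = unname(sm$conf.int[1, "upper .95"]),
      p_value = unname(sm$coefficients[1, "Pr(>|z|)"]),
      medians = medians,
      cox = cox, km = km, data = dat
    ),
    class = "glyc_survcmp"
  )
}

#' @export
print.glyc_survcmp <- function(x, ...) {
  cat(sprintf("<glyc_survcmp> HR(NR vs R) %.2f (95%% CI %.2f-%.2f), p = %.3g\n",
              x$hr, x$ci_low, x$ci_high, x$p_value))
  invisible(x)
}

#' @rdname survival_compare
#' @param x A `glyc_survcmp`.
#' @param ... Unused.
#' @method tidy glyc_survcmp
#' @export
tidy.glyc_survcmp <- function(x, ...) x$medians

#' @rdname survival_compare
#' @method glance glyc_survcmp
#' @export
glance.glyc_survcmp <- function(x, ...) {
  tibble(hr = x$hr, ci_low = x$ci_low, ci_high = x$ci_high, p_value = x$p_value)
}
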