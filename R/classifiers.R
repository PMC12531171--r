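# Internal classifier zoo behind train_select()/predict_response().
# Uniform surface: .clf_fit(algorithm, x, y, params) returns a fitted
# object; .clf_prob(fit, x) returns P(class == "NR") per row of x.
# x is samples x features; y is a factor with levels R, NR.

.clf_algorithms <- c("nb", "knn", "rf", "svm", "logitboost", "adaboost", "cancerclass")

# default (small, fixed) tuning grids; one row per candidate
.clf_grid <- function(algorithm, n_features) {
  switch(algorithm,
    # the naive Bayes configuration of record: no Laplace smoothing on the
    # class priors, Gaussian-kernel densities at Silverman bandwidth x 1
    nb = tibble(fL = 0, adjust = 1, usekernel = TRUE),
    knn = tibble(k = c(5L, 11L, 21L)),
    rf = tibble(ntree = 300L, mtry = max(1L, floor(sqrt(n_features)))),
    svm = tibble(cost = 1),
    logitboost = tibble(nrounds = c(20L, 50L)),
    adaboost = tibble(nrounds = c(30L, 60L), max_depth = 2L),
    cancerclass = tibble(),
    abort(paste0("unknown algorithm: ", algorithm))
  )
}

.clf_fit <- function(algorithm, x, y, params = list()) {
  stopifnot(is.matrix(x), is.factor(y), nlevels(y) == 2)
  if (length(unique(y)) < 2) abort("training data must contain both classes.")
  fit <- switch(algorithm,
    nb = .nb_fit(x, y,
                 fL = params$fL %||% 0,
                 adjust = params$adjust %||% 1,
                 usekernel = params$usekernel %||% TRUE),
    knn = list(x = x, y = y, k = params$k %||% 5L),
    rf = randomForest::randomForest(
      x, y,
      ntree = params$ntree %||% 300L,
      mtry = params$mtry %||% max(1L, floor(sqrt(ncol(x))))
    ),
    svm = e1071::svm(x, y, kernel = "radial", cost = params$cost %||% 1,
                     probability = TRUE),
    logitboost = .xgb_fit(x, y, booster = "gblinear",
                          nrounds = params$nrounds %||% 50L),
    adaboost = .xgb_fit(x, y, booster = "gbtree",
                        nrounds = params$nrounds %||% 60L,
                        max_depth = params$max_depth %||% 2L),
    cancerclass = .centroid_fit(x, y),
    abort(paste0("unknown algorithm: ", algorithm))
  )
  structure(list(algorithm = algorithm, fit = fit, params = params,
                 features = colnames(x), levels = levels(y)),
            class = "glyc_classifier")
}

.clf_prob <- function(clf, x) {
  stopifnot(inherits(clf, "glyc_classifier"))
  if (!is.null(clf$features)) x <- x[, clf$features, drop = FALSE]
  switch(clf$algorithm,
    nb = .nb_prob(clf$fit, x),
    knn = {
      pred <- class::knn(clf$fit$x, x, clf$fit$y, k = clf$fit$k, prob = TRUE)
      win <- attr(pred, "prob")
      ifelse(pred == "NR", win, 1 - win)
    },
    rf = predict(clf$fit, x, type = "prob")[, "NR"],
    svm = {
      pr <- predict(clf$fit, x, probability = TRUE)
      attr(pr, "probabilities")[, "NR"]
    },
    logitboost = predict(clf$fit, xgboost::xgb.DMatrix(x)),
    adaboost = predict(clf$fit, xgboost::xgb.DMatrix(x)),
    cancerclass = .centroid_prob(clf$fit, x),
    abort(paste0("unknown algorithm: ", clf$algorithm))
  )
}

# --- naive Bayes with optional Gaussian-kernel densities -----------------
# Class priors use Laplace smoothing fL: (n_c + fL) / (n + fL * K).
# usekernel = TRUE: class-conditional feature densities are Gaussian KDEs
# with Silverman's bandwidth (bw.nrd0) scaled by `adjust`; FALSE: a single
# Gaussian per class/feature.
.nb_fit <- function(x, y, fL = 0, adjust = 1, usekernel = TRUE) {
  classes <- levels(y)
  n <- length(y)
  prior <- (table(y) + fL) / (n + fL * length(classes))
  per_class <- lapply(classes, function(cl) {
    xc <- x[y == cl, , drop = FALSE]
    lapply(seq_len(ncol(x)), function(j) {
      v <- xc[, j]
      s <- sd(v)
      if (usekernel) {
        bw <- if (s > 0) bw.nrd0(v) * adjust else 1e-3
        list(kernel = TRUE, obs = v, bw = max(bw, 1e-8))
      } else {
        list(kernel = FALSE, mean = mean(v), sd = max(s, 1e-8))
      }
    })
  })
  names(per_class) <- classes
  list(prior = as.numeric(prior), classes = classes, per_class = per_class,
       usekernel = usekernel)
}

.nb_density <- function(spec, t) {
  if (spec$kernel) {
    vapply(t, function(ti) mean(dnorm(ti, mean = spec$obs, sd = spec$bw)), numeric(1))
  } else {
    dnorm(t, mean = spec$mean, sd = spec$sd)
  }
}

.nb_prob <- function(fit, x) {
  loglik <- vapply(seq_along(fit$classes), function(ci) {
    lp <- rep(log(fit$prior[ci]), nrow(x))
    for (j in seq_len(ncol(x))) {
      dens <- .nb_density(fit$per_class[[ci]][[j]], x[, j])
      lp <- lp + log(pmax(dens, 1e-300))
    }
    lp
  }, numeric(nrow(x)))
  loglik <- matrix(loglik, nrow = nrow(x))
  mx <- apply(loglik, 1, max)
  post <- exp(loglik - mx)
  post <- post / rowSums(post)
  post[, match("NR", fit$classes)]
}

# --- gradient-boosted stand-ins ------------------------------------------
# gbtree = generic boosted classification trees (AdaBoost stand-in);
# gblinear = additive boosted logistic model (LogitBoost stand-in).
.xgb_fit <- function(x, y, booster, nrounds, max_depth = 2L) {
  label <- as.numeric(y == "NR")
  params <- list(objective = "binary:logistic", booster = booster,
                 nthread = 1L, eta = 0.3)
  if (booster == "gbtree") params$max_depth <- max_depth
  xgboost::xgb.train(
    params = params,
    data = xgboost::xgb.DMatrix(x, label = label),
    nrounds = nrounds, verbose = 0
  )
}

# --- nearest-centroid, Pearson-correlation distance ----------------------
# Parameter-free classifier: class centroids are per-feature means; a
# sample's dissimilarity to a class is 1 - cor(sample, centroid), and the
# NR score is d_R / (d_R + d_NR) (closer to the NR centroid -> higher).
.centroid_fit <- function(x, y) {
  centroids <- lapply(levels(y), function(cl) colMeans(x[y == cl, , drop = FALSE]))
  names(centroids) <- levels(y)
  centroids
}

.centroid_prob <- function(centroids, x) {
  dis <- vapply(centroids, function(ctr) {
    apply(x, 1, function(v) {
      if (sd(v) == 0 || sd(ctr) == 0) {
        sqrt(mean((v - ctr)^2)) # correlation undefined: fall back to RMS distance
      } else {
        1 - cor(v, ctr)
      }
    })
  }, numeric(nrow(x)))
  dis <- matrix(dis, nrow = nrow(x), dimnames = list(NULL, names(centroids)))
  d_r <- dis[, "R"]
  d_nr <- dis[, "NR"]
  tot <- d_r + d_nr
  ifelse(tot == 0, 0.5, d_r / tot)
}
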