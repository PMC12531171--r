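# ggplot2 views of the main result types. Each autoplot() returns a plain
# ggplot object the caller can restyle.

#' @describeIn aggregate_signature Geometric-mean correlation against
#'   dataset support for every candidate gene, with the signature
#'   admission region marked.
#' @param object A `signature_aggregate`.
#' @method autoplot signature_aggregate
#' @export
autoplot.signature_aggregate <- function(object, ...) {
  dat <- tidy(object)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$n_datasets, y = .data$geo_mean_r,
                                    colour = .data$in_signature)) +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.7) +
    ggplot2::geom_hline(yintercept = object$r_threshold, linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#C0392B", `FALSE` = "grey55"),
                                 name = "in signature") +
    ggplot2::labs(x = "datasets supporting gene (in Gn)",
                  y = "geometric mean Spearman R",
                  title = "Signature aggregation across datasets")
}

#' @describeIn roc_auc ROC curve with the AUC in the subtitle.
#' @param object A `glyc_roc`.
#' @method autoplot glyc_roc
#' @export
autoplot.glyc_roc <- function(object, ...) {
  dat <- tibble(
    fpr = rev(1 - object$roc$specificities),
    tpr = rev(object$roc$sensitivities)
  )
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step(linewidth = 0.8, colour = "#2C3E50") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "false positive rate", y = "true positive rate",
      title = "ROC, non-response prediction",
      subtitle = sprintf("AUC %.3f (95%% CI %.3f-%.3f)",
                         object$auc, object$ci_low, object$ci_high)
    )
}

#' @describeIn survival_compare Kaplan-Meier curves for the predicted risk
#'   groups, annotated with the Cox hazard ratio.
#' @param object A `glyc_survcmp`.
#' @method autoplot glyc_survcmp
#' @export
autoplot.glyc_survcmp <- function(object, ...) {
  km <- object$km
  strata <- rep(sub("^group=", "", names(km$strata)), km$strata)
  dat <- dplyr::bind_rows(
    tibble(time = 0, surv = 1, group = sub("^group=", "", names(km$strata))),
    tibble(time = km$time, surv = km$surv, group = strata)
  )
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$time, y = .data$surv,
                                    colour = .data$group)) +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::scale_colour_manual(values = c(R = "#2980B9", NR = "#C0392B"),
                                 name = "predicted") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(
      x = "overall survival (months)", y = "survival probability",
      title = "Survival by predicted response",
      subtitle = sprintf("Cox HR(NR vs R) %.2f (95%% CI %.2f-%.2f), p = %.2g",
                         object$hr, object$ci_low, object$ci_high, object$p_value)
    )
}

#' Waterfall plot of a CRISPR immune-resistance ranking
#'
#' Genes in rank order against mean Z, optionally highlighting a gene set
#' (e.g. planted resistance genes or a signature).
#'
#' @param ranked Tibble from [aggregate_rank()].
#' @param highlight Optional [gene_set] (or character vector) to mark.
#' @return A ggplot object.
#' @export
plot_crispr_ranking <- function(ranked, highlight = NULL) {
  dat <- ranked
  dat$highlighted <- if (is.null(highlight)) {
    FALSE
  } else {
    dat$gene %in% as_gene_set(highlight, "HIGHLIGHT")$genes
  }
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$rank, y = .data$mean_z)) +
    ggplot2::geom_point(data = dat[!dat$highlighted, ], colour = "grey60", size = 0.6) +
    ggplot2::geom_point(data = dat[dat$highlighted, ], colour = "#C0392B", size = 1.4) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "rank (1 = strongest resistance candidate)",
                  y = "mean Z across screens",
                  title = "CRISPR screen aggregate ranking")
}
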