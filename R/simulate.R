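#' Ground-truth specifications for the synthetic-data generators
#'
#' Each generator takes a truth object describing the planted structure and
#' returns it, untouched, alongside the data, so that parameter-recovery
#' tests compare against recorded truth rather than anything inferred from
#' the data.
#'
#' @param planted_program_genes [gene_set] of genes overexpressed in
#'   malignant cells and coupled to the latent glycolysis activity; must be
#'   a subset of the simulated gene universe.
#' @param malignant_logfc Positive log-scale overexpression of planted
#'   genes in malignant cells.
#' @param corr_strength Value in (0, 1]: planted (and glycolysis-reference)
#'   gene means scale with `a^corr_strength` where `a` is the per-cell
#'   latent glycolysis activity; 1 = linear coupling, values near 0
#'   decouple the program from the activity.
#' @param seed Integer seed; generators are bit-reproducible given
#'   (parameters, seed).
#' @return A truth list of the corresponding class.
#' @export
sc_sim_truth <- function(planted_program_genes, malignant_logfc = 1,
                         corr_strength = 1, seed = 1L) {
  stopifnot(malignant_logfc >= 0, corr_strength > 0, corr_strength <= 1)
  structure(
    list(
      planted_program_genes = as_gene_set(planted_program_genes, "PLANTED"),
      malignant_logfc = malignant_logfc,
      corr_strength = corr_strength,
      seed = as.integer(seed)
    ),
    class = "sc_sim_truth"
  )
}

#' @param signature_effect Log-scale shift of signature-gene expression in
#'   non-responders.
#' @param batch_loc_sd,batch_scale_sd Standard deviations of the per-cohort
#'   per-gene additive location shifts and multiplicative (log-normal)
#'   scale factors; 0 disables batch effects.
#' @param true_hr Hazard ratio (> 0) linking non-response to overall
#'   survival.
#' @rdname sc_sim_truth
#' @export
cohort_sim_truth <- function(signature_effect = 1, batch_loc_sd = 0.5,
                             batch_scale_sd = 0.2, true_hr = 2, seed = 1L) {
  stopifnot(true_hr > 0, batch_loc_sd >= 0, batch_scale_sd >= 0)
  structure(
    list(
      signature_effect = signature_effect,
      batch_loc_sd = batch_loc_sd,
      batch_scale_sd = batch_scale_sd,
      true_hr = true_hr,
      seed = as.integer(seed)
    ),
    class = "cohort_sim_truth"
  )
}

#' @param resistance_genes [gene_set] of planted immune-resistance genes.
#' @param lfc_shift Shift (< 0 for resistance) added to the log-fold change
#'   of resistance genes in every screen.
#' @param n_datasets Number of screens (>= 2).
#' @param missing_rate Fraction in [0, 1) of (gene, dataset) pairs dropped.
#' @rdname sc_sim_truth
#' @export
screen_sim_truth <- function(resistance_genes, lfc_shift = -2,
                             n_datasets = 10, missing_rate = 0, seed = 1L) {
  stopifnot(missing_rate >= 0, missing_rate < 1, n_datasets >= 2)
  if (lfc_shift >= 0) {
    warn("lfc_shift >= 0: planted genes will not rank low (not resistance-like).")
  }
  structure(
    list(
      resistance_genes = as_gene_set(resistance_genes, "RESISTANCE"),
      lfc_shift = lfc_shift,
      n_datasets = as.integer(n_datasets),
      missing_rate = missing_rate,
      seed = as.integer(seed)
    ),
    class = "screen_sim_truth"
  )
}

# internal: default gene universe labels G0001...Gn
.gene_universe <- function(n_genes) sprintf("G%04d", seq_len(n_genes))

#' Simulate a single-cell expression dataset with a planted glycolytic program
#'
#' Draws negative-binomial counts (fixed dispersion, log-normal library
#' sizes) for a mixture of cell types, one of which is malignant. Each cell
#' carries a latent glycolysis activity `a ~ Uniform(0, 1)`. Two gene
#' programs are planted: a glycolysis *reference* set whose means scale
#' with `a^corr_strength` in all cells (so rank-based set scoring can
#' recover `a`), and the planted signature program, whose means scale with
#' `a^corr_strength` and are additionally shifted by `malignant_logfc`, in
#' malignant cells only. The reference set is deliberately not
#' malignant-specific, so it cannot leak into a derived signature through
#' the overexpression filter.
#'
#' @param n_genes Size of the gene universe (symbols `G0001`...).
#' @param n_cells Number of cells.
#' @param cell_type_props Named numeric vector of cell-type proportions
#'   summing to 1; exactly one name must match `malignant_type`.
#' @param truth An [sc_sim_truth()]; its planted genes must lie in the
#'   universe. `NULL` plants a default 50-gene program.
#' @param malignant_type Name of the malignant cell type.
#' @param n_glyc_genes Size of the planted glycolysis reference set (taken
#'   from the start of the universe, disjoint from the program by default).
#' @param n_patients Cells are assigned round-robin to this many patients.
#' @param dispersion Negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2).
#'
#' @return A list with `expr` ([expr_matrix], counts layer), `annotations`
#'   (tibble: cell_id, cell_type, malignant, patient), `glyc_activity`
#'   (named numeric, the latent `a` per cell), `glyc_set` (the planted
#'   reference [gene_set]) and `truth` (the input truth, unmodified).
#' @export
#' @examples
#' sim <- simulate_sc_dataset(n_genes = 100, n_cells = 60)
#' dim(sim$expr)
simulate_sc_dataset <- function(n_genes = 2000, n_cells = 1000,
                                cell_type_props = c(malignant = 0.5, immune = 0.3, stromal = 0.2),
                                truth = NULL,
                                malignant_type = "malignant",
                                n_glyc_genes = 30,
                                n_patients = 4,
                                dispersion = 0.5) {
  stopifnot(abs(sum(cell_type_props) - 1) < 1e-8)
  if (!malignant_type %in% names(cell_type_props)) {
    abort("one cell type must be flagged malignant via `malignant_type`.")
  }
  universe <- .gene_universe(n_genes)
  glyc_set <- gene_set("GLYC_REFERENCE", universe[seq_len(min(n_glyc_genes, n_genes))])
  if (is.null(truth)) {
    planted <- universe[seq(n_glyc_genes + 1, length.out = min(50, n_genes - n_glyc_genes))]
    truth <- sc_sim_truth(gene_set("PLANTED", planted))
  }
  planted <- truth$planted_program_genes$genes
  if (!all(planted %in% universe)) {
    abort("planted program genes must be a subset of the simulated gene universe.")
  }

  set.seed(truth$seed)
  # per-gene baseline means: log-normal, mostly low; planted/reference genes
  # get a moderately expressed baseline so rank statistics have signal
  base_mean <- rlnorm(n_genes, meanlog = 0, sdlog = 1)
  names(base_mean) <- universe
  base_mean[glyc_set$genes] <- runif(length(glyc_set$genes), 5, 20)
  base_mean[planted] <- runif(length(planted), 5, 20)

  cell_type <- sample(names(cell_type_props), n_cells, replace = TRUE, prob = cell_type_props)
  malignant <- cell_type == malignant_type
  a <- runif(n_cells)
  libsize_factor <- rlnorm(n_cells, meanlog = 0, sdlog = 0.3)

  # coupling multiplier (1+c) * a^c has expectation 1 for every c, so
  # malignant_logfc keeps its interpretation as the log-scale
  # overexpression and c -> 0 recovers the no-coupling null exactly
  c_str <- truth$corr_strength
  coupling <- (1 + c_str) * a^c_str

  mu <- matrix(base_mean, nrow = n_genes, ncol = n_cells)
  glyc_idx <- match(glyc_set$genes, universe)
  planted_idx <- match(planted, universe)
  mu[glyc_idx, ] <- mu[glyc_idx, ] * rep(coupling, each = length(glyc_idx))
  if (any(malignant)) {
    mult <- exp(truth$malignant_logfc) * coupling[malignant]
    mu[planted_idx, malignant] <- mu[planted_idx, malignant] *
      rep(mult, each = length(planted_idx))
  }
  mu <- mu * rep(libsize_factor, each = n_genes)

  counts <- matrix(
    rnbinom(n_genes * n_cells, size = 1 / dispersion, mu = as.vector(mu)),
    nrow = n_genes
  )
  cell_ids <- sprintf("cell%05d", seq_len(n_cells))
  dimnames(counts) <- list(universe, cell_ids)

  annotations <- tibble(
    cell_id = cell_ids,
    cell_type = cell_type,
    malignant = malignant,
    patient = sprintf("P%02d", (seq_len(n_cells) - 1L) %% n_patients + 1L)
  )
  list(
    expr = expr_matrix(counts, layer = "counts"),
    annotations = annotations,
    glyc_activity = setNames(a, cell_ids),
    glyc_set = glyc_set,
    truth = truth
  )
}

#' Simulate bulk ICI cohorts with batch effects and linked survival
#'
#' Generates `n_cohorts` bulk expression matrices on the log scale
#' (Gaussian), with signature genes shifted by `signature_effect` in
#' non-responders, cohort-specific per-gene location/scale batch effects,
#' exponential survival with the non-responder hazard multiplied by
#' `true_hr`, and administrative censoring at the 70th percentile of the
#' simulated event times (so both events and censoring are present).
#'
#' @param n_cohorts Number of cohorts (batches).
#' @param n_per_cohort Samples per cohort (>= 10). Scalar or vector.
#' @param signature [gene_set] whose genes carry the response effect; must
#'   intersect the universe.
#' @param truth A [cohort_sim_truth()].
#' @param n_genes Gene universe size.
#' @param p_response Probability a sample is a responder.
#' @param baseline_median_os Median overall survival (months) of responders.
#'
#' @return A list with `expr` (named list of [expr_matrix], `lognorm`
#'   layer, one per cohort), `clinical` (tibble of sample_id, cohort,
#'   response, os_months, event, tmb, ith) and `truth`.
#' @export
simulate_ici_cohorts <- function(n_cohorts = 5, n_per_cohort = 100,
                                 signature, truth = cohort_sim_truth(),
                                 n_genes = 500, p_response = 0.5,
                                 baseline_median_os = 20) {
  signature <- as_gene_set(signature, "SIGNATURE")
  if (any(n_per_cohort < 10)) abort("n_per_cohort must be >= 10.")
  n_per_cohort <- rep(n_per_cohort, length.out = n_cohorts)
  universe <- .gene_universe(n_genes)
  sig_genes <- intersect(signature$genes, universe)
  if (length(sig_genes) == 0) abort("signature is disjoint from the simulated gene universe.")

  set.seed(truth$seed)
  gene_mean <- rnorm(n_genes, mean = 5, sd = 1)
  cohort_ids <- sprintf("C%02d", seq_len(n_cohorts))
  sig_idx <- match(sig_genes, universe)

  expr_list <- list()
  clin_list <- list()
  for (b in seq_len(n_cohorts)) {
    n <- n_per_cohort[[b]]
    response <- ifelse(runif(n) < p_response, "R", "NR")
    x <- matrix(rnorm(n_genes * n, mean = gene_mean, sd = 1), nrow = n_genes)
    nr <- response == "NR"
    if (any(nr)) x[sig_idx, nr] <- x[sig_idx, nr] + truth$signature_effect
    # batch effect: per-gene additive shift and multiplicative scale
    gamma <- rnorm(n_genes, 0, truth$batch_loc_sd)
    delta <- exp(rnorm(n_genes, 0, truth$batch_scale_sd))
    x <- x * delta + gamma

    sample_ids <- sprintf("%s_s%03d", cohort_ids[[b]], seq_len(n))
    dimnames(x) <- list(universe, sample_ids)

    hazard <- log(2) / baseline_median_os * ifelse(nr, truth$true_hr, 1)
    t_event <- rexp(n, rate = hazard)
    censor_at <- quantile(t_event, 0.7, names = FALSE)
    os <- pmin(t_event, censor_at)
    event <- as.integer(t_event <= censor_at)

    expr_list[[cohort_ids[[b]]]] <- expr_matrix(x, layer = "lognorm")
    clin_list[[b]] <- tibble(
      sample_id = sample_ids,
      cohort = cohort_ids[[b]],
      response = response,
      os_months = os,
      event = event,
      tmb = rlnorm(n, meanlog = 1.5, sdlog = 0.8),
      ith = runif(n)
    )
  }
  list(expr = expr_list, clinical = dplyr::bind_rows(clin_list), truth = truth)
}

#' Simulate multi-dataset CRISPR screens with planted resistance genes
#'
#' Per dataset, each gene's true log-fold change is `Normal(0, 1)`, shifted
#' by `lfc_shift` for planted resistance genes; each gene contributes
#' `n_sgrna` guide-level measurements (gene effect plus Normal guide
#' noise), and each (gene, dataset) pair is dropped independently with
#' probability `missing_rate`.
#'
#' @param n_genes Gene universe size.
#' @param truth A [screen_sim_truth()].
#' @param n_sgrna Guides per gene.
#' @param sgrna_sd Guide-level noise standard deviation.
#' @return A list with `screens` (named list of tibbles with columns
#'   dataset, gene, sgrna, lfc) and `truth`.
#' @export
simulate_crispr_screens <- function(n_genes = 1000, truth, n_sgrna = 4,
                                    sgrna_sd = 0.3) {
  stopifnot(inherits(truth, "screen_sim_truth"))
  universe <- .gene_universe(n_genes)
  planted <- truth$resistance_genes$genes
  if (!all(planted %in% universe)) {
    abort("resistance genes must be a subset of the simulated gene universe.")
  }
  set.seed(truth$seed)
  datasets <- sprintf("D%02d", seq_len(truth$n_datasets))
  screens <- lapply(datasets, function(d) {
    gene_eff <- rnorm(n_genes) + ifelse(universe %in% planted, truth$lfc_shift, 0)
    keep <- runif(n_genes) >= truth$missing_rate
    genes <- universe[keep]
    eff <- gene_eff[keep]
    tibble(
      dataset = d,
      gene = rep(genes, each = n_sgrna),
      sgrna = paste0(rep(genes, each = n_sgrna), "_sg", seq_len(n_sgrna)),
      lfc = rep(eff, each = n_sgrna) + rnorm(length(genes) * n_sgrna, sd = sgrna_sd)
    )
  })
  names(screens) <- datasets
  list(screens = screens, truth = truth)
}
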