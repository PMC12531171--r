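#' Read and write GMT gene-set files
#'
#' GMT (MSigDB dialect): one set per line, tab-separated
#' `name<TAB>description<TAB>gene1<TAB>gene2...`. The description field is
#' discarded on read and written back as `"na"`. Symbols are upper-cased,
#' order preserved, duplicates dropped.
#'
#' @param path File path.
#' @return `read_gmt()`: a named list of [gene_set] objects, in file order.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(seq_along(lines), function(i) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      abort(sprintf("malformed GMT line %d: %d field(s), need >= 3", i, length(fields)))
    }
    genes <- fields[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (length(toupper(genes)[!duplicated(toupper(genes))]) == 0) {
      abort(sprintf("GMT line %d: empty gene list after deduplication", i))
    }
    gene_set(fields[[1]], genes)
  })
  names(sets) <- vapply(sets, function(s) s$name, character(1))
  sets
}

#' @param sets A list of [gene_set] objects (or a single one).
#' @rdname read_gmt
#' @export
write_gmt <- function(sets, path) {
  if (inherits(sets, "gene_set")) sets <- list(sets)
  lines <- vapply(sets, function(s) {
    paste(c(s$name, "na", s$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read and write expression matrices
#'
#' Two on-disk formats are supported: dense TSV (header row of observation
#' ids, first column gene ids) and MatrixMarket coordinate MTX with sidecar
#' plain-text row/column name files (one id per line). Values are read as
#' the `counts` layer unless overridden.
#'
#' @param path File path (for MTX, the `.mtx` triplet file).
#' @param format `"tsv"` or `"mtx"`.
#' @param layer Layer tag to stamp on the result.
#' @param row_file,col_file Sidecar name files for MTX; default
#'   `<path>.rownames` / `<path>.colnames`.
#' @return `read_expression()`: an [expr_matrix].
#' @export
read_expression <- function(path, format = c("tsv", "mtx"),
                            layer = "counts",
                            row_file = paste0(path, ".rownames"),
                            col_file = paste0(path, ".colnames")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  if (format == "tsv") {
    tab <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE)
    gene_ids <- tab[[1]]
    obs_ids <- names(tab)[-1]
    vals <- as.matrix(tab[, -1, drop = FALSE])
    num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
    bad <- which(is.na(num) & !(vals %in% c("NA", "")), arr.ind = TRUE)
    if (nrow(bad) > 0) {
      abort(sprintf(
        "non-numeric value '%s' at gene %s, observation %s",
        vals[bad[1, 1], bad[1, 2]], gene_ids[bad[1, 1]], obs_ids[bad[1, 2]]
      ))
    }
    dimnames(num) <- list(gene_ids, obs_ids)
    expr_matrix(num, layer = layer)
  } else {
    for (f in c(row_file, col_file)) {
      if (!file.exists(f)) abort(paste0("missing MTX sidecar file: ", f))
    }
    sp <- Matrix::readMM(path)
    gene_ids <- readLines(row_file, warn = FALSE)
    obs_ids <- readLines(col_file, warn = FALSE)
    if (length(gene_ids) != nrow(sp) || length(obs_ids) != ncol(sp)) {
      abort("sidecar id counts do not match MTX dimensions.")
    }
    dense <- as.matrix(sp)
    dimnames(dense) <- list(gene_ids, obs_ids)
    expr_matrix(dense, layer = layer)
  }
}

#' @param m An [expr_matrix] (or plain matrix with dimnames).
#' @rdname read_expression
#' @export
write_expression <- function(m, path, format = c("tsv", "mtx"),
                             row_file = paste0(path, ".rownames"),
                             col_file = paste0(path, ".colnames")) {
  format <- match.arg(format)
  m <- as_expr_matrix(m, layer = if (is_expr_matrix(m)) expr_layer(m) else "counts")
  if (format == "tsv") {
    tab <- as_tibble(unclass(m), rownames = "gene")
    readr::write_tsv(tab, path, progress = FALSE)
  } else {
    Matrix::writeMM(Matrix::Matrix(unclass(m)[, , drop = FALSE], sparse = TRUE), path)
    writeLines(rownames(m), row_file)
    writeLines(colnames(m), col_file)
  }
  invisible(path)
}

.response_levels <- c("R", "NR")

#' Read and write clinical tables
#'
#' Clinical TSV with required columns `sample_id`, `cohort`, `response`
#' (values `R`, `NR`, or missing) and optional `os_months`, `event`, `tmb`,
#' `ith`. Missing values are the empty string or `"NA"`; no other sentinel
#' is accepted. Overall-survival months require an accompanying event flag.
#' Mapping cohort-specific response vocabularies (CR/PR/SD/PD, ...) to
#' R/NR is the caller's job; see [map_response()].
#'
#' @param path File path.
#' @return `read_clinical()`: a tibble with one row per sample, typed
#'   columns, in file order.
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         na = c("", "NA"), progress = FALSE)
  required <- c("sample_id", "cohort", "response")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0) {
    abort(paste0("missing required column(s): ", paste(missing_cols, collapse = ", ")))
  }
  bad_resp <- setdiff(unique(tab$response[!is.na(tab$response)]), .response_levels)
  if (length(bad_resp) > 0) {
    abort(paste0(
      "invalid response label(s): ", paste(bad_resp, collapse = ", "),
      " (allowed: ", paste(.response_levels, collapse = ", "),
      "; map cohort vocabularies to R/NR before reading)"
    ))
  }
  num_or_na <- function(col) if (col %in% names(tab)) as.numeric(tab[[col]]) else rep(NA_real_, nrow(tab))
  out <- tibble(
    sample_id = tab$sample_id,
    cohort = tab$cohort,
    response = tab$response,
    os_months = num_or_na("os_months"),
    event = as.integer(num_or_na("event")),
    tmb = num_or_na("tmb"),
    ith = num_or_na("ith")
  )
  if (any(!is.na(out$os_months) & is.na(out$event))) {
    abort("os_months present without an event flag for some samples.")
  }
  if (any(!out$event[!is.na(out$event)] %in% c(0L, 1L))) abort("event must be 0/1 or NA.")
  if (any(out$os_months < 0, na.rm = TRUE)) abort("os_months must be non-negative.")
  out
}

#' @param clinical A clinical tibble as returned by `read_clinical()` or
#'   [simulate_ici_cohorts()].
#' @rdname read_clinical
#' @export
write_clinical <- function(clinical, path) {
  readr::write_tsv(clinical, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Map cohort response vocabularies to R/NR
#'
#' Collapses per-cohort response labels (e.g. RECIST CR/PR/SD/PD) to the
#' binary R/NR used throughout the pipeline. The default mapping follows
#' the common convention CR/PR -> R, SD/PD -> NR; supply your own named
#' vector to override per-cohort conventions.
#'
#' @param labels Character vector of raw response labels.
#' @param mapping Named character vector, raw label -> "R"/"NR".
#' @return Character vector of "R"/"NR"/NA.
#' @export
#' @examples
#' map_response(c("CR", "PD", NA))
map_response <- function(labels,
                         mapping = c(CR = "R", PR = "R", R = "R",
                                     SD = "NR", PD = "NR", NR = "NR")) {
  stopifnot(all(mapping %in% .response_levels))
  unknown <- setdiff(unique(labels[!is.na(labels)]), names(mapping))
  if (length(unknown) > 0) {
    abort(paste0("no mapping for response label(s): ", paste(unknown, collapse = ", ")))
  }
  unname(mapping[labels])
}
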