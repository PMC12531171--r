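#' Expression matrix container
#'
#' A thin S3 wrapper around a base numeric matrix holding expression values
#' with genes in rows and observations (cells or bulk samples) in columns.
#' The single fixed orientation -- genes in rows, everywhere -- prevents
#' silent transposition bugs. A `layer` attribute records what the values
#' are: raw `counts`, log-normalized expression (`lognorm`), or
#' batch-`adjusted` expression.
#'
#' @param x Numeric matrix, genes x observations.
#' @param gene_ids Character vector of unique gene symbols (upper-cased on
#'   construction). Defaults to `rownames(x)`.
#' @param obs_ids Character vector of unique observation ids. Defaults to
#'   `colnames(x)`.
#' @param layer One of `"counts"`, `"lognorm"`, `"adjusted"`. The counts
#'   layer must be finite and non-negative.
#'
#' @return An `expr_matrix`: a numeric matrix with unique dimnames and a
#'   `layer` attribute.
#' @export
#' @examples
#' m <- expr_matrix(matrix(0:3, 2, 2, dimnames = list(c("A", "B"), c("c1", "c2"))))
#' expr_layer(m)
expr_matrix <- function(x, gene_ids = rownames(x), obs_ids = colnames(x),
                        layer = c("counts", "lognorm", "adjusted")) {
  layer <- match.arg(layer)
  if (!is.matrix(x) || !is.numeric(x)) {
    abort("`x` must be a numeric matrix (genes x observations).")
  }
  if (is.null(gene_ids) || is.null(obs_ids)) {
    abort("gene and observation ids are required (rownames/colnames or arguments).")
  }
  gene_ids <- toupper(as.character(gene_ids))
  obs_ids <- as.character(obs_ids)
  if (length(gene_ids) != nrow(x) || length(obs_ids) != ncol(x)) {
    abort("id lengths must match matrix dimensions.")
  }
  dup_g <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup_g) > 0) {
    abort(paste0("duplicate gene ids: ", paste(head(dup_g, 5), collapse = ", ")))
  }
  dup_o <- unique(obs_ids[duplicated(obs_ids)])
  if (length(dup_o) > 0) {
    abort(paste0("duplicate observation ids: ", paste(head(dup_o, 5), collapse = ", ")))
  }
  if (layer == "counts") {
    if (any(!is.finite(x)) || any(x < 0)) {
      abort("counts layer must be finite and non-negative.")
    }
  }
  dimnames(x) <- list(gene_ids, obs_ids)
  structure(x, layer = layer, class = c("expr_matrix", class(matrix())))
}

#' @rdname expr_matrix
#' @export
expr_layer <- function(x) attr(x, "layer") %||% "counts"

#' @rdname expr_matrix
#' @export
is_expr_matrix <- function(x) inherits(x, "expr_matrix")

# internal: coerce plain matrix input from users, preserving a stated layer
as_expr_matrix <- function(x, layer = "counts") {
  if (is_expr_matrix(x)) x else expr_matrix(as.matrix(x), layer = layer)
}

# internal: rewrap a matrix derived from `m`, with a (possibly new) layer
rewrap <- function(values, m, layer = expr_layer(m)) {
  expr_matrix(values, layer = layer)
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf(
    "<expr_matrix> %d genes x %d observations, layer = %s\n",
    nrow(x), ncol(x), expr_layer(x)
  ))
  invisible(x)
}

#' Gene set
#'
#' An ordered, deduplicated set of upper-cased gene symbols with a name,
#' mirroring one line of a GMT file.
#'
#' @param name Single string naming the set.
#' @param genes Character vector of gene symbols; upper-cased, duplicates
#'   dropped keeping first occurrence.
#' @param allow_empty Permit an empty set (used by filter operations whose
#'   result may legitimately be empty); parsing/ingest keeps the default
#'   and errors on empty sets.
#' @return A `gene_set` list with elements `name` and `genes`.
#' @export
#' @examples
#' gene_set("GLYC", c("ldha", "PKM", "LDHA"))
gene_set <- function(name, genes, allow_empty = FALSE) {
  stopifnot(is.character(name), length(name) == 1)
  genes <- toupper(as.character(genes))
  genes <- genes[!duplicated(genes) & nzchar(genes)]
  if (length(genes) == 0 && !allow_empty) {
    abort(paste0("gene set '", name, "' is empty after deduplication."))
  }
  structure(list(name = name, genes = genes), class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %s: %d genes\n", x$name, length(x$genes)))
  invisible(x)
}

# internal: accept a gene_set or a bare character vector
as_gene_set <- function(x, name = "SET") {
  if (inherits(x, "gene_set")) x else gene_set(name, x)
}
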