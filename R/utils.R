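# Shared validators and conversions between the tidy (tibble) surface and
# the internal matrix representations.

#' Convert a wide expression tibble to a numeric matrix
#'
#' @param expr A tibble whose first column (`gene`) holds gene symbols and
#'   whose remaining columns are one numeric column per patient.
#' @return Numeric matrix, rows = genes, columns = patients.
#' @keywords internal
#' @noRd
expr_matrix <- function(expr) {
  check_expression(expr)
  m <- as.matrix(expr[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- expr$gene
  m
}

check_expression <- function(expr) {
  if (!is.data.frame(expr) || ncol(expr) < 2L || names(expr)[1] != "gene") {
    abort("`expr` must be a data frame with a first column `gene` and one column per patient.")
  }
  if (anyDuplicated(expr$gene)) {
    dup <- unique(expr$gene[duplicated(expr$gene)])
    abort(paste0("duplicate gene identifiers: ", paste(head(dup, 5), collapse = ", ")))
  }
  pats <- names(expr)[-1]
  if (anyDuplicated(pats)) {
    abort("duplicate patient identifiers in expression columns")
  }
  vals <- as.matrix(expr[, -1, drop = FALSE])
  if (!is.numeric(vals)) abort("expression values must all be numeric")
  if (any(!is.finite(vals))) {
    bad <- which(!is.finite(vals), arr.ind = TRUE)[1, ]
    abort(paste0("non-finite expression value at gene '", expr$gene[bad[1]],
                 "', patient '", pats[bad[2]], "'"))
  }
  invisible(expr)
}

#' Canonicalize an edge table so gene_i < gene_j and rows are unique
#' @keywords internal
#' @noRd
canonical_edges <- function(edges) {
  stopifnot(all(c("gene_i", "gene_j") %in% names(edges)))
  a <- as.character(edges$gene_i)
  b <- as.character(edges$gene_j)
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  out <- tibble(gene_i = lo, gene_j = hi)
  out <- dplyr::distinct(out[out$gene_i != out$gene_j, , drop = FALSE])
  dplyr::arrange(out, .data$gene_i, .data$gene_j)
}

check_network <- function(net) {
  if (!is.data.frame(net) || !all(c("gene_i", "gene_j") %in% names(net))) {
    abort("a gene network must be a data frame with columns `gene_i` and `gene_j`")
  }
  if (any(net$gene_i == net$gene_j)) abort("gene network contains self-loops")
  invisible(net)
}

edge_key <- function(edges) paste(edges$gene_i, edges$gene_j, sep = "|")

network_nodes <- function(net) sort(unique(c(net$gene_i, net$gene_j)))

#' Coerce a gene collection (character vector or tibble with `gene`) to a
#' character vector of unique symbols
#' @keywords internal
#' @noRd
as_gene_vector <- function(x, arg = "genes") {
  if (is.data.frame(x)) {
    if (!"gene" %in% names(x)) abort(paste0("`", arg, "` data frame needs a `gene` column"))
    x <- x$gene
  }
  if (!is.character(x)) abort(paste0("`", arg, "` must be gene symbols"))
  unique(x)
}
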