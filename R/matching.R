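# Candidate-driver extraction: node-edge bipartite graph of a personalized
# network, maximum matching, and assembly of the binary gene-patient
# association matrix.

#' Node-edge bipartite graph of a personalized network
#'
#' Left nodes are the genes of the network, right nodes are its edges
#' (identified as `"gene_i|gene_j"`), and a gene is linked to every edge
#' it is an endpoint of, so each right node has exactly two incident left
#' nodes. All incidence weights default to 1.
#'
#' @param gp A `pgin` tibble (or any edge tibble with `gene_i`, `gene_j`).
#' @return A `node_edge_bipartite` object: list with `left` (sorted
#'   genes), `right` (sorted edge ids), `incidence` (tibble `gene`,
#'   `edge_id`, `weight`).
#' @examples
#' tri <- tibble::tibble(gene_i = c("a", "a", "b"), gene_j = c("b", "c", "c"))
#' build_bipartite(tri)
#' @export
build_bipartite <- function(gp) {
  check_network(gp)
  edges <- canonical_edges(gp)
  if (nrow(edges) == 0L) {
    bg <- list(left = character(), right = character(),
               incidence = tibble(gene = character(), edge_id = character(),
                                  weight = double()))
    return(structure(bg, class = "node_edge_bipartite"))
  }
  ids <- edge_key(edges)
  inc <- tibble(
    gene = c(edges$gene_i, edges$gene_j),
    edge_id = c(ids, ids),
    weight = 1
  )
  inc <- dplyr::arrange(inc, .data$edge_id, .data$gene)
  bg <- list(
    left = sort(unique(inc$gene)),
    right = sort(ids),
    incidence = inc
  )
  structure(bg, class = "node_edge_bipartite")
}

#' @export
print.node_edge_bipartite <- function(x, ...) {
  cat("Node-edge bipartite graph: ", length(x$left), " genes x ",
      length(x$right), " edges, ", nrow(x$incidence), " incidences\n", sep = "")
  invisible(x)
}

#' Maximum matching of a node-edge bipartite graph
#'
#' Finds a maximum-cardinality matching between genes (left) and network
#' edges (right). With unit weights (the default) this maximizes the total
#' matched weight, and the matched genes are the candidate drivers. The
#' search is deterministic: right nodes are processed in sorted order and
#' the augmenting-path search scans left neighbours in sorted order, so
#' ties among equally large matchings are always broken the same way.
#'
#' Non-unit incidence weights switch to an exact maximum-weight bipartite
#' matching (via \pkg{igraph}); the deterministic tie-break above is only
#' guaranteed in the unit-weight mode.
#'
#' @param bg A `node_edge_bipartite` object from [build_bipartite()].
#' @return A `driver_matching` object: list with `pairs` (tibble `gene`,
#'   `edge_id`), `genes` (matched gene symbols), `objective` (total
#'   matched weight).
#' @examples
#' tri <- tibble::tibble(gene_i = c("a", "a", "b"), gene_j = c("b", "c", "c"))
#' maximum_matching(build_bipartite(tri))
#' @export
maximum_matching <- function(bg) {
  stopifnot(inherits(bg, "node_edge_bipartite"))
  if (length(bg$right) == 0L) {
    res <- list(pairs = tibble(gene = character(), edge_id = character()),
                genes = character(), objective = 0)
    return(structure(res, class = "driver_matching"))
  }
  if (any(bg$incidence$weight <= 0)) abort("incidence weights must be positive")
  unit <- all(bg$incidence$weight == bg$incidence$weight[1])

  if (unit) {
    pairs <- kuhn_matching(bg)
    objective <- nrow(pairs) * bg$incidence$weight[1]
  } else {
    pairs <- weighted_matching(bg)
    w <- dplyr::inner_join(pairs, bg$incidence, by = c("gene", "edge_id"))$weight
    objective <- sum(w)
  }
  pairs <- dplyr::arrange(pairs, .data$edge_id)
  res <- list(pairs = pairs, genes = sort(unique(pairs$gene)),
              objective = objective)
  structure(res, class = "driver_matching")
}

# Kuhn's augmenting-path maximum-cardinality matching, matching right
# nodes (edges) to left nodes (genes). Deterministic: right nodes in
# sorted order, neighbour scan in sorted order.
kuhn_matching <- function(bg) {
  nbrs <- split(bg$incidence$gene, bg$incidence$edge_id)
  nbrs <- lapply(nbrs, sort)
  match_of_gene <- character(0)   # gene -> edge_id

  try_augment <- function(edge_id, visited) {
    for (g in nbrs[[edge_id]]) {
      if (g %in% visited$seen) next
      visited$seen <- c(visited$seen, g)
      current <- match_of_gene[g]
      if (is.na(current) || !nzchar(current) || length(current) == 0L ||
          try_augment(current, visited)) {
        match_of_gene[g] <<- edge_id
        return(TRUE)
      }
    }
    FALSE
  }

  match_of_gene <- setNames(rep(NA_character_, length(bg$left)), bg$left)
  for (e in sort(bg$right)) {
    visited <- new.env()
    visited$seen <- character(0)
    try_augment(e, visited)
  }
  matched <- !is.na(match_of_gene)
  tibble(gene = names(match_of_gene)[matched],
         edge_id = unname(match_of_gene[matched]))
}

# Exact maximum-weight matching for the non-unit-weight mode.
weighted_matching <- function(bg) {
  g <- igraph::graph_from_data_frame(
    data.frame(from = paste0("L:", bg$incidence$gene),
               to = paste0("R:", bg$incidence$edge_id)),
    directed = FALSE
  )
  igraph::V(g)$type <- startsWith(igraph::V(g)$name, "R:")
  w <- bg$incidence$weight
  mm <- igraph::max_bipartite_match(g, weights = w)
  mate <- mm$matching
  left_names <- paste0("L:", bg$left)
  keep <- left_names[!is.na(mate[left_names])]
  tibble(gene = sub("^L:", "", keep),
         edge_id = sub("^R:", "", unname(mate[keep])))
}

#' @export
print.driver_matching <- function(x, ...) {
  cat("Maximum matching: ", nrow(x$pairs), " matched pairs, objective ",
      format(x$objective), "\n", sep = "")
  invisible(x)
}

#' @describeIn maximum_matching Matched (gene, edge) pairs as a tibble.
#' @param x A `driver_matching` object.
#' @param ... Unused.
#' @export
tidy.driver_matching <- function(x, ...) x$pairs

#' @describeIn maximum_matching One-row summary (matched genes, objective).
#' @export
glance.driver_matching <- function(x, ...) {
  tibble(n_matched = nrow(x$pairs), n_genes = length(x$genes),
         objective = x$objective)
}

#' Assemble the gene-patient association matrix
#'
#' Stacks per-patient matchings into the binary matrix `M[i, j] = 1` iff
#' gene `i` is in the matched (candidate-driver) set of patient `j`. Rows
#' are the sorted union of matched genes over all patients; genes never
#' matched for any patient do not appear (no all-zero rows).
#'
#' @param matchings Named list of `driver_matching` objects (names =
#'   patient IDs), or a named list of character vectors of matched genes.
#' @return A tibble with first column `gene` and one 0/1 column per
#'   patient (sorted patient order), of class `gene_patient_assoc`.
#' @export
assemble_associations <- function(matchings) {
  if (length(matchings) == 0L || is.null(names(matchings))) {
    abort("`matchings` must be a non-empty named list (names = patient IDs)")
  }
  gene_sets <- lapply(matchings, function(m) {
    if (inherits(m, "driver_matching")) m$genes else as_gene_vector(m)
  })
  genes <- sort(unique(unlist(gene_sets)))
  if (length(genes) == 0L) {
    abort("all matchings are empty: no gene-patient associations to propagate")
  }
  patients <- sort(names(matchings))
  out <- tibble(gene = genes)
  for (p in patients) {
    out[[p]] <- as.integer(genes %in% gene_sets[[p]])
  }
  structure(out, class = c("gene_patient_assoc", class(out)))
}

#' Association tibble as a numeric matrix
#'
#' @param mgp A `gene_patient_assoc` tibble (or compatible `gene` + patient
#'   columns tibble).
#' @return Numeric matrix, rows = genes, columns = patients.
#' @export
assoc_matrix <- function(mgp) {
  m <- as.matrix(mgp[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- mgp$gene
  m
}
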