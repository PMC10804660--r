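# Personalized gene interaction networks: per-patient difference between
# the cohort-wide and leave-one-patient-out significant co-expression
# networks, restricted to a reference interactome.

#' Significant co-expression network of a cohort
#'
#' For every candidate gene pair, computes the Pearson correlation across
#' the included patient columns and its two-sided p-value from the exact t
#' distribution, `t = r * sqrt((m - 2) / (1 - r^2))` with `m - 2` degrees
#' of freedom, and retains the pair as an edge iff `p_value < alpha_edge`.
#' No multiple-testing correction is applied (the threshold is a raw cut).
#' Pairs involving a zero-variance gene are excluded.
#'
#' @param expr Expression tibble (first column `gene`, one numeric column
#'   per patient).
#' @param exclude_patient Optional patient ID to leave out before
#'   computing correlations.
#' @param alpha_edge Significance threshold in (0, 1); default 0.05.
#' @param pairs Optional tibble of candidate pairs (`gene_i`, `gene_j`);
#'   when `NULL`, all unordered pairs of genes in `expr` are scanned.
#' @return Tibble of retained edges with columns `gene_i`, `gene_j`
#'   (canonical order), `pcc`, `p_value`, sorted by endpoints.
#' @examples
#' expr <- tibble::tibble(gene = c("a", "b"),
#'                        !!!setNames(as.data.frame(matrix(rnorm(20), 2)),
#'                                    sprintf("p%02d", 1:10)))
#' expr[2, -1] <- expr[1, -1] * 2 + 1   # exact affine copy: pcc = 1
#' correlation_network(expr)
#' @export
correlation_network <- function(expr, exclude_patient = NULL,
                                alpha_edge = 0.05, pairs = NULL) {
  if (!is.numeric(alpha_edge) || alpha_edge <= 0 || alpha_edge >= 1) {
    abort("`alpha_edge` must lie in (0, 1)")
  }
  X <- expr_matrix(expr)
  if (!is.null(exclude_patient)) {
    if (!exclude_patient %in% colnames(X)) {
      abort(paste0("patient '", exclude_patient, "' not found in expression data"))
    }
    X <- X[, setdiff(colnames(X), exclude_patient), drop = FALSE]
  }
  m <- ncol(X)
  if (m < 3L) abort("need at least 3 included patients to test a correlation")

  genes <- rownames(X)
  if (is.null(pairs)) {
    if (length(genes) < 2L) {
      return(tibble(gene_i = character(), gene_j = character(),
                    pcc = double(), p_value = double()))
    }
    cmb <- combn(sort(genes), 2L)
    pairs <- tibble(gene_i = cmb[1, ], gene_j = cmb[2, ])
  } else {
    pairs <- canonical_edges(pairs)
    pairs <- pairs[pairs$gene_i %in% genes & pairs$gene_j %in% genes, , drop = FALSE]
  }
  if (nrow(pairs) == 0L) {
    return(tibble(gene_i = character(), gene_j = character(),
                  pcc = double(), p_value = double()))
  }

  Xc <- X - rowMeans(X)
  ss <- sqrt(rowSums(Xc^2))
  i <- match(pairs$gene_i, genes)
  j <- match(pairs$gene_j, genes)
  denom <- ss[i] * ss[j]
  r <- ifelse(denom > 0, rowSums(Xc[i, , drop = FALSE] * Xc[j, , drop = FALSE]) / denom, NA_real_)
  r <- pmin(1, pmax(-1, r))
  tstat <- r * sqrt((m - 2) / pmax(1 - r^2, 0))  # |r| = 1 gives t = Inf, p = 0
  p <- 2 * pt(-abs(tstat), df = m - 2)

  keep <- !is.na(r) & p < alpha_edge
  out <- tibble(gene_i = pairs$gene_i[keep], gene_j = pairs$gene_j[keep],
                pcc = r[keep], p_value = p[keep])
  dplyr::arrange(out, .data$gene_i, .data$gene_j)
}

#' Personalized gene interaction network for one patient
#'
#' Builds `G1`, the significant co-expression network over all patients,
#' and `G2`, the same network with the focal patient left out, then keeps
#' the edges present in exactly one of the two (their symmetric
#' difference) and restricted to the reference interactome. Edges whose
#' significance status is tipped by the focal patient's presence are the
#' ones retained. The gene universe is the intersection of the expression
#' genes and the reference-network nodes, and by default the pair scan is
#' restricted to reference edges (`restrict_pairs = TRUE`), which leaves
#' the final network unchanged because non-reference edges are discarded
#' anyway.
#'
#' @param expr Expression tibble.
#' @param patient Focal patient ID (must be a column of `expr`).
#' @param reference Reference network edge tibble (`gene_i`, `gene_j`).
#' @param alpha_edge Per-edge significance threshold; default 0.05.
#' @param restrict_pairs Restrict the correlation scan to reference pairs
#'   (default `TRUE`; the result is identical either way).
#' @return A `pgin` tibble with columns `gene_i`, `gene_j`, `provenance`
#'   (`"from_G1_only"` or `"from_G2_only"`), carrying the focal patient ID
#'   and threshold as attributes `patient` and `alpha_edge`.
#' @seealso [personalized_networks()] for all patients of a cohort.
#' @export
personalized_network <- function(expr, patient, reference,
                                 alpha_edge = 0.05, restrict_pairs = TRUE) {
  check_expression(expr)
  check_network(reference)
  if (!patient %in% names(expr)[-1]) {
    abort(paste0("patient '", patient, "' not found in expression data"))
  }
  reference <- canonical_edges(reference)
  universe <- intersect(expr$gene, network_nodes(reference))
  expr_u <- expr[expr$gene %in% universe, , drop = FALSE]
  ref_u <- reference[reference$gene_i %in% universe &
                       reference$gene_j %in% universe, , drop = FALSE]
  pairs <- if (restrict_pairs) ref_u else NULL

  g1 <- correlation_network(expr_u, NULL, alpha_edge, pairs)
  g2 <- correlation_network(expr_u, patient, alpha_edge, pairs)

  k1 <- edge_key(g1)
  k2 <- edge_key(g2)
  kr <- edge_key(ref_u)
  only1 <- setdiff(k1, k2)
  only2 <- setdiff(k2, k1)
  keys <- c(only1, only2)
  prov <- rep(c("from_G1_only", "from_G2_only"), c(length(only1), length(only2)))
  in_ref <- keys %in% kr
  keys <- keys[in_ref]
  prov <- prov[in_ref]

  parts <- strsplit(keys, "|", fixed = TRUE)
  out <- tibble(
    gene_i = vapply(parts, `[[`, character(1), 1L),
    gene_j = vapply(parts, `[[`, character(1), 2L),
    provenance = prov
  )
  out <- dplyr::arrange(out, .data$gene_i, .data$gene_j)
  structure(out, patient = patient, alpha_edge = alpha_edge,
            class = c("pgin", class(out)))
}

#' Personalized networks for every patient of a cohort
#'
#' @inheritParams personalized_network
#' @param patients Patients to process (default: all, in sorted order).
#' @return Named list of `pgin` tibbles, one per patient.
#' @export
personalized_networks <- function(expr, reference, alpha_edge = 0.05,
                                  patients = NULL, restrict_pairs = TRUE) {
  check_expression(expr)
  if (is.null(patients)) patients <- sort(names(expr)[-1])
  out <- lapply(patients, function(p) {
    personalized_network(expr, p, reference, alpha_edge, restrict_pairs)
  })
  setNames(out, patients)
}

#' Export a personalized network as an edge-list TSV
#'
#' Writes columns `gene_i`, `gene_j`, `provenance` to
#' `<patient>.pgin.tsv` under `dir`.
#'
#' @param gp A `pgin` tibble.
#' @param dir Output directory.
#' @return The file path, invisibly.
#' @export
write_pgin <- function(gp, dir) {
  patient <- attr(gp, "patient")
  path <- file.path(dir, paste0(patient, ".pgin.tsv"))
  readr::write_tsv(as_tibble(gp), path, progress = FALSE)
  invisible(path)
}
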