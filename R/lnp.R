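# Linear neighborhood similarity and label propagation: reconstruct each
# gene's association profile from its k nearest neighbours under a
# simplex-constrained quadratic program, assemble the row-stochastic
# similarity matrix S, and diffuse the binary associations to scores
# F* = (1 - alpha) (I - alpha S)^{-1} F0.

#' Fit linear neighborhood reconstruction weights
#'
#' Treats each gene's row of the association matrix as a feature vector
#' `y_i`, finds its `k` nearest neighbours by Euclidean distance (ties
#' broken by gene symbol ascending; a gene is never its own neighbour),
#' and solves, per gene, the convex quadratic program
#'
#' \deqn{\min_w \; w^T (G^i + \gamma I) w \quad \text{s.t.}\; \sum_j w_j = 1,\; w \ge 0}
#'
#' where `G^i[j, l] = (y_i - y_{ij})^T (y_i - y_{il})` is the local Gram
#' matrix of reconstruction residuals and `gamma` a Tikhonov ridge that
#' keeps the problem strictly convex. When every neighbour coincides with
#' `y_i` (zero Gram matrix) the weights are uniform `1/k`.
#'
#' @param mgp Association tibble from [assemble_associations()] (first
#'   column `gene`, one numeric column per patient).
#' @param k Neighbour count, `1 <= k <= n - 1`. Default
#'   `min(n - 1, ceiling(0.1 * n))`: a small fractional neighbourhood.
#' @param gamma Regularization coefficient (> 0); default 1.
#' @return An `lns_fit` object: list with `genes`, `k`, `gamma`,
#'   `neighbors` (named list of neighbour gene vectors, nearest first) and
#'   `weights` (named list of weight vectors aligned with `neighbors`;
#'   each non-negative and summing to 1).
#' @export
fit_neighborhood <- function(mgp, k = NULL, gamma = 1) {
  Y <- assoc_matrix(mgp)
  n <- nrow(Y)
  if (n < 2L) abort("need at least 2 genes to define neighbourhoods")
  if (is.null(k)) k <- min(n - 1L, as.integer(ceiling(0.1 * n)))
  k <- as.integer(k)
  if (k < 1L || k > n - 1L) {
    abort(paste0("`k` must lie in [1, ", n - 1L, "]"))
  }
  if (!is.numeric(gamma) || gamma <= 0) abort("`gamma` must be > 0")

  genes <- rownames(Y)
  ord_genes <- order(genes)
  D <- as.matrix(dist(Y))
  neighbors <- vector("list", n)
  weights <- vector("list", n)
  names(neighbors) <- names(weights) <- genes
  for (i in seq_len(n)) {
    # k smallest distances, excluding self; ties by gene symbol ascending
    cand <- setdiff(seq_len(n), i)
    ord <- cand[order(D[i, cand], genes[cand])]
    nb <- ord[seq_len(k)]
    Z <- Y[rep(i, k), , drop = FALSE] - Y[nb, , drop = FALSE]
    G <- Z %*% t(Z)
    H <- G + gamma * diag(k)
    w <- simplex_qp(H)
    neighbors[[i]] <- genes[nb]
    weights[[i]] <- setNames(w, genes[nb])
  }
  structure(list(genes = genes, k = k, gamma = gamma,
                 neighbors = neighbors, weights = weights),
            class = "lns_fit")
}

# Exact active-set solver for min w'Hw s.t. sum(w) = 1, w >= 0, with H
# symmetric positive definite. On the working set the equality-constrained
# KKT system H w = mu/2 * 1 is solved directly; variables driven negative
# are clamped to zero, and zero-clamped variables whose KKT multiplier is
# negative are released. Falls back to projected gradient if the active
# set cycles (cannot happen for strictly convex H in exact arithmetic).
simplex_qp <- function(H, max_cycles = NULL) {
  k <- nrow(H)
  if (k == 1L) return(1)
  if (is.null(max_cycles)) max_cycles <- 50L * k
  active <- rep(FALSE, k)
  for (iter in seq_len(max_cycles)) {
    free <- which(!active)
    z <- tryCatch(solve(H[free, free, drop = FALSE], rep(1, length(free))),
                  error = function(e) NULL)
    if (is.null(z) || abs(sum(z)) < 1e-14) {
      # near-singular working set: perturb with a tiny extra ridge
      z <- solve(H[free, free, drop = FALSE] + 1e-10 * diag(length(free)),
                 rep(1, length(free)))
    }
    w_free <- z / sum(z)
    if (min(w_free) < -1e-12) {
      active[free[which.min(w_free)]] <- TRUE
      next
    }
    w <- numeric(k)
    w[free] <- pmax(w_free, 0)
    w <- w / sum(w)
    g <- as.vector(2 * H %*% w)
    mu <- mean(g[free])
    viol <- which(active & g < mu - 1e-10)
    if (length(viol) == 0L) return(w)
    active[viol[which.min(g[viol])]] <- FALSE
  }
  simplex_qp_pg(H)  # safeguard; not expected to be reached
}

# Projected-gradient fallback with fixed step 1/L and simplex projection.
simplex_qp_pg <- function(H, iters = 20000L) {
  k <- nrow(H)
  w <- rep(1 / k, k)
  L <- max(eigen(H, symmetric = TRUE, only.values = TRUE)$values)
  for (t in seq_len(iters)) {
    w <- project_simplex(w - (1 / L) * as.vector(2 * H %*% w))
  }
  w
}

project_simplex <- function(v) {
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u)
  rho <- max(which(u + (1 - css) / seq_along(u) > 0))
  theta <- (css[rho] - 1) / rho
  pmax(v - theta, 0)
}

#' @export
print.lns_fit <- function(x, ...) {
  cat("Linear neighborhood model: ", length(x$genes), " genes, k = ", x$k,
      ", gamma = ", format(x$gamma), "\n", sep = "")
  invisible(x)
}

#' @describeIn fit_neighborhood Long tibble of reconstruction weights
#'   (`gene`, `neighbor`, `weight`).
#' @param x An `lns_fit` object.
#' @param ... Unused.
#' @export
tidy.lns_fit <- function(x, ...) {
  purrr::map2_dfr(x$genes, x$weights, function(g, w) {
    tibble(gene = g, neighbor = names(w), weight = unname(w))
  })
}

#' @describeIn fit_neighborhood One-row model summary.
#' @export
glance.lns_fit <- function(x, ...) {
  w <- unlist(x$weights, use.names = FALSE)
  tibble(n_genes = length(x$genes), k = x$k, gamma = x$gamma,
         max_row_sum_error = max(abs(vapply(x$weights, sum, double(1)) - 1)),
         mean_max_weight = mean(vapply(x$weights, max, double(1))),
         min_weight = min(w))
}

#' Assemble the sparse linear-neighborhood similarity matrix
#'
#' `S[i, j]` is gene `i`'s reconstruction weight on neighbour `j`, zero
#' elsewhere: non-negative, zero diagonal, at most `k` nonzeros per row,
#' each row summing to 1. `S` is generally asymmetric because
#' neighbourhoods are directional.
#'
#' @param model An `lns_fit` object from [fit_neighborhood()].
#' @param symmetrize Replace `S` by `(S + t(S)) / 2` (off by default;
#'   propagation uses the asymmetric `S` as fitted, which is the exact
#'   algebra of the reconstruction model; symmetrization halves the row
#'   sums' exactness and is provided only for exploratory use).
#' @return A sparse `dgCMatrix` with gene dimnames.
#' @export
build_similarity <- function(model, symmetrize = FALSE) {
  stopifnot(inherits(model, "lns_fit"))
  n <- length(model$genes)
  idx <- match(unlist(model$neighbors, use.names = FALSE), model$genes)
  S <- Matrix::sparseMatrix(
    i = rep(seq_len(n), each = model$k),
    j = idx,
    x = unlist(model$weights, use.names = FALSE),
    dims = c(n, n), dimnames = list(model$genes, model$genes)
  )
  if (symmetrize) S <- (S + Matrix::t(S)) / 2
  S
}

#' Similarity matrix as sparse triplets
#'
#' @param S Similarity matrix from [build_similarity()].
#' @return Tibble `gene_i`, `gene_j`, `weight` for the nonzero entries.
#' @export
similarity_edges <- function(S) {
  tr <- Matrix::summary(methods::as(S, "TsparseMatrix"))
  out <- tibble(gene_i = rownames(S)[tr$i], gene_j = colnames(S)[tr$j],
                weight = tr$x)
  dplyr::arrange(out, .data$gene_i, .data$gene_j)
}

#' Propagate associations to driver scores
#'
#' Diffuses the binary gene-patient associations `F0` over the similarity
#' graph. The fixed point of the iteration
#' `F_{t+1} = alpha * S F_t + (1 - alpha) * F0` is
#' `F* = (1 - alpha) (I - alpha S)^{-1} F0`; the closed-form mode solves
#' the linear system `(I - alpha S) F* = (1 - alpha) F0` directly (never
#' forming an inverse), the iterative mode runs the fixed-point iteration
#' until the maximum absolute change drops below `tol`. Both agree within
#' a small multiple of `tol`. Each gene's score blends its own initial
#' label (weight `1 - alpha`) with its neighbours' propagated labels
#' (weight `alpha`).
#'
#' @param mgp Association tibble (first column `gene`, patient columns).
#' @param S Similarity matrix from [build_similarity()], rows/columns in
#'   `mgp` gene order.
#' @param alpha Propagation proportion in `[0, 1)`; default 0.5.
#' @param mode `"closed_form"` (default) or `"iterative"`.
#' @param tol Convergence tolerance of the iterative mode (default 1e-8).
#' @param max_iter Iteration cap (default 1000).
#' @return A `driver_scores` tibble: columns `patient`, `gene`, `score`,
#'   `rank` (rank 1 = highest score within a patient, ties by gene symbol
#'   ascending), with attributes `alpha`, `mode`, `gene_ids`,
#'   `patient_ids`.
#' @examples
#' mgp <- tibble::tibble(gene = c("a", "b"), p1 = c(1, 0))
#' S <- Matrix::Matrix(matrix(c(0, 1, 1, 0), 2,
#'                     dimnames = list(c("a", "b"), c("a", "b"))), sparse = TRUE)
#' propagate(mgp, S, alpha = 0.5)   # scores 2/3 and 1/3
#' @export
propagate <- function(mgp, S, alpha = 0.5, mode = c("closed_form", "iterative"),
                      tol = 1e-8, max_iter = 1000L) {
  mode <- match.arg(mode)
  if (!is.numeric(alpha) || alpha < 0 || alpha >= 1) {
    abort("`alpha` must lie in [0, 1): at alpha >= 1 the spectral radius of alpha*S can reach 1 and convergence is lost")
  }
  F0 <- assoc_matrix(mgp)
  n <- nrow(F0)
  stopifnot(nrow(S) == n, ncol(S) == n)
  if (!is.null(rownames(S)) && !identical(rownames(S), rownames(F0))) {
    S <- S[rownames(F0), rownames(F0), drop = FALSE]
  }

  if (alpha == 0) {
    Fstar <- F0
    iterations <- 0L
  } else if (mode == "closed_form") {
    A <- Matrix::Diagonal(n) - alpha * S
    Fstar <- as.matrix(Matrix::solve(A, (1 - alpha) * F0))
    dimnames(Fstar) <- dimnames(F0)
    iterations <- NA_integer_
  } else {
    Fi <- F0
    iterations <- max_iter
    for (t in seq_len(max_iter)) {
      Fnew <- as.matrix(alpha * (S %*% Fi) + (1 - alpha) * F0)
      if (max(abs(Fnew - Fi)) < tol) {
        iterations <- t
        Fi <- Fnew
        break
      }
      Fi <- Fnew
    }
    Fstar <- Fi
    dimnames(Fstar) <- dimnames(F0)
  }

  out <- tidyr::pivot_longer(
    dplyr::mutate(as_tibble(Fstar), gene = rownames(Fstar)),
    cols = -"gene", names_to = "patient", values_to = "score"
  )
  out <- dplyr::arrange(out, .data$patient, dplyr::desc(.data$score), .data$gene)
  out <- dplyr::mutate(dplyr::group_by(out, .data$patient), rank = dplyr::row_number())
  out <- dplyr::ungroup(dplyr::select(out, "patient", "gene", "score", "rank"))
  structure(out, alpha = alpha, mode = mode, iterations = iterations,
            gene_ids = rownames(F0), patient_ids = colnames(F0),
            class = c("driver_scores", class(out)))
}

#' Driver scores as a genes-by-patients matrix
#'
#' @param scores A `driver_scores` tibble.
#' @return Numeric matrix (genes x patients) of propagated scores.
#' @export
score_matrix <- function(scores) {
  genes <- attr(scores, "gene_ids")
  patients <- attr(scores, "patient_ids")
  m <- matrix(NA_real_, length(genes), length(patients),
              dimnames = list(genes, patients))
  m[cbind(match(scores$gene, genes), match(scores$patient, patients))] <- scores$score
  m
}

#' @describeIn propagate One-row summary of a score table.
#' @param x A `driver_scores` tibble.
#' @param ... Unused.
#' @export
glance.driver_scores <- function(x, ...) {
  tibble(n_genes = length(attr(x, "gene_ids")),
         n_patients = length(attr(x, "patient_ids")),
         alpha = attr(x, "alpha"), mode = attr(x, "mode"),
         min_score = min(x$score), max_score = max(x$score))
}
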