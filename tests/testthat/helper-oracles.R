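# Independent oracles and random-instance generators used across the
# suite. Each oracle is a deliberately naive recomputation (nested loops,
# exhaustive enumeration, grid search) kept separate from the package
# implementation it checks.

# ---- bipartite matching -----------------------------------------------

# Exhaustive maximum-matching cardinality: branch over each right node
# (skip it, or match it to any unused left neighbour).
bf_matching_size <- function(bg) {
  nbrs <- lapply(split(bg$incidence$gene, bg$incidence$edge_id), unique)
  nbrs <- nbrs[bg$right]
  recurse <- function(idx, used) {
    if (idx > length(nbrs)) return(0L)
    best <- recurse(idx + 1L, used)
    for (g in nbrs[[idx]]) {
      if (!g %in% used) {
        best <- max(best, 1L + recurse(idx + 1L, c(used, g)))
      }
    }
    best
  }
  recurse(1L, character(0))
}

# Random simple undirected graph with <= max_genes nodes, <= max_edges
# edges (the personalized-network scale of the matching oracle checks).
random_gp <- function(seed, max_genes = 8L, max_edges = 10L) {
  set.seed(seed)
  n <- sample(2:max_genes, 1L)
  genes <- sprintf("g%02d", seq_len(n))
  all_pairs <- t(combn(genes, 2L))
  n_edges <- sample(1:min(max_edges, nrow(all_pairs)), 1L)
  idx <- sample(nrow(all_pairs), n_edges)
  tibble::tibble(gene_i = all_pairs[idx, 1], gene_j = all_pairs[idx, 2])
}

# LP relaxation optimum of the matching program, solved by an external
# LP solver (scipy / HiGHS) on a batch of instances.
lp_matching_optima <- function(bgs) {
  payload <- lapply(bgs, function(bg) {
    list(left = bg$left, right = bg$right,
         inc_left = bg$incidence$gene, inc_right = bg$incidence$edge_id)
  })
  script <- system.file("lp", "lp_matching.py", package = "driverprop")
  stopifnot(nzchar(script))
  out <- system2("python", script, input = jsonlite::toJSON(payload),
                 stdout = TRUE)
  as.numeric(jsonlite::fromJSON(paste(out, collapse = "")))
}

# ---- simplex quadratic program ----------------------------------------

# Grid search over the probability simplex at the given resolution;
# returns the minimum of w' H w over grid points. Supports k <= 3.
grid_simplex_min <- function(H, res = 0.01) {
  k <- nrow(H)
  obj <- function(w) drop(t(w) %*% H %*% w)
  if (k == 1L) return(obj(1))
  g <- seq(0, 1, by = res)
  best <- Inf
  if (k == 2L) {
    for (a in g) best <- min(best, obj(c(a, 1 - a)))
  } else if (k == 3L) {
    for (a in g) {
      for (b in g[g <= 1 - a + 1e-12]) {
        best <- min(best, obj(c(a, b, 1 - a - b)))
      }
    }
  } else {
    stop("grid oracle supports k <= 3")
  }
  best
}

# Objective of a fitted gene's weights under its local Gram matrix.
lns_objective <- function(Y, i, nb_idx, w, gamma) {
  Z <- Y[rep(i, length(nb_idx)), , drop = FALSE] - Y[nb_idx, , drop = FALSE]
  H <- Z %*% t(Z) + gamma * diag(length(nb_idx))
  drop(t(w) %*% H %*% w)
}

# Random binary association matrix with no all-zero rows.
random_mgp <- function(seed, n_genes, n_patients) {
  set.seed(seed)
  repeat {
    vals <- matrix(rbinom(n_genes * n_patients, 1, 0.4), n_genes, n_patients)
    if (all(rowSums(vals) > 0)) break
  }
  out <- tibble::tibble(gene = sprintf("g%02d", seq_len(n_genes)))
  for (j in seq_len(n_patients)) out[[sprintf("p%02d", j)]] <- vals[, j]
  out
}

# ---- personalized networks --------------------------------------------

# Brute-force personalized network: per-pair cor.test over ALL pairs of
# the expression/reference gene universe, explicit set algebra, then
# intersection with the reference edges. Returns sorted edge keys.
bf_pgin_keys <- function(expr, patient, reference, alpha = 0.05) {
  genes <- intersect(expr$gene, sort(unique(c(reference$gene_i, reference$gene_j))))
  genes <- sort(genes)
  X <- as.matrix(expr[match(genes, expr$gene), -1, drop = FALSE])
  rownames(X) <- genes
  sig_edges <- function(X) {
    keys <- character(0)
    for (a in seq_along(genes)) {
      for (b in seq_along(genes)) {
        if (a >= b) next
        x <- X[a, ]; y <- X[b, ]
        if (sd(x) == 0 || sd(y) == 0) next
        if (cor.test(x, y)$p.value < alpha) {
          keys <- c(keys, paste(genes[a], genes[b], sep = "|"))
        }
      }
    }
    keys
  }
  k1 <- sig_edges(X)
  k2 <- sig_edges(X[, setdiff(colnames(X), patient), drop = FALSE])
  ref_keys <- paste(pmin(reference$gene_i, reference$gene_j),
                    pmax(reference$gene_i, reference$gene_j), sep = "|")
  sort(intersect(union(setdiff(k1, k2), setdiff(k2, k1)), ref_keys))
}

# Small random cohort plus random reference network over its genes.
random_cohort <- function(seed, n_genes = 10L, n_patients = 8L,
                          n_ref_edges = NULL) {
  set.seed(seed)
  genes <- sprintf("g%02d", seq_len(n_genes))
  patients <- sprintf("p%02d", seq_len(n_patients))
  X <- matrix(rnorm(n_genes * n_patients), n_genes, n_patients)
  # plant a handful of correlated pairs so both networks are non-trivial
  for (rep in seq_len(max(1L, n_genes %/% 4))) {
    ij <- sample(n_genes, 2L)
    X[ij[2], ] <- X[ij[1], ] + rnorm(n_patients, sd = 0.6)
  }
  expr <- tibble::tibble(gene = genes)
  for (j in seq_along(patients)) expr[[patients[j]]] <- X[, j]
  all_pairs <- t(combn(genes, 2L))
  if (is.null(n_ref_edges)) n_ref_edges <- min(nrow(all_pairs), 3L * n_genes)
  idx <- sample(nrow(all_pairs), n_ref_edges)
  reference <- tibble::tibble(gene_i = all_pairs[idx, 1],
                              gene_j = all_pairs[idx, 2])
  list(expr = expr, reference = reference, patients = patients)
}

# Expression tibble with a single high-leverage patient that makes the
# pair {a, b} significant only while that patient is included.
leverage_pair_expr <- function(n_patients = 10L, seed = 42L) {
  set.seed(seed)
  patients <- sprintf("p%02d", seq_len(n_patients))
  x <- rnorm(n_patients, sd = 0.3)
  y <- rnorm(n_patients, sd = 0.3)
  x[n_patients] <- 8
  y[n_patients] <- 8
  expr <- tibble::tibble(gene = c("a", "b", "c"))
  vals <- rbind(x, y, rnorm(n_patients, sd = 0.3))
  for (j in seq_along(patients)) expr[[patients[j]]] <- vals[, j]
  list(expr = expr, focal = patients[n_patients])
}
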