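# Linear neighborhood similarity (simplex QP) and label propagation.

two_gene_S <- function() {
  S <- Matrix::Matrix(matrix(c(0, 1, 1, 0), 2), sparse = TRUE)
  dimnames(S) <- list(c("a", "b"), c("a", "b"))
  S
}

test_that("with two genes the constraint forces weight 1 on the other gene", {
  mgp <- tibble::tibble(gene = c("a", "b"), p1 = c(1, 0), p2 = c(0, 1))
  fit <- fit_neighborhood(mgp, k = 1)
  expect_equal(fit$neighbors$a, "b")
  expect_equal(fit$neighbors$b, "a")
  expect_equal(unname(fit$weights$a), 1)
  S <- build_similarity(fit)
  expect_equal(as.matrix(S), matrix(c(0, 1, 1, 0), 2,
                                    dimnames = list(c("a", "b"), c("a", "b"))))
})

test_that("an exactly duplicating neighbour receives more weight than a far one", {
  # gene g is identical to neighbour a and far from neighbour b
  mgp <- tibble::tibble(
    gene = c("g", "a", "b"),
    p1 = c(1, 1, 0), p2 = c(0, 0, 1), p3 = c(1, 1, 1), p4 = c(0, 0, 1)
  )
  fit <- fit_neighborhood(mgp, k = 2, gamma = 1)
  w <- fit$weights$g
  expect_gt(w[["a"]], w[["b"]])

  # grid-search oracle at 1e-4 resolution agrees on the optimum
  Y <- assoc_matrix(mgp)
  nb <- match(fit$neighbors$g, rownames(Y))
  got <- lns_objective(Y, 1, nb, unname(w), 1)
  Z <- Y[c(1, 1), ] - Y[nb, ]
  H <- Z %*% t(Z) + diag(2)
  expect_lte(got, grid_simplex_min(H, res = 1e-4) + 1e-8)
})

test_that("QP weights satisfy the simplex constraints and beat uniform weights", {
  for (seed in 1:6) {
    mgp <- random_mgp(seed, n_genes = 6L, n_patients = 4L)
    fit <- fit_neighborhood(mgp, k = 3, gamma = 1)
    Y <- assoc_matrix(mgp)
    for (i in seq_along(fit$genes)) {
      w <- unname(fit$weights[[i]])
      expect_true(all(w >= 0))
      expect_lt(abs(sum(w) - 1), 1e-8)
      nb <- match(fit$neighbors[[i]], rownames(Y))
      obj <- lns_objective(Y, i, nb, w, 1)
      obj_uniform <- lns_objective(Y, i, nb, rep(1 / 3, 3), 1)
      expect_lte(obj, obj_uniform + 1e-10)
      # matches the brute-force simplex grid at 0.01 resolution
      Z <- Y[rep(i, 3), ] - Y[nb, ]
      H <- Z %*% t(Z) + diag(3)
      expect_lte(obj, grid_simplex_min(H, res = 0.01) + 1e-6)
    }
  }
})

test_that("similarity rows are stochastic, hollow and k-sparse", {
  mgp <- random_mgp(3, n_genes = 12L, n_patients = 6L)
  fit <- fit_neighborhood(mgp, k = 4, gamma = 1)
  S <- build_similarity(fit)
  expect_true(all(S@x >= 0))
  expect_equal(unname(Matrix::diag(S)), rep(0, 12))
  expect_true(all(abs(Matrix::rowSums(S) - 1) < 1e-8))
  expect_true(all(Matrix::rowSums(S != 0) <= 4))

  # k = 1: each row is an indicator of the single nearest neighbour
  fit1 <- fit_neighborhood(mgp, k = 1)
  S1 <- build_similarity(fit1)
  expect_true(all(S1@x == 1))
  expect_equal(unname(Matrix::rowSums(S1)), rep(1, 12))
})

test_that("degenerate neighbourhoods fall back to uniform weights", {
  # three identical genes: all residuals zero, Gram matrix 0
  mgp <- tibble::tibble(gene = c("a", "b", "c"), p1 = c(1, 1, 1),
                        p2 = c(0, 0, 0))
  fit <- fit_neighborhood(mgp, k = 2, gamma = 1)
  expect_equal(unname(fit$weights$a), c(0.5, 0.5))
})

test_that("parameter validation rejects out-of-range k, gamma and alpha", {
  mgp <- random_mgp(1, 5L, 3L)
  expect_error(fit_neighborhood(mgp, k = 0), "k")
  expect_error(fit_neighborhood(mgp, k = 5), "k")
  expect_error(fit_neighborhood(mgp, k = 2, gamma = 0), "gamma")
  S <- build_similarity(fit_neighborhood(mgp, k = 2))
  expect_error(propagate(mgp, S, alpha = 1), "alpha")
})

test_that("propagation at alpha 0 returns the initial labels exactly", {
  mgp <- random_mgp(2, 7L, 4L)
  S <- build_similarity(fit_neighborhood(mgp, k = 2))
  sc <- propagate(mgp, S, alpha = 0)
  expect_identical(score_matrix(sc), assoc_matrix(mgp))
})

test_that("the two-gene system has the known closed-form fixed point", {
  mgp <- tibble::tibble(gene = c("a", "b"), p1 = c(1, 0))
  sc <- propagate(mgp, two_gene_S(), alpha = 0.5)
  m <- score_matrix(sc)
  expect_equal(unname(m[, 1]), c(2 / 3, 1 / 3), tolerance = 1e-9)
})

test_that("closed-form and iterative propagation agree and satisfy the fixed point", {
  for (seed in 1:5) {
    mgp <- random_mgp(seed + 10, n_genes = 15L, n_patients = 6L)
    S <- build_similarity(fit_neighborhood(mgp, k = 3))
    a <- score_matrix(propagate(mgp, S, alpha = 0.5, mode = "closed_form"))
    b <- score_matrix(propagate(mgp, S, alpha = 0.5, mode = "iterative"))
    expect_lt(max(abs(a - b)), 1e-6)
    # fixed point: F = alpha S F + (1 - alpha) F0
    F0 <- assoc_matrix(mgp)
    resid <- a - as.matrix(0.5 * S %*% a + 0.5 * F0)
    expect_lt(max(abs(resid)), 1e-8)
    expect_true(all(a >= 0))
  }
})

test_that("propagation conserves column mass when S is doubly stochastic", {
  # mutual nearest-neighbour pairs with k = 1 give a symmetric permutation S
  mgp <- tibble::tibble(
    gene = c("a", "b", "c", "d"),
    p1 = c(1, 1, 0, 0), p2 = c(0, 0, 1, 1), p3 = c(1, 0, 0, 1)
  )
  fit <- fit_neighborhood(mgp, k = 1)
  S <- build_similarity(fit)
  expect_equal(unname(Matrix::colSums(S)), rep(1, 4))   # doubly stochastic
  sc <- score_matrix(propagate(mgp, S, alpha = 0.7))
  expect_equal(colSums(sc), colSums(assoc_matrix(mgp)), tolerance = 1e-6)
})

test_that("scores of unlabelled genes increase with the propagation proportion", {
  mgp <- random_mgp(5, n_genes = 10L, n_patients = 5L)
  S <- build_similarity(fit_neighborhood(mgp, k = 3))
  F0 <- assoc_matrix(mgp)
  zero_idx <- which(F0 == 0)
  prev <- NULL
  for (alpha in seq(0.1, 0.9, by = 0.2)) {
    m <- score_matrix(propagate(mgp, S, alpha = alpha))
    if (!is.null(prev)) {
      expect_true(all(m[zero_idx] >= prev[zero_idx] - 1e-10),
                  info = paste("alpha", alpha))
    }
    prev <- m
  }
})

test_that("genes with identical association patterns stay closer after propagation", {
  # two blocks of identical rows
  blockA <- c(1, 1, 0, 0, 0)
  blockB <- c(0, 0, 0, 1, 1)
  mgp <- tibble::tibble(gene = sprintf("g%d", 1:6))
  vals <- rbind(blockA, blockA, blockA, blockB, blockB, blockB)
  for (j in 1:5) mgp[[sprintf("p%d", j)]] <- vals[, j]
  S <- build_similarity(fit_neighborhood(mgp, k = 2))
  m <- score_matrix(propagate(mgp, S, alpha = 0.5))
  D <- as.matrix(dist(m))
  within <- c(D[1:3, 1:3][upper.tri(diag(3))], D[4:6, 4:6][upper.tri(diag(3))])
  between <- as.vector(D[1:3, 4:6])
  expect_lt(mean(within), mean(between))
  # silhouette-style margin is strictly positive
  expect_gt(mean(between) - mean(within), 0)
})
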