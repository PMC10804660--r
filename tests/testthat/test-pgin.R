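# Co-expression networks and the per-patient leave-one-out difference.

make_expr <- function(mat, genes, patients) {
  out <- tibble::tibble(gene = genes)
  for (j in seq_along(patients)) out[[patients[j]]] <- mat[, j]
  out
}

test_that("perfect correlations form edges and constant genes never do", {
  withr::local_seed(1)
  x <- rnorm(10)
  mat <- rbind(x, 2 * x + 1, rep(3, 10))
  expr <- make_expr(mat, c("a", "b", "c"), sprintf("p%02d", 1:10))
  net <- correlation_network(expr)
  expect_equal(nrow(net), 1L)
  expect_equal(net$gene_i, "a")
  expect_equal(net$gene_j, "b")
  expect_equal(net$pcc, 1)
  expect_equal(net$p_value, 0)
})

test_that("edge retention matches a per-pair textbook significance test", {
  withr::local_seed(7)
  n <- 5; m <- 20
  mat <- matrix(rnorm(n * m), n, m)
  mat[2, ] <- mat[1, ] + rnorm(m, sd = 0.33)   # planted pair at r ~ 0.95
  genes <- letters[1:n]
  expr <- make_expr(mat, genes, sprintf("p%02d", 1:m))
  net <- correlation_network(expr, alpha_edge = 0.05)
  got <- paste(net$gene_i, net$gene_j, sep = "|")

  want <- character(0)
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      if (cor.test(mat[i, ], mat[j, ])$p.value < 0.05) {
        want <- c(want, paste(genes[i], genes[j], sep = "|"))
      }
    }
  }
  expect_setequal(got, want)
  expect_true(paste("a", "b", sep = "|") %in% got)
})

test_that("fewer than three included patients is an error", {
  expr <- make_expr(matrix(rnorm(6), 2), c("a", "b"), c("p1", "p2", "p3"))
  expect_error(correlation_network(expr, exclude_patient = "p1"),
               "at least 3")
  expect_error(personalized_network(
    make_expr(matrix(rnorm(4), 2), c("a", "b"), c("p1", "p2")),
    "p1", tibble::tibble(gene_i = "a", gene_j = "b")
  ), "at least 3")
})

test_that("stable correlations cancel in the leave-one-out difference", {
  withr::local_seed(2)
  x <- rnorm(12)
  mat <- rbind(x, x + rnorm(12, sd = 1e-3), rnorm(12))
  expr <- make_expr(mat, c("a", "b", "c"), sprintf("p%02d", 1:12))
  ref <- tibble::tibble(gene_i = c("a", "a"), gene_j = c("b", "c"))
  gp <- personalized_network(expr, "p01", ref)
  expect_equal(nrow(gp), 0L)   # edge {a,b} is in both G1 and G2
})

test_that("a single leverage patient yields exactly one provenance-tagged edge", {
  lp <- leverage_pair_expr()
  ref <- tibble::tibble(gene_i = "a", gene_j = "b")
  gp <- personalized_network(lp$expr, lp$focal, ref)
  expect_equal(nrow(gp), 1L)
  expect_equal(gp$gene_i, "a")
  expect_equal(gp$gene_j, "b")
  expect_equal(gp$provenance, "from_G1_only")
  expect_equal(attr(gp, "patient"), lp$focal)

  # same cohort, but the reference does not support {a,b}: refined away
  ref2 <- tibble::tibble(gene_i = "a", gene_j = "c")
  gp2 <- personalized_network(lp$expr, lp$focal, ref2)
  expect_equal(nrow(gp2), 0L)
})

test_that("personalized networks equal an independent brute-force recomputation", {
  for (seed in 1:4) {
    cohort <- random_cohort(seed, n_genes = 10L, n_patients = 8L)
    for (p in cohort$patients) {
      gp <- personalized_network(cohort$expr, p, cohort$reference)
      expect_identical(
        paste(gp$gene_i, gp$gene_j, sep = "|"),
        bf_pgin_keys(cohort$expr, p, cohort$reference),
        info = sprintf("seed %d patient %s", seed, p)
      )
    }
  }
})

test_that("restricting the pair scan to reference pairs changes nothing", {
  cohort <- random_cohort(11, n_genes = 9L, n_patients = 7L)
  for (p in cohort$patients[1:3]) {
    a <- personalized_network(cohort$expr, p, cohort$reference,
                              restrict_pairs = TRUE)
    b <- personalized_network(cohort$expr, p, cohort$reference,
                              restrict_pairs = FALSE)
    expect_identical(tibble::as_tibble(a), tibble::as_tibble(b))
  }
})

test_that("network edges always lie within the reference", {
  for (seed in 5:7) {
    cohort <- random_cohort(seed)
    ref_keys <- paste(cohort$reference$gene_i, cohort$reference$gene_j, sep = "|")
    for (p in cohort$patients[1:4]) {
      gp <- personalized_network(cohort$expr, p, cohort$reference)
      expect_true(all(paste(gp$gene_i, gp$gene_j, sep = "|") %in% ref_keys))
    }
  }
})

test_that("lowering the significance threshold never adds an edge", {
  cohort <- random_cohort(21, n_genes = 8L, n_patients = 10L)
  alphas <- c(0.2, 0.1, 0.05, 0.01)
  prev <- NULL
  for (a in alphas) {
    net <- correlation_network(cohort$expr, alpha_edge = a)
    keys <- paste(net$gene_i, net$gene_j, sep = "|")
    if (!is.null(prev)) expect_true(all(keys %in% prev))
    prev <- keys
  }
})

test_that("results do not depend on gene or patient input order", {
  cohort <- random_cohort(31, n_genes = 8L, n_patients = 8L)
  expr <- cohort$expr
  withr::local_seed(1)
  expr_perm <- expr[sample(nrow(expr)), c("gene", sample(cohort$patients))]
  ref_perm <- cohort$reference[sample(nrow(cohort$reference)),
                               c("gene_j", "gene_i")]
  names(ref_perm) <- c("gene_i", "gene_j")   # reversed endpoint columns
  p <- cohort$patients[3]
  a <- personalized_network(expr, p, cohort$reference)
  b <- personalized_network(expr_perm, p, ref_perm)
  expect_identical(tibble::as_tibble(a), tibble::as_tibble(b))
})
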