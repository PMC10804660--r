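# End-to-end orchestration: personalized networks for every patient,
# matching, association assembly, label propagation, driver calls and
# optional benchmark evaluation / rare-driver flagging, plus a
# machine-readable run manifest.

#' Run the full personalized driver-gene pipeline
#'
#' For every patient (in sorted ID order) builds the personalized network,
#' extracts candidate drivers by maximum matching, assembles the
#' gene-patient association matrix, refines it by linear-neighborhood
#' label propagation, and calls cohort-level drivers. When a benchmark
#' list is supplied the cohort drivers are scored by precision / recall /
#' F-measure; when a mutation table is supplied rare drivers are flagged.
#'
#' When `reference_fraction < 1`, a seeded random subsample of the
#' patient columns is used as the reference sample set for network
#' construction; the focal patient is always re-added before the
#' leave-one-out comparison.
#'
#' @param expression Expression tibble (first column `gene`).
#' @param reference Reference network edge tibble (`gene_i`, `gene_j`).
#' @param benchmark Optional benchmark gene list (tibble with `gene`, or
#'   character vector).
#' @param mutations Optional mutation tibble (`patient`, `gene`).
#' @param alpha Propagation proportion (default 0.5).
#' @param alpha_edge Correlation significance threshold (default 0.05).
#' @param k Neighbour count for the similarity model (default: fractional
#'   rule of [fit_neighborhood()]).
#' @param gamma Tikhonov regularization (default 1).
#' @param top_n Per-patient candidate window (default 100).
#' @param recurrence Cohort recurrence threshold (default 0.8).
#' @param reference_fraction Fraction of patient columns used as reference
#'   samples, in (0, 1] (default 1).
#' @param seed Seed for the reference subsample (default 1).
#' @param mode Propagation mode (`"closed_form"` or `"iterative"`).
#' @param out_dir Optional output directory; when given, scores,
#'   associations, cohort drivers, evaluation, rare drivers and the run
#'   manifest are written there.
#' @param write_networks Also export each patient's network edge list
#'   under `out_dir/networks/` (default `FALSE`).
#' @return A `driver_run` object: list with `networks` (per-patient `pgin`
#'   tibbles), `matchings`, `associations`, `lns`, `similarity`, `scores`,
#'   `calls`, `evaluation` (or `NULL`), `rare` (or `NULL`), `manifest`.
#' @examples
#' \donttest{
#' cohort <- simulate_cohort(n_genes = 30, n_patients = 12, seed = 3)
#' run <- run_pipeline(cohort$expression, cohort$reference,
#'                     benchmark = cohort$truth_drivers)
#' run$evaluation
#' }
#' @export
run_pipeline <- function(expression, reference, benchmark = NULL,
                         mutations = NULL, alpha = 0.5, alpha_edge = 0.05,
                         k = NULL, gamma = 1, top_n = 100L, recurrence = 0.8,
                         reference_fraction = 1, seed = 1L,
                         mode = c("closed_form", "iterative"),
                         out_dir = NULL, write_networks = FALSE) {
  mode <- match.arg(mode)
  if (reference_fraction <= 0 || reference_fraction > 1) {
    abort("`reference_fraction` must lie in (0, 1]")
  }
  check_expression(expression)
  check_network(reference)
  patients <- sort(names(expression)[-1])

  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      abort(paste0("stage '", name, "' failed: ", conditionMessage(e)))
    })
    message(sprintf("[driverprop] %-12s %6.2fs", name,
                    proc.time()[["elapsed"]] - t0))
    res
  }

  ref_cols <- patients
  if (reference_fraction < 1) {
    set.seed(seed)
    n_ref <- max(3L, as.integer(ceiling(reference_fraction * length(patients))))
    ref_cols <- sort(sample(patients, n_ref))
  }

  networks <- stage("networks", {
    lapply(setNames(patients, patients), function(p) {
      cols <- sort(union(ref_cols, p))
      sub <- expression[, c("gene", cols), drop = FALSE]
      personalized_network(sub, p, reference, alpha_edge)
    })
  })

  matchings <- stage("matching", {
    lapply(networks, function(gp) maximum_matching(build_bipartite(gp)))
  })
  non_empty <- vapply(matchings, function(m) length(m$genes) > 0, logical(1))
  if (!any(non_empty)) {
    abort("stage 'matching' failed: every patient's matching is empty")
  }

  associations <- stage("associations", assemble_associations(matchings))
  lns <- stage("similarity", fit_neighborhood(associations, k = k, gamma = gamma))
  S <- build_similarity(lns)
  scores <- stage("propagation",
                  propagate(associations, S, alpha = alpha, mode = mode))
  calls <- stage("calls", call_drivers(scores, top_n = top_n, recurrence = recurrence))

  evaluation <- NULL
  if (!is.null(benchmark) && length(calls$cohort_drivers) > 0) {
    evaluation <- stage("evaluation", f_measure(calls$cohort_drivers, benchmark))
  }
  rare <- NULL
  if (!is.null(mutations)) {
    rare <- stage("rare_drivers",
                  rare_drivers(scores, mutations, rank_cutoff = top_n))
  }

  manifest <- list(
    package = "driverprop",
    version = as.character(utils::packageVersion("driverprop")),
    parameters = list(alpha = alpha, alpha_edge = alpha_edge, k = lns$k,
                      gamma = gamma, top_n = as.integer(top_n),
                      recurrence = recurrence,
                      reference_fraction = reference_fraction,
                      seed = as.integer(seed), mode = mode),
    inputs = list(
      n_genes = nrow(expression), n_patients = length(patients),
      n_reference_edges = nrow(canonical_edges(reference)),
      expression_hash = rlang::hash(expression),
      reference_hash = rlang::hash(canonical_edges(reference)),
      benchmark_hash = if (is.null(benchmark)) NULL else rlang::hash(benchmark),
      mutations_hash = if (is.null(mutations)) NULL else rlang::hash(mutations)
    ),
    reference_samples = ref_cols,
    sizes = list(
      mean_network_edges = mean(vapply(networks, nrow, double(1))),
      n_associated_genes = nrow(associations),
      n_cohort_drivers = length(calls$cohort_drivers)
    )
  )

  run <- structure(
    list(networks = networks, matchings = matchings,
         associations = associations, lns = lns, similarity = S,
         scores = scores, calls = calls, evaluation = evaluation,
         rare = rare, manifest = manifest),
    class = "driver_run"
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_scores(scores, file.path(out_dir, "scores.tsv"))
    write_associations(associations, file.path(out_dir, "associations.tsv"))
    writeLines(calls$cohort_drivers, file.path(out_dir, "cohort_drivers.txt"))
    if (!is.null(evaluation)) {
      write_evaluation(evaluation, file.path(out_dir, "evaluation.tsv"))
    }
    if (!is.null(rare)) {
      readr::write_tsv(rare, file.path(out_dir, "rare_drivers.tsv"),
                       progress = FALSE)
    }
    if (write_networks) {
      net_dir <- file.path(out_dir, "networks")
      dir.create(net_dir, showWarnings = FALSE)
      lapply(networks, write_pgin, dir = net_dir)
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  run
}

#' @export
print.driver_run <- function(x, ...) {
  cat("driverprop run: ", length(x$networks), " patients, ",
      nrow(x$associations), " associated genes, ",
      length(x$calls$cohort_drivers), " cohort drivers\n", sep = "")
  if (!is.null(x$evaluation)) {
    cat(sprintf("  precision %.3f  recall %.3f  F-measure %.3f\n",
                x$evaluation$precision, x$evaluation$recall,
                x$evaluation$f_measure))
  }
  invisible(x)
}

#' @describeIn run_pipeline Per-patient summary of a run.
#' @param x A `driver_run` object.
#' @param ... Unused.
#' @export
tidy.driver_run <- function(x, ...) {
  tibble(
    patient = names(x$networks),
    n_network_edges = vapply(x$networks, nrow, double(1)),
    n_matched_genes = vapply(x$matchings, function(m) length(m$genes), double(1))
  )
}

#' @describeIn run_pipeline One-row summary of a run.
#' @export
glance.driver_run <- function(x, ...) {
  out <- tibble(
    n_patients = length(x$networks),
    n_genes = nrow(x$associations),
    n_cohort_drivers = length(x$calls$cohort_drivers),
    alpha = x$manifest$parameters$alpha,
    k = x$manifest$parameters$k
  )
  if (!is.null(x$evaluation)) {
    out <- dplyr::bind_cols(out, x$evaluation[, c("precision", "recall", "f_measure")])
  }
  out
}
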