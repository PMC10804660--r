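# Cohort-level driver calls, benchmark F-measure, and personalized
# rare-driver flagging.

#' Call cohort-level drivers from per-patient scores
#'
#' Takes each patient's top `top_n` genes by propagated score (ties broken
#' by gene symbol ascending) and calls a gene a cohort driver when it
#' appears in the top list of strictly more than `recurrence` of the
#' patients ("over 80%" at the default).
#'
#' @param scores A `driver_scores` tibble from [propagate()].
#' @param top_n Per-patient window size (default 100).
#' @param recurrence Cohort recurrence threshold in (0, 1]; strict
#'   inequality (default 0.8).
#' @return A `driver_calls` object: list with `per_patient_top` (tibble
#'   `patient`, `gene`, `score`, `rank`), `recurrence_counts` (tibble
#'   `gene`, `n_patients`, `fraction`), `cohort_drivers` (character),
#'   plus the parameters used.
#' @export
call_drivers <- function(scores, top_n = 100L, recurrence = 0.8) {
  if (!is.data.frame(scores) || nrow(scores) == 0L) abort("`scores` is empty")
  if (top_n < 1L) abort("`top_n` must be >= 1")
  if (recurrence <= 0 || recurrence > 1) abort("`recurrence` must lie in (0, 1]")
  top <- dplyr::filter(scores, .data$rank <= top_n)
  m <- length(unique(scores$patient))
  counts <- dplyr::summarise(dplyr::group_by(top, .data$gene),
                             n_patients = dplyr::n(), .groups = "drop")
  counts <- dplyr::mutate(counts, fraction = .data$n_patients / m)
  counts <- dplyr::arrange(counts, dplyr::desc(.data$fraction), .data$gene)
  cohort <- counts$gene[counts$fraction > recurrence]
  structure(
    list(per_patient_top = dplyr::select(top, "patient", "gene", "score", "rank"),
         recurrence_counts = counts,
         cohort_drivers = sort(cohort),
         top_n = as.integer(top_n), recurrence = recurrence, n_patients = m),
    class = "driver_calls"
  )
}

#' @export
print.driver_calls <- function(x, ...) {
  cat("Driver calls: ", length(x$cohort_drivers), " cohort drivers (top ",
      x$top_n, " per patient, recurrence > ", x$recurrence, " of ",
      x$n_patients, " patients)\n", sep = "")
  if (length(x$cohort_drivers)) {
    cat("  ", paste(head(x$cohort_drivers, 10), collapse = ", "),
        if (length(x$cohort_drivers) > 10) ", ..." else "", "\n", sep = "")
  }
  invisible(x)
}

#' @describeIn call_drivers Per-gene recurrence table.
#' @param x A `driver_calls` object.
#' @param ... Unused.
#' @export
tidy.driver_calls <- function(x, ...) x$recurrence_counts

#' @describeIn call_drivers One-row summary.
#' @export
glance.driver_calls <- function(x, ...) {
  tibble(n_cohort_drivers = length(x$cohort_drivers),
         top_n = x$top_n, recurrence = x$recurrence,
         n_patients = x$n_patients)
}

#' Precision, recall and F-measure against a benchmark list
#'
#' `precision = |hits| / |predicted|`, `recall = |hits| / |benchmark|`,
#' and `F = 2 * precision * recall / (precision + recall)` (0 when both
#' are 0). Matching is exact symbol equality; predicted genes absent from
#' the benchmark universe still count in precision's denominator.
#'
#' @param predicted Predicted driver genes (character vector, or a data
#'   frame with a `gene` column).
#' @param benchmark Benchmark gene list (same forms accepted); must be
#'   non-empty.
#' @return One-row tibble: `precision`, `recall`, `f_measure`,
#'   `n_predicted`, `n_benchmark`, `n_hit`.
#' @examples
#' f_measure(c("a", "b", "c", "d"), c(letters[1:2], letters[5:10]))
#' @export
f_measure <- function(predicted, benchmark) {
  predicted <- as_gene_vector(predicted, "predicted")
  benchmark <- as_gene_vector(benchmark, "benchmark")
  if (length(benchmark) == 0L) abort("`benchmark` must be non-empty")
  if (length(predicted) == 0L) abort("`predicted` must be non-empty")
  hit <- length(intersect(predicted, benchmark))
  precision <- hit / length(predicted)
  recall <- hit / length(benchmark)
  f <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  tibble(precision = precision, recall = recall, f_measure = f,
         n_predicted = length(predicted), n_benchmark = length(benchmark),
         n_hit = hit)
}

#' Flag personalized rare driver genes
#'
#' A (patient, gene) pair is a rare-driver record when the gene is mutated
#' in at least one patient but in no more than `freq_cutoff` of the
#' cohort, and ranks within the patient's top `rank_cutoff` predicted
#' drivers. The cohort is the set of patients in the score table.
#'
#' @param scores A `driver_scores` tibble from [propagate()].
#' @param mutations Mutation tibble (`patient`, `gene`).
#' @param freq_cutoff Maximum cohort mutation frequency (default 0.05).
#' @param rank_cutoff Maximum per-patient rank (default 100).
#' @return Tibble `patient`, `gene`, `rank`, `cohort_mutation_frequency`,
#'   sorted by patient then rank. Empty mutation tables give an empty
#'   result.
#' @export
rare_drivers <- function(scores, mutations, freq_cutoff = 0.05,
                         rank_cutoff = 100L) {
  stopifnot(all(c("patient", "gene") %in% names(mutations)))
  patients <- unique(scores$patient)
  m <- length(patients)
  muts <- dplyr::distinct(tibble(patient = mutations$patient,
                                 gene = mutations$gene))
  freq <- dplyr::summarise(
    dplyr::group_by(muts[muts$patient %in% patients, , drop = FALSE], .data$gene),
    cohort_mutation_frequency = dplyr::n_distinct(.data$patient) / m,
    .groups = "drop"
  )
  rare <- freq[freq$cohort_mutation_frequency > 0 &
                 freq$cohort_mutation_frequency <= freq_cutoff, , drop = FALSE]
  out <- dplyr::inner_join(
    dplyr::filter(scores, .data$rank <= rank_cutoff), rare, by = "gene"
  )
  out <- dplyr::select(out, "patient", "gene", "rank", "cohort_mutation_frequency")
  dplyr::arrange(out, .data$patient, .data$rank, .data$gene)
}

#' Union of benchmark gene lists
#'
#' @param ... Gene-list tibbles (`gene`, `source`) or character vectors.
#' @return Tibble `gene`, `source` with one row per gene; genes present in
#'   several lists carry the concatenated source labels (`"CGC;NCG"`).
#' @export
benchmark_union <- function(...) {
  lists <- list(...)
  if (length(lists) == 0L) abort("need at least one gene list")
  tabs <- purrr::imap(lists, function(x, idx) {
    if (is.data.frame(x)) {
      stopifnot("gene" %in% names(x))
      tibble(gene = x$gene,
             source = if ("source" %in% names(x)) x$source else paste0("list", idx))
    } else {
      tibble(gene = as.character(x), source = paste0("list", idx))
    }
  })
  all <- dplyr::distinct(dplyr::bind_rows(tabs))
  out <- dplyr::summarise(dplyr::group_by(all, .data$gene),
                          source = paste(sort(unique(.data$source)), collapse = ";"),
                          .groups = "drop")
  dplyr::arrange(out, .data$gene)
}

#' Write an evaluation report
#'
#' @param report One-row tibble from [f_measure()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_evaluation <- function(report, path) {
  readr::write_tsv(report, path, progress = FALSE)
  invisible(path)
}
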