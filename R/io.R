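# Readers and writers for the plain-text formats the pipeline consumes:
# expression TSV (genes x patients), whitespace-delimited edge lists with
# '#' comments, one-symbol-per-line gene catalogues, two-column mutation
# tables, and the score/association exports.

#' Read a gene-by-patient expression table
#'
#' Expects a TSV whose header row names the patients, whose first column
#' holds gene symbols, and whose body is fully numeric. Expression values
#' are taken as supplied (no transformation or normalization is applied).
#'
#' @param path Path to a tab-separated expression file.
#' @return A tibble with first column `gene` and one numeric column per
#'   patient.
#' @details Duplicate gene rows, duplicate patient columns, missing values
#'   and non-numeric cells are errors; the error message names the
#'   offending row or column.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("gene\tp1\tp2", "g1\t1.5\t2.0", "g2\t0.1\t0.2"), tf)
#' read_expression(tf)
#' @export
read_expression <- function(path) {
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (length(header) < 2L) abort("malformed header: expected gene column plus at least one patient column")
  patients <- header[-1]
  if (anyDuplicated(patients)) {
    abort(paste0("duplicate patient ID in header: ",
                 paste(unique(patients[duplicated(patients)]), collapse = ", ")))
  }
  raw <- readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE, name_repair = "minimal"
  )
  names(raw)[1] <- "gene"
  if (anyDuplicated(raw$gene)) {
    abort(paste0("duplicate gene row: ",
                 paste(unique(raw$gene[duplicated(raw$gene)]), collapse = ", ")))
  }
  for (p in patients) {
    v <- suppressWarnings(as.numeric(raw[[p]]))
    bad <- which(is.na(v))
    if (length(bad)) {
      abort(paste0("non-numeric or missing value '", raw[[p]][bad[1]],
                   "' at gene '", raw$gene[bad[1]], "', patient '", p, "'"))
    }
    raw[[p]] <- v
  }
  check_expression(raw)
  raw
}

#' Write an expression table
#'
#' Inverse of [read_expression()]; finite decimal inputs round-trip
#' bit-identically.
#'
#' @param expr Expression tibble (first column `gene`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  check_expression(expr)
  readr::write_tsv(expr, path, progress = FALSE)
  invisible(path)
}

#' Read an undirected gene interaction network from an edge list
#'
#' Parses a whitespace-delimited edge list of gene symbols: one edge per
#' line, first two fields are the endpoints, extra fields are ignored, and
#' lines starting with `#` (or blank lines) are skipped. Duplicate and
#' reversed-duplicate edges are collapsed to a single canonical edge
#' (`gene_i < gene_j`); self-loops are dropped with a warning reporting how
#' many were removed.
#'
#' @param path Path to the edge-list file.
#' @return A tibble with columns `gene_i`, `gene_j` (each row one
#'   undirected edge, lexicographically ordered endpoints).
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("# reference interactome", "a\tb", "b\ta"), tf)
#' read_network(tf)
#' @export
read_network <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  fields <- strsplit(lines[keep], "[ \t]+")
  n_fields <- lengths(fields)
  if (any(n_fields < 2L)) {
    abort(paste0("edge-list line ", which(keep)[which(n_fields < 2L)[1]],
                 " has fewer than two columns"))
  }
  a <- vapply(fields, `[[`, character(1), 1L)
  b <- vapply(fields, `[[`, character(1), 2L)
  n_loops <- sum(a == b)
  if (n_loops > 0) {
    warn(paste0("dropped ", n_loops, " self-loop(s)"))
  }
  canonical_edges(tibble(gene_i = a, gene_j = b))
}

#' Write a gene network as a two-column edge list
#'
#' @param net Edge tibble with columns `gene_i`, `gene_j`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  check_network(net)
  readr::write_tsv(canonical_edges(net), path, col_names = FALSE,
                   progress = FALSE)
  invisible(path)
}

#' Read a benchmark gene list
#'
#' One gene symbol per line; `#` comments and blank lines are skipped.
#'
#' @param path Path to the file.
#' @param name Label for the list (e.g. `"CGC"`); defaults to the file name.
#' @return Tibble with columns `gene`, `source`.
#' @export
read_gene_list <- function(path, name = NULL) {
  if (is.null(name)) name <- tools::file_path_sans_ext(basename(path))
  lines <- trimws(readLines(path))
  genes <- unique(lines[nzchar(lines) & !startsWith(lines, "#")])
  if (length(genes) == 0L) abort(paste0("gene list '", path, "' is empty"))
  tibble(gene = sort(genes), source = name)
}

#' Read a patient-gene mutation table
#'
#' Two-column TSV with a header row; the first column is the patient
#' identifier, the second the mutated gene symbol. Duplicate pairs are
#' collapsed.
#'
#' @param path Path to the file.
#' @return Tibble with columns `patient`, `gene`.
#' @export
read_mutations <- function(path) {
  raw <- readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE, name_repair = "minimal"
  )
  if (ncol(raw) < 2L) abort("mutation table needs two columns: patient, gene")
  out <- tibble(patient = raw[[1]], gene = raw[[2]])
  dplyr::arrange(dplyr::distinct(out), .data$patient, .data$gene)
}

#' Write per-patient driver scores
#'
#' Writes one row per (patient, gene) with columns `patient_id`, `gene_id`,
#' `score`, `rank`. Rank 1 is the highest score within a patient; ties are
#' broken by gene symbol ascending. An empty score table produces a
#' header-only file.
#'
#' @param scores A `driver_scores` tibble from [propagate()] (columns
#'   `patient`, `gene`, `score`, `rank`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path) {
  stopifnot(all(c("patient", "gene", "score", "rank") %in% names(scores)))
  out <- tibble(
    patient_id = scores$patient, gene_id = scores$gene,
    score = scores$score, rank = scores$rank
  )
  out <- dplyr::arrange(out, .data$patient_id, .data$rank)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Export a binary gene-patient association matrix as a dense TSV
#'
#' @param mgp Association tibble from [assemble_associations()] (first
#'   column `gene`, one 0/1 column per patient).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_associations <- function(mgp, path) {
  readr::write_tsv(mgp, path, progress = FALSE)
  invisible(path)
}
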