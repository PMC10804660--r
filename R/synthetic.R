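# Seeded synthetic cohorts with planted driver modules. Each driver is the
# hub of a co-expression module; in a chosen subset of patients the hub is
# decoupled from its module, so the leave-one-patient-out network differs
# at the hub's edges for exactly the kind of patients the pipeline is
# meant to flag.

#' Generate a synthetic cohort with planted drivers
#'
#' Builds an expression matrix, reference network, benchmark driver list
#' and mutation table with known ground truth:
#'
#' 1. Background genes are i.i.d. standard normal across patients.
#' 2. Each driver module shares a per-patient latent factor: every module
#'    gene is `sqrt(base_corr) * factor + sqrt(1 - base_corr) * noise_sd *
#'    noise`, so with `noise_sd = 1` the within-module correlation is
#'    `base_corr`.
#' 3. For each driver (the first gene of its module), the expression of
#'    the driver itself is resampled independently in
#'    `perturb_patients_per_driver` randomly chosen patients, decoupling
#'    the hub from its partners there. The default count places the
#'    contaminated cohort-level driver-partner correlation at the
#'    significance boundary `r_crit` of the `alpha_edge = 0.05` test,
#'    `ceiling(n_patients * (1 - r_crit / base_corr))`: the regime where a
#'    single patient's presence tips an edge in or out of significance,
#'    which is exactly the signal the leave-one-out construction detects.
#' 4. The reference network contains every within-module edge plus an
#'    equal number of random decoy edges among background pairs, so the
#'    reference-refinement step is exercised nontrivially.
#' 5. Each perturbed (patient, driver) pair is mutated with probability
#'    0.5, plus sparse background mutations at a 1% rate.
#'
#' All randomness derives from `seed`; identical seeds give identical
#' cohorts.
#'
#' @param n_genes Total genes (default 60).
#' @param n_patients Patients (default 30).
#' @param n_drivers Planted driver modules (default 3).
#' @param module_size Genes per module, hub included (default 5).
#' @param perturb_patients_per_driver Patients whose hub expression is
#'   decoupled, per driver; default as described above (17 at the default
#'   geometry).
#' @param base_corr Target within-module correlation in (0, 1); default 0.8.
#' @param noise_sd Residual noise scale; default 1.
#' @param seed Integer RNG seed (default 1).
#' @return A `synthetic_cohort` object: list with `expression` (wide
#'   tibble), `reference` (edge tibble), `truth_drivers` (tibble `gene`,
#'   `source`), `truth_assignments` (tibble `patient`, `gene`: which
#'   patients were perturbed for which driver), `mutations` (tibble
#'   `patient`, `gene`) and `config`.
#' @examples
#' cohort <- simulate_cohort(n_genes = 30, n_patients = 12, seed = 7)
#' cohort$truth_drivers
#' @export
simulate_cohort <- function(n_genes = 60L, n_patients = 30L, n_drivers = 3L,
                            module_size = 5L,
                            perturb_patients_per_driver = NULL,
                            base_corr = 0.8, noise_sd = 1, seed = 1L) {
  if (n_drivers * module_size > n_genes) {
    abort("n_drivers * module_size must not exceed n_genes")
  }
  if (base_corr <= 0 || base_corr >= 1) abort("`base_corr` must lie in (0, 1)")
  if (n_patients < 4L) abort("need at least 4 patients")
  if (is.null(perturb_patients_per_driver)) {
    tcrit <- qt(0.975, n_patients - 2)
    rcrit <- sqrt(tcrit^2 / (tcrit^2 + n_patients - 2))
    perturb_patients_per_driver <-
      max(1L, min(n_patients, as.integer(ceiling(n_patients * (1 - rcrit / base_corr)))))
  }
  if (perturb_patients_per_driver > n_patients) {
    abort("perturb_patients_per_driver must not exceed n_patients")
  }

  gene_ids <- sprintf("G%03d", seq_len(n_genes))
  patient_ids <- sprintf("P%02d", seq_len(n_patients))

  set.seed(seed)
  X <- matrix(rnorm(n_genes * n_patients), n_genes, n_patients,
              dimnames = list(gene_ids, patient_ids))

  modules <- if (n_drivers > 0) {
    split(seq_len(n_drivers * module_size), rep(seq_len(n_drivers), each = module_size))
  } else list()
  drivers <- vapply(modules, `[`, integer(1), 1L)
  assignments <- list()

  for (d in seq_along(modules)) {
    f <- rnorm(n_patients)
    for (g in modules[[d]]) {
      X[g, ] <- sqrt(base_corr) * f +
        sqrt(1 - base_corr) * noise_sd * rnorm(n_patients)
    }
    pert <- sort(sample(n_patients, perturb_patients_per_driver))
    X[drivers[d], pert] <- rnorm(length(pert))
    assignments[[d]] <- patient_ids[pert]
  }

  # reference network: within-module edges + equal number of decoys
  within <- if (n_drivers > 0) {
    dplyr::bind_rows(lapply(modules, function(mod) {
      cmb <- combn(gene_ids[mod], 2L)
      tibble(gene_i = cmb[1, ], gene_j = cmb[2, ])
    }))
  } else tibble(gene_i = character(), gene_j = character())
  within <- canonical_edges(within)
  n_decoys <- if (nrow(within) > 0) nrow(within) else 30L
  module_genes <- gene_ids[unlist(modules)]
  background <- setdiff(gene_ids, module_genes)
  decoys <- tibble(gene_i = character(), gene_j = character())
  if (length(background) >= 2L) {
    seen <- character(0)
    while (length(seen) < n_decoys) {
      cand <- sort(sample(background, 2L))
      key <- paste(cand, collapse = "|")
      if (!key %in% seen) seen <- c(seen, key)
    }
    parts <- strsplit(seen, "|", fixed = TRUE)
    decoys <- tibble(gene_i = vapply(parts, `[[`, character(1), 1L),
                     gene_j = vapply(parts, `[[`, character(1), 2L))
  }
  reference <- canonical_edges(dplyr::bind_rows(within, decoys))

  # mutations: planted (patient, driver) pairs at 0.5, background at 1%
  planted <- if (length(assignments)) {
    dplyr::bind_rows(lapply(seq_along(assignments), function(d) {
      pts <- assignments[[d]]
      keep <- runif(length(pts)) < 0.5
      tibble(patient = pts[keep], gene = gene_ids[drivers[d]])
    }))
  } else tibble(patient = character(), gene = character())
  bg_mask <- matrix(runif(n_genes * n_patients) < 0.01, n_genes, n_patients)
  bg_idx <- which(bg_mask, arr.ind = TRUE)
  background_muts <- tibble(patient = patient_ids[bg_idx[, 2]],
                            gene = gene_ids[bg_idx[, 1]])
  mutations <- dplyr::arrange(
    dplyr::distinct(dplyr::bind_rows(planted, background_muts)),
    .data$patient, .data$gene
  )

  expression <- dplyr::bind_cols(tibble(gene = gene_ids), as_tibble(X))
  truth_assignments <- if (length(assignments)) {
    dplyr::arrange(dplyr::bind_rows(lapply(seq_along(assignments), function(d) {
      tibble(patient = assignments[[d]], gene = gene_ids[drivers[d]])
    })), .data$patient, .data$gene)
  } else tibble(patient = character(), gene = character())

  structure(
    list(
      expression = expression,
      reference = reference,
      truth_drivers = tibble(gene = gene_ids[drivers], source = "truth"),
      truth_assignments = truth_assignments,
      mutations = mutations,
      config = list(n_genes = n_genes, n_patients = n_patients,
                    n_drivers = n_drivers, module_size = module_size,
                    perturb_patients_per_driver = perturb_patients_per_driver,
                    base_corr = base_corr, noise_sd = noise_sd, seed = seed)
    ),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cfg <- x$config
  cat("Synthetic cohort: ", cfg$n_genes, " genes x ", cfg$n_patients,
      " patients, ", cfg$n_drivers, " planted driver(s), seed ", cfg$seed,
      "\n", sep = "")
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Writes `expression.tsv`, `reference.tsv`, `truth_drivers.txt`,
#' `truth_assignments.tsv` and `mutations.tsv` under `dir`.
#'
#' @param cohort A `synthetic_cohort` object.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression(cohort$expression, file.path(dir, "expression.tsv"))
  write_network(cohort$reference, file.path(dir, "reference.tsv"))
  writeLines(cohort$truth_drivers$gene, file.path(dir, "truth_drivers.txt"))
  readr::write_tsv(cohort$truth_assignments,
                   file.path(dir, "truth_assignments.tsv"), progress = FALSE)
  readr::write_tsv(cohort$mutations, file.path(dir, "mutations.tsv"),
                   progress = FALSE)
  invisible(dir)
}
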