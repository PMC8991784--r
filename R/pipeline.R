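# End-to-end pipeline: cohort -> sharing graph -> size-constrained
# communities -> patient allocation -> network profiles and correlations.

#' Run the full network-construction pipeline on a claims bundle
#'
#' Executes the five construction steps in order: cohort definition
#' (specialty, diagnosis-group and billing-type filters), shared-patient
#' counting and edge thresholding, iterative size-constrained community
#' detection, allocation of patients to their usual provider network, and
#' the per-network profile and Spearman correlation stage (the correlation
#' matrix is computed when at least four networks are retained).
#'
#' @param bundle a [claims_bundle()].
#' @param config a [pipeline_config()].
#' @param seed integer seed for the community detection stage (defaults to
#'   the config seed).
#' @param verbose log stage-level row counts.
#' @return an object of class `claims_pipeline`: list with `cohort`,
#'   `shared_counts`, `panel`, `graph`, `partition`, `allocation`,
#'   `profiles`, `spearman` (or `NULL`), and the `config`.
#' @export
run_pipeline <- function(bundle, config = pipeline_config(),
                         seed = config$seed, verbose = FALSE) {
  cohort <- build_cohort(bundle, config)
  if (verbose)
    message(sprintf("cohort: %d physicians, %d patients, %d consultations",
                    length(cohort$included_physicians),
                    length(cohort$included_patients),
                    nrow(cohort$qualifying_consultations)))
  shared <- count_shared_patients(cohort$qualifying_consultations)
  panel <- panel_sizes(cohort$qualifying_consultations)
  graph <- build_graph(shared, panel, config, verbose = verbose)
  if (verbose) print(graph)
  partition <- iterative_split(graph, config, seed = seed, verbose = verbose)
  if (verbose) print(partition)
  if (length(partition$networks) == 0) {
    warning("pipeline ended with no retained network; allocation and profiles skipped",
            call. = FALSE)
    return(structure(list(cohort = cohort, shared_counts = shared,
                          panel = panel, graph = graph, partition = partition,
                          allocation = NULL, profiles = NULL, spearman = NULL,
                          config = config),
                     class = "claims_pipeline"))
  }
  allocation <- allocate_patients(cohort, partition, config, verbose = verbose)
  profiles <- build_profiles(partition, allocation, cohort, graph,
                             bundle$physicians, config)
  spearman <- if (nrow(profiles) >= 4) spearman_matrix(profiles) else NULL
  structure(
    list(cohort = cohort, shared_counts = shared, panel = panel,
         graph = graph, partition = partition, allocation = allocation,
         profiles = profiles, spearman = spearman, config = config),
    class = "claims_pipeline"
  )
}

#' @export
print.claims_pipeline <- function(x, ...) {
  cat("<claims_pipeline>\n")
  cat(sprintf("  cohort: %d physicians, %d patients\n",
              length(x$cohort$included_physicians),
              length(x$cohort$included_patients)))
  cat(sprintf("  sharing graph: %d vertices, %d edges\n",
              length(x$graph$vertices), nrow(x$graph$edges)))
  cat(sprintf("  networks: %d (sizes %s); discarded physicians: %d\n",
              length(x$partition$networks),
              if (length(x$partition$networks))
                paste0(min(lengths(x$partition$networks)), "-",
                       max(lengths(x$partition$networks))) else "-",
              length(x$partition$discarded)))
  if (!is.null(x$allocation)) {
    n_alloc <- sum(!is.na(x$allocation$allocated_network_id))
    cat(sprintf("  allocated patients: %d of %d (%.1f%%)\n", n_alloc,
                nrow(x$allocation), 100 * n_alloc / nrow(x$allocation)))
  }
  invisible(x)
}

#' Write every pipeline product as CSV files
#'
#' Writes the stage outputs in plain CSV: the cohort tables, `edges.csv` and
#' `panels.csv`, `networks.csv` / `discarded.csv` / `trace.csv`,
#' `allocation.csv`, `profiles.csv`, `spearman.csv` and
#' `central_physicians.csv`.
#'
#' @param result a `claims_pipeline` from [run_pipeline()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_pipeline_outputs <- function(result, dir) {
  stopifnot(inherits(result, "claims_pipeline"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fwrite(data.table(physician_id = result$cohort$included_physicians),
         file.path(dir, "included_physicians.csv"))
  fwrite(result$cohort$patient_groups, file.path(dir, "patient_groups.csv"))
  fwrite(result$cohort$qualifying_consultations,
         file.path(dir, "qualifying_consultations.csv"), dateTimeAs = "ISO")
  fwrite(result$shared_counts, file.path(dir, "edges_candidate.csv"))
  fwrite(result$graph$edges, file.path(dir, "edges.csv"))
  fwrite(result$panel, file.path(dir, "panels.csv"))
  fwrite(result$partition$assignment, file.path(dir, "networks.csv"))
  fwrite(data.table(physician_id = result$partition$discarded),
         file.path(dir, "discarded.csv"))
  fwrite(result$partition$modularity_trace, file.path(dir, "trace.csv"))
  if (!is.null(result$allocation))
    fwrite(result$allocation, file.path(dir, "allocation.csv"))
  if (!is.null(result$profiles)) {
    fwrite(result$profiles, file.path(dir, "profiles.csv"))
    cp <- central_physicians(result$partition, result$graph, top = 3L)
    fwrite(cp, file.path(dir, "central_physicians.csv"))
  }
  if (!is.null(result$spearman))
    fwrite(result$spearman$table, file.path(dir, "spearman.csv"))
  invisible(dir)
}

#' Share of allocated patients per diagnosis group
#'
#' For each retained network (and overall), the share of its allocated
#' patients carrying each of the 14 diagnosis groups.
#'
#' @param allocation an `allocation_table`.
#' @param cohort a `cohort_bundle`.
#' @return data.table (`network_id`, `group_id`, `n`, `share` of the
#'   network's allocated patients).
#' @export
diagnosis_mix <- function(allocation, cohort) {
  alloc <- as.data.table(allocation)[!is.na(allocated_network_id),
                                     .(patient_id, network_id = allocated_network_id)]
  pg <- merge(cohort$patient_groups, alloc, by = "patient_id")
  npat <- alloc[, .(n_alloc = .N), by = network_id]
  out <- pg[, .(n = uniqueN(patient_id)), by = .(network_id, group_id)]
  out <- merge(out, npat, by = "network_id")
  out[, share := n / n_alloc]
  out[, n_alloc := NULL]
  setorder(out, network_id, group_id)
  out[]
}
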