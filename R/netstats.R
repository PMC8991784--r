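# Per-network characteristics and graph statistics, central physicians,
# specialty composition and the Spearman correlation matrix.

#' Network-level degree centrality (edges per vertex)
#'
#' Defined, at the network level, as the ratio of the number of edges to the
#' number of vertices of the network's induced subgraph.
#'
#' @param n_edges,n_vertices counts of the induced intra-network subgraph.
#' @return scalar `E/V`.
#' @export
degree_centrality <- function(n_edges, n_vertices) {
  stopifnot(n_vertices >= 1)
  n_edges / n_vertices
}

#' Edge density of a network subgraph
#'
#' Number of existing edges divided by the number of possible edges
#' `V(V-1)/2`; undefined (returned as `NA` with a warning) for fewer than
#' two vertices.
#'
#' @param n_edges,n_vertices counts of the induced intra-network subgraph.
#' @return scalar in `[0, 1]`, or `NA`.
#' @export
edge_density <- function(n_edges, n_vertices) {
  if (n_vertices < 2) {
    warning("edge density undefined for fewer than 2 vertices", call. = FALSE)
    return(NA_real_)
  }
  n_edges / (n_vertices * (n_vertices - 1) / 2)
}

#' Global clustering coefficient (transitivity) of a network subgraph
#'
#' `3 x triangles / connected triples`, computed on the unweighted subgraph.
#' Returns `NA` with a warning when the subgraph has no connected triple.
#'
#' @param edges data.table of intra-network edges (`phys_a`, `phys_b`).
#' @param vertices vertex ids of the subgraph.
#' @return scalar in `[0, 1]`, or `NA`.
#' @export
transitivity_coefficient <- function(edges, vertices) {
  edges <- as.data.table(edges)
  if (length(vertices) < 3 || nrow(edges) == 0) {
    warning("transitivity undefined: no connected triples", call. = FALSE)
    return(NA_real_)
  }
  if (!"weight" %in% names(edges)) edges[, weight := 1]
  g <- .as_igraph(edges[, .(phys_a, phys_b, weight)], vertices)
  tr <- igraph::transitivity(g, type = "global")
  if (is.nan(tr)) {
    warning("transitivity undefined: no connected triples", call. = FALSE)
    return(NA_real_)
  }
  tr
}

#' Per-network characteristics and statistics
#'
#' One profile row per retained network: member and allocated-patient counts,
#' specialty and practice diversity, the patient-averaged proportions of
#' physicians and of treatment days inside the network, and the graph
#' statistics (degree centrality `E/V`, edge density, transitivity, mean
#' shared patients per connected pair, mean degree `2E/V`).
#'
#' @param partition a `network_partition` from [iterative_split()].
#' @param allocation an `allocation_table` from [allocate_patients()].
#' @param cohort a `cohort_bundle` from [build_cohort()].
#' @param graph the `sharing_graph` the partition was computed on.
#' @param physicians the physician table of the original bundle (for
#'   specialty and practice lookups).
#' @param config a [pipeline_config()].
#' @return data.table with one row per network, class `network_profiles`.
#' @export
build_profiles <- function(partition, allocation, cohort, graph, physicians,
                           config = pipeline_config()) {
  stopifnot(inherits(partition, "network_partition"))
  assignment <- partition$assignment
  ph <- as.data.table(physicians)[, .(physician_id, specialty_code, practice_id)]
  memb <- merge(assignment, ph, by = "physician_id", all.x = TRUE)

  ## graph statistics on induced subgraphs
  edges <- as.data.table(graph$edges)
  net_of <- setNames(assignment$network_id, assignment$physician_id)
  edges[, `:=`(na = net_of[phys_a], nb = net_of[phys_b])]
  intra <- edges[!is.na(na) & na == nb]

  gstats <- rbindlist(lapply(names(partition$networks), function(nid) {
    members <- partition$networks[[nid]]
    V <- length(members)
    e <- intra[na == nid]
    E <- nrow(e)
    tr <- if (V >= 3 && E > 0)
      suppressWarnings(transitivity_coefficient(e[, .(phys_a, phys_b, weight)],
                                                members))
    else NA_real_
    data.table(
      network_id = nid,
      n_physicians = V,
      n_edges = E,
      degree_centrality = degree_centrality(E, V),
      density = suppressWarnings(edge_density(E, V)),
      transitivity = tr,
      mean_shared_per_edge = if (E > 0) mean(e$weight) else NA_real_,
      mean_degree = 2 * E / V
    )
  }))

  ## composition
  comp <- memb[, .(
    n_specialties = uniqueN(specialty_code),
    n_practices = uniqueN(practice_id),
    mean_physicians_per_practice = .N / uniqueN(practice_id)
  ), by = network_id]

  ## patient-averaged within-network proportions over allocated patients
  alloc <- as.data.table(allocation)[!is.na(allocated_network_id)]
  co <- cohort$qualifying_consultations[patient_id %in% alloc$patient_id]
  units <- unique(co[, .(patient_id, physician_id, service_date)])
  units <- merge(units, assignment, by = "physician_id", all.x = TRUE)
  units <- merge(units, alloc[, .(patient_id, allocated_network_id)],
                 by = "patient_id")
  units[, keep := !is.na(network_id) & network_id == allocated_network_id]
  per_pat <- units[, .(
    prop_visits = mean(keep),
    prop_physicians = uniqueN(physician_id[keep]) / uniqueN(physician_id),
    allocated_network_id = allocated_network_id[1L]
  ), by = patient_id]
  within <- per_pat[, .(
    n_patients = .N,
    prop_physicians_within = mean(prop_physicians),
    prop_visits_within = mean(prop_visits)
  ), by = .(network_id = allocated_network_id)]

  out <- Reduce(function(a, b) merge(a, b, by = "network_id", all.x = TRUE),
                list(gstats, comp, within))
  out[is.na(n_patients), n_patients := 0L]
  setcolorder(out, c("network_id", "n_physicians", "n_patients",
                     "n_specialties", "n_practices",
                     "mean_physicians_per_practice",
                     "prop_physicians_within", "prop_visits_within",
                     "degree_centrality", "density", "transitivity",
                     "n_edges", "mean_shared_per_edge", "mean_degree"))
  setorder(out, network_id)
  structure(out, class = c("network_profiles", class(out)))
}

#' Specialty composition per network
#'
#' @param partition a `network_partition`.
#' @param physicians the physician table.
#' @return data.table (`network_id`, `specialty_code`, `n`, `share`); shares
#'   sum to 1 within each network.
#' @export
specialty_composition <- function(partition, physicians) {
  memb <- merge(partition$assignment,
                as.data.table(physicians)[, .(physician_id, specialty_code)],
                by = "physician_id", all.x = TRUE)
  out <- memb[, .(n = .N), by = .(network_id, specialty_code)]
  out[, share := n / sum(n), by = network_id]
  setorder(out, network_id, -n, specialty_code)
  out[]
}

#' Central physicians per network
#'
#' Ranks each network's members by their number of connections to other
#' members of the same network (intra-network degree); ties are broken by
#' physician id.
#'
#' @param partition a `network_partition`.
#' @param graph the `sharing_graph` the partition was computed on.
#' @param top keep the `top` most central physicians per network (default 1;
#'   `Inf` keeps all).
#' @return data.table (`network_id`, `physician_id`, `degree`, `rank_order`).
#' @export
central_physicians <- function(partition, graph, top = 1L) {
  assignment <- partition$assignment
  net_of <- setNames(assignment$network_id, assignment$physician_id)
  edges <- as.data.table(graph$edges)
  edges[, `:=`(na = net_of[phys_a], nb = net_of[phys_b])]
  intra <- edges[!is.na(na) & na == nb]
  deg <- rbindlist(list(
    intra[, .(physician_id = phys_a, network_id = na)],
    intra[, .(physician_id = phys_b, network_id = nb)]
  ))[, .(degree = .N), by = .(network_id, physician_id)]
  # members with no intra-network edge have degree 0
  all_members <- assignment[, .(physician_id, network_id)]
  deg <- merge(all_members, deg, by = c("network_id", "physician_id"),
               all.x = TRUE)
  deg[is.na(degree), degree := 0L]
  setorder(deg, network_id, -degree, physician_id)
  deg[, rank_order := seq_len(.N), by = network_id]
  out <- deg[rank_order <= top]
  out[]
}

#' Spearman rank correlation matrix over network profiles
#'
#' Pairwise Spearman correlations (average ranks on ties, pairwise deletion
#' of missing values) between profile columns, with p-values from the
#' t-distribution approximation `t = rho * sqrt((n-2)/(1-rho^2))`. Constant
#' columns yield `NA` correlations.
#'
#' @param profiles a `network_profiles` table (or any data.frame).
#' @param columns profile columns to correlate; the default is the ten
#'   characteristics of the published correlation table.
#' @return list with `rho` and `p` matrices and `table` (long-format
#'   data.table `var_a`, `var_b`, `rho`, `p_value`, `n`).
#' @export
spearman_matrix <- function(profiles,
                            columns = c("n_physicians", "n_patients",
                                        "n_specialties", "n_practices",
                                        "mean_physicians_per_practice",
                                        "prop_physicians_within",
                                        "prop_visits_within",
                                        "degree_centrality", "density",
                                        "transitivity")) {
  df <- as.data.table(profiles)
  miss <- setdiff(columns, names(df))
  if (length(miss))
    stop(sprintf("profiles lack column(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  x <- as.matrix(df[, ..columns])
  if (nrow(x) < 4)
    stop("need at least 4 networks for a correlation matrix", call. = FALSE)
  rho <- suppressWarnings(cor(x, method = "spearman", use = "pairwise.complete.obs"))
  k <- length(columns)
  nmat <- matrix(0L, k, k, dimnames = dimnames(rho))
  for (i in seq_len(k)) for (j in seq_len(k))
    nmat[i, j] <- sum(complete.cases(x[, c(i, j)]))
  tt <- rho * sqrt((nmat - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * pt(abs(tt), df = nmat - 2, lower.tail = FALSE)
  diag(p) <- 0
  long <- data.table(
    var_a = rep(columns, each = k),
    var_b = rep(columns, times = k),
    rho = as.vector(t(rho)),
    p_value = as.vector(t(p)),
    n = as.vector(t(nmat))
  )[match(var_a, columns) < match(var_b, columns)]
  list(rho = rho, p = p, table = long)
}
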