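# Independent oracles and fixture builders used across the suite. These are
# deliberately naive (brute-force set intersections, O(V^3) triple counting,
# full set-partition enumeration) so they share no code path with the
# package implementation they check.

library(data.table)

# --- brute-force shared-patient counts: pairwise panel intersections --------
brute_shared_counts <- function(consultations) {
  panels <- tapply(consultations$patient_id, consultations$physician_id,
                   function(x) unique(x))
  ids <- sort(names(panels))
  out <- list()
  if (length(ids) >= 2) {
    for (i in seq_along(ids)[-length(ids)]) {
      for (j in (i + 1):length(ids)) {
        n <- length(intersect(panels[[ids[i]]], panels[[ids[j]]]))
        if (n > 0)
          out[[length(out) + 1]] <- data.table(
            phys_a = ids[i], phys_b = ids[j], shared_patients = n)
      }
    }
  }
  if (length(out)) rbindlist(out)[order(phys_a, phys_b)]
  else data.table(phys_a = character(0), phys_b = character(0),
                  shared_patients = integer(0))
}

# --- O(V^3) transitivity: enumerate all vertex triples ----------------------
brute_transitivity <- function(edges, vertices) {
  n <- length(vertices)
  A <- matrix(0L, n, n, dimnames = list(vertices, vertices))
  for (r in seq_len(nrow(edges))) {
    A[edges$phys_a[r], edges$phys_b[r]] <- 1L
    A[edges$phys_b[r], edges$phys_a[r]] <- 1L
  }
  triangles <- 0L
  triples <- 0L
  if (n >= 3) {
    for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
      e <- A[i, j] + A[i, k] + A[j, k]
      if (e == 3L) triangles <- triangles + 1L
      # connected triples centred at each vertex with two incident edges
    }
  }
  # count connected triples (paths of length 2) per centre vertex: choose 2
  # neighbours
  deg <- rowSums(A)
  triples <- sum(choose(deg, 2))
  if (triples == 0) return(NA_real_)
  3 * triangles / triples
}

# --- Spearman oracle: rank (average ties) then Pearson ----------------------
spearman_oracle <- function(x, y) {
  keep <- stats::complete.cases(x, y)
  stats::cor(rank(x[keep]), rank(y[keep]), method = "pearson")
}

# --- exhaustive modularity: enumerate every set partition -------------------
# restricted-growth-string enumeration of all partitions of n elements
all_partitions <- function(n) {
  out <- list()
  rec <- function(labels, mx) {
    i <- length(labels) + 1L
    if (i > n) { out[[length(out) + 1L]] <<- labels; return(invisible(NULL)) }
    for (lab in seq_len(mx + 1L)) rec(c(labels, lab), max(mx, lab))
    invisible(NULL)
  }
  rec(integer(0), 0L)
  out
}

# modularity from the adjacency matrix, summed over ordered vertex pairs:
# Q = (1/2m) * sum_ij (A_ij - k_i k_j / 2m) [c_i == c_j]
matrix_modularity <- function(A, labels) {
  two_m <- sum(A)
  k <- rowSums(A)
  B <- A - outer(k, k) / two_m
  same <- outer(labels, labels, `==`)
  sum(B[same]) / two_m
}

# global optimum of modularity over all partitions of the vertex set
exhaustive_best_modularity <- function(edges, vertices) {
  n <- length(vertices)
  A <- matrix(0, n, n, dimnames = list(vertices, vertices))
  for (r in seq_len(nrow(edges))) {
    w <- if ("weight" %in% names(edges)) edges$weight[r] else 1
    A[edges$phys_a[r], edges$phys_b[r]] <- A[edges$phys_a[r], edges$phys_b[r]] + w
    A[edges$phys_b[r], edges$phys_a[r]] <- A[edges$phys_b[r], edges$phys_a[r]] + w
  }
  best <- -Inf
  best_labels <- NULL
  for (p in all_partitions(n)) {
    q <- matrix_modularity(A, p)
    if (q > best) { best <- q; best_labels <- p }
  }
  list(q = best, labels = stats::setNames(best_labels, vertices))
}

# --- graph fixture builders -------------------------------------------------
# a sharing_graph object built directly from an edge table, bypassing the
# thresholding stage (for community/statistics unit tests)
sg_fixture <- function(edges, vertices = NULL) {
  edges <- as.data.table(edges)
  if (!"weight" %in% names(edges)) edges[, weight := 1]
  if (is.null(vertices))
    vertices <- sort(unique(c(edges$phys_a, edges$phys_b)))
  structure(
    list(edges = edges, vertices = vertices,
         panel = stats::setNames(rep(NA_integer_, length(vertices)), vertices),
         isolated = setdiff(vertices, unique(c(edges$phys_a, edges$phys_b))),
         min_shared_patients = NA_integer_, min_relative_share = NA_real_),
    class = "sharing_graph")
}

# complete graph (clique) edge table on the given vertex ids
clique_edges <- function(ids, weight = 1) {
  cmb <- t(utils::combn(sort(ids), 2))
  data.table(phys_a = cmb[, 1], phys_b = cmb[, 2], weight = weight)
}

# Erdos-Renyi style random edge table over n vertices
random_edges <- function(n, p = 0.4, weighted = FALSE, prefix = "v") {
  ids <- sprintf("%s%02d", prefix, seq_len(n))
  cmb <- t(utils::combn(ids, 2))
  keep <- stats::runif(nrow(cmb)) < p
  e <- data.table(phys_a = cmb[keep, 1], phys_b = cmb[keep, 2])
  e[, weight := if (weighted) sample(1:9, .N, replace = TRUE) else 1]
  e
}

adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)

# --- a tiny hand-written claims bundle --------------------------------------
tiny_bundle <- function() {
  physicians <- data.table(
    physician_id = c("d1", "d2", "d3", "d4"),
    specialty_code = c("gp", "gp", "cardiology", "radiology"),
    practice_id = c("pr1", "pr1", "pr2", "pr3"),
    region_code = "R1")
  patients <- data.table(
    patient_id = c("p1", "p2", "p3", "p4"),
    birth_year = c(1950L, 1960L, 1990L, 2010L),
    gender = c("F", "M", "F", "F"),
    dialysis = c(FALSE, FALSE, FALSE, FALSE))
  consultations <- data.table(
    patient_id   = c("p1", "p1", "p2", "p2", "p3", "p4"),
    physician_id = c("d1", "d2", "d1", "d3", "d2", "d1"),
    service_date = as.Date(c("2016-01-10", "2016-02-11", "2016-03-12",
                             "2016-04-13", "2016-05-14", "2016-06-15")),
    billing_type_code = c("office_visit", "office_visit", "office_visit",
                          "office_visit", "office_visit", "office_visit"))
  diagnoses <- data.table(
    patient_id = c("p1", "p1", "p2", "p3", "p4"),
    icd10_code = c("I10", "I10.0", "K52", "E11", "J06"),
    quarter    = c(1L, 3L, 2L, 1L, 2L),
    qualifier  = c("confirmed", "confirmed", "confirmed", "confirmed",
                   "confirmed"))
  claims_bundle(physicians, patients, consultations, diagnoses,
                observation_year = 2016L)
}

# a network_partition object built directly from a list of member vectors
partition_fixture <- function(networks) {
  ids <- names(networks)
  assignment <- data.table(
    physician_id = unlist(networks, use.names = FALSE),
    network_id = rep.int(ids, lengths(networks)))
  data.table::setorder(assignment, physician_id)
  structure(list(assignment = assignment,
                 networks = lapply(networks, sort),
                 discarded = character(0),
                 oversized_terminal = character(0),
                 modularity_trace = data.table()),
            class = "network_partition")
}

# consultation rows from (patient, physician, date) triples
visits <- function(patient_id, physician_id, date) {
  data.table(patient_id = patient_id, physician_id = physician_id,
             service_date = as.Date(date), billing_type_code = "office_visit")
}
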