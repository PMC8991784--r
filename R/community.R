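# Size-constrained community detection: weighted Newman-Girvan modularity,
# multilevel (Louvain) partitioning, and iterative splitting until every
# community fits the configured size band.

.membership_vector <- function(partition, vertices) {
  if (is.null(names(partition))) {
    if (length(partition) != length(vertices))
      stop("partition must be named or cover all vertices in order", call. = FALSE)
    partition <- setNames(partition, vertices)
  }
  miss <- setdiff(vertices, names(partition))
  if (length(miss))
    stop(sprintf("partition does not cover vertex/vertices: %s%s",
                 paste(head(miss, 5), collapse = ", "),
                 if (length(miss) > 5) ", ..." else ""), call. = FALSE)
  partition[vertices]
}

#' Weighted Newman-Girvan modularity of a partition
#'
#' Computes `Q = (1/2m) * sum_ij (w_ij - k_i k_j / 2m) * delta(c_i, c_j)`
#' with `k_i` the weighted degree, `m` the total edge weight and the sum over
#' ordered vertex pairs; equivalently `sum_c (e_c/m - (k_c/2m)^2)` over
#' communities, with `e_c` the intra-community edge weight. `Q` lies in
#' `[-0.5, 1)`; the one-community partition always scores 0.
#'
#' @param graph a `sharing_graph` (see [build_graph()]) or a data.table of
#'   edges (`phys_a`, `phys_b`, `weight`).
#' @param partition named vector mapping vertex id to community label; must
#'   cover every vertex of the graph.
#' @param vertices vertex ids; defaults to the graph's vertex set.
#' @return scalar modularity.
#' @export
modularity_q <- function(graph, partition, vertices = NULL) {
  if (inherits(graph, "sharing_graph")) {
    edges <- graph$edges
    if (is.null(vertices)) vertices <- graph$vertices
  } else {
    edges <- as.data.table(graph)
    if (is.null(vertices))
      vertices <- sort(unique(c(edges$phys_a, edges$phys_b, names(partition))))
  }
  m <- sum(edges$weight)
  if (!is.finite(m) || m <= 0)
    stop("modularity is undefined on a graph with zero total edge weight",
         call. = FALSE)
  memb <- .membership_vector(partition, vertices)
  same <- memb[edges$phys_a] == memb[edges$phys_b]
  e_in <- sum(edges$weight[same])
  deg <- tapply(c(edges$weight, edges$weight),
                c(edges$phys_a, edges$phys_b), sum)
  k_c <- tapply(deg, memb[names(deg)], sum)
  e_in / m - sum((k_c / (2 * m))^2)
}

#' Multilevel (Louvain) modularity-maximising partition
#'
#' One full multilevel run: repeated local-moving passes followed by graph
#' aggregation until no pass improves modularity, as implemented by
#' [igraph::cluster_louvain()] on the weighted sharing graph. Deterministic
#' under a fixed seed. On a graph without any edge the partition is returned
#' as singleton labels with a warning (modularity is undefined there).
#'
#' @param graph a `sharing_graph` or edge data.table.
#' @param seed integer seed for the seeded vertex ordering.
#' @param vertices vertex ids; defaults to the graph's vertex set.
#' @return named integer vector: vertex id -> community label (1-based).
#' @export
multilevel_partition <- function(graph, seed = 1L, vertices = NULL) {
  if (inherits(graph, "sharing_graph")) {
    edges <- graph$edges
    if (is.null(vertices)) vertices <- graph$vertices
  } else {
    edges <- as.data.table(graph)
    if (is.null(vertices)) vertices <- sort(unique(c(edges$phys_a, edges$phys_b)))
  }
  if (length(vertices) == 0) stop("graph has no vertices", call. = FALSE)
  if (nrow(edges) == 0) {
    warning("graph has no edges: returning singleton communities (modularity undefined)",
            call. = FALSE)
    return(setNames(seq_along(vertices), vertices))
  }
  g <- .as_igraph(edges, vertices)
  set.seed(seed)
  cl <- igraph::cluster_louvain(g, weights = igraph::E(g)$weight)
  setNames(as.integer(igraph::membership(cl)), igraph::V(g)$name)
}

#' Iteratively split communities to the configured size band
#'
#' Runs the multilevel algorithm on the full sharing graph, then recursively
#' re-applies it to the induced subgraph (intra-community edges at original
#' weights) of every community larger than `max_network_size`, until all
#' communities fit the band or cannot be split further. A community the
#' algorithm returns unchanged is terminal and retained even if oversized,
#' with a flag. Only after the recursion converges are communities smaller
#' than `min_network_size` moved to `discarded`, so that small fragments of
#' an oversized community are not lost before that community's own recursion
#' completes.
#'
#' @param graph a `sharing_graph` from [build_graph()].
#' @param config a [pipeline_config()].
#' @param seed integer seed; each recursion level derives its own sub-seed
#'   deterministically.
#' @param verbose log each recursion step.
#' @return an object of class `network_partition`: list with `assignment`
#'   (data.table `physician_id`, `network_id`), `networks` (named list of
#'   member vectors), `discarded` (character vector), `oversized_terminal`
#'   (network ids retained above the band), and `modularity_trace`
#'   (data.table, one row per multilevel run).
#' @export
iterative_split <- function(graph, config = pipeline_config(),
                            seed = config$seed, verbose = FALSE) {
  stopifnot(inherits(graph, "sharing_graph"))
  edges <- graph$edges
  vertices <- graph$vertices
  if (length(vertices) == 0) stop("graph has no vertices", call. = FALSE)

  trace <- list()
  final <- list()       # list of list(members, oversized_flag)
  run_id <- 0L

  run_multilevel <- function(sub_edges, sub_vertices, depth) {
    run_id <<- run_id + 1L
    sub_seed <- (seed + 7919L * run_id) %% .Machine$integer.max
    if (nrow(sub_edges) == 0) {
      memb <- setNames(seq_along(sub_vertices), sub_vertices)
      q_after <- NA_real_
    } else {
      memb <- suppressWarnings(
        multilevel_partition(sub_edges, seed = sub_seed, vertices = sub_vertices))
      q_after <- modularity_q(sub_edges, memb, vertices = sub_vertices)
    }
    sizes <- table(memb)
    trace[[length(trace) + 1L]] <<- data.table(
      run = run_id, depth = depth, n_vertices = length(sub_vertices),
      n_edges = nrow(sub_edges), n_communities = length(sizes),
      q = q_after,
      sizes = paste(sort(as.integer(sizes), decreasing = TRUE), collapse = "/"))
    memb
  }

  process <- function(sub_vertices, depth) {
    sub_edges <- edges[phys_a %in% sub_vertices & phys_b %in% sub_vertices]
    memb <- run_multilevel(sub_edges, sub_vertices, depth)
    comms <- split(names(memb), memb)
    if (length(comms) == 1L ||
        max(lengths(comms)) == length(sub_vertices)) {
      # no size-reducing split: terminal community
      final[[length(final) + 1L]] <<- list(
        members = sub_vertices,
        oversized = length(sub_vertices) > config$max_network_size)
      if (verbose && length(sub_vertices) > config$max_network_size)
        message(sprintf("terminal oversized community of %d physicians (depth %d)",
                        length(sub_vertices), depth))
      return(invisible(NULL))
    }
    for (cm in comms) {
      if (length(cm) > config$max_network_size) {
        process(cm, depth + 1L)
      } else {
        final[[length(final) + 1L]] <<- list(members = cm, oversized = FALSE)
      }
    }
    invisible(NULL)
  }

  process(vertices, depth = 0L)

  sizes <- vapply(final, function(x) length(x$members), integer(1))
  keep <- sizes >= config$min_network_size
  discarded <- sort(unlist(lapply(final[!keep], `[[`, "members"), use.names = FALSE))
  if (!any(keep))
    warning("no community reached the minimum network size: empty partition",
            call. = FALSE)
  kept <- final[keep]
  # deterministic network ids: decreasing size, ties by smallest member id
  min_ids <- vapply(kept, function(x) min(x$members), character(1))
  ord <- order(-sizes[keep], min_ids)
  kept <- kept[ord]
  ids <- sprintf("N%03d", seq_along(kept))
  networks <- setNames(lapply(kept, function(x) sort(x$members)), ids)
  assignment <- if (length(kept)) {
    data.table(
      physician_id = unlist(networks, use.names = FALSE),
      network_id = rep.int(ids, vapply(networks, length, integer(1))))
  } else data.table(physician_id = character(0), network_id = character(0))
  setorder(assignment, physician_id)

  structure(
    list(assignment = assignment,
         networks = networks,
         discarded = if (length(discarded)) discarded else character(0),
         oversized_terminal = ids[vapply(kept, `[[`, logical(1), "oversized")],
         modularity_trace = rbindlist(trace)),
    class = "network_partition"
  )
}

#' @export
print.network_partition <- function(x, ...) {
  szs <- lengths(x$networks)
  cat("<network_partition>\n")
  cat(sprintf("  networks: %d; physicians retained: %d; discarded: %d\n",
              length(x$networks), nrow(x$assignment), length(x$discarded)))
  if (length(szs))
    cat(sprintf("  sizes: min %d, median %.0f, max %d; terminal oversized: %d\n",
                min(szs), stats::median(szs), max(szs),
                length(x$oversized_terminal)))
  invisible(x)
}
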