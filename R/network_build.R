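# Patient-sharing graph: distinct shared cohort patients per physician pair,
# thresholded on an absolute count and a relative panel share.

#' Count distinct shared patients for every physician pair
#'
#' For each unordered pair of physicians, counts the number of distinct
#' patients having at least one qualifying consultation with both. Pairs are
#' enumerated per patient over that patient's distinct physician set (the
#' result is provably identical to comparing every pair of physician panels,
#' but scales with consultations rather than with the square of the
#' physician count). Pairs sharing zero patients are absent.
#'
#' @param consultations qualifying consultation table (`patient_id`,
#'   `physician_id`, ...), already restricted to the cohort.
#' @return data.table (`phys_a`, `phys_b`, `shared_patients`) with
#'   `phys_a < phys_b`.
#' @export
count_shared_patients <- function(consultations) {
  pp <- unique(as.data.table(consultations)[, .(patient_id, physician_id)])
  if (nrow(pp) == 0)
    return(data.table(phys_a = character(0), phys_b = character(0),
                      shared_patients = integer(0)))
  setkeyv(pp, "patient_id")
  pairs <- pp[pp, on = "patient_id", allow.cartesian = TRUE][
    physician_id < i.physician_id]
  if (nrow(pairs) == 0)
    return(data.table(phys_a = character(0), phys_b = character(0),
                      shared_patients = integer(0)))
  out <- pairs[, .(shared_patients = .N),
               by = .(phys_a = physician_id, phys_b = i.physician_id)]
  setorder(out, phys_a, phys_b)
  out[]
}

#' Panel size per physician
#'
#' The panel ("total patient population") of a physician is the number of
#' distinct cohort patients with at least one qualifying consultation during
#' the observation year; it is the denominator of the relative edge
#' threshold.
#'
#' @param consultations qualifying consultation table.
#' @return data.table (`physician_id`, `panel`).
#' @export
panel_sizes <- function(consultations) {
  pp <- unique(as.data.table(consultations)[, .(patient_id, physician_id)])
  out <- pp[, .(panel = .N), by = physician_id]
  setorder(out, physician_id)
  out[]
}

#' Build the thresholded patient-sharing graph
#'
#' Retains the edge between physicians i and j iff the number of distinct
#' shared patients satisfies both conditions: `w_ij >= min_shared_patients`,
#' and `w_ij` amounts to at least `min_relative_share` (inclusive) of the
#' panel of at least one of the two physicians. Physicians present in the
#' panel table but with no retained edge remain as isolated, flagged
#' vertices.
#'
#' @param shared_counts data.table from [count_shared_patients()].
#' @param panel_size data.table from [panel_sizes()], covering every
#'   physician appearing in `shared_counts`.
#' @param config a [pipeline_config()].
#' @param verbose log the number of edges removed by each criterion.
#' @return an object of class `sharing_graph`: list with `edges`
#'   (`phys_a`, `phys_b`, `weight`), `vertices` (character), `panel`
#'   (named integer vector), `isolated` (character vector of flagged
#'   vertices), and the threshold values used.
#' @export
build_graph <- function(shared_counts, panel_size, config = pipeline_config(),
                        verbose = FALSE) {
  sc <- as.data.table(shared_counts)
  ps <- as.data.table(panel_size)
  in_counts <- unique(c(sc$phys_a, sc$phys_b))
  missing <- setdiff(in_counts, ps$physician_id)
  if (length(missing))
    stop(sprintf("panel_size missing for physician(s): %s%s",
                 paste(head(missing, 5), collapse = ", "),
                 if (length(missing) > 5) ", ..." else ""), call. = FALSE)
  panel <- setNames(as.integer(ps$panel), ps$physician_id)

  if (nrow(sc)) {
    w <- sc$shared_patients
    pass_abs <- w >= config$min_shared_patients
    rel_a <- w / panel[sc$phys_a]
    rel_b <- w / panel[sc$phys_b]
    pass_rel <- pmax(rel_a, rel_b) >= config$min_relative_share
    keep <- pass_abs & pass_rel
    if (verbose)
      message(sprintf(
        "edges: %d candidate; %d fail absolute (w < %d), %d fail relative (< %.1f%%); %d retained",
        length(w), sum(!pass_abs), config$min_shared_patients,
        sum(pass_abs & !pass_rel), 100 * config$min_relative_share, sum(keep)))
    edges <- sc[keep, .(phys_a, phys_b, weight = as.numeric(shared_patients))]
  } else {
    edges <- data.table(phys_a = character(0), phys_b = character(0),
                        weight = numeric(0))
  }
  vertices <- sort(ps$physician_id)
  isolated <- setdiff(vertices, unique(c(edges$phys_a, edges$phys_b)))
  structure(
    list(edges = edges, vertices = vertices, panel = panel,
         isolated = isolated,
         min_shared_patients = config$min_shared_patients,
         min_relative_share = config$min_relative_share),
    class = "sharing_graph"
  )
}

#' @export
print.sharing_graph <- function(x, ...) {
  cat("<sharing_graph>\n")
  cat(sprintf("  vertices: %d (%d isolated)\n", length(x$vertices),
              length(x$isolated)))
  cat(sprintf("  edges: %d (w >= %d and relative share >= %.1f%%)\n",
              nrow(x$edges), x$min_shared_patients,
              100 * x$min_relative_share))
  if (nrow(x$edges))
    cat(sprintf("  mean shared patients per edge: %.1f\n", mean(x$edges$weight)))
  invisible(x)
}

# igraph view of a sharing graph (or of an edge subset)
.as_igraph <- function(edges, vertices) {
  g <- igraph::graph_from_data_frame(
    edges[, .(from = phys_a, to = phys_b, weight)],
    directed = FALSE,
    vertices = data.frame(name = vertices, stringsAsFactors = FALSE))
  g
}
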