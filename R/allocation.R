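# Patient allocation: each cohort patient is attributed to the unique "usual
# provider network" receiving a strict majority of their treatment days, or
# left unallocated.

.treatment_day_table <- function(consultations, assignment,
                                 day_granularity = "physician_day") {
  co <- as.data.table(consultations)[, .(patient_id, physician_id, service_date)]
  co <- merge(co, assignment, by = "physician_id", all.x = TRUE)
  if (day_granularity == "physician_day") {
    days <- unique(co[, .(patient_id, physician_id, service_date, network_id)])
  } else {
    # calendar-day granularity: one unit per distinct (patient, date, network)
    days <- unique(co[, .(patient_id, service_date, network_id)])
  }
  days
}

#' Treatment days of one patient, per network
#'
#' A treatment day is a distinct (physician, service date) pair (default) or
#' a distinct calendar date (`day_granularity = "calendar_day"`). Visits to
#' physicians outside every retained network (discarded or isolated) count
#' toward the total but toward no network.
#'
#' @param consultations one patient's qualifying consultations.
#' @param assignment data.table (`physician_id`, `network_id`) from a
#'   [iterative_split()] partition.
#' @param day_granularity `"physician_day"` or `"calendar_day"`.
#' @return list with `per_network` (named integer vector, possibly empty)
#'   and `total` (integer).
#' @export
treatment_days <- function(consultations, assignment,
                           day_granularity = "physician_day") {
  days <- .treatment_day_table(consultations, assignment, day_granularity)
  if (day_granularity == "calendar_day") {
    total <- uniqueN(days[, .(patient_id, service_date)])
  } else {
    total <- nrow(days)
  }
  per <- days[!is.na(network_id), .(days = .N), by = network_id]
  list(per_network = setNames(as.integer(per$days), per$network_id),
       total = as.integer(total))
}

#' Allocate patients to their usual provider network
#'
#' A patient is allocated to the network holding the largest number of their
#' treatment days, but only when that number strictly exceeds
#' `allocation_majority` (default 50%) of all the patient's treatment days —
#' including days spent with physicians outside every retained network. At
#' most one network can hold a strict majority, so no tie-breaking is
#' needed; patients without such a network remain unallocated.
#'
#' @param cohort a `cohort_bundle` from [build_cohort()].
#' @param partition a `network_partition` from [iterative_split()].
#' @param config a [pipeline_config()].
#' @param verbose log allocated/unallocated counts.
#' @return an `allocation_table`: data.table (`patient_id`,
#'   `allocated_network_id` — `NA` when unallocated, `visits_total`,
#'   `visits_in_allocated`, `share`).
#' @export
allocate_patients <- function(cohort, partition, config = pipeline_config(),
                              verbose = FALSE) {
  stopifnot(inherits(cohort, "cohort_bundle"),
            inherits(partition, "network_partition"))
  if (length(partition$networks) == 0)
    stop("partition has no retained networks: nothing to allocate to",
         call. = FALSE)
  co <- cohort$qualifying_consultations
  days <- .treatment_day_table(co, partition$assignment, config$day_granularity)

  if (config$day_granularity == "calendar_day") {
    totals <- unique(days[, .(patient_id, service_date)])[, .(total_days = .N),
                                                          by = patient_id]
  } else {
    totals <- days[, .(total_days = .N), by = patient_id]
  }
  per <- days[!is.na(network_id), .(days = .N), by = .(patient_id, network_id)]
  # best network per patient; ties irrelevant (a strict majority is unique)
  setorder(per, patient_id, -days, network_id)
  best <- per[, .SD[1L], by = patient_id]
  tab <- merge(totals, best, by = "patient_id", all.x = TRUE)
  tab[is.na(days), days := 0L]
  tab[, share := days / total_days]
  tab[, allocated := share > config$allocation_majority]
  out <- tab[, .(
    patient_id,
    allocated_network_id = fifelse(allocated, network_id, NA_character_),
    visits_total = as.integer(total_days),
    visits_in_allocated = fifelse(allocated, as.integer(days), NA_integer_),
    share = fifelse(allocated, share, NA_real_)
  )]
  # patients in the cohort but (defensively) without any consultation row
  missing <- setdiff(cohort$included_patients, out$patient_id)
  if (length(missing)) {
    warning(sprintf("%d cohort patient(s) had no qualifying consultations; left unallocated",
                    length(missing)), call. = FALSE)
    out <- rbind(out, data.table(
      patient_id = missing, allocated_network_id = NA_character_,
      visits_total = 0L, visits_in_allocated = NA_integer_, share = NA_real_))
  }
  setorder(out, patient_id)
  if (verbose)
    message(sprintf("allocated %d of %d patients (%.1f%%)",
                    sum(!is.na(out$allocated_network_id)), nrow(out),
                    100 * mean(!is.na(out$allocated_network_id))))
  structure(out, class = c("allocation_table", class(out)))
}

#' Independently audit an allocation against raw consultations
#'
#' Recomputes, directly from the consultation rows, each allocated patient's
#' within-network share of treatment days and checks it strictly exceeds the
#' configured majority. Intended as a post-hoc consistency check of the
#' allocation stage.
#'
#' @param allocation an `allocation_table` from [allocate_patients()].
#' @param consultations the qualifying consultation table used for it.
#' @param partition the `network_partition` used for it.
#' @param config a [pipeline_config()].
#' @return data.table (`patient_id`, `allocated_network_id`, `share_recount`,
#'   `ok`); attribute `all_ok` summarises the audit.
#' @export
audit_allocation <- function(allocation, consultations, partition,
                             config = pipeline_config()) {
  alloc <- as.data.table(allocation)[!is.na(allocated_network_id),
                                     .(patient_id, allocated_network_id)]
  if (nrow(alloc) == 0) {
    out <- data.table(patient_id = character(0),
                      allocated_network_id = character(0),
                      share_recount = numeric(0), ok = logical(0))
    data.table::setattr(out, "all_ok", TRUE)
    return(out[])
  }
  co <- as.data.table(consultations)[patient_id %in% alloc$patient_id]
  units <- unique(co[, .(patient_id, physician_id, service_date)])
  units <- merge(units, partition$assignment, by = "physician_id", all.x = TRUE)
  units <- merge(units, alloc, by = "patient_id")
  units[, keep := !is.na(network_id) & network_id == allocated_network_id]
  if (config$day_granularity == "calendar_day") {
    tot <- unique(units[, .(patient_id, service_date)])[, .(total_days = .N),
                                                        by = patient_id]
    inn <- unique(units[keep == TRUE,
                        .(patient_id, service_date)])[, .(days = .N),
                                                      by = patient_id]
  } else {
    tot <- units[, .(total_days = .N), by = patient_id]
    inn <- units[keep == TRUE, .(days = .N), by = patient_id]
  }
  out <- merge(merge(alloc, tot, by = "patient_id", all.x = TRUE),
               inn, by = "patient_id", all.x = TRUE)
  out[is.na(days), days := 0L]
  out[, share_recount := fifelse(is.na(total_days) | total_days == 0,
                                 NA_real_, days / total_days)]
  out[, ok := !is.na(share_recount) & share_recount > config$allocation_majority]
  out <- out[, .(patient_id, allocated_network_id, share_recount, ok)]
  setorder(out, patient_id)
  data.table::setattr(out, "all_ok", all(out$ok))
  out[]
}
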