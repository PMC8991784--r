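# Cohort definition: physician specialty filter, ambulatory-care-sensitive
# diagnosis group classification (M1Q/M2Q validation rules), consultation
# billing-type filter.

#' Default catalog of the 14 ambulatory-care-sensitive diagnosis groups
#'
#' Returns the rule table used to classify patients into the 14 diagnosis
#' groups that define the cohort. Each row is one sub-rule: groups 1
#' (ischemic heart diseases) and 4 (bronchitis/COPD) consist of two sub-rules
#' (`1a`/`1b`, `4a`/`4b`) evaluated separately but reported under one merged
#' group id. `frequency_rule` is `M2Q` (diagnosis coded in at least two
#' distinct quarters of the observation year) for chronic conditions and
#' `M1Q` (at least one quarter) for acute ones; `qualifier_rule` states which
#' coding qualifiers count (`confirmed_only`, `confirmed_or_status_post`, or
#' `status_post_only`).
#'
#' @return data.table with columns `rule_id`, `group_id` (1--14), `label`,
#'   `icd_prefixes` (list column of ICD-10 code prefixes), `frequency_rule`,
#'   `qualifier_rule`.
#' @export
default_diagnosis_catalog <- function() {
  expand_range <- function(stem, lo, hi)
    sprintf("%s%02d", stem, lo:hi)
  rules <- list(
    list("1a", 1L, "Ischemic heart diseases", c("I20", "I25"),
         "M2Q", "confirmed_or_status_post"),
    list("1b", 1L, "Ischemic heart diseases", c("I21", "I22", "I23", "I24"),
         "M2Q", "status_post_only"),
    list("2", 2L, "Heart failure", "I50", "M2Q", "confirmed_or_status_post"),
    list("3", 3L, "Other diseases of the circulatory system",
         c("I05", "I06", "I07", "I09", "I08", "I49", "I48", "I67", "I70",
           "I73", "I78", "I80", "I83", "I86", "I87", "I95", "R00", "I42", "I74"),
         "M2Q", "confirmed_or_status_post"),
    list("4a", 4L, "Bronchitis",
         c("J20", "J21", "J22", "J40", "J41", "J42", "J43"),
         "M1Q", "confirmed_only"),
    list("4b", 4L, "COPD", c("J44", "J47"), "M2Q", "confirmed_or_status_post"),
    list("5", 5L, "Mental and behavioral disorders due to the use of alcohol or opioids",
         c("F10", "F11"), "M2Q", "confirmed_or_status_post"),
    list("6", 6L, "Back pain [dorsopathies]",
         c("M42", "M47", "M53", "M54", "M50", "M51"),
         "M2Q", "confirmed_or_status_post"),
    list("7", 7L, "Hypertension", expand_range("I", 10, 15),
         "M2Q", "confirmed_or_status_post"),
    list("8", 8L, "Gastroenteritis and other intestinal diseases",
         c("K52", "K57", "K58", "K59"), "M1Q", "confirmed_only"),
    list("9", 9L, "Intestinal infectious diseases", expand_range("A", 0, 9),
         "M1Q", "confirmed_only"),
    list("10", 10L, "Influenza and pneumonia",
         c("J10", "J11", "J13", "J14", "J15", "J16", "J18", "J12"),
         "M1Q", "confirmed_only"),
    list("11", 11L, "Ear, nose, and throat infections",
         c("H66", "J01", "J02", "J03", "J06", "J31", "J32", "J35", "H65",
           "H73", "J04", "R07.0"),
         "M1Q", "confirmed_only"),
    list("12", 12L, "Depressive disorders", c("F32", "F33"),
         "M2Q", "confirmed_or_status_post"),
    list("13", 13L, "Diabetes mellitus", c("E10", "E11", "E13", "E14", "E16"),
         "M2Q", "confirmed_or_status_post"),
    list("14", 14L, "Gonarthrosis", "M17", "M2Q", "confirmed_or_status_post")
  )
  data.table(
    rule_id        = vapply(rules, `[[`, character(1), 1L),
    group_id       = vapply(rules, `[[`, integer(1), 2L),
    label          = vapply(rules, `[[`, character(1), 3L),
    icd_prefixes   = lapply(rules, `[[`, 4L),
    frequency_rule = vapply(rules, `[[`, character(1), 5L),
    qualifier_rule = vapply(rules, `[[`, character(1), 6L)
  )
}

# long form of the catalog: one row per (rule, prefix), used for joins
.catalog_prefixes <- function(catalog) {
  out <- catalog[, .(icd_prefix = unlist(icd_prefixes)),
                 by = .(rule_id, group_id, frequency_rule, qualifier_rule)]
  out[, prefix_len := nchar(icd_prefix)]
  out
}

.qualifiers_for_rule <- function(rule) {
  switch(rule,
         confirmed_only           = "confirmed",
         confirmed_or_status_post = c("confirmed", "status_post"),
         status_post_only         = "status_post",
         stop(sprintf("unknown qualifier_rule '%s'", rule), call. = FALSE))
}

#' Restrict physicians to included specialties (and regions)
#'
#' Drops physicians whose specialty is on the configured exclusion list —
#' disciplines caring for patients outside the cohort or mainly providing
#' contract services with little direct patient contact. When
#' `allowed_regions` is configured, physicians outside those regions are
#' dropped too.
#'
#' @param bundle a [claims_bundle()].
#' @param config a [pipeline_config()].
#' @return character vector of retained physician ids.
#' @export
filter_physicians <- function(bundle, config) {
  ph <- bundle$physicians
  keep <- !(ph$specialty_code %in% config$excluded_specialties)
  if (!is.null(config$allowed_regions))
    keep <- keep & ph$region_code %in% config$allowed_regions
  out <- ph$physician_id[keep]
  if (length(out) == 0)
    warning("physician filter retained no physicians", call. = FALSE)
  out
}

#' Classify one patient's diagnoses into diagnosis groups
#'
#' A group qualifies if the patient's records matching one of its sub-rules'
#' ICD prefixes and permitted qualifiers occur in at least two distinct
#' quarters (M2Q rules) or at least one quarter (M1Q rules). Prefix matching
#' is at the printed precision: rule code `I10` matches `I10`, `I10.0`,
#' `I10.90`; `R07.0` matches only `R07.0`-prefixed codes.
#'
#' @param diagnoses data.frame of one patient's diagnosis records with
#'   columns `icd10_code`, `quarter`, `qualifier`.
#' @param catalog rule table, see [default_diagnosis_catalog()].
#' @return sorted integer vector of qualifying (merged) group ids.
#' @export
classify_patient <- function(diagnoses, catalog = default_diagnosis_catalog()) {
  dx <- as.data.table(diagnoses)
  if (nrow(dx) == 0) return(integer(0))
  bad <- setdiff(unique(dx$qualifier), .QUALIFIER_LEVELS)
  if (length(bad))
    stop(sprintf("unknown diagnosis qualifier label(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  groups <- integer(0)
  for (r in seq_len(nrow(catalog))) {
    quals <- .qualifiers_for_rule(catalog$qualifier_rule[r])
    prefixes <- catalog$icd_prefixes[[r]]
    hit <- dx$qualifier %in% quals &
      Reduce(`|`, lapply(prefixes, function(p) startsWith(dx$icd10_code, p)))
    need <- if (catalog$frequency_rule[r] == "M2Q") 2L else 1L
    if (uniqueN(dx$quarter[hit]) >= need)
      groups <- c(groups, catalog$group_id[r])
  }
  sort(unique(groups))
}

#' Classify all patients of a bundle into diagnosis groups
#'
#' Vectorised equivalent of [classify_patient()] over the whole diagnosis
#' table.
#'
#' @param diagnoses the diagnosis table of a [claims_bundle()].
#' @param catalog rule table, see [default_diagnosis_catalog()].
#' @return data.table (`patient_id`, `group_id`), one row per qualifying
#'   patient-group pair.
#' @export
classify_patients <- function(diagnoses, catalog = default_diagnosis_catalog()) {
  dx <- as.data.table(diagnoses)
  if (nrow(dx) == 0)
    return(data.table(patient_id = character(0), group_id = integer(0)))
  bad <- setdiff(unique(dx$qualifier), .QUALIFIER_LEVELS)
  if (length(bad))
    stop(sprintf("unknown diagnosis qualifier label(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  pref <- .catalog_prefixes(catalog)
  hits <- vector("list", length(unique(pref$prefix_len)))
  i <- 1L
  for (len in unique(pref$prefix_len)) {
    p <- pref[prefix_len == len]
    d <- dx[, .(patient_id, quarter, qualifier,
                code_cut = substr(icd10_code, 1L, len))]
    h <- d[p, on = .(code_cut = icd_prefix), nomatch = NULL, allow.cartesian = TRUE]
    hits[[i]] <- h[, .(patient_id, quarter, qualifier, rule_id, group_id,
                       frequency_rule, qualifier_rule)]
    i <- i + 1L
  }
  hits <- rbindlist(hits)
  if (nrow(hits) == 0)
    return(data.table(patient_id = character(0), group_id = integer(0)))
  hits <- hits[
    (qualifier_rule == "confirmed_or_status_post" & qualifier %in% c("confirmed", "status_post")) |
    (qualifier_rule == "confirmed_only" & qualifier == "confirmed") |
    (qualifier_rule == "status_post_only" & qualifier == "status_post")
  ]
  byrule <- hits[, .(n_quarters = uniqueN(quarter)),
                 by = .(patient_id, rule_id, group_id, frequency_rule)]
  ok <- byrule[(frequency_rule == "M2Q" & n_quarters >= 2L) |
               (frequency_rule == "M1Q" & n_quarters >= 1L)]
  unique(ok[, .(patient_id, group_id)])[order(patient_id, group_id)]
}

#' Keep qualifying face-to-face consultations
#'
#' Retains consultations whose billing type is not on the exclusion list
#' (laboratory referrals, emergency services, ...) and whose physician and
#' patient are both included.
#'
#' @param bundle a [claims_bundle()].
#' @param included_physicians,included_patients character id vectors.
#' @param config a [pipeline_config()].
#' @return the filtered consultation data.table.
#' @export
filter_consultations <- function(bundle, included_physicians, included_patients,
                                 config) {
  co <- bundle$consultations
  co[!(billing_type_code %in% config$excluded_billing_types) &
       physician_id %in% included_physicians &
       patient_id %in% included_patients]
}

#' Build the analysis cohort (physicians, patients, qualifying consultations)
#'
#' Composes the three cohort filters: physicians restricted to included
#' specialties; patients restricted to adults in at least one of the 14
#' diagnosis groups, excluding dialysis patients; consultations restricted to
#' qualifying billing types between included parties. Patients left without
#' any qualifying consultation are dropped.
#'
#' @param bundle a [claims_bundle()].
#' @param config a [pipeline_config()].
#' @return an object of class `cohort_bundle`: list with
#'   `included_physicians`, `included_patients`, `qualifying_consultations`,
#'   `patient_groups` (data.table `patient_id`, `group_id`) and the config.
#' @export
build_cohort <- function(bundle, config = pipeline_config()) {
  stopifnot(inherits(bundle, "claims_bundle"))
  if (nrow(bundle$diagnoses) == 0)
    stop("bundle has no diagnosis records: cohort would be empty", call. = FALSE)

  phys <- filter_physicians(bundle, config)

  groups <- classify_patients(bundle$diagnoses, config$diagnosis_catalog)
  pats <- unique(groups$patient_id)

  pt <- bundle$patients
  if (config$min_patient_age > 0) {
    ref_year <- if (!is.null(bundle$observation_year)) bundle$observation_year
                else config$observation_year
    adult <- pt$patient_id[!is.na(pt$birth_year) &
                             (ref_year - pt$birth_year) >= config$min_patient_age]
    pats <- intersect(pats, adult)
  }
  if (config$exclude_dialysis && "dialysis" %in% names(pt)) {
    dial <- pt$patient_id[as.logical(pt$dialysis) %in% TRUE]
    pats <- setdiff(pats, dial)
  }

  cons <- filter_consultations(bundle, phys, pats, config)
  pats <- intersect(pats, unique(cons$patient_id))
  cons <- cons[patient_id %in% pats]
  groups <- groups[patient_id %in% pats]

  if (length(pats) == 0)
    warning("cohort is empty after filtering", call. = FALSE)

  structure(
    list(included_physicians = phys,
         included_patients = pats,
         qualifying_consultations = cons,
         patient_groups = groups,
         config = config),
    class = "cohort_bundle"
  )
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat("<cohort_bundle>\n")
  cat(sprintf("  included physicians: %d\n", length(x$included_physicians)))
  cat(sprintf("  included patients:   %d\n", length(x$included_patients)))
  cat(sprintf("  qualifying consultations: %d\n", nrow(x$qualifying_consultations)))
  invisible(x)
}
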