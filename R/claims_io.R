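#' @importFrom data.table data.table as.data.table setcolorder setkeyv copy :=
#'   fwrite fread setnames rbindlist setorder setorderv uniqueN .N .SD fifelse
#' @importFrom stats cor pt rnorm runif rbinom rpois rnbinom setNames
#'   complete.cases uniroot
#' @importFrom utils head modifyList
NULL

# silence R CMD check notes for data.table NSE column names
utils::globalVariables(c(
  ".", "..keep", "patient_id", "physician_id", "specialty_code", "practice_id",
  "region_code", "birth_year", "gender", "dialysis", "service_date",
  "billing_type_code", "icd10_code", "quarter", "qualifier", "group_id",
  "rule_id", "weight", "panel", "network_id", "n_members", "community",
  "home_community", "cohort_flag", "n_quarters", "keep", "share", "days",
  "total_days", "allocated_network_id", "i.physician_id", "phys_a", "phys_b",
  "shared_patients", "rel_a", "rel_b", "n_physicians", "n_patients", "degree",
  "var_a", "var_b", "rho", "p_value", "specialty", "n", "prop", "rank_order",
  "visits_total", "visits_in_allocated", "freq_rule", "qualifier_rule",
  "icd_prefix", "prefix_len", "code_cut", "min_id", "label", "icd_prefixes",
  "frequency_rule", "allocated", "na", "nb", "n_edges", "n_alloc", "ok",
  "prop_physicians", "prop_visits", "share_recount", "n_specialties",
  "n_practices", "..columns", "from", "to"
))

.BUNDLE_SCHEMAS <- list(
  physicians    = c("physician_id", "specialty_code", "practice_id", "region_code"),
  patients      = c("patient_id", "birth_year", "gender"),
  consultations = c("patient_id", "physician_id", "service_date", "billing_type_code"),
  diagnoses     = c("patient_id", "icd10_code", "quarter", "qualifier")
)

.QUALIFIER_LEVELS <- c("confirmed", "status_post", "other")

#' Bundle the four claims tables into a validated container
#'
#' A claims bundle holds the four linked tables every pipeline stage consumes:
#' physicians (with specialty, practice and region), patients (birth year,
#' gender, optional dialysis flag), consultations (one row per billed
#' patient-physician contact) and quarter-resolved diagnoses with a coding
#' qualifier (`confirmed`, `status_post` or `other`).
#'
#' @param physicians data.frame with columns `physician_id`, `specialty_code`,
#'   `practice_id`, `region_code`.
#' @param patients data.frame with columns `patient_id`, `birth_year`,
#'   `gender` and optionally `dialysis` (logical).
#' @param consultations data.frame with columns `patient_id`, `physician_id`,
#'   `service_date` (Date or ISO-8601 string), `billing_type_code`.
#' @param diagnoses data.frame with columns `patient_id`, `icd10_code`,
#'   `quarter` (1--4), `qualifier`.
#' @param observation_year optional integer; when given, consultation dates
#'   must fall inside that calendar year.
#' @param validate run [validate_bundle()] (default `TRUE`).
#' @return An object of class `claims_bundle`: a list of the four
#'   data.tables plus the observation year.
#' @export
claims_bundle <- function(physicians, patients, consultations, diagnoses,
                          observation_year = NULL, validate = TRUE) {
  b <- structure(
    list(
      physicians    = as.data.table(physicians),
      patients      = as.data.table(patients),
      consultations = as.data.table(consultations),
      diagnoses     = as.data.table(diagnoses),
      observation_year = observation_year
    ),
    class = "claims_bundle"
  )
  if (nrow(b$consultations) > 0 && !inherits(b$consultations$service_date, "Date")) {
    b$consultations[, service_date := as.Date(service_date)]
  } else if (nrow(b$consultations) == 0) {
    b$consultations[, service_date := as.Date(service_date)]
  }
  if (nrow(b$diagnoses) >= 0) b$diagnoses[, quarter := as.integer(quarter)]
  b$patients[, birth_year := as.integer(birth_year)]
  for (tab in names(.BUNDLE_SCHEMAS)) {
    idcols <- intersect(c("physician_id", "patient_id", "practice_id"), names(b[[tab]]))
    for (cc in idcols) data.table::set(b[[tab]], j = cc, value = as.character(b[[tab]][[cc]]))
  }
  if (validate) validate_bundle(b)
  b
}

#' @export
print.claims_bundle <- function(x, ...) {
  cat("<claims_bundle>\n")
  cat(sprintf("  physicians:    %d (%d practices, %d regions)\n",
              nrow(x$physicians), uniqueN(x$physicians$practice_id),
              uniqueN(x$physicians$region_code)))
  cat(sprintf("  patients:      %d\n", nrow(x$patients)))
  cat(sprintf("  consultations: %d\n", nrow(x$consultations)))
  cat(sprintf("  diagnoses:     %d\n", nrow(x$diagnoses)))
  if (!is.null(x$observation_year))
    cat(sprintf("  observation year: %d\n", x$observation_year))
  invisible(x)
}

.check_cols <- function(dt, tab) {
  need <- .BUNDLE_SCHEMAS[[tab]]
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop(sprintf("table '%s' is missing column(s): %s", tab,
                 paste(miss, collapse = ", ")), call. = FALSE)
}

.bad_rows_msg <- function(rows, what, n_show = 5) {
  shown <- head(rows, n_show)
  sprintf("%s at row(s) %s%s (%d total)", what,
          paste(shown, collapse = ", "),
          if (length(rows) > n_show) ", ..." else "", length(rows))
}

#' Validate referential integrity and field domains of a claims bundle
#'
#' Checks column presence, id uniqueness within the physician and patient
#' tables, foreign-key resolution from consultations and diagnoses, the
#' quarter and qualifier domains, and (when an observation year is set) that
#' consultation dates fall in that year. Violations raise an error naming the
#' offending rows.
#'
#' @param bundle a [claims_bundle()].
#' @return the bundle, invisibly, if valid.
#' @export
validate_bundle <- function(bundle) {
  stopifnot(inherits(bundle, "claims_bundle"))
  for (tab in names(.BUNDLE_SCHEMAS)) .check_cols(bundle[[tab]], tab)

  errs <- character(0)
  if (anyDuplicated(bundle$physicians$physician_id))
    errs <- c(errs, .bad_rows_msg(which(duplicated(bundle$physicians$physician_id)),
                                  "duplicate physician_id in physicians"))
  if (anyDuplicated(bundle$patients$patient_id))
    errs <- c(errs, .bad_rows_msg(which(duplicated(bundle$patients$patient_id)),
                                  "duplicate patient_id in patients"))

  phys_ids <- bundle$physicians$physician_id
  pat_ids  <- bundle$patients$patient_id
  if (nrow(bundle$consultations)) {
    bad <- which(!(bundle$consultations$physician_id %in% phys_ids))
    if (length(bad))
      errs <- c(errs, .bad_rows_msg(bad, "consultations: unknown physician_id"))
    bad <- which(!(bundle$consultations$patient_id %in% pat_ids))
    if (length(bad))
      errs <- c(errs, .bad_rows_msg(bad, "consultations: unknown patient_id"))
    bad <- which(is.na(bundle$consultations$service_date))
    if (length(bad))
      errs <- c(errs, .bad_rows_msg(bad, "consultations: unparseable service_date"))
    if (!is.null(bundle$observation_year)) {
      yr <- as.integer(format(bundle$consultations$service_date, "%Y"))
      bad <- which(!is.na(yr) & yr != bundle$observation_year)
      if (length(bad))
        errs <- c(errs, .bad_rows_msg(bad, sprintf(
          "consultations: service_date outside observation year %d",
          bundle$observation_year)))
    }
  }
  if (nrow(bundle$diagnoses)) {
    bad <- which(!(bundle$diagnoses$patient_id %in% pat_ids))
    if (length(bad))
      errs <- c(errs, .bad_rows_msg(bad, "diagnoses: unknown patient_id"))
    bad <- which(!(bundle$diagnoses$quarter %in% 1:4))
    if (length(bad))
      errs <- c(errs, .bad_rows_msg(bad, "diagnoses: quarter not in 1..4"))
    bad <- which(!(bundle$diagnoses$qualifier %in% .QUALIFIER_LEVELS))
    if (length(bad))
      errs <- c(errs, .bad_rows_msg(bad, sprintf(
        "diagnoses: qualifier not in {%s}", paste(.QUALIFIER_LEVELS, collapse = ", "))))
  }
  if (length(errs))
    stop("claims bundle validation failed:\n  - ",
         paste(errs, collapse = "\n  - "), call. = FALSE)
  invisible(bundle)
}

#' Write a claims bundle as four CSV files
#'
#' Files are UTF-8, comma-separated, RFC 4180 quoted, with a header row:
#' `physicians.csv`, `patients.csv`, `consultations.csv`, `diagnoses.csv`.
#' Dates are written as ISO-8601 strings so that the write/read round trip is
#' the identity.
#'
#' @param bundle a [claims_bundle()].
#' @param dir output directory (created if absent).
#' @param verbose log row counts per table.
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir, verbose = FALSE) {
  stopifnot(inherits(bundle, "claims_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (tab in names(.BUNDLE_SCHEMAS)) {
    f <- file.path(dir, paste0(tab, ".csv"))
    fwrite(bundle[[tab]], f, dateTimeAs = "ISO")
    if (verbose) message(sprintf("wrote %s: %d rows", f, nrow(bundle[[tab]])))
  }
  invisible(dir)
}

#' Read a claims bundle from a directory of CSV files
#'
#' Expects the four files written by [write_bundle()]. Rows violating the
#' bundle invariants are reported with row-level diagnostics via
#' [validate_bundle()].
#'
#' @param dir directory containing the four CSVs.
#' @param observation_year optional integer passed to [claims_bundle()].
#' @param validate run validation after reading (default `TRUE`).
#' @param verbose log row counts per table.
#' @return a [claims_bundle()].
#' @export
read_bundle <- function(dir, observation_year = NULL, validate = TRUE,
                        verbose = FALSE) {
  tabs <- list()
  for (tab in names(.BUNDLE_SCHEMAS)) {
    f <- file.path(dir, paste0(tab, ".csv"))
    if (!file.exists(f)) stop(sprintf("missing claims file: %s", f), call. = FALSE)
    tabs[[tab]] <- fread(f, colClasses = list(
      character = intersect(c("physician_id", "patient_id", "practice_id",
                              "specialty_code", "region_code", "icd10_code",
                              "qualifier", "billing_type_code", "gender"),
                            names(fread(f, nrows = 0)))))
    if (verbose) message(sprintf("read %s: %d rows", f, nrow(tabs[[tab]])))
  }
  claims_bundle(tabs$physicians, tabs$patients, tabs$consultations,
                tabs$diagnoses, observation_year = observation_year,
                validate = validate)
}

# ---- pipeline configuration --------------------------------------------------

#' Specialties excluded from network construction
#'
#' The default physician exclusion list: specialties caring for patients
#' outside the adult cohort or with little direct patient contact whose high
#' patient volume would otherwise dominate the sharing graph (laboratory
#' medicine, radiology and similar contract-service disciplines).
#'
#' @return character vector of specialty codes.
#' @export
default_excluded_specialties <- function() {
  c("pediatrics", "laboratory_medicine", "microbiology",
    "oral_maxillofacial_surgery", "pathology", "radiology",
    "radiation_therapy", "transfusion_medicine")
}

#' Billing service types excluded from qualifying consultations
#'
#' Default exclusion list approximating non-face-to-face or emergency
#' contacts: laboratory contract referrals and laboratory-community requests,
#' emergency and rescue services, and holiday/illness replacement services.
#'
#' @return character vector of billing-type codes.
#' @export
default_excluded_billing_types <- function() {
  c("lab_contract_referral", "lab_community_request", "medical_emergency",
    "holiday_replacement", "emergency", "emergency_taxi", "rescue_service",
    "central_emergency")
}

#' Pipeline configuration with the framework's default thresholds
#'
#' Collects every tunable of the network-construction pipeline. Defaults are
#' the published framework values: an edge requires at least 20 shared
#' patients that amount to 5% or more of at least one physician's panel;
#' retained networks have between 20 and 120 physicians; a patient is
#' allocated to the network holding strictly more than 50% of their
#' treatment days.
#'
#' @param min_shared_patients minimum distinct shared patients per edge.
#' @param min_relative_share minimum shared-patient share of at least one
#'   physician's panel (inclusive), in (0, 1).
#' @param min_network_size,max_network_size retained network size band.
#' @param allocation_majority strict lower bound on the within-network share
#'   of treatment days required for allocation, in (0, 1).
#' @param excluded_specialties specialty codes removed in the physician
#'   filter; see [default_excluded_specialties()].
#' @param excluded_billing_types billing-type codes removed from qualifying
#'   consultations; see [default_excluded_billing_types()].
#' @param diagnosis_catalog diagnosis group rules, see
#'   [default_diagnosis_catalog()].
#' @param min_patient_age minimum patient age (years) at the end of the
#'   observation year; the cohort targets adult patients.
#' @param allowed_regions optional character vector restricting physicians to
#'   specific region codes (`NULL` keeps all).
#' @param exclude_dialysis drop patients flagged `dialysis` (default `TRUE`).
#' @param day_granularity `"physician_day"` (a treatment day is a distinct
#'   physician-date pair) or `"calendar_day"` (distinct dates).
#' @param observation_year calendar year of the observation period.
#' @param seed integer seed used by seeded pipeline stages.
#' @return an object of class `pipeline_config` (a named list).
#' @export
pipeline_config <- function(min_shared_patients = 20L,
                            min_relative_share = 0.05,
                            min_network_size = 20L,
                            max_network_size = 120L,
                            allocation_majority = 0.5,
                            excluded_specialties = default_excluded_specialties(),
                            excluded_billing_types = default_excluded_billing_types(),
                            diagnosis_catalog = default_diagnosis_catalog(),
                            min_patient_age = 18L,
                            allowed_regions = NULL,
                            exclude_dialysis = TRUE,
                            day_granularity = c("physician_day", "calendar_day"),
                            observation_year = 2016L,
                            seed = 1L) {
  day_granularity <- match.arg(day_granularity)
  cfg <- list(
    min_shared_patients = as.integer(min_shared_patients),
    min_relative_share = min_relative_share,
    min_network_size = as.integer(min_network_size),
    max_network_size = as.integer(max_network_size),
    allocation_majority = allocation_majority,
    excluded_specialties = as.character(excluded_specialties),
    excluded_billing_types = as.character(excluded_billing_types),
    diagnosis_catalog = diagnosis_catalog,
    min_patient_age = as.integer(min_patient_age),
    allowed_regions = allowed_regions,
    exclude_dialysis = isTRUE(exclude_dialysis),
    day_granularity = day_granularity,
    observation_year = as.integer(observation_year),
    seed = as.integer(seed)
  )
  .validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

.validate_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) stop("invalid configuration: ", msg, call. = FALSE)
  chk(length(cfg$min_shared_patients) == 1 && !is.na(cfg$min_shared_patients) &&
        cfg$min_shared_patients >= 1, "min_shared_patients must be a positive count")
  chk(is.numeric(cfg$min_relative_share) && cfg$min_relative_share > 0 &&
        cfg$min_relative_share < 1, "min_relative_share must lie in (0, 1)")
  chk(cfg$min_network_size >= 1, "min_network_size must be a positive count")
  chk(cfg$min_network_size <= cfg$max_network_size,
      "min_network_size must not exceed max_network_size")
  chk(is.numeric(cfg$allocation_majority) && cfg$allocation_majority > 0 &&
        cfg$allocation_majority < 1, "allocation_majority must lie in (0, 1)")
  chk(cfg$min_patient_age >= 0, "min_patient_age must be non-negative")
  chk(cfg$day_granularity %in% c("physician_day", "calendar_day"),
      "day_granularity must be 'physician_day' or 'calendar_day'")
  invisible(cfg)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  cat(sprintf("  edge thresholds: >= %d shared patients, >= %.1f%% relative share\n",
              x$min_shared_patients, 100 * x$min_relative_share))
  cat(sprintf("  network size band: [%d, %d]\n", x$min_network_size, x$max_network_size))
  cat(sprintf("  allocation majority: > %.0f%% of treatment days (%s)\n",
              100 * x$allocation_majority, x$day_granularity))
  cat(sprintf("  excluded specialties: %d; excluded billing types: %d\n",
              length(x$excluded_specialties), length(x$excluded_billing_types)))
  cat(sprintf("  diagnosis rules: %d (groups 1-14); min patient age: %d\n",
              nrow(x$diagnosis_catalog), x$min_patient_age))
  invisible(x)
}

#' Load a pipeline configuration from a YAML file
#'
#' Keys absent from the file keep their defaults from [pipeline_config()];
#' unknown keys raise a configuration error. The diagnosis catalog itself is
#' not settable from the file.
#'
#' @param path YAML file; an empty file yields the full default configuration.
#' @return a `pipeline_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path), call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  allowed <- setdiff(names(formals(pipeline_config)), "diagnosis_catalog")
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown))
    stop(sprintf("unknown configuration key(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  do.call(pipeline_config, raw)
}
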