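# Synthetic claims generator: claims bundles with planted physician
# communities and known cohort membership, emulating the structure of German
# ambulatory billing data (which is access-restricted) at configurable scale.

# Relative frequencies of the 14 diagnosis groups in the pre-allocation
# patient population (shares of patients carrying each group, in %); used as
# sampling weights for assigning disease groups to synthetic patients.
.GROUP_PREVALENCE <- c(
  `1` = 10, `2` = 4, `3` = 25, `4` = 24, `5` = 2, `6` = 35, `7` = 42,
  `8` = 15, `9` = 12, `10` = 3, `11` = 39, `12` = 16, `13` = 15, `14` = 9
)

# Included-specialty mix: mass 0.45 on general practice, gynecology ~0.10,
# orthopedics and ophthalmology ~0.05 each, remainder spread over other
# office-based disciplines.
.DEFAULT_SPECIALTIES <- c(
  gp = 0.45, gynecology = 0.10, orthopedics = 0.05, ophthalmology = 0.05,
  internal_medicine = 0.09, dermatology = 0.05, ent = 0.05, neurology = 0.03,
  urology = 0.03, cardiology = 0.03, surgery = 0.03)
.DEFAULT_SPECIALTIES <- c(.DEFAULT_SPECIALTIES,
                          psychotherapy = 1 - sum(.DEFAULT_SPECIALTIES))

#' Configuration of the synthetic claims generator
#'
#' Defines the study conditions the generator emulates: physician and patient
#' counts, planted physician communities expressed through patients'
#' preferential within-community visiting, the specialty mix (45% general
#' practitioners by default), a mean of 2.5 diagnosis groups per cohort
#' patient, 55% female patients and a mean age of 54 years.
#'
#' @param n_physicians number of physicians (ignored when `community_sizes`
#'   is given).
#' @param n_practices number of practices; practices never span planted
#'   communities. Default: one practice per ~1.5 physicians.
#' @param n_patients number of patients.
#' @param n_planted_communities number of planted physician communities
#'   (ignored when `community_sizes` is given).
#' @param community_sizes optional integer vector of planted community sizes;
#'   overrides `n_physicians` and `n_planted_communities`.
#' @param within_community_visit_prob probability that a consultation targets
#'   the patient's home community; must be at least
#'   `1/n_planted_communities`, otherwise there is no planted signal.
#' @param specialty_distribution named probability vector over included
#'   specialty codes; must sum to 1.
#' @param prop_excluded_specialty share of physicians drawn from the excluded
#'   specialty list (so the physician filter has work to do).
#' @param mean_diseases_per_patient mean number of distinct diagnosis groups
#'   per cohort patient (zero-truncated Poisson).
#' @param prop_noncohort share of patients generated without any qualifying
#'   diagnosis.
#' @param prop_dialysis share of patients flagged as dialysis patients.
#' @param prop_excluded_billing share of consultations carrying an excluded
#'   billing-service code (laboratory referral, emergency, ...).
#' @param mean_visits_per_patient mean consultation count per patient
#'   (negative binomial, truncated at 1).
#' @param visit_dispersion negative-binomial size parameter (smaller = more
#'   overdispersed).
#' @param female_share probability that a patient is female.
#' @param mean_age mean patient age in years at the observation year.
#' @param sd_age standard deviation of patient age.
#' @param quarters number of quarters in the observation period.
#' @param observation_year calendar year stamped on consultations.
#' @param seed integer RNG seed; the generator is deterministic given the
#'   full configuration and seed.
#' @return an object of class `sim_config` (a named list).
#' @export
sim_config <- function(n_physicians = 120L,
                       n_practices = NULL,
                       n_patients = 4000L,
                       n_planted_communities = 4L,
                       community_sizes = NULL,
                       within_community_visit_prob = 0.9,
                       specialty_distribution = .DEFAULT_SPECIALTIES,
                       prop_excluded_specialty = 0.05,
                       mean_diseases_per_patient = 2.5,
                       prop_noncohort = 0.15,
                       prop_dialysis = 0.02,
                       prop_excluded_billing = 0.05,
                       mean_visits_per_patient = 8,
                       visit_dispersion = 2,
                       female_share = 0.55,
                       mean_age = 54,
                       sd_age = 16,
                       quarters = 4L,
                       observation_year = 2016L,
                       seed = 1L) {
  if (!is.null(community_sizes)) {
    community_sizes <- as.integer(community_sizes)
    n_physicians <- sum(community_sizes)
    n_planted_communities <- length(community_sizes)
  }
  cfg <- list(
    n_physicians = as.integer(n_physicians),
    n_practices = if (is.null(n_practices)) max(1L, round(n_physicians / 1.5))
                  else as.integer(n_practices),
    n_patients = as.integer(n_patients),
    n_planted_communities = as.integer(n_planted_communities),
    community_sizes = community_sizes,
    within_community_visit_prob = within_community_visit_prob,
    specialty_distribution = specialty_distribution,
    prop_excluded_specialty = prop_excluded_specialty,
    mean_diseases_per_patient = mean_diseases_per_patient,
    prop_noncohort = prop_noncohort,
    prop_dialysis = prop_dialysis,
    prop_excluded_billing = prop_excluded_billing,
    mean_visits_per_patient = mean_visits_per_patient,
    visit_dispersion = visit_dispersion,
    female_share = female_share,
    mean_age = mean_age,
    sd_age = sd_age,
    quarters = as.integer(quarters),
    observation_year = as.integer(observation_year),
    seed = as.integer(seed)
  )
  .validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

.validate_sim_config <- function(cfg) {
  bad <- function(field, msg)
    stop(sprintf("invalid generator configuration: %s %s", field, msg), call. = FALSE)
  counts <- c("n_physicians", "n_practices", "n_patients",
              "n_planted_communities", "quarters")
  for (f in counts)
    if (length(cfg[[f]]) != 1 || is.na(cfg[[f]]) || cfg[[f]] < 1)
      bad(f, "must be a positive count")
  probs <- c("within_community_visit_prob", "prop_excluded_specialty",
             "prop_noncohort", "prop_dialysis", "prop_excluded_billing",
             "female_share")
  for (f in probs)
    if (!is.numeric(cfg[[f]]) || is.na(cfg[[f]]) || cfg[[f]] < 0 || cfg[[f]] > 1)
      bad(f, "must be a probability in [0, 1]")
  if (abs(sum(cfg$specialty_distribution) - 1) > 1e-9)
    bad("specialty_distribution", "probabilities must sum to 1")
  if (is.null(names(cfg$specialty_distribution)) ||
      any(!nzchar(names(cfg$specialty_distribution))))
    bad("specialty_distribution", "must be a named probability vector")
  if (cfg$within_community_visit_prob < 1 / cfg$n_planted_communities)
    bad("within_community_visit_prob",
        sprintf("must be >= 1/n_planted_communities (%.3f): below that there is no planted signal",
                1 / cfg$n_planted_communities))
  if (cfg$mean_diseases_per_patient <= 0)
    bad("mean_diseases_per_patient", "must be positive")
  if (cfg$mean_visits_per_patient <= 0) bad("mean_visits_per_patient", "must be positive")
  if (cfg$visit_dispersion <= 0) bad("visit_dispersion", "must be positive")
  if (cfg$n_practices > cfg$n_physicians)
    bad("n_practices", "cannot exceed n_physicians")
  if (cfg$n_planted_communities > cfg$n_physicians)
    bad("n_planted_communities", "cannot exceed n_physicians")
  if (!is.null(cfg$community_sizes) && any(cfg$community_sizes < 1))
    bad("community_sizes", "must all be positive")
  invisible(cfg)
}

# Poisson rate whose zero-truncated mean equals `target`:
# mean of ZTP(lambda) = lambda / (1 - exp(-lambda))
.ztpois_rate <- function(target) {
  if (target <= 1) return(1e-8)
  uniroot(function(l) l / (1 - exp(-l)) - target,
          interval = c(1e-8, max(2 * target, 10)), tol = 1e-10)$root
}

.rztpois <- function(n, lambda) {
  # inverse-CDF sampling conditioned on X >= 1
  u <- runif(n, min = exp(-lambda), max = 1)
  stats::qpois(u, lambda)
}

#' Generate a synthetic claims bundle with planted physician communities
#'
#' Produces four internally consistent claims tables plus the ground truth
#' they were generated from. Physicians are split into planted communities
#' and into practices nested within communities; each patient has a home
#' community and directs each consultation to a physician of that community
#' with probability `within_community_visit_prob`, otherwise to a uniformly
#' chosen other community. Cohort patients receive diagnosis records that
#' satisfy the M1Q/M2Q rules of the 14-group catalog; non-cohort patients
#' receive only non-qualifying records. A configurable share of
#' consultations carries an excluded billing-service code, and a share of
#' physicians an excluded specialty, so the cohort filters are exercised.
#'
#' @param config a [sim_config()].
#' @return list with elements `bundle` (a [claims_bundle()]) and `truth`
#'   (class `ground_truth`): `physician_community` (data.table
#'   `physician_id`, `community`), `patient_home_community` (`patient_id`,
#'   `home_community`), `cohort_flag` (`patient_id`, `cohort_flag`).
#' @export
generate_bundle <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  K <- config$n_planted_communities

  ## --- physicians: planted communities, nested practices, specialties -----
  n_ph <- config$n_physicians
  comm_sizes <- if (!is.null(config$community_sizes)) config$community_sizes else {
    base <- rep(n_ph %/% K, K)
    extra <- n_ph - sum(base)
    if (extra > 0) base[seq_len(extra)] <- base[seq_len(extra)] + 1L
    base
  }
  phys_comm <- rep.int(seq_len(K), comm_sizes)
  physician_id <- sprintf("ph%05d", seq_len(n_ph))

  n_excl <- rbinom(1L, n_ph, config$prop_excluded_specialty)
  excl_idx <- if (n_excl > 0) sample.int(n_ph, n_excl) else integer(0)
  specialty <- character(n_ph)
  incl_idx <- setdiff(seq_len(n_ph), excl_idx)
  specialty[incl_idx] <- sample(names(config$specialty_distribution),
                                length(incl_idx), replace = TRUE,
                                prob = config$specialty_distribution)
  if (length(excl_idx))
    specialty[excl_idx] <- sample(default_excluded_specialties(),
                                  length(excl_idx), replace = TRUE)

  # practices partition physicians within a community (never across)
  n_pr_comm <- pmax(1L, round(config$n_practices * comm_sizes / sum(comm_sizes)))
  practice_id <- character(n_ph)
  pr_counter <- 0L
  for (k in seq_len(K)) {
    members <- which(phys_comm == k)
    npr <- min(n_pr_comm[k], length(members))
    lab <- sprintf("pr%05d", pr_counter + seq_len(npr))
    # each practice gets >= 1 physician; remaining assigned at random
    assignment <- c(seq_len(npr), sample.int(npr, length(members) - npr, replace = TRUE))
    practice_id[members] <- lab[assignment[sample.int(length(members))]]
    pr_counter <- pr_counter + npr
  }

  physicians <- data.table(
    physician_id = physician_id,
    specialty_code = specialty,
    practice_id = practice_id,
    region_code = "R1"
  )

  ## --- patients -----------------------------------------------------------
  n_pt <- config$n_patients
  patient_id <- sprintf("pt%07d", seq_len(n_pt))
  age <- pmin(pmax(round(rnorm(n_pt, config$mean_age, config$sd_age)), 1), 100)
  patients <- data.table(
    patient_id = patient_id,
    birth_year = config$observation_year - as.integer(age),
    gender = fifelse(runif(n_pt) < config$female_share, "F", "M"),
    dialysis = runif(n_pt) < config$prop_dialysis
  )
  # home community drawn proportionally to community size: larger physician
  # communities serve proportionally more patients
  home_comm <- sample.int(K, n_pt, replace = TRUE, prob = comm_sizes)
  cohort_flag <- runif(n_pt) >= config$prop_noncohort

  ## --- diagnoses ----------------------------------------------------------
  catalog <- default_diagnosis_catalog()
  diagnoses <- .simulate_diagnoses(patient_id, cohort_flag, catalog, config)

  ## --- consultations ------------------------------------------------------
  n_visits <- pmax(1L, rnbinom(n_pt, size = config$visit_dispersion,
                               mu = config$mean_visits_per_patient))
  pat_of_visit <- rep.int(seq_len(n_pt), n_visits)
  n_total <- length(pat_of_visit)

  stay_home <- runif(n_total) < config$within_community_visit_prob
  target_comm <- home_comm[pat_of_visit]
  if (K > 1L) {
    away <- which(!stay_home)
    if (length(away)) {
      # uniformly random *other* community
      shift <- sample.int(K - 1L, length(away), replace = TRUE)
      target_comm[away] <- 1L + (target_comm[away] - 1L + shift) %% K
    }
  }
  # uniform physician within the target community
  comm_start <- cumsum(c(0L, comm_sizes))
  offset <- floor(runif(n_total) * comm_sizes[target_comm]) + 1L
  phys_of_visit <- comm_start[target_comm] + offset

  day_span <- as.integer(config$quarters * 91.25)
  dates <- as.Date(sprintf("%d-01-01", config$observation_year)) +
    floor(runif(n_total) * day_span)
  billing <- rep("office_visit", n_total)
  n_excl_bill <- rbinom(1L, n_total, config$prop_excluded_billing)
  if (n_excl_bill > 0) {
    idx <- sample.int(n_total, n_excl_bill)
    billing[idx] <- sample(default_excluded_billing_types(), n_excl_bill,
                           replace = TRUE)
  }
  consultations <- data.table(
    patient_id = patient_id[pat_of_visit],
    physician_id = physician_id[phys_of_visit],
    service_date = dates,
    billing_type_code = billing
  )

  bundle <- claims_bundle(physicians, patients, consultations, diagnoses,
                          observation_year = config$observation_year,
                          validate = FALSE)
  truth <- structure(
    list(
      physician_community = data.table(physician_id = physician_id,
                                       community = phys_comm),
      patient_home_community = data.table(patient_id = patient_id,
                                          home_community = home_comm),
      cohort_flag = data.table(patient_id = patient_id,
                               cohort_flag = cohort_flag),
      config = config
    ),
    class = "ground_truth"
  )
  list(bundle = bundle, truth = truth)
}

# diagnosis records: cohort patients get >= 1 qualifying group (zero-truncated
# Poisson count, groups sampled by population prevalence weights); non-cohort
# patients get only non-qualifying records (single-quarter M2Q codes, wrong
# qualifiers, or out-of-catalog codes)
.simulate_diagnoses <- function(patient_id, cohort_flag, catalog, config) {
  n_pt <- length(patient_id)
  qtrs <- seq_len(config$quarters)
  lam <- .ztpois_rate(config$mean_diseases_per_patient)

  coh <- which(cohort_flag)
  n_coh <- length(coh)
  n_dis_coh <- if (n_coh) pmin(.rztpois(n_coh, lam), 14L) else integer(0)

  # sample distinct groups per cohort patient, weighted by prevalence, via
  # the Gumbel-top-k trick (fully vectorised: one global order() call)
  w <- .GROUP_PREVALENCE / sum(.GROUP_PREVALENCE)
  ng <- length(w)
  if (n_coh) {
    key <- -log(-log(runif(n_coh * ng))) + rep(log(w), each = n_coh)
    row_id <- rep.int(seq_len(n_coh), ng)
    col_id <- rep(seq_len(ng), each = n_coh)
    o <- order(row_id, -key)
    grp_sorted <- col_id[o]                       # per row: groups by key desc
    take <- sequence(n_dis_coh) + rep((seq_len(n_coh) - 1L) * ng, n_dis_coh)
    grp_of_row <- grp_sorted[take]
    pat_idx <- rep.int(coh, n_dis_coh)
  } else {
    grp_of_row <- integer(0); pat_idx <- integer(0)
  }

  # map each (patient, merged group) to a sub-rule; groups with two sub-rules
  # (1a/1b, 4a/4b) pick one at random
  first_rule <- vapply(split(seq_len(nrow(catalog)), catalog$group_id)[
    as.character(seq_len(ng))], `[`, integer(1), 1L)
  n_sub <- tabulate(catalog$group_id, nbins = ng)
  rule_of_row <- first_rule[grp_of_row]
  two <- n_sub[grp_of_row] == 2L
  rule_of_row[two] <- rule_of_row[two] + (runif(sum(two)) < 0.5)

  if (length(rule_of_row)) {
    freq <- catalog$frequency_rule[rule_of_row]
    n_rec <- fifelse(freq == "M2Q", 2L, 1L)
    rec_rule <- rep.int(rule_of_row, n_rec)
    rec_pat  <- rep.int(pat_idx, n_rec)
    # quarters: M2Q disease rows get two distinct quarters
    q1 <- sample(qtrs, length(rule_of_row), replace = TRUE)
    q2 <- 1L + (q1 - 1L + sample.int(config$quarters - 1L, length(rule_of_row),
                                     replace = TRUE)) %% config$quarters
    qq <- as.integer(rbind(q1, q2))  # interleaved q1,q2 per disease row
    keep2 <- rep(TRUE, 2L * length(rule_of_row))
    keep2[seq(2L, by = 2L, length.out = length(rule_of_row))] <- freq == "M2Q"
    rec_q <- qq[keep2]
    # qualifier per record under the sub-rule
    rec_qrule <- catalog$qualifier_rule[rec_rule]
    rec_qual <- character(length(rec_qrule))
    rec_qual[rec_qrule == "confirmed_only"] <- "confirmed"
    rec_qual[rec_qrule == "status_post_only"] <- "status_post"
    both <- rec_qrule == "confirmed_or_status_post"
    rec_qual[both] <- fifelse(runif(sum(both)) < 0.8, "confirmed", "status_post")
    # a concrete code, uniform over the sub-rule's prefix list
    flat <- unlist(catalog$icd_prefixes)
    len <- lengths(catalog$icd_prefixes)
    off <- cumsum(c(0L, len))
    rec_code <- flat[off[rec_rule] + floor(runif(length(rec_rule)) * len[rec_rule]) + 1L]
    qualifying <- data.table(
      patient_id = patient_id[rec_pat],
      icd10_code = rec_code,
      quarter = rec_q,
      qualifier = rec_qual
    )
  } else qualifying <- NULL

  # non-qualifying noise: for non-cohort patients 1-2 records that never
  # satisfy any rule; light noise for cohort patients too
  non <- which(!cohort_flag)
  noise_pat <- c(rep.int(non, pmax(1L, rpois(length(non), 1.2))),
                 coh[runif(n_coh) < 0.3])
  if (length(noise_pat)) {
    kind <- sample.int(3L, length(noise_pat), replace = TRUE)
    code <- character(length(noise_pat))
    qual <- character(length(noise_pat))
    # kind 1: out-of-catalog code; kind 2: confirmed M2Q-group code pinned to
    # a patient-specific single quarter (cannot reach two distinct quarters);
    # kind 3: M1Q confirmed-only code with a non-qualifying label
    code[kind == 1L] <- sample(c("Z00", "Z76", "B99", "T78"), sum(kind == 1L),
                               replace = TRUE)
    qual[kind == 1L] <- "confirmed"
    code[kind == 2L] <- sample(c("I50", "M17", "F32"), sum(kind == 2L),
                               replace = TRUE)
    qual[kind == 2L] <- "confirmed"
    code[kind == 3L] <- sample(c("K52", "J20", "A04"), sum(kind == 3L),
                               replace = TRUE)
    qual[kind == 3L] <- sample(c("status_post", "other"), sum(kind == 3L),
                               replace = TRUE)
    # quarter fixed per patient so repeated single-quarter codes of the same
    # non-cohort patient can never jointly satisfy an M2Q rule
    noise_q <- 1L + (noise_pat %% config$quarters)
    noise <- data.table(
      patient_id = patient_id[noise_pat],
      icd10_code = code,
      quarter = as.integer(noise_q),
      qualifier = qual
    )
  } else noise <- NULL

  out <- rbindlist(list(qualifying, noise))
  if (nrow(out) == 0)
    out <- data.table(patient_id = character(0), icd10_code = character(0),
                      quarter = integer(0), qualifier = character(0))
  out[order(patient_id, icd10_code, quarter)]
}

#' Write generator ground truth as CSV files
#'
#' Writes `physician_community.csv`, `patient_home_community.csv` and
#' `cohort_flag.csv` next to the bundle tables.
#'
#' @param truth the `ground_truth` element returned by [generate_bundle()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_ground_truth <- function(truth, dir) {
  stopifnot(inherits(truth, "ground_truth"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fwrite(truth$physician_community, file.path(dir, "physician_community.csv"))
  fwrite(truth$patient_home_community, file.path(dir, "patient_home_community.csv"))
  fwrite(truth$cohort_flag, file.path(dir, "cohort_flag.csv"))
  invisible(dir)
}
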