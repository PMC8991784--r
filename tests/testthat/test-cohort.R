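test_that("the 50-patient truth table classifies identically to hand computation", {
  tt <- cohort_truth_table()
  expect_length(tt, 50)
  for (nm in names(tt)) {
    got <- classify_patient(tt[[nm]][[1]])
    expect_identical(got, sort(unique(tt[[nm]][[2]])), info = nm)
  }
})

test_that("vectorised classification agrees with the per-patient path on the truth table", {
  tt <- cohort_truth_table()
  dx <- data.table::rbindlist(lapply(tt, `[[`, 1), idcol = "patient_id")
  got <- classify_patients(dx)
  for (nm in names(tt)) {
    expect_identical(got[patient_id == nm, sort(group_id)],
                     sort(unique(tt[[nm]][[2]])), info = nm)
  }
})

test_that("classification is monotone: adding records never removes a group", {
  catalog <- default_diagnosis_catalog()
  codes <- c(unlist(catalog$icd_prefixes), "Z00", "B99")
  quals <- c("confirmed", "status_post", "other")
  set.seed(99)
  for (i in 1:25) {
    n <- sample(1:8, 1)
    base <- data.table::data.table(
      icd10_code = sample(codes, n, replace = TRUE),
      quarter = sample(1:4, n, replace = TRUE),
      qualifier = sample(quals, n, replace = TRUE))
    extra <- data.table::data.table(
      icd10_code = sample(codes, 2, replace = TRUE),
      quarter = sample(1:4, 2, replace = TRUE),
      qualifier = sample(quals, 2, replace = TRUE))
    g1 <- classify_patient(base)
    g2 <- classify_patient(rbind(base, extra))
    expect_true(all(g1 %in% g2))
  }
})

test_that("ICD prefix matching works at the printed precision", {
  expect_identical(classify_patient(rbind(dx_rec("I10.90", 1), dx_rec("I10", 3))), 7L)
  # a 3-character rule code matches any extension
  expect_identical(classify_patient(rbind(dx_rec("I10.0", 1), dx_rec("I10.0", 2))), 7L)
  # the range I10-I15 is inclusive on both ends
  expect_identical(classify_patient(rbind(dx_rec("I14", 1), dx_rec("I14", 2))), 7L)
  # unknown qualifier labels are a validation error
  expect_error(classify_patient(dx_rec("I10", 1, "maybe")), "qualifier")
})

test_that("physician filter drops excluded specialties and supports regions", {
  ph <- data.table::data.table(
    physician_id = sprintf("d%02d", 1:10),
    specialty_code = c(rep("gp", 6), "radiology", "radiology", "ent", "urology"),
    practice_id = "pr1", region_code = c(rep("R1", 9), "R2"))
  b <- claims_bundle(ph, tiny_bundle()$patients, tiny_bundle()$consultations[0],
                     tiny_bundle()$diagnoses, validate = FALSE)
  cfg <- pipeline_config()
  expect_length(filter_physicians(b, cfg), 8)

  cfg0 <- pipeline_config(excluded_specialties = character(0))
  expect_length(filter_physicians(b, cfg0), 10)

  cfgr <- pipeline_config(allowed_regions = "R1")
  expect_length(filter_physicians(b, cfgr), 7)

  cfg_all <- pipeline_config(excluded_specialties = unique(ph$specialty_code))
  expect_warning(out <- filter_physicians(b, cfg_all), "no physicians")
  expect_length(out, 0)
})

test_that("consultation filter removes excluded billing types and excluded parties", {
  b <- tiny_bundle()
  b$consultations[5, billing_type_code := "lab_contract_referral"]
  b$consultations[6, billing_type_code := "emergency"]
  cfg <- pipeline_config()
  kept <- filter_consultations(b, included_physicians = c("d1", "d2", "d3"),
                               included_patients = b$patients$patient_id, cfg)
  expect_equal(nrow(kept), 4)  # 2 excluded billing codes dropped

  # consultation with an excluded radiologist (d4) is dropped even for an
  # included patient
  kept2 <- filter_consultations(b, included_physicians = filter_physicians(b, cfg),
                                included_patients = b$patients$patient_id, cfg)
  expect_false("d4" %in% kept2$physician_id)

  # with an empty exclusion list only the id restriction applies
  cfg0 <- pipeline_config(excluded_billing_types = character(0))
  kept3 <- filter_consultations(b, b$physicians$physician_id,
                                b$patients$patient_id, cfg0)
  expect_equal(nrow(kept3), 6)
})

test_that("build_cohort matches the generator's ground-truth flags", {
  sim <- generate_bundle(sim_config(n_physicians = 60, n_patients = 1500,
                                    prop_noncohort = 0.3, seed = 23))
  cfg <- pipeline_config()
  cohort <- build_cohort(sim$bundle, cfg)

  b <- sim$bundle
  flagged <- sim$truth$cohort_flag[cohort_flag == TRUE, patient_id]
  adult <- b$patients[2016L - birth_year >= 18L, patient_id]
  not_dialysis <- b$patients[dialysis == FALSE, patient_id]
  eligible <- intersect(intersect(flagged, adult), not_dialysis)
  # minus those left without a qualifying consultation
  incl_phys <- filter_physicians(b, cfg)
  qual_cons <- b$consultations[
    !(billing_type_code %in% cfg$excluded_billing_types) &
      physician_id %in% incl_phys & patient_id %in% eligible]
  expected <- intersect(eligible, unique(qual_cons$patient_id))
  expect_setequal(cohort$included_patients, expected)

  # invariants: every included patient has >= 1 group; consultations
  # reference included ids only
  expect_setequal(unique(cohort$patient_groups$patient_id),
                  cohort$included_patients)
  expect_true(all(cohort$qualifying_consultations$patient_id %in%
                    cohort$included_patients))
  expect_true(all(cohort$qualifying_consultations$physician_id %in%
                    cohort$included_physicians))
})

test_that("degenerate cohorts are handled loudly", {
  b <- tiny_bundle()
  b$diagnoses <- b$diagnoses[0]
  expect_error(build_cohort(b, pipeline_config()), "no diagnosis records")

  # a patient whose only consultations are emergency-coded is excluded
  b2 <- tiny_bundle()
  b2$consultations[patient_id == "p1", billing_type_code := "emergency"]
  cohort <- build_cohort(b2, pipeline_config())
  expect_false("p1" %in% cohort$included_patients)
})

test_that("dialysis patients and minors are excluded from the cohort", {
  b <- tiny_bundle()
  # p1 qualifies (I10 M2Q, adult); flag as dialysis -> dropped
  b$patients[patient_id == "p1", dialysis := TRUE]
  cohort <- build_cohort(b, pipeline_config())
  expect_false("p1" %in% cohort$included_patients)
  # p4 (born 2010) carries a qualifying M1Q code but is a minor
  expect_false("p4" %in% cohort$included_patients)
})
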