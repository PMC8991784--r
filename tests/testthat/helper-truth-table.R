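# 50 hand-written patient diagnosis fixtures with hand-computed expected
# diagnosis-group sets. Covers every frequency/qualifier rule combination:
# M2Q with confirmed-or-status-post, M2Q with status-post-only (ischemic
# sub-rule 1b), M1Q with confirmed-only, ICD range boundaries, prefix
# matching at printed precision, mixed qualifiers across quarters, and
# single-quarter boundary failures.

dx_rec <- function(code, q, qual = "confirmed")
  data.table(icd10_code = code, quarter = as.integer(q), qualifier = qual)

cohort_truth_table <- function() {
  d <- function(...) rbindlist(list(...))
  list(
    t01 = list(d(dx_rec("I10", 1), dx_rec("I10", 3)), 7L),
    t02 = list(d(dx_rec("I10", 1)), integer(0)),                 # M2Q, one quarter
    t03 = list(d(dx_rec("I10", 1), dx_rec("I10", 1)), integer(0)), # same quarter
    t04 = list(d(dx_rec("I10", 1), dx_rec("I10.0", 4)), 7L),     # prefix match
    t05 = list(d(dx_rec("I10", 2), dx_rec("I12", 3)), 7L),       # same rule, two codes
    t06 = list(d(dx_rec("I10", 2), dx_rec("I10", 3, "status_post")), 7L),
    t07 = list(d(dx_rec("I10", 2, "status_post"), dx_rec("I10", 3, "status_post")), 7L),
    t08 = list(d(dx_rec("I10", 2, "other"), dx_rec("I10", 3)), integer(0)),
    t09 = list(d(dx_rec("I15", 1), dx_rec("I15", 2)), 7L),       # range upper end
    t10 = list(d(dx_rec("I16", 1), dx_rec("I16", 2)), integer(0)), # outside I10-I15
    t11 = list(d(dx_rec("A02", 2)), 9L),                         # M1Q
    t12 = list(d(dx_rec("A02", 2, "status_post")), integer(0)),  # confirmed only
    t13 = list(d(dx_rec("A02", 2, "other")), integer(0)),
    t14 = list(d(dx_rec("A00", 1)), 9L),                         # range lower end
    t15 = list(d(dx_rec("A09", 4)), 9L),
    t16 = list(d(dx_rec("A10", 1)), integer(0)),                 # outside A00-A09
    t17 = list(d(dx_rec("R07.0", 1)), 11L),                      # printed 4-digit code
    t18 = list(d(dx_rec("R07.1", 1)), integer(0)),               # not R07.0-prefixed
    t19 = list(d(dx_rec("R07.00", 1)), 11L),                     # extension of R07.0
    t20 = list(d(dx_rec("J06", 3)), 11L),
    t21 = list(d(dx_rec("I21", 1, "status_post"), dx_rec("I21", 3, "status_post")), 1L),
    t22 = list(d(dx_rec("I21", 1), dx_rec("I21", 3)), integer(0)), # 1b wants status_post
    t23 = list(d(dx_rec("I21", 1, "status_post"), dx_rec("I21", 3)), integer(0)),
    t24 = list(d(dx_rec("I20", 1), dx_rec("I20", 2, "status_post")), 1L),
    t25 = list(d(dx_rec("I20", 1), dx_rec("I21", 2, "status_post")), integer(0)),
    t26 = list(d(dx_rec("I25", 2), dx_rec("I25", 4)), 1L),
    t27 = list(d(dx_rec("J20", 1)), 4L),                         # bronchitis M1Q
    t28 = list(d(dx_rec("J20", 1, "status_post")), integer(0)),
    t29 = list(d(dx_rec("J44", 1), dx_rec("J44", 2, "status_post")), 4L), # COPD M2Q
    t30 = list(d(dx_rec("J44", 3)), integer(0)),
    t31 = list(d(dx_rec("J20", 1), dx_rec("J44", 2)), 4L),       # 4a alone qualifies
    t32 = list(d(dx_rec("I50", 1), dx_rec("I50", 2)), 2L),
    t33 = list(d(dx_rec("I50", 1)), integer(0)),
    t34 = list(d(dx_rec("K52", 2)), 8L),
    t35 = list(d(dx_rec("K59", 4)), 8L),
    t36 = list(d(dx_rec("K52", 1, "status_post")), integer(0)),
    t37 = list(d(dx_rec("F10", 1), dx_rec("F11", 3)), 5L),
    t38 = list(d(dx_rec("F10", 2)), integer(0)),
    t39 = list(d(dx_rec("M54", 1), dx_rec("M54", 2)), 6L),
    t40 = list(d(dx_rec("M17", 1), dx_rec("M17", 2, "status_post")), 14L),
    t41 = list(d(dx_rec("E11", 1), dx_rec("E11", 1, "status_post")), integer(0)),
    t42 = list(d(dx_rec("E11", 1), dx_rec("E11", 2), dx_rec("A03", 3)), c(9L, 13L)),
    t43 = list(d(dx_rec("I10", 1), dx_rec("I10", 2), dx_rec("J18", 1),
                 dx_rec("M54", 1)), c(7L, 10L)),
    t44 = list(d(dx_rec("F32", 1), dx_rec("F33", 4, "status_post")), 12L),
    t45 = list(dx_rec("I10", 1)[0], integer(0)),                 # no records
    t46 = list(d(dx_rec("Z00", 1)), integer(0)),                 # out of catalog
    t47 = list(d(dx_rec("I48", 1), dx_rec("I48", 2)), 3L),
    t48 = list(d(dx_rec("R00", 1), dx_rec("R00", 3, "status_post")), 3L),
    t49 = list(d(dx_rec("J12", 2)), 10L),
    t50 = list(d(dx_rec("I10", 1), dx_rec("I10", 2), dx_rec("I50", 2),
                 dx_rec("I50", 3, "status_post"), dx_rec("A00", 1),
                 dx_rec("J20", 2), dx_rec("I21", 3, "status_post")),
               c(2L, 4L, 7L, 9L))
  )
}
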