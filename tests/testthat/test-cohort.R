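cohort_default <- generate_cohort(iss_config(seed = 11))

test_that("default cohort has the matched nested case-control structure", {
  pat <- cohort_default$patients
  expect_identical(nrow(pat), 616L)
  expect_identical(sum(pat$cancer), 308L)
  expect_identical(sum(!pat$cancer), 308L)
  # every patient has exactly one observation series and a partition label
  expect_setequal(unique(cohort_default$observations$patient_id),
                  pat$patient_id)
  expect_true(all(pat$partition %in% c("train", "validation")))
  # cases have diagnosis times, controls do not
  expect_true(all(!is.na(pat$diagnosis_time[pat$cancer])))
  expect_true(all(pat$diagnosis_time[pat$cancer] > 0))
  expect_true(all(is.na(pat$diagnosis_time[!pat$cancer])))
  # eligibility window and positive pack-years
  expect_true(all(pat$age >= 55 & pat$age <= 74))
  expect_true(all(pat$pack_years > 0))
  # follow-up covers the last observation
  last_obs <- tapply(cohort_default$observations$t,
                     cohort_default$observations$patient_id, max)
  expect_true(all(pat$followup_duration >= last_obs[pat$patient_id]))
})

test_that("matching is 1:1 within each diagnosis-year stratum", {
  pat <- cohort_default$patients
  cases <- pat[pat$cancer, ]
  ctrls <- pat[!pat$cancer, ]
  # brute-force tally over pairs: controls inherit their case's year
  expect_identical(table(ctrls$diagnosis_year), table(cases$diagnosis_year))
  expect_setequal(ctrls$pair_id, cases$patient_id)
  expect_identical(anyDuplicated(ctrls$pair_id), 0L)
})

test_that("stratum exhaustion is reported with the offending year", {
  cases <- list(patients = data.frame(patient_id = c("a", "b"),
                                      diagnosis_year = c(2L, 2L),
                                      stringsAsFactors = FALSE),
                observations = data.frame())
  pool <- list(patients = data.frame(patient_id = "x", diagnosis_year = 2L,
                                     stringsAsFactors = FALSE),
               observations = data.frame(patient_id = character(0)))
  expect_error(match_case_control(cases, pool, seed = 1),
               "diagnosis year 2")
})

test_that("a forced single match selects the only eligible control", {
  cases <- list(patients = data.frame(patient_id = "a", diagnosis_year = 3L,
                                      stringsAsFactors = FALSE),
                observations = data.frame(patient_id = "a", t = 0,
                                          diameter = 5))
  pool <- list(patients = data.frame(patient_id = c("x", "y"),
                                     diagnosis_year = c(3L, 4L),
                                     stringsAsFactors = FALSE),
               observations = data.frame(patient_id = c("x", "y"), t = 0,
                                         diameter = 5))
  m <- match_case_control(cases, pool, seed = 1)
  expect_setequal(m$patients$patient_id, c("a", "x"))
})

test_that("train/validation split reproduces the 462/154 design and stratifies", {
  pat <- cohort_default$patients
  expect_identical(sum(pat$partition == "train"), 462L)
  expect_identical(sum(pat$partition == "validation"), 154L)
  # case share in each partition within 1 patient of the overall 50%
  for (p in c("train", "validation")) {
    sub <- pat[pat$partition == p, ]
    expect_lte(abs(sum(sub$cancer) - nrow(sub) / 2), 1)
  }
  # floor rounding at an extreme fraction: two patients split 1/1
  tiny <- list(patients = data.frame(patient_id = c("a", "b"),
                                     cancer = c(TRUE, FALSE),
                                     stringsAsFactors = FALSE))
  tiny <- split_train_validation(tiny, 1 - 1e-9, seed = 1)
  expect_identical(sort(tiny$patients$partition), c("train", "validation"))
  expect_error(split_train_validation(list(patients = data.frame()), 1.2, 1),
               "train_fraction")
})

test_that("zero benign jitter makes every control's diameters constant", {
  ch <- small_cohort(n_cases = 8, seed = 5, benign_jitter_sd = 0)
  ctrl_ids <- ch$patients$patient_id[!ch$patients$cancer]
  for (id in ctrl_ids) {
    d <- ch$observations$diameter[ch$observations$patient_id == id]
    expect_identical(length(unique(d)), 1L)
  }
})

test_that("the generator is deterministic given the seed, to the output byte", {
  cfg <- iss_config(n_cases = 25, seed = 99)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1$patients, c2$patients)
  expect_identical(c1$observations, c2$observations)
  d1 <- file.path(tempdir(), "coh1"); d2 <- file.path(tempdir(), "coh2")
  write_cohort(c1, d1); write_cohort(c2, d2)
  expect_identical(unname(tools::md5sum(file.path(d1, "patients.csv"))),
                   unname(tools::md5sum(file.path(d2, "patients.csv"))))
  expect_identical(unname(tools::md5sum(file.path(d1, "observations.csv"))),
                   unname(tools::md5sum(file.path(d2, "observations.csv"))))
  c3 <- generate_cohort(iss_config(n_cases = 25, seed = 100))
  expect_false(identical(c1$patients, c3$patients))
})

test_that("generated covariate marginals converge to the configured targets", {
  # the per-arm targets blend to overall means of 63.0 y age, 58.75% male,
  # 25.5% family history and a median near 53 pack-years
  sums <- t(vapply(1:50, function(s) {
    pat <- generate_cohort(iss_config(seed = 1000L + s))$patients
    c(age = mean(pat$age), male = mean(pat$sex == "male"),
      fh = mean(pat$family_history), py = median(pat$pack_years))
  }, numeric(4)))
  mc_se <- apply(sums, 2, function(x) sd(x) / sqrt(nrow(sums)))
  expect_lt(abs(mean(sums[, "age"]) - 63.0), 3 * mc_se["age"] + 0.1)
  expect_lt(abs(mean(sums[, "male"]) - 0.5875), 3 * mc_se["male"] + 0.005)
  expect_lt(abs(mean(sums[, "fh"]) - 0.255), 3 * mc_se["fh"] + 0.005)
  expect_lt(abs(mean(sums[, "py"]) - 53.1), 3 * mc_se["py"] + 0.5)
})

test_that("case diameters drift upward and control diameters have no drift", {
  obs <- cohort_default$observations
  pat <- cohort_default$patients
  slope_of <- function(id) {
    o <- obs[obs$patient_id == id, ]
    if (nrow(o) < 2) return(NA_real_)
    coef(lm(diameter ~ t, o))[["t"]]
  }
  case_slopes <- vapply(pat$patient_id[pat$cancer], slope_of, numeric(1))
  ctrl_slopes <- vapply(pat$patient_id[!pat$cancer], slope_of, numeric(1))
  expect_gt(mean(case_slopes, na.rm = TRUE), 0.005)   # mm/day, clearly positive
  se <- sd(ctrl_slopes) / sqrt(length(ctrl_slopes))
  expect_lt(abs(mean(ctrl_slopes)), 4 * se + 1e-5)
})

test_that("invalid configuration fields are rejected by name", {
  expect_error(iss_config(n_cases = 0), "n_cases")
  expect_error(iss_config(train_fraction = 1.5), "train_fraction")
  expect_error(iss_config(benign_jitter_sd = -1), "benign_jitter_sd")
  bad_case <- list(age_mean = 63.7, age_sd = 5.2, male_p = 1.4,
                   current_smoker_p = 0.5, family_history_p = 0.2,
                   pack_years_median = 57, pack_years_iqr = c(45, 80),
                   followup_median = 1018, followup_iqr = c(757, 1679))
  expect_error(iss_config(case = bad_case), "male_p")
})
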