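# Shared fixtures, all built in code.

# small default-structure cohort for structural tests
small_cohort <- function(n_cases = 10, seed = 42, ...) {
  generate_cohort(iss_config(n_cases = n_cases, seed = seed, ...))
}

# hand-built observation series
series_two_point <- function() {
  data.frame(t = c(0, 365), diameter = c(4, 6),
             attenuation = c("solid", "part_solid"),
             spiculated = c(FALSE, FALSE), stringsAsFactors = FALSE)
}

# linear-growth series: diameter d0 + g * t/365, observed at the three screens
growth_series <- function(d0, g_per_year) {
  tt <- c(0, 365, 730)
  data.frame(t = tt, diameter = d0 + g_per_year * tt / 365,
             attenuation = "solid", spiculated = FALSE,
             stringsAsFactors = FALSE)
}

# Noiseless two-patient discrete instance: one benign flat nodule (4 mm),
# one malignant growing nodule (12 mm baseline, +8 mm/year). The cancer
# diagnosis time is far beyond the horizon so the delayed flag never fires
# and all rewards are exactly affine in the delta-variant features.
toy_discrete_cohort <- function() {
  patients <- data.frame(
    patient_id = c("benign", "malignant"),
    age = c(60L, 60L), sex = "male", smoking_status = "former",
    pack_years = c(40, 40), family_history = FALSE,
    cancer = c(FALSE, TRUE), diagnosis_time = c(NA, 10000),
    diagnosis_year = c(NA, 27L), followup_duration = c(10000, 10000),
    cancer_stage = c(NA, "I"), partition = "train",
    stringsAsFactors = FALSE)
  observations <- rbind(
    cbind(patient_id = "benign", growth_series(4, 0)),
    cbind(patient_id = "malignant", growth_series(12, 8)))
  structure(list(patients = patients, observations = observations,
                 config = NULL), class = "iss_cohort")
}

# bank-shaped frame for direct fit_stage tests: single stage-3-style fit on
# a known linear model of diameter with state-action interactions
synthetic_stage3_bank <- function(n, beta, noise_sd = 0, seed = 1) {
  set.seed(seed)
  d <- runif(n, 2, 30)
  a <- sample(c("F12", "DIAG", "F3", "END"), n, replace = TRUE)
  mm <- cbind(1, a == "DIAG", a == "F3", a == "END", d,
              d * (a == "DIAG"), d * (a == "F3"), d * (a == "END"))
  y <- drop(mm %*% beta) + rnorm(n, 0, noise_sd)
  # history diameters independent so the direct-history design is full rank;
  # their true coefficients are zero
  data.frame(n_stages = 3, action3 = a, diameter3 = d,
             diameter2 = runif(n, 2, 30), diameter1 = runif(n, 2, 30),
             delta3 = 0, attenuation3 = "solid",
             spiculated3 = FALSE, reward3 = y, stringsAsFactors = FALSE)
}

# catch-all single-action rule table
constant_policy <- function(action) {
  rule_table(paste0("always-", action), list(list(action = action)))
}
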