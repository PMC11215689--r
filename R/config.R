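#' Cohort generator configuration
#'
#' Builds the configuration object consumed by [generate_cohort()]. Defaults
#' are calibrated so that a default cohort of 308 matched case-control pairs
#' reproduces the marginal patient characteristics of the NLST-derived nested
#' case-control sample this package emulates: overall mean age 63.0 years,
#' 58.8% men, median 53 smoking pack-years, 25.5% with a family history of
#' lung cancer, and median follow-up of 1018 days in cases versus 2449.5 days
#' in controls.
#'
#' Per-arm covariate marginals are supplied as lists with elements
#' `age_mean`, `age_sd` (years; sampled from a normal truncated to
#' `age_range`, with the latent mean solved so the truncated mean equals
#' `age_mean`), `male_p`, `current_smoker_p`, `family_history_p`
#' (proportions), `pack_years_median` / `pack_years_iqr` and
#' `followup_median` / `followup_iqr` (lognormal, fitted to the stated
#' median and interquartile range).
#'
#' @param n_cases Number of cancer cases (controls are matched 1:1).
#' @param case,control Per-arm covariate marginal lists; see Details.
#' @param age_range Eligibility window in years (inclusive).
#' @param baseline_diameter Lognormal baseline nodule diameter parameters per
#'   arm: list with `case_meanlog`, `control_meanlog`, `sdlog` (mm scale).
#'   Case baselines are truncated below `trigger_mm` so diagnosis always
#'   occurs after baseline.
#' @param growth_rate Lognormal malignant diameter growth rate (mm/day):
#'   list with `meanlog`, `sdlog`.
#' @param benign_jitter_sd Standard deviation (mm) of the Gaussian
#'   measurement jitter around a control nodule's constant true diameter.
#' @param attenuation_probs Named probability vectors (`solid`, `part_solid`,
#'   `non_solid`) per arm.
#' @param spiculated_p Probability of a spiculated margin per arm.
#' @param trigger_mm Diameter threshold (mm) at which a malignant nodule is
#'   diagnosed at the first scheduled screen reaching it.
#' @param interval_window Days (length-2) for the uniform draw of the
#'   diagnosis time of cases whose nodule never reaches `trigger_mm` at a
#'   scheduled screen.
#' @param screen_times Scheduled screen times in days from baseline.
#' @param stage_probs Named probability vector over pathological stages
#'   at diagnosis (reporting only).
#' @param truncate_controls Logical; if `TRUE`, a control's observation
#'   series is truncated at its matched case's diagnosis time.
#' @param pool_factor Control pool size per diagnosis-year stratum, as a
#'   multiple of the stratum's case count.
#' @param train_fraction Fraction of patients assigned to the training
#'   partition (stratified by case status).
#' @param seed Integer seed; the generator is deterministic given it.
#'
#' @return An object of class `iss_config` (a validated list).
#' @examples
#' cfg <- iss_config(n_cases = 20, seed = 1)
#' cohort <- generate_cohort(cfg)
#' @export
iss_config <- function(n_cases = 308L,
                       case = list(age_mean = 63.7, age_sd = 5.2,
                                   male_p = 0.581, current_smoker_p = 0.481,
                                   family_history_p = 0.234,
                                   pack_years_median = 57, pack_years_iqr = c(45, 80),
                                   followup_median = 1018, followup_iqr = c(757, 1679)),
                       control = list(age_mean = 62.2, age_sd = 5.2,
                                      male_p = 0.594, current_smoker_p = 0.545,
                                      family_history_p = 0.276,
                                      pack_years_median = 50, pack_years_iqr = c(40, 65),
                                      followup_median = 2449.5, followup_iqr = c(2314, 2578)),
                       age_range = c(55, 74),
                       baseline_diameter = list(case_meanlog = log(8),
                                                control_meanlog = log(6),
                                                sdlog = 0.4),
                       growth_rate = list(meanlog = log(0.010), sdlog = 0.6),
                       benign_jitter_sd = 0.5,
                       attenuation_probs = list(
                         case = c(solid = 0.55, part_solid = 0.30, non_solid = 0.15),
                         control = c(solid = 0.70, part_solid = 0.15, non_solid = 0.15)),
                       spiculated_p = c(case = 0.35, control = 0.08),
                       trigger_mm = 15,
                       interval_window = c(731, 1460),
                       screen_times = c(0, 365, 730),
                       stage_probs = c(I = 0.567, II = 0.048, III = 0.165,
                                       IV = 0.199, occult = 0.021),
                       truncate_controls = FALSE,
                       pool_factor = 3,
                       train_fraction = 0.75,
                       seed = 20240701L) {
  cfg <- list(n_cases = as.integer(n_cases), case = case, control = control,
              age_range = age_range, baseline_diameter = baseline_diameter,
              growth_rate = growth_rate, benign_jitter_sd = benign_jitter_sd,
              attenuation_probs = attenuation_probs, spiculated_p = spiculated_p,
              trigger_mm = trigger_mm, interval_window = interval_window,
              screen_times = screen_times,
              stage_probs = stage_probs / sum(stage_probs),
              truncate_controls = isTRUE(truncate_controls),
              pool_factor = pool_factor,
              train_fraction = train_fraction, seed = as.integer(seed))
  validate_iss_config(cfg)
  structure(cfg, class = "iss_config")
}

validate_iss_config <- function(cfg) {
  fail <- function(field, why) {
    stop(sprintf("invalid generator config: field '%s' %s", field, why),
         call. = FALSE)
  }
  if (!is.numeric(cfg$n_cases) || length(cfg$n_cases) != 1 ||
      is.na(cfg$n_cases) || cfg$n_cases <= 0)
    fail("n_cases", "must be a positive count")
  if (!is.numeric(cfg$train_fraction) || cfg$train_fraction <= 0 ||
      cfg$train_fraction >= 1)
    fail("train_fraction", "must lie in (0, 1)")
  for (arm in c("case", "control")) {
    m <- cfg[[arm]]
    for (p in c("male_p", "current_smoker_p", "family_history_p"))
      if (!is.numeric(m[[p]]) || m[[p]] < 0 || m[[p]] > 1)
        fail(paste0(arm, "$", p), "must be a probability in [0, 1]")
    if (m$age_sd <= 0) fail(paste0(arm, "$age_sd"), "must be positive")
    if (m$pack_years_median <= 0)
      fail(paste0(arm, "$pack_years_median"), "must be positive")
    if (any(m$pack_years_iqr <= 0) || diff(m$pack_years_iqr) <= 0)
      fail(paste0(arm, "$pack_years_iqr"), "must be an increasing positive pair")
    if (m$followup_median <= 0)
      fail(paste0(arm, "$followup_median"), "must be positive")
  }
  for (arm in c("case", "control")) {
    pr <- cfg$attenuation_probs[[arm]]
    if (any(pr < 0) || any(pr > 1) || abs(sum(pr) - 1) > 1e-8)
      fail(paste0("attenuation_probs$", arm), "must be probabilities summing to 1")
  }
  if (any(cfg$spiculated_p < 0) || any(cfg$spiculated_p > 1))
    fail("spiculated_p", "must be probabilities in [0, 1]")
  if (cfg$benign_jitter_sd < 0) fail("benign_jitter_sd", "must be non-negative")
  if (cfg$trigger_mm <= 0) fail("trigger_mm", "must be positive")
  if (length(cfg$age_range) != 2 || diff(cfg$age_range) <= 0)
    fail("age_range", "must be an increasing pair")
  if (length(cfg$interval_window) != 2 || diff(cfg$interval_window) < 0)
    fail("interval_window", "must be a non-decreasing pair of days")
  if (cfg$pool_factor < 1) fail("pool_factor", "must be >= 1")
  invisible(cfg)
}

#' Reward-function weights
#'
#' The per-episode reward is
#' `base - w_misdiag * misdiagnosis - w_missed * missed - w_delayed * delayed
#'  - w_test * n_tests`,
#' where misdiagnosis means immediate work-up (DIAG) for a cancer-free
#' patient, missed diagnosis means discontinuation (END) for a cancer
#' patient, delayed diagnosis means the schedule resolves after the
#' ground-truth diagnosis time, and `n_tests` counts the F3/F12 follow-up
#' scans (0-3). The defaults give a total-reward range of 10 to 100 across
#' all legal schedules.
#'
#' @param base Baseline reward for an unpenalized schedule.
#' @param w_misdiag,w_missed,w_delayed,w_test Non-negative penalty weights.
#' @return An object of class `iss_reward_weights`.
#' @examples
#' reward_weights()
#' @export
reward_weights <- function(base = 100, w_misdiag = 70, w_missed = 60,
                           w_delayed = 5, w_test = 10) {
  w <- list(base = base, w_misdiag = w_misdiag, w_missed = w_missed,
            w_delayed = w_delayed, w_test = w_test)
  if (any(unlist(w[-1]) < 0))
    stop("reward weights must be non-negative", call. = FALSE)
  structure(w, class = "iss_reward_weights")
}
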