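#' @importFrom stats dnorm pnorm qnorm runif rbinom rlnorm rnorm uniroot
#'   plnorm qlnorm quantile median coef lm model.matrix as.formula terms
#'   predict setNames aggregate
NULL

# mean of a normal(mu, sd) truncated to [lo, hi]
trunc_norm_mean <- function(mu, sd, lo, hi) {
  a <- (lo - mu) / sd
  b <- (hi - mu) / sd
  mu + sd * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
}

# latent mean such that the truncated mean equals `target`
trunc_norm_latent <- function(target, sd, lo, hi) {
  uniroot(function(m) trunc_norm_mean(m, sd, lo, hi) - target,
          interval = c(lo - 4 * sd, hi + 4 * sd))$root
}

rtrunc_norm <- function(n, mu, sd, lo, hi) {
  p <- runif(n, pnorm(lo, mu, sd), pnorm(hi, mu, sd))
  qnorm(p, mu, sd)
}

# lognormal parameters from a stated median and interquartile range
lnorm_from_median_iqr <- function(med, iqr) {
  list(meanlog = log(med), sdlog = log(iqr[2] / iqr[1]) / (2 * qnorm(0.75)))
}

sample_arm_covariates <- function(n, marg, age_range, prefix) {
  mu <- trunc_norm_latent(marg$age_mean, marg$age_sd, age_range[1], age_range[2])
  py <- lnorm_from_median_iqr(marg$pack_years_median, marg$pack_years_iqr)
  fu <- lnorm_from_median_iqr(marg$followup_median, marg$followup_iqr)
  data.frame(
    patient_id = sprintf("%s%04d", prefix, seq_len(n)),
    age = as.integer(round(rtrunc_norm(n, mu, marg$age_sd,
                                       age_range[1], age_range[2]))),
    sex = ifelse(rbinom(n, 1, marg$male_p) == 1, "male", "female"),
    smoking_status = ifelse(rbinom(n, 1, marg$current_smoker_p) == 1,
                            "current", "former"),
    pack_years = round(rlnorm(n, py$meanlog, py$sdlog), 1),
    family_history = rbinom(n, 1, marg$family_history_p) == 1,
    followup_duration = round(rlnorm(n, fu$meanlog, fu$sdlog)),
    stringsAsFactors = FALSE
  )
}

sample_nodule_classes <- function(n, probs, spic_p) {
  list(attenuation = sample(names(probs), n, replace = TRUE, prob = probs),
       spiculated = rbinom(n, 1, spic_p) == 1)
}

# observed diameter: rounded to the nearest integer millimetre, floored at 1
observe_diameter <- function(true_mm) pmax(1, round(true_mm))

generate_cases <- function(config) {
  n <- config$n_cases
  pat <- sample_arm_covariates(n, config$case, config$age_range, "case")
  pat$cancer <- TRUE

  bd <- config$baseline_diameter
  # baseline truncated below the diagnosis trigger so diagnosis follows baseline
  p_hi <- plnorm(config$trigger_mm, bd$case_meanlog, bd$sdlog)
  baseline <- qlnorm(runif(n, 0, p_hi), bd$case_meanlog, bd$sdlog)
  rate <- rlnorm(n, config$growth_rate$meanlog, config$growth_rate$sdlog)

  cls <- sample_nodule_classes(n, config$attenuation_probs$case,
                               config$spiculated_p[["case"]])
  st <- config$screen_times
  true_diam <- outer(baseline, rep(1, length(st))) +
    outer(rate, st)                               # linear growth, mm

  diagnosis_time <- numeric(n)
  for (i in seq_len(n)) {
    hit <- st[true_diam[i, ] >= config$trigger_mm]
    diagnosis_time[i] <- if (length(hit)) hit[1] else
      round(runif(1, config$interval_window[1], config$interval_window[2]))
  }
  pat$diagnosis_time <- diagnosis_time
  pat$diagnosis_year <- as.integer(floor(diagnosis_time / 365))
  pat$cancer_stage <- sample(names(config$stage_probs), n, replace = TRUE,
                             prob = config$stage_probs)

  obs <- do.call(rbind, lapply(seq_len(n), function(i) {
    # screens up to the diagnosing screen; interval-detected cases keep all
    keep <- if (diagnosis_time[i] > max(st)) rep(TRUE, length(st)) else
      st <= diagnosis_time[i]
    tt <- st[keep]
    data.frame(patient_id = pat$patient_id[i], t = tt,
               diameter = observe_diameter(true_diam[i, keep]),
               attenuation = cls$attenuation[i],
               spiculated = cls$spiculated[i],
               stringsAsFactors = FALSE)
  }))
  pat$followup_duration <- pmax(pat$followup_duration, pat$diagnosis_time,
                                vapply(split(obs$t, obs$patient_id)[pat$patient_id],
                                       max, numeric(1)))
  list(patients = pat, observations = obs)
}

generate_control_pool <- function(config, year_counts) {
  sizes <- ceiling(config$pool_factor * year_counts)
  n <- sum(sizes)
  pat <- sample_arm_covariates(n, config$control, config$age_range, "ctrl")
  pat$cancer <- FALSE
  pat$diagnosis_time <- NA_real_
  pat$diagnosis_year <- as.integer(rep(as.integer(names(year_counts)), sizes))
  pat$cancer_stage <- NA_character_

  bd <- config$baseline_diameter
  baseline <- rlnorm(n, bd$control_meanlog, bd$sdlog)
  cls <- sample_nodule_classes(n, config$attenuation_probs$control,
                               config$spiculated_p[["control"]])
  st <- config$screen_times
  jitter <- matrix(rnorm(n * length(st), 0, config$benign_jitter_sd),
                   nrow = n)
  obs <- do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(patient_id = pat$patient_id[i], t = st,
               diameter = observe_diameter(baseline[i] + jitter[i, ]),
               attenuation = cls$attenuation[i],
               spiculated = cls$spiculated[i],
               stringsAsFactors = FALSE)
  }))
  # a pool control must still be under follow-up in its candidate index year
  pat$followup_duration <- pmax(pat$followup_duration,
                                365 * pat$diagnosis_year, max(st))
  list(patients = pat, observations = obs)
}

#' Match controls to cases by diagnosis year
#'
#' Performs 1:1 nested case-control matching: within each stratum of the
#' cancer diagnosis year, controls are sampled from the pool without
#' replacement and each matched control inherits its case's diagnosis year
#' as index year.
#'
#' @param cases List with `patients` and `observations` data frames for the
#'   cancer cases.
#' @param control_pool Same structure for the candidate controls; pool
#'   patients carry a candidate `diagnosis_year`.
#' @param seed Integer seed making the pairing reproducible.
#' @return A list with matched `patients` (cases followed by their matched
#'   controls, with a shared `pair_id`) and the corresponding `observations`.
#' @export
match_case_control <- function(cases, control_pool, seed) {
  set.seed(as.integer(seed))
  cp <- cases$patients
  pool <- control_pool$patients
  chosen <- character(0)
  pair_of <- character(0)
  for (yr in sort(unique(cp$diagnosis_year))) {
    case_ids <- cp$patient_id[cp$diagnosis_year == yr]
    avail <- setdiff(pool$patient_id[pool$diagnosis_year == yr], chosen)
    if (length(avail) < length(case_ids))
      stop(sprintf(
        "control pool exhausted for diagnosis year %d: %d case(s), %d control(s)",
        yr, length(case_ids), length(avail)), call. = FALSE)
    pick <- if (length(avail) == 1) avail else
      sample(avail, length(case_ids))
    chosen <- c(chosen, pick)
    pair_of <- c(pair_of, setNames(case_ids, pick))
  }
  ctrl <- pool[match(chosen, pool$patient_id), ]
  ctrl$pair_id <- pair_of[ctrl$patient_id]
  cp$pair_id <- cp$patient_id
  patients <- rbind(cp[names(ctrl)], ctrl)
  rownames(patients) <- NULL
  obs <- rbind(cases$observations,
               control_pool$observations[
                 control_pool$observations$patient_id %in% chosen, ])
  rownames(obs) <- NULL
  list(patients = patients, observations = obs)
}

#' Stratified train/validation split
#'
#' Assigns each patient to the training or validation partition, stratified
#' by case/control status. The total training size is
#' `floor(train_fraction * n)`, allocated across strata by largest-remainder
#' apportionment, so the case share of each partition stays within one
#' patient of the overall share.
#'
#' @param cohort An `iss_cohort` (or a list with a `patients` data frame)
#'   whose partition is not yet set.
#' @param train_fraction Fraction in (0, 1) assigned to training.
#' @param seed Integer seed.
#' @return The cohort with a filled `partition` column
#'   (`"train"`/`"validation"`).
#' @export
split_train_validation <- function(cohort, train_fraction, seed) {
  if (!is.numeric(train_fraction) || train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must lie in (0, 1)", call. = FALSE)
  if (!is.null(cohort$patients$partition) &&
      !all(is.na(cohort$patients$partition)))
    stop("cohort partition is already set", call. = FALSE)
  set.seed(as.integer(seed))
  pat <- cohort$patients
  n_train <- floor(train_fraction * nrow(pat))
  strata <- split(seq_len(nrow(pat)), pat$cancer)
  quota <- vapply(strata, length, integer(1)) * train_fraction
  base <- floor(quota)
  extra <- n_train - sum(base)
  if (extra > 0) {
    ord <- order(quota - base, decreasing = TRUE)
    base[ord[seq_len(extra)]] <- base[ord[seq_len(extra)]] + 1
  }
  partition <- rep("validation", nrow(pat))
  for (s in names(strata)) {
    idx <- strata[[s]]
    k <- base[[s]]
    if (k > 0) {
      pick <- if (length(idx) == 1) idx else sample(idx, k)
      partition[pick] <- "train"
    }
  }
  cohort$patients$partition <- partition
  cohort
}

#' Generate a synthetic nested case-control screening cohort
#'
#' Simulates a matched case-control sample of lung-cancer screening
#' participants with up to three annual low-dose CT observations per
#' patient. Cases carry a malignant nodule whose true diameter grows
#' linearly at a patient-specific lognormal rate; the diagnosis time is the
#' first scheduled screen at which the true diameter reaches the trigger
#' threshold, or an interval-detection time drawn uniformly from the
#' configured window if no screen reaches it. Controls carry a benign
#' nodule whose observed diameter is the constant true diameter plus
#' Gaussian jitter. Controls are matched 1:1 to cases on diagnosis year and
#' the cohort is split into training and validation partitions stratified
#' by case status.
#'
#' @param config An [iss_config()] object.
#' @return An object of class `iss_cohort`: a list with `patients` and
#'   `observations` data frames and the generating `config`. `patients`
#'   carries one row per participant including the partition label;
#'   `observations` is long format, one row per screen.
#' @examples
#' cohort <- generate_cohort(iss_config(n_cases = 15, seed = 7))
#' table(cohort$patients$cancer, cohort$patients$partition)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "iss_config"))
  validate_iss_config(config)
  set.seed(config$seed)
  cases <- generate_cases(config)
  year_counts <- table(cases$patients$diagnosis_year)
  pool <- generate_control_pool(config, year_counts)
  cohort <- match_case_control(cases, pool, seed = config$seed + 1L)
  if (config$truncate_controls) {
    dt <- setNames(cohort$patients$diagnosis_time[cohort$patients$cancer],
                   cohort$patients$pair_id[cohort$patients$cancer])
    is_ctrl <- !cohort$patients$cancer
    lim <- setNames(dt[cohort$patients$pair_id[is_ctrl]],
                    cohort$patients$patient_id[is_ctrl])
    keep <- rep(TRUE, nrow(cohort$observations))
    m <- match(cohort$observations$patient_id, names(lim))
    keep[!is.na(m)] <- cohort$observations$t[!is.na(m)] <= lim[m[!is.na(m)]]
    cohort$observations <- cohort$observations[keep, ]
  }
  cohort <- split_train_validation(cohort, config$train_fraction,
                                   seed = config$seed + 2L)
  cohort$config <- config
  class(cohort) <- "iss_cohort"
  cohort
}

#' @export
print.iss_cohort <- function(x, ...) {
  pat <- x$patients
  cat("Synthetic screening cohort\n")
  cat(sprintf("  %d patients (%d cases, %d controls)\n", nrow(pat),
              sum(pat$cancer), sum(!pat$cancer)))
  if (!is.null(pat$partition))
    cat(sprintf("  partition: %d train / %d validation\n",
                sum(pat$partition == "train"),
                sum(pat$partition == "validation")))
  cat(sprintf("  %d nodule observations (%.1f per patient)\n",
              nrow(x$observations), nrow(x$observations) / nrow(pat)))
  invisible(x)
}

#' @export
summary.iss_cohort <- function(object, ...) {
  pat <- object$patients
  out <- data.frame(
    n = nrow(pat),
    mean_age = mean(pat$age),
    pct_male = 100 * mean(pat$sex == "male"),
    pct_current_smoker = 100 * mean(pat$smoking_status == "current"),
    median_pack_years = median(pat$pack_years),
    pct_family_history = 100 * mean(pat$family_history),
    median_followup_case = median(pat$followup_duration[pat$cancer]),
    median_followup_control = median(pat$followup_duration[!pat$cancer])
  )
  class(out) <- c("summary.iss_cohort", "data.frame")
  out
}
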