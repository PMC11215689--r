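#' Write a cohort to CSV
#'
#' Writes `patients.csv` (one row per patient; booleans coded 0/1, a
#' control's missing diagnosis time and stage as empty fields) and
#' `observations.csv` (long format, one row per screen; times in integer
#' days, 0 at the baseline screen) into `dir`.
#'
#' @param cohort An `iss_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the two file paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pat <- cohort$patients
  pat$family_history <- as.integer(pat$family_history)
  pat$cancer <- as.integer(pat$cancer)
  obs <- cohort$observations
  obs$spiculated <- as.integer(obs$spiculated)
  pf <- file.path(dir, "patients.csv")
  of <- file.path(dir, "observations.csv")
  utils::write.csv(pat, pf, row.names = FALSE, na = "")
  utils::write.csv(obs, of, row.names = FALSE, na = "")
  invisible(c(patients = pf, observations = of))
}

#' Read a cohort from CSV
#'
#' Inverse of [write_cohort()], with schema validation: a cancer patient
#' without a diagnosis time, a listed patient without observations, or
#' non-increasing observation times are rejected with the offending row or
#' patient named.
#'
#' @param dir Directory containing `patients.csv` and `observations.csv`.
#' @return An `iss_cohort`.
#' @export
read_cohort <- function(dir) {
  pat <- utils::read.csv(file.path(dir, "patients.csv"),
                         stringsAsFactors = FALSE, na.strings = c("NA", ""))
  obs <- utils::read.csv(file.path(dir, "observations.csv"),
                         stringsAsFactors = FALSE, na.strings = c("NA", ""))
  req <- c("patient_id", "age", "sex", "smoking_status", "pack_years",
           "family_history", "cancer", "diagnosis_time", "followup_duration")
  miss <- setdiff(req, names(pat))
  if (length(miss))
    stop(sprintf("patients.csv lacks column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  pat$family_history <- pat$family_history == 1
  pat$cancer <- pat$cancer == 1
  bad <- which(pat$cancer & is.na(pat$diagnosis_time))
  if (length(bad))
    stop(sprintf("patients.csv row %d: cancer patient '%s' lacks diagnosis_time",
                 bad[1], pat$patient_id[bad[1]]), call. = FALSE)
  obs$spiculated <- obs$spiculated == 1
  orphan <- setdiff(pat$patient_id, obs$patient_id)
  if (length(orphan))
    stop(sprintf("no observations for patient(s): %s",
                 paste(orphan, collapse = ", ")), call. = FALSE)
  for (id in unique(obs$patient_id)) {
    tt <- obs$t[obs$patient_id == id]
    if (is.unsorted(tt, strictly = TRUE))
      stop(sprintf("observations.csv: times for patient '%s' are not strictly increasing",
                   id), call. = FALSE)
  }
  structure(list(patients = pat, observations = obs, config = NULL),
            class = "iss_cohort")
}

#' Serialize a fitted policy to JSON
#'
#' Stores the variant, discount rate, reward weights, and per-stage
#' coefficient tables with their inference and feature-coding metadata
#' (formula, factor levels, column order), from which [read_policy()]
#' rebuilds a policy whose predictions are identical.
#'
#' @param policy A fitted `iss_policy`.
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_policy <- function(policy, path) {
  stages <- lapply(policy$stage_models, function(sm) {
    list(stage = sm$stage,
         formula_rhs = sm$formula_rhs,
         feature_names = sm$feature_names,
         xlevels = sm$xlevels,
         coefficients = as.list(sm$coefficients),
         se = as.list(sm$se),
         p_values = as.list(sm$p_values),
         sigma = sm$sigma, n = sm$n)
  })
  obj <- list(variant = policy$variant$name, gamma = policy$gamma,
              alpha = policy$alpha,
              weights = unclass(policy$weights),
              max_stages = policy$max_stages,
              n_episodes = policy$n_episodes,
              fitting_order = policy$fitting_order,
              stage_models = stages)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a fitted policy from JSON
#'
#' @param path JSON file written by [write_policy()].
#' @return An `iss_policy` whose predictions equal the original's.
#' @export
read_policy <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  stage_models <- lapply(obj$stage_models, function(sm) {
    tt <- delete_response(terms(as.formula(
      paste(".q_outcome", sm$formula_rhs))))
    attr(tt, ".Environment") <- baseenv()
    structure(list(
      stage = sm$stage,
      coefficients = unlist(sm$coefficients),
      se = unlist(sm$se),
      p_values = unlist(sm$p_values),
      sigma = sm$sigma, n = sm$n,
      terms = tt,
      formula_rhs = sm$formula_rhs,
      xlevels = lapply(sm$xlevels, unlist),
      feature_names = unlist(sm$feature_names)
    ), class = "iss_stage_model")
  })
  structure(list(variant = variant_spec(obj$variant),
                 stage_models = stage_models,
                 gamma = obj$gamma, alpha = obj$alpha,
                 weights = do.call(reward_weights, obj$weights),
                 max_stages = obj$max_stages,
                 fitting_order = unlist(obj$fitting_order),
                 n_episodes = obj$n_episodes),
            class = "iss_policy")
}

#' Rule-table JSON round trip
#'
#' @param table An `iss_rule_table`.
#' @param path JSON path.
#' @return Invisibly, `path`.
#' @export
write_rule_table <- function(table, path) {
  jsonlite::write_json(unclass(table), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_rule_table
#' @export
read_rule_table <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  rules <- lapply(obj$rules, function(r) {
    if (!is.null(r$attenuation)) r$attenuation <- unlist(r$attenuation)
    if (!is.null(r$stages)) r$stages <- as.integer(unlist(r$stages))
    for (f in c("dmin", "dmax"))
      if (!is.null(r[[f]])) r[[f]] <- as.numeric(r[[f]])
    r
  })
  rule_table(obj$name, rules, growth_threshold = obj$growth_threshold,
             provenance = if (is.null(obj$provenance)) "" else obj$provenance)
}

#' Run the full analysis pipeline on synthetic data
#'
#' End-to-end orchestration: generate the cohort, write it out, build the
#' training and validation episode banks, fit every requested policy-model
#' variant, evaluate adverse-event rates on both partitions, rank the
#' variants, and benchmark the best three against the rule-based guideline
#' tables with head-to-head and subgroup reports. All artifacts are written
#' under `out_dir` together with a machine-readable manifest (seed, file
#' hashes); rerunning with the same configuration reproduces every file
#' byte for byte.
#'
#' @param config An [iss_config()].
#' @param out_dir Output directory.
#' @param variants Character vector of variant names to fit.
#' @param weights [reward_weights()].
#' @param rule_tables Named list of benchmark rule tables.
#' @param n_benchmark Number of top-ranked variants entering the
#'   head-to-head benchmark.
#' @return Invisibly, a list with the cohort, fitted policies, rate table,
#'   ranking, head-to-head result, subgroup report and the manifest.
#' @export
run_pipeline <- function(config, out_dir,
                         variants = VARIANT_NAMES,
                         weights = reward_weights(),
                         rule_tables = default_rule_tables(),
                         n_benchmark = 3) {
  t0 <- proc.time()[["elapsed"]]
  log_stage <- function(fmt, ...) {
    message(sprintf("[issq %7.1fs] %s", proc.time()[["elapsed"]] - t0,
                    sprintf(fmt, ...)))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE))
  }

  log_stage("simulate: generating cohort (seed %d)", config$seed)
  cohort <- run_stage("simulate", generate_cohort(config))
  write_cohort(cohort, out_dir)

  log_stage("episodes: building episode banks")
  bank_train <- run_stage("episodes",
                          build_episode_bank(cohort, "train", weights))
  bank_valid <- run_stage("episodes",
                          build_episode_bank(cohort, "validation", weights))
  ep_out <- bank_train
  ep_out$spiculated1 <- as.integer(ep_out$spiculated1)
  ep_out$spiculated2 <- as.integer(ep_out$spiculated2)
  ep_out$spiculated3 <- as.integer(ep_out$spiculated3)
  ep_out$family_history <- as.integer(ep_out$family_history)
  ep_out$cancer <- as.integer(ep_out$cancer)
  utils::write.csv(ep_out, file.path(out_dir, "episodes.csv"),
                   row.names = FALSE, na = "")

  log_stage("fit: %d policy-model variants", length(variants))
  policies <- list()
  effects <- list()
  for (v in variants) {
    policies[[v]] <- run_stage(paste0("fit:", v),
                               qlearn_policy(bank_train, variant = v,
                                             weights = weights))
    write_policy(policies[[v]],
                 file.path(out_dir, sprintf("policy_%s.json", v)))
    eff <- effect_significance(policies[[v]])
    eff$variant <- v
    effects[[v]] <- eff
  }
  utils::write.csv(do.call(rbind, effects),
                   file.path(out_dir, "effects.csv"), row.names = FALSE)

  log_stage("evaluate: adverse-event rates")
  rates <- do.call(rbind, lapply(variants, function(v) {
    rbind(evaluate_policy_rates(policies[[v]], cohort, "train", name = v),
          evaluate_policy_rates(policies[[v]], cohort, "validation",
                                name = v))
  }))
  utils::write.csv(rates, file.path(out_dir, "rates.csv"),
                   row.names = FALSE)
  ranking <- rank_models(rates[rates$dataset == "validation", ])

  log_stage("benchmark: head-to-head on validation")
  top <- ranking$policy[seq_len(min(n_benchmark, nrow(ranking)))]
  contenders <- c(policies[top], rule_tables)
  for (nm in names(rule_tables))
    write_rule_table(rule_tables[[nm]],
                     file.path(out_dir, sprintf("rules_%s.json", nm)))
  h2h <- run_stage("benchmark",
                   head_to_head_optimal(contenders, cohort, "validation"))
  utils::write.csv(h2h$probabilities,
                   file.path(out_dir, "head_to_head.csv"), row.names = FALSE)
  subgroups <- subgroup_optimal_rates(h2h, cohort)
  utils::write.csv(subgroups, file.path(out_dir, "subgroups.csv"),
                   row.names = FALSE)

  files <- sort(setdiff(list.files(out_dir), "manifest.json"))
  manifest <- list(
    package = "issq",
    version = as.character(utils::packageVersion("issq")),
    seed = config$seed,
    n_cases = config$n_cases,
    variants = as.list(variants),
    benchmarked = as.list(top),
    files = lapply(setNames(files, files), function(f)
      unname(tools::md5sum(file.path(out_dir, f)))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  log_stage("done: %d files in %s", length(files) + 1, out_dir)
  invisible(list(cohort = cohort, policies = policies, rates = rates,
                 ranking = ranking, head_to_head = h2h,
                 subgroups = subgroups, manifest = manifest))
}
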