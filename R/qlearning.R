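VARIANT_NAMES <- c("D", "DN", "DP", "DNP", "Dd", "DdN", "DdP", "DdNP")

#' Policy-model variant specification
#'
#' Parses a variant name into its state-variable flags. The eight variants
#' combine the nodule diameter (always present) with the nodule appearance
#' block (`N`: attenuation and margin), the patient-information block (`P`:
#' age, sex, smoking status, pack-years, family history), and the choice of
#' diameter history coding: direct (the raw diameters observed so far) or
#' delta (`d`: the current diameter plus its rate of change in mm/day).
#'
#' @param name One of `"D"`, `"DN"`, `"DP"`, `"DNP"`, `"Dd"`, `"DdN"`,
#'   `"DdP"`, `"DdNP"`.
#' @return A list with `name`, `delta_mode`, `use_appearance`,
#'   `use_patient_info`.
#' @export
variant_spec <- function(name) {
  if (!name %in% VARIANT_NAMES)
    stop(sprintf("unknown policy-model variant '%s' (expected one of %s)",
                 name, paste(VARIANT_NAMES, collapse = ", ")), call. = FALSE)
  list(name = name,
       delta_mode = grepl("d", name, fixed = TRUE),
       use_appearance = grepl("N", name, fixed = TRUE),
       use_patient_info = grepl("P", name, fixed = TRUE))
}

ATTENUATION_LEVELS <- c("solid", "part_solid", "non_solid")
SEX_LEVELS <- c("male", "female")
SMOKING_LEVELS <- c("former", "current")
# reference action for the dummy coding: annual follow-up, the default
# behaviour under rule-based screening
ACTION_LEVELS <- c("F12", "DIAG", "F3", "END")

#' Assemble the feature frame for one decision stage
#'
#' Maps raw state values to the numeric/factor columns of a stage's linear
#' Q-function under a given variant. Diameter history enters from stage 2
#' onward, either as the previously observed decision-time diameters
#' (direct mode) or as the rate of change over the last decision interval
#' (delta mode); stage 1 uses the current diameter only in all variants.
#' Reference levels are solid attenuation, non-spiculated margin, male sex,
#' former smoker, and no family history.
#'
#' @param vars Data frame with columns `diameter`, `diam_prev`,
#'   `diam_first`, `delta`, `attenuation`, `spiculated`, and (for `P`
#'   variants) `age`, `sex`, `smoking_status`, `pack_years`,
#'   `family_history`. History columns may be `NA` at stage 1.
#' @param stage Decision stage (1-3).
#' @param variant A [variant_spec()] (or a variant name).
#' @return A data frame of model covariates with a deterministic column
#'   order.
#' @export
build_features <- function(vars, stage, variant) {
  if (is.character(variant)) variant <- variant_spec(variant)
  if (variant$delta_mode && stage == 1 && !is.null(vars$request_delta) &&
      any(vars$request_delta))
    stop("delta is undefined at stage 1", call. = FALSE)
  out <- data.frame(diameter = vars$diameter)
  if (stage >= 2) {
    if (variant$delta_mode) {
      out$delta <- vars$delta
    } else {
      out$diam_prev <- vars$diam_prev
      if (stage >= 3) out$diam_first <- vars$diam_first
    }
  }
  if (variant$use_appearance) {
    out$attenuation <- factor(vars$attenuation, levels = ATTENUATION_LEVELS)
    out$spiculated <- as.numeric(vars$spiculated)
  }
  if (variant$use_patient_info) {
    out$age <- vars$age
    out$sex <- factor(vars$sex, levels = SEX_LEVELS)
    out$smoking_status <- factor(vars$smoking_status, levels = SMOKING_LEVELS)
    out$pack_years <- vars$pack_years
    out$family_history <- as.numeric(vars$family_history)
  }
  out
}

# raw state columns for stage s of an episode bank (or bank-shaped frame)
bank_stage_vars <- function(bank, stage) {
  data.frame(
    diameter = bank[[paste0("diameter", stage)]],
    diam_prev = if (stage >= 2) bank[[paste0("diameter", stage - 1)]] else NA_real_,
    diam_first = bank[["diameter1"]],
    delta = if (stage >= 2) bank[[paste0("delta", stage)]] else NA_real_,
    attenuation = bank[[paste0("attenuation", stage)]],
    spiculated = bank[[paste0("spiculated", stage)]],
    age = if (!is.null(bank$age)) bank$age else NA_real_,
    sex = if (!is.null(bank$sex)) bank$sex else NA_character_,
    smoking_status = if (!is.null(bank$smoking_status)) bank$smoking_status
                     else NA_character_,
    pack_years = if (!is.null(bank$pack_years)) bank$pack_years else NA_real_,
    family_history = if (!is.null(bank$family_history)) bank$family_history
                     else NA,
    stringsAsFactors = FALSE
  )
}

stage_formula <- function(features) {
  as.formula(paste(".q_outcome ~ action * (",
                   paste(names(features), collapse = " + "), ")"))
}

# linear Q-value for each requested action at the given feature rows
predict_stage_q <- function(model, features, actions = ACTION_LEVELS) {
  qs <- sapply(actions, function(a) {
    df <- features
    df$action <- factor(a, levels = ACTION_LEVELS)
    df$.q_outcome <- 0
    mm <- model.matrix(model$terms, df, xlev = model$xlevels)
    drop(mm[, names(model$coefficients), drop = FALSE] %*%
           model$coefficients)
  })
  if (is.null(dim(qs))) qs <- matrix(qs, nrow = 1,
                                     dimnames = list(NULL, actions))
  qs
}

# argmax over actions with the fixed least-harm tie-break END > F12 > F3 > DIAG
argmax_action <- function(qrow, tol = 1e-9) {
  best <- max(qrow)
  tied <- names(qrow)[qrow >= best - tol]
  TIE_BREAK_ORDER[TIE_BREAK_ORDER %in% tied][1]
}

#' Fit one stage's linear Q-function
#'
#' Ordinary-least-squares fit of the stage Q-function
#' `Q_t(s, a) = beta + theta' s + action main effects + omega' (s x action)`
#' on the episode bank. The pseudo-outcome is the stage reward plus, for
#' episodes that continue past this stage, `gamma` times the maximum of the
#' next stage model's predicted Q over all actions at the realized next
#' state (model-free backward induction: no transition model is used). At
#' the final stage, or for terminal actions, the pseudo-outcome is the
#' stage reward alone.
#'
#' @param bank Episode bank from [build_episode_bank()].
#' @param stage Decision stage to fit.
#' @param next_model The already-fitted model for `stage + 1` (required for
#'   stages before the last).
#' @param variant [variant_spec()] or variant name.
#' @param gamma Discount rate (default 1: all stages weighted equally).
#' @param max_stages Decision horizon of the bank.
#' @return A list of class `iss_stage_model`: coefficient table with
#'   standard errors and p-values, the terms object and factor levels used
#'   for prediction, and the stage index.
#' @export
fit_stage <- function(bank, stage, next_model = NULL, variant, gamma = 1,
                      max_stages = 3) {
  if (is.character(variant)) variant <- variant_spec(variant)
  if (stage < max_stages && is.null(next_model))
    stop("next_model is required for stages before the last", call. = FALSE)
  idx <- bank$n_stages >= stage
  sub <- bank[idx, , drop = FALSE]
  y <- sub[[paste0("reward", stage)]]
  if (!is.null(next_model) && gamma != 0) {
    cont <- sub$n_stages > stage   # episode has a decision at stage + 1
    if (any(cont)) {
      nxt <- build_features(bank_stage_vars(sub[cont, , drop = FALSE],
                                            stage + 1), stage + 1, variant)
      vmax <- apply(predict_stage_q(next_model, nxt), 1, max)
      y[cont] <- y[cont] + gamma * vmax
    }
  }
  features <- build_features(bank_stage_vars(sub, stage), stage, variant)
  df <- features
  df$action <- factor(sub[[paste0("action", stage)]], levels = ACTION_LEVELS)
  df$.q_outcome <- y
  fit <- lm(stage_formula(features), data = df)
  cf <- coef(fit)
  if (anyNA(cf))
    stop(sprintf("rank-deficient design at stage %d; collinear columns: %s",
                 stage, paste(names(cf)[is.na(cf)], collapse = ", ")),
         call. = FALSE)
  fs <- suppressWarnings(summary(fit))  # zero-residual fits are legitimate here
  sm <- fs$coefficients
  tt <- terms(fit)
  attr(tt, ".Environment") <- baseenv()
  structure(list(
    stage = stage,
    coefficients = cf,
    se = sm[names(cf), "Std. Error"],
    p_values = sm[names(cf), "Pr(>|t|)"],
    sigma = fs$sigma,
    n = nrow(df),
    terms = delete_response(tt),
    formula_rhs = paste("~ action * (",
                        paste(names(features), collapse = " + "), ")"),
    xlevels = fit$xlevels,
    feature_names = names(features)
  ), class = "iss_stage_model")
}

delete_response <- function(tt) stats::delete.response(tt)

#' Fit a Q-learning screening policy
#'
#' The package's central fitting function. Fits backward-induction linear
#' Q-functions over the three decision stages of an episode bank: the final
#' stage is fitted first by regressing the stage reward on state, action
#' and state-action interaction terms; each earlier stage is then fitted on
#' the pseudo-outcome combining its own stage reward with the maximized
#' prediction of the later model at the realized next state. The greedy
#' policy (argmax of the fitted Q over actions, ties broken by the fixed
#' least-harm order END, F12, F3, DIAG) is available through
#' [predict.iss_policy()] / [recommend_sequence()].
#'
#' @param bank Episode bank from [build_episode_bank()].
#' @param variant Variant name (see [variant_spec()]); default the full
#'   delta model with appearance and patient information.
#' @param weights Reward weights used to build the bank (recorded for
#'   provenance; defaults to the bank's attribute).
#' @param gamma Discount rate; 1 weighs all stages equally, 0 reduces each
#'   stage fit to a myopic regression on its own stage reward.
#' @param alpha Significance level used by [effect_significance()].
#' @return An object of class `iss_policy` with components `variant`,
#'   `stage_models` (fitted last stage first is recorded in
#'   `fitting_order`), `gamma`, `weights`, `alpha`.
#' @examples
#' cohort <- generate_cohort(iss_config(n_cases = 20, seed = 3))
#' bank <- build_episode_bank(cohort, "train")
#' pol <- qlearn_policy(bank, variant = "Dd")
#' pol
#' @export
qlearn_policy <- function(bank, variant = "DdNP",
                          weights = attr(bank, "weights"),
                          gamma = 1, alpha = 0.05) {
  if (nrow(bank) == 0) stop("empty episode bank", call. = FALSE)
  spec <- variant_spec(if (is.character(variant)) variant else variant$name)
  if (is.null(weights)) weights <- reward_weights()
  max_stages <- attr(bank, "max_stages")
  if (is.null(max_stages)) max_stages <- max(bank$n_stages)
  stage_models <- vector("list", max_stages)
  nxt <- NULL
  for (s in rev(seq_len(max_stages))) {
    stage_models[[s]] <- fit_stage(bank, s, next_model = nxt,
                                   variant = spec, gamma = gamma,
                                   max_stages = max_stages)
    nxt <- stage_models[[s]]
  }
  structure(list(variant = spec, stage_models = stage_models,
                 gamma = gamma, weights = weights, alpha = alpha,
                 max_stages = max_stages,
                 fitting_order = rev(seq_len(max_stages)),
                 n_episodes = nrow(bank)),
            class = "iss_policy")
}

#' Greedy recommended action sequence
#'
#' Rolls the fitted policy forward for one patient: at each stage the
#' nodule state is interpolated from the observation series at the
#' scheduled decision time, the stage Q-function is evaluated for all four
#' actions, and the greedy action is taken (ties broken END, F12, F3,
#' DIAG). Recommendation stops at a terminal action (DIAG/END) or at the
#' stage horizon.
#'
#' @param policy A fitted [qlearn_policy()] or an [rule_table()] guideline
#'   policy.
#' @param series One patient's observation series (`t`, `diameter`,
#'   `attenuation`, `spiculated`).
#' @param covariates One-row data frame (or list) of patient covariates
#'   (needed for `P` variants).
#' @param ... Passed to methods.
#' @return Character vector of actions, always one of the legal scenarios.
#' @export
recommend_sequence <- function(policy, series, covariates = NULL, ...) {
  UseMethod("recommend_sequence")
}

#' @export
recommend_sequence.iss_policy <- function(policy, series, covariates = NULL,
                                          ...) {
  actions <- character(0)
  t_now <- 0
  t_prev <- NULL
  for (stage in seq_len(policy$max_stages)) {
    st <- interpolated_state(series, t_now, t_prev)
    vars <- data.frame(
      diameter = st$diameter,
      diam_prev = if (stage >= 2)
        diameter_at(series, t_prev) else NA_real_,
      diam_first = diameter_at(series, 0),
      delta = if (!is.null(st$delta)) st$delta else NA_real_,
      attenuation = st$attenuation, spiculated = st$spiculated,
      age = cov_field(covariates, "age"),
      sex = cov_field(covariates, "sex"),
      smoking_status = cov_field(covariates, "smoking_status"),
      pack_years = cov_field(covariates, "pack_years"),
      family_history = cov_field(covariates, "family_history"),
      stringsAsFactors = FALSE)
    feats <- build_features(vars, stage, policy$variant)
    q <- predict_stage_q(policy$stage_models[[stage]], feats)
    a <- argmax_action(q[1, ])
    actions <- c(actions, a)
    if (a %in% TERMINAL_ACTIONS) break
    t_prev <- t_now
    t_now <- t_now + ACTION_INTERVALS[[a]]
  }
  actions
}

cov_field <- function(covariates, field) {
  if (is.null(covariates) || is.null(covariates[[field]])) NA else
    covariates[[field]]
}

#' Recommended sequences for a cohort
#'
#' @param object A fitted `iss_policy`.
#' @param cohort An `iss_cohort`.
#' @param partition `"train"`, `"validation"`, or `"all"`.
#' @param ... Unused.
#' @return Data frame with `patient_id` and the recommended `scenario`
#'   string.
#' @export
predict.iss_policy <- function(object, cohort, partition = "all", ...) {
  recommend_cohort(object, cohort, partition)
}

recommend_cohort <- function(policy, cohort, partition = "all") {
  pat <- cohort$patients
  if (partition != "all") pat <- pat[pat$partition == partition, ]
  if (nrow(pat) == 0) stop("empty partition", call. = FALSE)
  obs_by_id <- split(cohort$observations, cohort$observations$patient_id)
  scen <- vapply(seq_len(nrow(pat)), function(i) {
    scenario_id(recommend_sequence(policy, obs_by_id[[pat$patient_id[i]]],
                                   pat[i, ]))
  }, character(1))
  data.frame(patient_id = pat$patient_id, scenario = scen,
             stringsAsFactors = FALSE)
}

#' State-variable effect significance report
#'
#' Summarizes, per stage and state variable, whether the variable's main
#' effect and its interaction with the action are statistically significant
#' in the fitted linear Q-functions. Variables coded by several dummy
#' columns (attenuation) are flagged significant if any of their
#' coefficients is.
#'
#' @param policy A fitted `iss_policy`.
#' @param alpha Significance level (defaults to the policy's).
#' @return Data frame with columns `stage`, `variable`, `main_p`,
#'   `main_significant`, `interaction_p`, `interaction_significant`.
#'   Variables absent from the variant (or stage) have no row; `main_p` is
#'   the smallest p-value in the variable's coefficient group.
#' @export
effect_significance <- function(policy, alpha = policy$alpha) {
  groups <- list(
    diameter = "diameter",
    diameter_history = c("diam_prev", "diam_first", "delta"),
    attenuation = paste0("attenuation", ATTENUATION_LEVELS[-1]),
    margin = "spiculated",
    age = "age", sex = "sexfemale",
    smoking_status = "smoking_statuscurrent",
    pack_years = "pack_years", family_history = "family_history")
  rows <- list()
  for (sm in policy$stage_models) {
    p <- sm$p_values
    for (v in names(groups)) {
      cols <- groups[[v]]
      main <- p[names(p) %in% cols]
      inter <- p[grepl(":", names(p)) &
                   sub(".*:", "", names(p)) %in% cols |
                 grepl(":", names(p)) &
                   sub(":.*", "", names(p)) %in% cols]
      if (length(main) == 0 && length(inter) == 0) next
      min_p <- function(p) {
        p <- p[!is.na(p)]
        if (length(p)) min(p) else NA_real_
      }
      rows[[length(rows) + 1]] <- data.frame(
        stage = sm$stage, variable = v,
        main_p = min_p(main),
        main_significant = isTRUE(min_p(main) < alpha),
        interaction_p = min_p(inter),
        interaction_significant = isTRUE(min_p(inter) < alpha),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$stage), ]
}

#' @export
print.iss_policy <- function(x, ...) {
  cat(sprintf("Linear Q-learning screening policy (variant %s)\n",
              x$variant$name))
  cat(sprintf("  %d stage models fitted backward (%s), gamma = %g\n",
              length(x$stage_models),
              paste(x$fitting_order, collapse = " -> "), x$gamma))
  cat(sprintf("  trained on %d episodes\n", x$n_episodes))
  cat(sprintf("  state blocks: diameter%s%s%s\n",
              if (x$variant$delta_mode) " (delta coding)" else " (direct coding)",
              if (x$variant$use_appearance) " + appearance" else "",
              if (x$variant$use_patient_info) " + patient info" else ""))
  invisible(x)
}

#' @export
coef.iss_policy <- function(object, ...) {
  lapply(setNames(object$stage_models,
                  paste0("stage",
                         vapply(object$stage_models,
                                function(m) as.numeric(m$stage), numeric(1)))),
         `[[`, "coefficients")
}

#' @export
summary.iss_policy <- function(object, ...) {
  tabs <- lapply(object$stage_models, function(sm) {
    data.frame(stage = sm$stage, term = names(sm$coefficients),
               estimate = unname(sm$coefficients),
               std_error = unname(sm$se), p_value = unname(sm$p_values),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, tabs)
  rownames(out) <- NULL
  structure(list(variant = object$variant$name, coefficients = out,
                 gamma = object$gamma, n_episodes = object$n_episodes),
            class = "summary.iss_policy")
}

#' @export
print.summary.iss_policy <- function(x, ...) {
  cat(sprintf("Q-learning policy, variant %s (gamma = %g, %d episodes)\n\n",
              x$variant, x$gamma, x$n_episodes))
  for (s in unique(x$coefficients$stage)) {
    cat(sprintf("Stage %d coefficients:\n", s))
    print(x$coefficients[x$coefficients$stage == s,
                         c("term", "estimate", "std_error", "p_value")],
          row.names = FALSE, digits = 4)
    cat("\n")
  }
  invisible(x)
}
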