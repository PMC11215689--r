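ACTIONS <- c("DIAG", "F3", "F12", "END")
TERMINAL_ACTIONS <- c("DIAG", "END")
CONTINUING_ACTIONS <- c("F3", "F12")
ACTION_INTERVALS <- c(F3 = 91, F12 = 365)
# fixed preference order used to break exact Q-value ties (least harm first)
TIE_BREAK_ORDER <- c("END", "F12", "F3", "DIAG")

#' Enumerate legal sequential screening scenarios
#'
#' All action sequences of at most `max_stages` decisions in which no action
#' follows an immediate work-up (DIAG) or a discontinuation (END): a
#' sequence either ends with a terminal action or runs to the stage horizon,
#' where it may end with any action. With the default three-stage horizon
#' there are exactly 22 scenarios.
#'
#' Sequences are returned in a canonical order: by length, then
#' lexicographically by the action order DIAG, F3, F12, END at each stage.
#'
#' @param max_stages Decision horizon (>= 1).
#' @return A list of character vectors of actions.
#' @examples
#' length(enumerate_scenarios())     # 22
#' length(enumerate_scenarios(1))    # 4
#' @export
enumerate_scenarios <- function(max_stages = 3) {
  if (max_stages < 1) stop("max_stages must be >= 1", call. = FALSE)
  out <- list()
  grow <- function(prefix) {
    for (a in ACTIONS) {
      seqa <- c(prefix, a)
      if (a %in% TERMINAL_ACTIONS || length(seqa) == max_stages) {
        out[[length(out) + 1]] <<- seqa
      } else {
        grow(seqa)
      }
    }
  }
  grow(character(0))
  out[order(lengths(out),
            vapply(out, function(s)
              paste(sprintf("%02d", match(s, ACTIONS)), collapse = ""),
              character(1)))]
}

scenario_id <- function(actions) paste(actions, collapse = "-")

parse_scenario <- function(id) strsplit(id, "-", fixed = TRUE)[[1]]

is_legal_sequence <- function(actions, max_stages = 3) {
  n <- length(actions)
  n >= 1 && n <= max_stages && all(actions %in% ACTIONS) &&
    all(actions[-n] %in% CONTINUING_ACTIONS)
}

#' Decision times of an action sequence
#'
#' The stage-1 decision occurs at `baseline_t`; each 3-month follow-up (F3)
#' advances the clock 91 days and each annual follow-up (F12) 365 days to
#' the next decision. Terminal actions occur at the current stage time.
#'
#' @param actions Character vector of actions (a legal sequence).
#' @param baseline_t Time of the first decision, days.
#' @return Numeric vector of decision times, one per stage.
#' @examples
#' schedule_visits(c("F12", "F3", "DIAG"))  # 0 365 456
#' @export
schedule_visits <- function(actions, baseline_t = 0) {
  if (!is_legal_sequence(actions))
    stop(sprintf("illegal action sequence: %s", scenario_id(actions)),
         call. = FALSE)
  cumsum(c(baseline_t,
           unname(ACTION_INTERVALS[actions[-length(actions)]])))
}

#' Label adverse screening events for an episode
#'
#' Applies the reward function's event definitions to one patient and one
#' action sequence: misdiagnosis is an immediate work-up (DIAG) for a
#' cancer-free patient; missed diagnosis is a discontinuation (END) for a
#' cancer patient; delayed diagnosis fires for a cancer patient whose
#' resolution time (the DIAG time if the sequence contains one, otherwise
#' the last visit time) strictly exceeds the ground-truth diagnosis time;
#' `n_tests` counts the F3/F12 follow-up scans.
#'
#' @param patient One-row data frame (or list) with `cancer` and, for
#'   cancer patients, `diagnosis_time`.
#' @param actions Legal action sequence.
#' @param visit_times Decision times from [schedule_visits()].
#' @return A list with `misdiagnosis`, `missed`, `delayed` (0/1) and
#'   `n_tests`.
#' @export
label_events <- function(patient, actions, visit_times) {
  cancer <- isTRUE(as.logical(patient$cancer))
  if (cancer && (is.null(patient$diagnosis_time) ||
                 is.na(patient$diagnosis_time)))
    stop("cancer patient lacks a ground-truth diagnosis_time", call. = FALSE)
  has_diag <- "DIAG" %in% actions
  resolution <- if (has_diag) visit_times[match("DIAG", actions)] else
    visit_times[length(visit_times)]
  list(
    misdiagnosis = as.integer(!cancer && has_diag),
    missed = as.integer(cancer && "END" %in% actions),
    delayed = as.integer(cancer && resolution > patient$diagnosis_time),
    n_tests = sum(actions %in% CONTINUING_ACTIONS)
  )
}

#' Per-stage reward decomposition
#'
#' Splits the episode's total reward across decision stages: every follow-up
#' scan (F3/F12) contributes its test penalty at its own stage, and the
#' final stage additionally carries the base reward minus the outcome
#' penalties. The stage rewards sum exactly to the total reward
#' `base - w_misdiag*misdiagnosis - w_missed*missed - w_delayed*delayed -
#' w_test*n_tests`; with a discount rate of 1 the total value is invariant
#' to this decomposition.
#'
#' @param flags Event labels from [label_events()].
#' @param actions Legal action sequence.
#' @param weights [reward_weights()].
#' @return Numeric vector of per-stage rewards.
#' @export
stage_rewards <- function(flags, actions, weights = reward_weights()) {
  n <- length(actions)
  r <- -weights$w_test * as.numeric(actions %in% CONTINUING_ACTIONS)
  r[n] <- r[n] + weights$base -
    weights$w_misdiag * flags$misdiagnosis -
    weights$w_missed * flags$missed -
    weights$w_delayed * flags$delayed
  r
}

total_reward <- function(flags, weights = reward_weights()) {
  weights$base - weights$w_misdiag * flags$misdiagnosis -
    weights$w_missed * flags$missed - weights$w_delayed * flags$delayed -
    weights$w_test * flags$n_tests
}

episode_states <- function(series, visit_times) {
  lapply(seq_along(visit_times), function(k) {
    interpolated_state(series, visit_times[k],
                       t_prev = if (k > 1) visit_times[k - 1] else NULL)
  })
}

#' Build the episode bank
#'
#' Crosses every patient in the requested partition with every legal
#' sequential scenario, interpolating the nodule state at each decision
#' time, labelling adverse events against the patient's ground truth, and
#' computing stage and total rewards. With the default three-stage horizon
#' each patient contributes 22 episodes.
#'
#' @param cohort An `iss_cohort`.
#' @param partition `"train"`, `"validation"`, or `"all"`.
#' @param weights [reward_weights()].
#' @param max_stages Decision horizon.
#' @return A data frame with one row per (patient, scenario) pair: scenario
#'   string, per-stage visit times, diameters, deltas and appearance
#'   classes, patient covariates, event flags, per-stage rewards and total
#'   reward. Carries the attribute `weights`.
#' @examples
#' cohort <- generate_cohort(iss_config(n_cases = 4, seed = 1))
#' bank <- build_episode_bank(cohort, "all")
#' nrow(bank)  # 8 patients x 22 scenarios
#' @export
build_episode_bank <- function(cohort, partition = "train",
                               weights = reward_weights(), max_stages = 3) {
  pat <- cohort$patients
  if (partition != "all") {
    if (is.null(pat$partition)) stop("cohort is not partitioned", call. = FALSE)
    pat <- pat[pat$partition == partition, ]
  }
  if (nrow(pat) == 0) stop("empty partition", call. = FALSE)
  obs_by_id <- split(cohort$observations, cohort$observations$patient_id)
  missing <- setdiff(pat$patient_id, names(obs_by_id))
  if (length(missing))
    stop(sprintf("missing observation series for: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)

  scenarios <- enumerate_scenarios(max_stages)
  sc_ids <- vapply(scenarios, scenario_id, character(1))
  visits <- lapply(scenarios, schedule_visits)

  n_sc <- length(scenarios)
  N <- nrow(pat) * n_sc
  col_num <- function() rep(NA_real_, N)
  col_chr <- function() rep(NA_character_, N)
  out <- list(patient_id = col_chr(), scenario = rep(sc_ids, nrow(pat)),
              n_stages = rep(lengths(scenarios), nrow(pat)))
  for (s in 1:max_stages) {
    out[[paste0("t", s)]] <- col_num()
    out[[paste0("action", s)]] <- col_chr()
    out[[paste0("diameter", s)]] <- col_num()
    out[[paste0("delta", s)]] <- col_num()
    out[[paste0("attenuation", s)]] <- col_chr()
    out[[paste0("spiculated", s)]] <- rep(NA, N)
    out[[paste0("reward", s)]] <- col_num()
  }
  for (nm in c("misdiagnosis", "missed", "delayed", "n_tests", "total_reward"))
    out[[nm]] <- col_num()

  all_t <- sort(unique(unlist(visits)))
  for (i in seq_len(nrow(pat))) {
    p <- pat[i, ]
    series <- obs_by_id[[p$patient_id]]
    # cache interpolated states at the handful of distinct decision times
    diam_cache <- setNames(diameter_at(series, all_t), all_t)
    app_cache <- lapply(setNames(all_t, all_t),
                        function(ti) appearance_at(series, ti))
    base_k <- (i - 1L) * n_sc
    for (j in seq_len(n_sc)) {
      k <- base_k + j
      acts <- scenarios[[j]]
      vt <- visits[[j]]
      fl <- label_events(p, acts, vt)
      sr <- stage_rewards(fl, acts, weights)
      out$patient_id[k] <- p$patient_id
      for (s in seq_along(acts)) {
        key <- as.character(vt[s])
        out[[paste0("t", s)]][k] <- vt[s]
        out[[paste0("action", s)]][k] <- acts[s]
        out[[paste0("diameter", s)]][k] <- diam_cache[[key]]
        if (s > 1) {
          out[[paste0("delta", s)]][k] <-
            (diam_cache[[key]] - diam_cache[[as.character(vt[s - 1])]]) /
            (vt[s] - vt[s - 1])
        }
        out[[paste0("attenuation", s)]][k] <- app_cache[[key]]$attenuation
        out[[paste0("spiculated", s)]][k] <- app_cache[[key]]$spiculated
        out[[paste0("reward", s)]][k] <- sr[s]
      }
      out$misdiagnosis[k] <- fl$misdiagnosis
      out$missed[k] <- fl$missed
      out$delayed[k] <- fl$delayed
      out$n_tests[k] <- fl$n_tests
      out$total_reward[k] <- sum(sr)
    }
  }
  bank <- as.data.frame(out, stringsAsFactors = FALSE)
  pm <- match(bank$patient_id, pat$patient_id)
  for (nm in c("age", "sex", "smoking_status", "pack_years",
               "family_history", "cancer"))
    bank[[nm]] <- pat[[nm]][pm]
  rownames(bank) <- NULL
  attr(bank, "weights") <- weights
  attr(bank, "max_stages") <- max_stages
  bank
}
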