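#' Construct a rule-based guideline policy table
#'
#' A rule table maps a nodule state (diameter, attenuation, margin, growth
#' flag, decision stage) to a recommended action through an ordered list of
#' predicates, first match wins. Each rule is a list with any of the
#' optional predicate fields `dmin` (mm, inclusive), `dmax` (mm,
#' exclusive), `attenuation` (character subset), `spiculated` (logical),
#' `growing` (logical), `stages` (integer subset), plus the mandatory
#' `action`. A nodule is "growing" when its diameter rate of change over
#' the last decision interval exceeds `growth_threshold`; the flag is false
#' at stage 1, where no rate is defined. The table must be exhaustive
#' (close it with a catch-all rule).
#'
#' @param name Policy name used in reports.
#' @param rules Ordered list of rule lists.
#' @param growth_threshold mm/day above which the growth flag fires.
#' @param provenance Free-text note on where the thresholds come from.
#' @return An object of class `iss_rule_table`.
#' @export
rule_table <- function(name, rules, growth_threshold = 1.5 / 365,
                       provenance = "") {
  stopifnot(is.character(name), length(rules) >= 1)
  for (i in seq_along(rules))
    if (is.null(rules[[i]]$action) || !rules[[i]]$action %in% ACTIONS)
      stop(sprintf("rule %d lacks a valid action", i), call. = FALSE)
  structure(list(name = name, rules = rules,
                 growth_threshold = growth_threshold,
                 provenance = provenance),
            class = "iss_rule_table")
}

#' Default guideline-style rule tables
#'
#' Two editable benchmark tables with size/attenuation/growth thresholds
#' loosely transcribed from published lung-cancer screening guidance (a
#' US-style and a China-style protocol). They are synthetic
#' approximations for benchmarking, not authoritative reproductions of any
#' guideline text; edit the JSON (see [write_rule_table()]) to change the
#' thresholds.
#'
#' @return Named list with elements `nccn_like` and `csed_like`.
#' @examples
#' tabs <- default_rule_tables()
#' rule_based_action(tabs$nccn_like,
#'                   list(diameter = 4, attenuation = "solid",
#'                        spiculated = FALSE, delta = NA), stage = 1)
#' @export
default_rule_tables <- function() {
  nccn <- rule_table(
    name = "NCCN-like",
    provenance = "synthetic approximation of a US-style size/growth protocol; non-authoritative",
    growth_threshold = 1.5 / 365,
    rules = list(
      list(dmin = 15, action = "DIAG"),
      list(dmin = 8, growing = TRUE, action = "DIAG"),
      list(growing = TRUE, action = "F3"),
      list(dmin = 8, spiculated = TRUE, action = "DIAG"),
      list(dmin = 8, action = "F3"),
      list(dmin = 6, attenuation = c("part_solid", "non_solid"),
           action = "F3"),
      list(dmax = 6, stages = 3L, action = "END"),
      list(action = "F12")))
  csed <- rule_table(
    name = "C-SED-like",
    provenance = "synthetic approximation of a China-style size/growth protocol; non-authoritative",
    growth_threshold = 2 / 365,
    rules = list(
      list(dmin = 15, action = "DIAG"),
      list(dmin = 10, growing = TRUE, action = "DIAG"),
      list(growing = TRUE, action = "F3"),
      list(dmin = 8, action = "F3"),
      list(dmax = 8, stages = 3L, action = "END"),
      list(action = "F12")))
  list(nccn_like = nccn, csed_like = csed)
}

#' Apply a rule table to one nodule state
#'
#' @param table An [rule_table()].
#' @param state List with `diameter` (mm), `attenuation`, `spiculated`, and
#'   `delta` (mm/day; `NA` at stage 1).
#' @param stage Decision stage.
#' @return The first matching rule's action.
#' @export
rule_based_action <- function(table, state, stage) {
  growing <- !is.na(state$delta) && !is.null(state$delta) &&
    state$delta > table$growth_threshold
  for (r in table$rules) {
    if (!is.null(r$dmin) && state$diameter < r$dmin) next
    if (!is.null(r$dmax) && state$diameter >= r$dmax) next
    if (!is.null(r$attenuation) && !(state$attenuation %in% r$attenuation))
      next
    if (!is.null(r$spiculated) && !identical(as.logical(state$spiculated),
                                             as.logical(r$spiculated))) next
    if (!is.null(r$growing) && !identical(growing, as.logical(r$growing)))
      next
    if (!is.null(r$stages) && !(stage %in% r$stages)) next
    return(r$action)
  }
  stop(sprintf("rule table '%s' is not exhaustive: no rule matches %.1f mm %s at stage %d",
               table$name, state$diameter, state$attenuation, stage),
       call. = FALSE)
}

#' @export
recommend_sequence.iss_rule_table <- function(policy, series,
                                              covariates = NULL, ...) {
  actions <- character(0)
  t_now <- 0
  t_prev <- NULL
  for (stage in 1:3) {
    st <- interpolated_state(series, t_now, t_prev)
    a <- rule_based_action(policy, st, stage)
    actions <- c(actions, a)
    if (a %in% TERMINAL_ACTIONS) break
    t_prev <- t_now
    t_now <- t_now + ACTION_INTERVALS[[a]]
  }
  actions
}

#' @export
print.iss_rule_table <- function(x, ...) {
  cat(sprintf("Rule-based screening policy '%s' (%d rules, growth threshold %.4g mm/day)\n",
              x$name, length(x$rules), x$growth_threshold))
  if (nzchar(x$provenance)) cat(" ", x$provenance, "\n")
  invisible(x)
}

policy_label <- function(policy) {
  if (inherits(policy, "iss_policy")) policy$variant$name
  else if (inherits(policy, "iss_rule_table")) policy$name
  else "policy"
}

#' Adverse-event rates of a screening policy
#'
#' Generates the recommended action sequence for every patient in a cohort
#' partition, labels the adverse events against ground truth, and reports
#' the misdiagnosis rate (denominator: cancer-free patients), and the
#' missed-diagnosis and delayed-diagnosis rates (denominator: cancer
#' patients), as percentages.
#'
#' @param policy A fitted `iss_policy` or an `iss_rule_table`.
#' @param cohort An `iss_cohort`.
#' @param partition `"train"`, `"validation"`, or `"all"`.
#' @param name Label for the report (defaults to the policy's own name).
#' @return One-row data frame with the policy name, dataset, the three
#'   rates, and the denominators.
#' @export
evaluate_policy_rates <- function(policy, cohort, partition = "validation",
                                  name = policy_label(policy)) {
  ev <- policy_events(policy, cohort, partition)
  cancer <- ev$cancer
  if (sum(!cancer) == 0 || sum(cancer) == 0)
    warning("a denominator is empty; the corresponding rate is NaN")
  data.frame(
    policy = name, dataset = partition,
    misdiagnosis_rate = 100 * sum(ev$misdiagnosis[!cancer]) / sum(!cancer),
    missed_rate = 100 * sum(ev$missed[cancer]) / sum(cancer),
    delayed_rate = 100 * sum(ev$delayed[cancer]) / sum(cancer),
    n_cancer = sum(cancer), n_cancer_free = sum(!cancer),
    stringsAsFactors = FALSE)
}

# per-patient recommendations plus event labels and schedule summaries
policy_events <- function(policy, cohort, partition) {
  recs <- recommend_cohort(policy, cohort, partition)
  pat <- cohort$patients[match(recs$patient_id, cohort$patients$patient_id), ]
  n <- nrow(recs)
  out <- data.frame(patient_id = recs$patient_id, scenario = recs$scenario,
                    cancer = pat$cancer, misdiagnosis = 0L, missed = 0L,
                    delayed = 0L, n_tests = 0L, diag_time = NA_real_,
                    resolution_time = NA_real_, total_reward = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    acts <- parse_scenario(recs$scenario[i])
    vt <- schedule_visits(acts)
    fl <- label_events(pat[i, ], acts, vt)
    out$misdiagnosis[i] <- fl$misdiagnosis
    out$missed[i] <- fl$missed
    out$delayed[i] <- fl$delayed
    out$n_tests[i] <- fl$n_tests
    out$diag_time[i] <- if ("DIAG" %in% acts) vt[match("DIAG", acts)] else
      NA_real_
    out$resolution_time[i] <- if ("DIAG" %in% acts)
      vt[match("DIAG", acts)] else vt[length(vt)]
    out$total_reward[i] <- total_reward(fl)
  }
  out
}

#' Rank policy models by their adverse-event rates
#'
#' Orders models by a max-then-mean composite: primarily the worst of the
#' three rates, ties broken by the mean rate, then by the input order
#' (stable). The three best models are flagged.
#'
#' @param rates Data frame of rows from [evaluate_policy_rates()].
#' @return The input with `composite`, `rank` and `top3` columns, ordered
#'   by rank.
#' @export
rank_models <- function(rates) {
  stopifnot(nrow(rates) >= 1)
  r3 <- as.matrix(rates[, c("misdiagnosis_rate", "missed_rate",
                            "delayed_rate")])
  composite <- apply(r3, 1, max)
  mean_rate <- rowMeans(r3)
  ord <- order(composite, mean_rate)
  out <- rates[ord, , drop = FALSE]
  out$composite <- composite[ord]
  out$rank <- seq_len(nrow(out))
  out$top3 <- out$rank <= 3
  rownames(out) <- NULL
  out
}

#' Head-to-head optimal-policy comparison
#'
#' Determines, for every patient in a cohort partition, which of the
#' candidate policies is optimal, allowing multiplicity on exact ties. For
#' a cancer patient, policies are ranked lexicographically by earliest
#' diagnostic work-up time (policies without DIAG rank after all that reach
#' one), then shortest total follow-up duration, then fewest follow-up
#' tests. For a cancer-free patient: shortest total follow-up, then fewest
#' tests, then absence of a diagnostic work-up.
#'
#' @param policies Named list of fitted policies and/or rule tables.
#' @param cohort An `iss_cohort`.
#' @param partition Cohort partition to compare on.
#' @return An object of class `iss_head_to_head`: a list with
#'   `per_patient` (logical optimality matrix plus patient id and cancer
#'   status) and `probabilities` (per-policy optimal-selection probability
#'   in percent; columns sum to >= 100 because of multiplicity).
#' @export
head_to_head_optimal <- function(policies, cohort, partition = "validation") {
  stopifnot(length(policies) >= 2)
  if (is.null(names(policies)) || any(!nzchar(names(policies))))
    names(policies) <- vapply(policies, policy_label, character(1))
  evs <- lapply(policies, policy_events, cohort = cohort,
                partition = partition)
  ids <- evs[[1]]$patient_id
  cancer <- evs[[1]]$cancer
  n <- length(ids)
  keys <- lapply(evs, function(e) {
    # lexicographic sort keys, smaller is better
    cbind(ifelse(cancer,
                 ifelse(is.na(e$diag_time), Inf, e$diag_time),
                 e$resolution_time),
          ifelse(cancer, e$resolution_time, e$n_tests),
          ifelse(cancer, e$n_tests, as.numeric(!is.na(e$diag_time))))
  })
  opt <- matrix(FALSE, n, length(policies),
                dimnames = list(NULL, names(policies)))
  for (i in seq_len(n)) {
    km <- t(vapply(keys, function(k) k[i, ], numeric(3)))
    best <- order(km[, 1], km[, 2], km[, 3])[1]
    opt[i, ] <- km[, 1] == km[best, 1] & km[, 2] == km[best, 2] &
      km[, 3] == km[best, 3]
  }
  probs <- data.frame(policy = colnames(opt),
                      optimal_pct = 100 * colMeans(opt),
                      stringsAsFactors = FALSE)
  rownames(probs) <- NULL
  structure(list(per_patient = data.frame(patient_id = ids, cancer = cancer,
                                          opt, stringsAsFactors = FALSE),
                 probabilities = probs, partition = partition),
            class = "iss_head_to_head")
}

#' @export
print.iss_head_to_head <- function(x, ...) {
  cat(sprintf("Head-to-head optimal-policy comparison (%s, n = %d)\n",
              x$partition, nrow(x$per_patient)))
  print(x$probabilities, row.names = FALSE, digits = 3)
  invisible(x)
}

default_groupings <- function(diameter_bins = c(0, 6, 8, 15, Inf),
                              age_cut = 65) {
  list(
    cancer = function(pat, base) ifelse(pat$cancer, "cancer", "cancer-free"),
    sex = function(pat, base) pat$sex,
    smoking_status = function(pat, base) pat$smoking_status,
    family_history = function(pat, base)
      ifelse(pat$family_history, "family history", "no family history"),
    age_group = function(pat, base)
      ifelse(pat$age < age_cut, sprintf("age < %d", age_cut),
             sprintf("age >= %d", age_cut)),
    baseline_diameter = function(pat, base)
      cut(base$diameter, diameter_bins, right = FALSE),
    attenuation = function(pat, base) base$attenuation,
    margin = function(pat, base)
      ifelse(base$spiculated, "spiculated", "non-spiculated"))
}

#' Optimal-selection probabilities by subgroup
#'
#' Splits the head-to-head result into patient and nodule subgroups and
#' reports each policy's optimal-selection probability per subgroup. Empty
#' subgroups are reported with `n = 0` rather than dropped.
#'
#' @param result An `iss_head_to_head`.
#' @param cohort The cohort the comparison was run on.
#' @param groupings Named list of functions `f(patients, baseline_state)`
#'   returning a group label per patient; defaults cover cancer status,
#'   demographics, baseline diameter bins, attenuation and margin.
#' @return Data frame with `grouping`, `group`, `policy`, `n`,
#'   `optimal_pct`.
#' @export
subgroup_optimal_rates <- function(result, cohort,
                                   groupings = default_groupings()) {
  pp <- result$per_patient
  pat <- cohort$patients[match(pp$patient_id, cohort$patients$patient_id), ]
  obs <- cohort$observations
  first_idx <- vapply(split(seq_len(nrow(obs)), obs$patient_id),
                      function(ix) ix[which.min(obs$t[ix])], integer(1))
  base <- obs[first_idx[pp$patient_id], ]
  pol_cols <- setdiff(names(pp), c("patient_id", "cancer"))
  rows <- list()
  for (g in names(groupings)) {
    lab <- groupings[[g]](pat, base)
    lvls <- if (is.factor(lab)) levels(lab) else
      sort(unique(stats::na.omit(lab)))
    for (lv in lvls) {
      idx <- which(!is.na(lab) & lab == lv)
      for (p in pol_cols) {
        rows[[length(rows) + 1]] <- data.frame(
          grouping = g, group = lv, policy = p, n = length(idx),
          optimal_pct = if (length(idx)) 100 * mean(pp[[p]][idx]) else
            NA_real_,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
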