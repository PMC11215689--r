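test_that("variant names map bijectively to state-variable flags", {
  flags <- t(vapply(c("D", "DN", "DP", "DNP", "Dd", "DdN", "DdP", "DdNP"),
                    function(v) {
                      s <- variant_spec(v)
                      c(s$delta_mode, s$use_appearance, s$use_patient_info)
                    }, logical(3)))
  expect_identical(anyDuplicated(flags), 0L)
  expect_identical(unname(flags["DdNP", ]), c(TRUE, TRUE, TRUE))
  expect_identical(unname(flags["D", ]), c(FALSE, FALSE, FALSE))
  expect_error(variant_spec("Dx"), "variant")
})

test_that("feature frames carry the variant's columns in a fixed order", {
  vars <- data.frame(diameter = 6, diam_prev = 4, diam_first = 4,
                     delta = 2 / 365, attenuation = "solid",
                     spiculated = FALSE, age = 60, sex = "male",
                     smoking_status = "former", pack_years = 40,
                     family_history = TRUE, stringsAsFactors = FALSE)
  expect_identical(names(build_features(vars, 1, "D")), "diameter")
  expect_identical(names(build_features(vars, 2, "D")),
                   c("diameter", "diam_prev"))
  expect_identical(names(build_features(vars, 3, "D")),
                   c("diameter", "diam_prev", "diam_first"))
  f <- build_features(vars, 2, "Dd")
  expect_identical(names(f), c("diameter", "delta"))
  expect_equal(f$delta, 2 / 365)
  # DNP at stage 2: diameter terms + appearance + the five patient covariates
  f <- build_features(vars, 2, "DNP")
  expect_identical(names(f),
                   c("diameter", "diam_prev", "attenuation", "spiculated",
                     "age", "sex", "smoking_status", "pack_years",
                     "family_history"))
  # stage 1 of a delta variant uses the current diameter only
  expect_identical(names(build_features(vars, 1, "DdNP")),
                   c("diameter", "attenuation", "spiculated", "age", "sex",
                     "smoking_status", "pack_years", "family_history"))
})

test_that("noiseless linear data are recovered to machine precision", {
  beta <- c(50, -30, 4, 12, 1.5, 2.5, -0.5, -3)
  bank <- synthetic_stage3_bank(400, beta, noise_sd = 0, seed = 2)
  sm <- fit_stage(bank, 3, variant = "D", max_stages = 3)
  est <- sm$coefficients[c("(Intercept)", "actionDIAG", "actionF3",
                           "actionEND", "diameter", "actionDIAG:diameter",
                           "actionF3:diameter", "actionEND:diameter")]
  expect_equal(unname(est), beta, tolerance = 1e-10)
})

test_that("noisy coefficient estimates cover the truth within 3 SE", {
  beta <- c(50, -30, 4, 12, 1.5, 2.5, -0.5, -3)
  ok <- vapply(1:100, function(r) {
    bank <- synthetic_stage3_bank(2000, beta, noise_sd = 5, seed = 100 + r)
    sm <- fit_stage(bank, 3, variant = "D", max_stages = 3)
    est <- sm$coefficients[c("(Intercept)", "actionDIAG", "actionF3",
                             "actionEND", "diameter",
                             "actionDIAG:diameter", "actionF3:diameter",
                             "actionEND:diameter")]
    all(abs(est - beta) <= 3 * sm$se[names(est)])
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("saturated fits equal per-cell mean pseudo-outcomes at every stage", {
  bank <- build_episode_bank(toy_discrete_cohort(), "train")
  pol <- qlearn_policy(bank, "Dd")

  # independent oracle: tabulated cell means with backward recursion
  cells3 <- bank[bank$n_stages == 3, ]
  key3 <- paste(cells3$diameter3, cells3$delta3, cells3$action3)
  q3_oracle <- tapply(cells3$reward3, key3, mean)
  q3_fit <- vapply(seq_len(nrow(cells3)), function(i) {
    f <- build_features(issq:::bank_stage_vars(cells3[i, ], 3), 3,
                        pol$variant)
    issq:::predict_stage_q(pol$stage_models[[3]], f,
                           actions = cells3$action3[i])[1, 1]
  }, numeric(1))
  expect_equal(unname(q3_fit), as.numeric(q3_oracle[key3]), tolerance = 1e-8)

  # stage-2 pseudo-outcomes from the tabulated stage-3 maxima
  rows2 <- bank[bank$n_stages >= 2, ]
  v3 <- vapply(seq_len(nrow(rows2)), function(i) {
    if (rows2$n_stages[i] == 2) return(0)
    st3 <- paste(rows2$diameter3[i], rows2$delta3[i])
    max(q3_oracle[paste(st3, c("DIAG", "F3", "F12", "END"))])
  }, numeric(1))
  y2 <- rows2$reward2 + v3
  key2 <- paste(rows2$diameter2, rows2$delta2, rows2$action2)
  q2_oracle <- tapply(y2, key2, mean)
  q2_fit <- vapply(seq_len(nrow(rows2)), function(i) {
    f <- build_features(issq:::bank_stage_vars(rows2[i, ], 2), 2,
                        pol$variant)
    issq:::predict_stage_q(pol$stage_models[[2]], f,
                           actions = rows2$action2[i])[1, 1]
  }, numeric(1))
  expect_equal(unname(q2_fit), as.numeric(q2_oracle[key2]), tolerance = 1e-8)
})

test_that("greedy policy attains the per-patient optimum on the noiseless instance", {
  ch <- toy_discrete_cohort()
  bank <- build_episode_bank(ch, "train")
  pol <- qlearn_policy(bank, "Dd")
  for (id in ch$patients$patient_id) {
    series <- ch$observations[ch$observations$patient_id == id, ]
    rec <- recommend_sequence(pol, series, ch$patients[
      ch$patients$patient_id == id, ])
    realized <- bank$total_reward[bank$patient_id == id &
                                    bank$scenario == paste(rec, collapse = "-")]
    expect_equal(realized, max(bank$total_reward[bank$patient_id == id]))
  }
  # immediate work-up strictly dominates for the malignant profile
  mal <- recommend_sequence(pol, ch$observations[
    ch$observations$patient_id == "malignant", ],
    ch$patients[2, ])
  expect_identical(mal, "DIAG")
  ben <- recommend_sequence(pol, ch$observations[
    ch$observations$patient_id == "benign", ], ch$patients[1, ])
  expect_identical(ben, "END")
})

test_that("recommended sequences are always legal scenarios", {
  ch <- small_cohort(n_cases = 10, seed = 6)
  bank <- build_episode_bank(ch, "train")
  ids <- vapply(enumerate_scenarios(), paste, character(1), collapse = "-")
  for (v in c("D", "DdNP")) {
    pol <- qlearn_policy(bank, v)
    recs <- predict(pol, ch, "all")
    expect_true(all(recs$scenario %in% ids))
  }
})

test_that("a zero discount reduces each stage to a myopic regression", {
  ch <- small_cohort(n_cases = 8, seed = 9)
  bank <- build_episode_bank(ch, "train")
  pol0 <- qlearn_policy(bank, "D", gamma = 0)
  # oracle: a plain regression of the stage reward on the same design
  sub <- bank[bank$n_stages >= 2, ]
  df <- data.frame(y = sub$reward2, diameter = sub$diameter2,
                   diam_prev = sub$diameter1,
                   action = factor(sub$action2,
                                   levels = c("F12", "DIAG", "F3", "END")))
  oracle <- coef(lm(y ~ action * (diameter + diam_prev), df))
  expect_equal(pol0$stage_models[[2]]$coefficients, oracle,
               tolerance = 1e-10)
})

test_that("episode row order does not change the fit", {
  ch <- small_cohort(n_cases = 8, seed = 10)
  bank <- build_episode_bank(ch, "train")
  set.seed(1)
  shuf <- bank[sample.int(nrow(bank)), ]
  attr(shuf, "weights") <- attr(bank, "weights")
  attr(shuf, "max_stages") <- 3
  p1 <- qlearn_policy(bank, "DdP")
  p2 <- qlearn_policy(shuf, "DdP")
  for (s in 1:3)
    expect_equal(p1$stage_models[[s]]$coefficients,
                 p2$stage_models[[s]]$coefficients, tolerance = 1e-9)
})

test_that("hand-built coefficients force the expected greedy sequence", {
  # data where END's reward dominates everywhere: Q(END) = 100, others 10
  beta <- c(10, 0, 0, 90, 0, 0, 0, 0)
  bank <- synthetic_stage3_bank(200, beta, noise_sd = 0, seed = 3)
  sm <- fit_stage(bank, 3, variant = "D", max_stages = 3)
  q <- issq:::predict_stage_q(sm, data.frame(diameter = 12,
                                             diam_prev = 12,
                                             diam_first = 12))
  expect_identical(issq:::argmax_action(q[1, ]), "END")
  # exact ties resolve by the least-harm preference order
  expect_identical(issq:::argmax_action(c(DIAG = 1, F3 = 1, F12 = 1, END = 1)),
                   "END")
  expect_identical(issq:::argmax_action(c(DIAG = 1, F3 = 1, F12 = 0, END = 0)),
                   "F3")
})

test_that("effect significance flags a real interaction and respects the variant", {
  set.seed(4)
  ch <- toy_discrete_cohort()
  bank <- build_episode_bank(ch, "train")
  # small noise keeps inference finite without hiding the strong delta signal
  for (s in 1:3) {
    col <- paste0("reward", s)
    ok <- !is.na(bank[[col]])
    bank[[col]][ok] <- bank[[col]][ok] + rnorm(sum(ok), 0, 0.5)
  }
  pol <- qlearn_policy(bank, "Dd")
  eff <- effect_significance(pol)
  hist23 <- eff[eff$variable == "diameter_history" & eff$stage >= 2, ]
  expect_true(all(hist23$interaction_significant))
  # variables absent from the variant produce no rows
  expect_false(any(eff$variable %in% c("age", "sex", "pack_years")))
  pol_d <- qlearn_policy(build_episode_bank(ch, "train"), "D")
  eff_d <- effect_significance(pol_d)
  expect_false(any(eff_d$variable %in% c("attenuation", "margin")))
})

test_that("pure-noise outcomes are flagged at roughly the nominal rate", {
  set.seed(5)
  flagged <- unlist(lapply(1:150, function(r) {
    bank <- synthetic_stage3_bank(150, rep(0, 8), noise_sd = 1,
                                  seed = 5000 + r)
    bank$reward3 <- rnorm(150)
    sm <- fit_stage(bank, 3, variant = "D", max_stages = 3)
    sm$p_values < 0.05
  }))
  expect_gt(mean(flagged), 0.02)
  expect_lt(mean(flagged), 0.09)
})
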