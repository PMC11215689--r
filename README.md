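# issq — individualized lung-cancer screening schedules via linear Q-learning

Rule-based guidelines for managing screen-detected pulmonary nodules map a
nodule's current size and appearance to one of a few follow-up options. They
are the same for every patient. `issq` implements a reinforcement-learning
alternative for researchers in screening policy and dynamic treatment
regimes: it learns *individualized screening schedules* — per-patient
sequences of up to three decisions among immediate diagnostic work-up
(`DIAG`), a repeat low-dose CT in 3 months (`F3`), an annual repeat CT
(`F12`), and discontinuation of screening (`END`) — from nested
case-control screening data, and benchmarks them against editable
guideline-style rule tables.

Because the cohorts this design needs (linked longitudinal nodule records
with cancer ground truth) are access-restricted, the package ships a
calibrated synthetic-cohort generator as a first-class module, so the whole
analysis is reproducible end to end without any data download.

## The model

Each complete schedule for a patient is scored with the reward function

    R = 100 − 70·misdiagnosis − 60·missed − 5·delayed − 10·n_tests

where *misdiagnosis* is `DIAG` for a cancer-free patient, *missed* is `END`
for a cancer patient, *delayed* means the schedule resolves after the
ground-truth diagnosis time, and `n_tests` counts the F3/F12 scans (0–3).
Under these weights every legal schedule scores between 10 and 100.

Legal schedules (nothing follows `DIAG` or `END`; at most three stages)
number exactly 22. Crossing them with every training patient yields an
episode bank on which stage-wise Q-functions are fitted by backward
induction with discount γ = 1:

    Q_t(s_t, a_t) = E[ R_t + γ · max_{a} Q*_{t+1}(s_{t+1}, a) ]

Each Q_t is an ordinary-least-squares linear model with state main effects,
action dummies, and a full state × action interaction block; the greedy
policy is π_t(s) = argmax_a Q_t(s, a). Eight state-variable variants are
fitted (`D`, `DN`, `DP`, `DNP` and their delta counterparts `Dd`, `DdN`,
`DdP`, `DdNP`), combining nodule diameter, its history either as raw past
diameters or as a growth rate (mm/day), nodule appearance (attenuation,
margin), and patient information (age, sex, smoking status, pack-years,
family history). Nodule state at arbitrary decision times comes from linear
interpolation/extrapolation of diameter and last-observation-carried-forward
appearance.

## Worked example

```r
library(issq)

cohort <- generate_cohort(iss_config(seed = 20240701))
summary(cohort)
#>     n mean_age pct_male pct_current_smoker median_pack_years pct_family_history
#> 1 616 62.77273 54.54545           50.48701             52.55           25.48701
#>   median_followup_case median_followup_control
#> 1                 1192                    2450

bank <- build_episode_bank(cohort, "train")
nrow(bank)
#> [1] 10164

pol <- qlearn_policy(bank, variant = "DdNP")
rbind(evaluate_policy_rates(pol, cohort, "train"),
      evaluate_policy_rates(pol, cohort, "validation"))
#>   policy    dataset misdiagnosis_rate missed_rate delayed_rate n_cancer n_cancer_free
#> 1   DdNP      train              1.73        12.6         5.63      231           231
#> 2   DdNP validation              0.00        11.7         3.90       77            77
```

The cohort is a 308-case / 308-control matched sample split 462/154 into
training and validation; the 462 training patients × 22 scenarios give the
10,164 episodes. The rates are percentages of cancer-free patients sent to
an unnecessary work-up (misdiagnosis) and of cancer patients whose cancer
the schedule discontinues past (missed) or resolves late (delayed).

Recommending a schedule for one patient, and benchmarking against the
shipped guideline-style rule tables:

```r
p1 <- cohort$patients[1, ]                       # a case: 9 → 14 → 19 mm
s1 <- cohort$observations[cohort$observations$patient_id == p1$patient_id, ]
recommend_sequence(pol, s1, p1)
#> [1] "F12"  "DIAG"

tabs <- default_rule_tables()                    # editable JSON rule tables
h <- head_to_head_optimal(c(list(DdNP = pol), tabs), cohort, "validation")
```

`head_to_head_optimal()` marks, per patient, every policy achieving the
lexicographically best outcome (earliest work-up / shortest follow-up), and
`subgroup_optimal_rates()` breaks the selection probabilities down by
patient and nodule subgroups. `run_pipeline()` executes the whole analysis
(simulate → episodes → fit all variants → evaluate → benchmark) into a
directory with a byte-reproducible manifest.

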