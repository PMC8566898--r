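test_that("correct/incorrect coding follows the contingency definitions", {
  trials <- data.frame(
    participant_id = 1, run = 1, condition = "control", block = 1,
    valence = c("gain", "gain", "loss", "loss", "neutral", "gain"),
    pair_id = "p", trial_in_pair = 1:6, side_of_correct = "left",
    stim_onset = 0, outcome_onset = 4,
    choice = c("correct", "incorrect", "correct", "incorrect", "correct",
               "missing"),
    outcome_r = c(0.5, 0, 0, -0.5, 0, NA))
  ct <- code_correct(trials)
  expect_equal(ct$correct, c(1, 0, 1, 0))  # neutral and missing dropped
  expect_equal(nrow(ct), 4)

  # coding depends only on the choice label, not the valence label
  flipped <- trials
  flipped$valence <- c("loss", "loss", "gain", "gain", "neutral", "loss")
  expect_equal(code_correct(flipped)$correct, ct$correct)

  bad <- trials
  bad$valence[1] <- "mystery"
  expect_error(code_correct(bad), "valence")

  empty <- trials[trials$valence == "neutral", ]
  expect_equal(nrow(code_correct(empty)), 0)
})

test_that("responder filter computes deltas and inclusion exactly", {
  reports <- data.frame(
    participant = rep(1:3, each = 4),
    condition = rep(rep(c("stress", "control"), each = 2), 3),
    block = rep(1:2, 6),
    rating = c(7, 7, 3, 5,   4, 4, 4, 4,   2, 4, 5, 5))
  f <- responder_filter(reports)
  expect_equal(f$delta$delta, c(3, 0, -2))
  expect_equal(f$included, 1)

  none <- reports
  none$rating <- 5
  expect_length(responder_filter(none)$included, 0)

  incomplete <- reports[reports$participant != 1 | reports$condition != "control", ]
  expect_error(responder_filter(incomplete), "participant 1")
})

test_that("manipulation ANOVA matches the sums-of-squares oracle", {
  set.seed(91)
  for (rep in 1:3) {
    reports <- expand.grid(participant = 1:10,
                           condition = c("stress", "control"), block = 1:2)
    reports$rating <- round(runif(nrow(reports), 1, 9))
    got <- manipulation_anova(reports)
    want <- oracle_rm_anova(reports)
    expect_equal(got$F, want$F, tolerance = 1e-8)
    expect_equal(got$pes, want$pes, tolerance = 1e-8)
  }

  # constructed pure condition effect (constant shift per subject):
  # interaction exactly null, condition effect with zero error variance
  reports <- expand.grid(participant = 1:8,
                         condition = c("stress", "control"), block = 1:2)
  base <- matrix(round(runif(16, 2, 6)), nrow = 8)  # subject x block
  reports$rating <- base[cbind(reports$participant, reports$block)] +
    2 * (reports$condition == "stress")
  got <- manipulation_anova(reports)
  expect_gt(got$F[got$effect == "condition"], 1e6)  # no subject x condition noise
  expect_equal(got$F[got$effect == "condition:block"], 0)

  # zero between-condition difference: condition F = 0
  reports$rating <- base[cbind(reports$participant, reports$block)]
  got0 <- manipulation_anova(reports)
  expect_equal(got0$F[got0$effect == "condition"], 0)

  expect_error(manipulation_anova(reports[-1, ]), "Unbalanced")
})

test_that("the trial-wise GLME detects gain-specific stress impairment", {
  coh <- cached_fixture("behav_cohort", {
    generate_cohort(effect_spec(n_participants = 12, responder_fraction = 1,
                                alpha_pos_control = 0.5,
                                alpha_pos_stress = 0.05,
                                beta_mean = 4, beta_sd = 0.5,
                                alpha_sd = 0.03, miss_prob = 0),
                    seed = 2101)
  })
  choices <- code_correct(do.call(rbind, coh$sessions))
  fit <- cached_fixture("behav_glme", performance_glme(choices))
  co <- fit$coefficients
  inter <- co[co$term == "conditionstress:valencegain", ]
  expect_lt(inter$estimate, 0)
  expect_lt(inter$p, 0.05)
  expect_true(inter$ci_lo < inter$estimate & inter$estimate < inter$ci_hi)
  expect_gt(fit$ranef_var, 0)

  gain <- posthoc_contrast(fit, "gain")
  loss <- posthoc_contrast(fit, "loss")
  expect_lt(gain$estimate, 0)
  expect_lt(gain$p, 0.05)
  expect_gt(loss$p, 0.05)
  # contrast algebra: simple effects recombine the fixed effects
  expect_equal(gain$estimate,
               sum(co$estimate[co$term %in%
                                 c("conditionstress",
                                   "conditionstress:valencegain")]))
  expect_equal(loss$estimate, co$estimate[co$term == "conditionstress"])

  # robustness: dropping one participant leaves the interaction sign
  sub <- choices[choices$participant != choices$participant[1], ]
  refit <- performance_glme(sub)
  expect_lt(refit$coefficients$estimate[
    refit$coefficients$term == "conditionstress:valencegain"], 0)
})

test_that("a chance-level generator yields null GLME coefficients", {
  coh <- generate_cohort(effect_spec(n_participants = 10,
                                     responder_fraction = 1,
                                     beta_mean = 0, beta_sd = 1e-6,
                                     alpha_sd = 0.03, miss_prob = 0),
                         seed = 2102)
  choices <- code_correct(do.call(rbind, coh$sessions))
  fit <- performance_glme(choices)
  co <- fit$coefficients
  nonint <- co[co$term != "(Intercept)", ]
  expect_true(all(abs(nonint$z) < 4))
  expect_error(performance_glme(choices[choices$participant == 1, ]),
               "2 participants")
})

test_that("learning curves aggregate correctly", {
  # perfect learner from trial 1: curve at 1 everywhere
  perfect <- expand.grid(participant = 1:5, condition = c("stress", "control"),
                         valence = c("gain", "loss"), block = 1:2, trial = 1:8)
  perfect$correct <- 1
  lc <- learning_curves(perfect)
  expect_true(all(lc$mean_correct == 1))
  expect_true(all(lc$sem == 0))
  expect_true(all(lc$n == 5))

  # means equal an independent tabulation on random data
  set.seed(93)
  rnd <- perfect
  rnd$correct <- rbinom(nrow(rnd), 1, 0.6)
  lc2 <- learning_curves(rnd)
  per_subj <- aggregate(correct ~ participant + condition + valence + trial,
                        rnd, mean)
  want <- tapply(per_subj$correct,
                 list(per_subj$condition, per_subj$valence, per_subj$trial),
                 mean)
  for (i in seq_len(nrow(lc2))) {
    expect_equal(lc2$mean_correct[i],
                 want[lc2$condition[i], lc2$valence[i],
                      as.character(lc2$trial[i])])
  }
  expect_error(learning_curves(perfect[0, ]), "Empty")
})
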