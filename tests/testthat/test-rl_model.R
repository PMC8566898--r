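test_that("prediction error and value update obey the model equations", {
  expect_equal(prediction_error(0.5, 0), 0.5)
  expect_equal(prediction_error(0.3, 0.3), 0)
  expect_equal(prediction_error(-0.5, 0.5), -1)
  p <- rl_params(0.4, 1, 3)
  expect_equal(update_value(0, 0.5, p), 0.2)
  expect_equal(update_value(0.37, 0, p), 0.37)
  expect_equal(update_value(0.5, -1, p), -0.5)
  expect_error(rl_params(1.2, 0.3, 1), "\\[0, 1\\]")
  expect_error(rl_params(0.2, 0.3, -1), "non-negative")
  expect_error(rl_params(NA, 0.3, 1), "finite")
})

test_that("softmax choice probabilities are symmetric, noise-limited and stable", {
  expect_equal(choice_probability(0.3, 0.3, 5), 0.5)
  expect_equal(choice_probability(0.5, -0.5, 0), 0.5)
  expect_equal(choice_probability(0.5, 0, 2), 1 / (1 + exp(-1)))
  # saturation without overflow at extreme drive
  expect_equal(choice_probability(0.5, -0.5, 1e6), 1)
  expect_equal(choice_probability(-0.5, 0.5, 1e6), 0)
})

test_that("hand-iterated win-win sequence reproduces the latent trace", {
  cfg <- task_config(pairs_per_block = 1, presentations = 2,
                     blocks_per_condition = 1, iti_min = 2, iti_max = 2)
  sched <- build_schedule(1, cfg, seed = 1)
  sched$choice <- "correct"
  sched$outcome_r <- 0.5
  sched <- sched[sched$condition == "control", ]  # one pair, two wins
  tr <- trace_from_choices(sched, rl_params(0.5, 0.5, 1))
  expect_equal(tr$delta, c(0.5, 0.25))
  expect_equal(tr$q_chosen, c(0, 0.25))
})

test_that("Q values and prediction errors stay within their bounds", {
  set.seed(99)
  for (rep in 1:15) {
    pars <- rl_params(runif(1), runif(1), runif(1, 0, 10))
    sim <- simulate_agent(build_schedule(rep, toy_config()), pars)
    fin <- !is.na(sim$delta)
    expect_true(all(sim$q_chosen[fin] >= -0.5 - 1e-12 &
                      sim$q_chosen[fin] <= 0.5 + 1e-12))
    expect_true(all(sim$delta[fin] >= -1 - 1e-12 & sim$delta[fin] <= 1 + 1e-12))
  }
})

test_that("replay round-trips a simulated run and rejects corrupt data", {
  pars <- list(stress = rl_params(0.2, 0.3, 3), control = rl_params(0.4, 0.3, 3))
  sim <- simulate_agent(build_schedule(2, seed = 4), pars, miss_prob = 0.01,
                        seed = 5)
  tr <- trace_from_choices(sim, pars)
  fin <- sim$valence %in% c("gain", "loss") & sim$choice != "missing"
  expect_equal(tr$delta, sim$delta[fin])
  expect_equal(tr$q_chosen, sim$q_chosen[fin])
  expect_equal(nrow(tr), sum(fin))

  # all-missing block yields an empty trace
  allmiss <- sim
  allmiss$choice <- "missing"
  allmiss$outcome_r <- NA_real_
  expect_equal(nrow(trace_from_choices(allmiss, pars)), 0)

  # outcome recorded on a missing trial is a data-integrity error
  bad <- sim
  i <- which(bad$valence == "gain")[1]
  bad$choice[i] <- "missing"
  expect_error(trace_from_choices(bad, pars), "integrity")
})

test_that("simulation is deterministic and respects policy limits", {
  pars <- rl_params(0.3, 0.3, 2)
  s <- build_schedule(1, toy_config(), seed = 6)
  expect_identical(simulate_agent(s, pars, seed = 10),
                   simulate_agent(s, pars, seed = 10))

  # beta = 0 agent chooses at chance on gain trials
  cfg <- task_config(pairs_per_block = 1, presentations = 500,
                     blocks_per_condition = 1, iti_min = 2, iti_max = 2)
  sim0 <- simulate_agent(build_schedule(1, cfg, seed = 1),
                         rl_params(0.5, 0.5, 0), seed = 2)
  rate <- mean(sim0$choice == "correct")
  expect_lt(abs(rate - 0.5), 3 * sqrt(0.25 / nrow(sim0)))

  # greedy limit: deterministic rewards, full learning, huge beta
  cfgd <- task_config(pairs_per_block = 1, presentations = 50,
                      blocks_per_condition = 1, p_good = 1,
                      iti_min = 2, iti_max = 2)
  simd <- simulate_agent(build_schedule(1, cfgd, seed = 3),
                         rl_params(1, 1, 20), seed = 4)
  first_win <- which(simd$outcome_r > 0)[1]
  later <- simd$choice[(first_win + 1):nrow(simd)]
  expect_gte(mean(later == "correct"), 0.95)  # near-greedy after full update
})

test_that("negative log-likelihood matches closed forms and the oracle", {
  cfg <- task_config(pairs_per_block = 1, presentations = 2,
                     blocks_per_condition = 1, iti_min = 2, iti_max = 2)
  one <- build_schedule(1, cfg, seed = 1)[1, ]
  one$choice <- "correct"
  one$outcome_r <- 0.5
  expect_equal(negative_log_likelihood(one, rl_params(0.5, 0.5, 3)), log(2))

  sim <- toy_dataset(11)
  n <- sum(sim$valence %in% c("gain", "loss") & sim$choice != "missing")
  expect_equal(negative_log_likelihood(sim, rl_params(0.4, 0.2, 0)),
               n * log(2))

  for (seed in c(21, 22, 23)) {
    d <- toy_dataset(seed)
    for (pars in list(c(0.4, 0.25, 2.5), c(0.9, 0.05, 7), c(0.1, 0.6, 0.4))) {
      expect_equal(
        negative_log_likelihood(d, rl_params(pars[1], pars[2], pars[3])),
        oracle_nll(d, pars[1], pars[2], pars[3]), tolerance = 1e-10)
    }
  }
})

test_that("equal learning rates reduce to single-alpha Rescorla-Wagner", {
  sim <- toy_dataset(31)
  tr <- trace_from_choices(sim, rl_params(0.35, 0.35, 2))
  ref <- oracle_single_alpha_trace(sim, 0.35)
  expect_equal(tr$q_chosen, ref$q_chosen)
  expect_equal(tr$delta, ref$delta)
})

test_that("the likelihood is centred on the generating parameters", {
  # On long data (2000 financial trials) the truth beats each +/-0.2
  # perturbation pair on average; single perturbations can win by sampling
  # noise, so the symmetric pair sum is the statistically stable check.
  cfg <- task_config(presentations = 250, iti_min = 2, iti_max = 2)
  truth <- c(0.4, 0.3, 3)
  for (seed in c(8, 18, 28)) {
    sim <- simulate_agent(build_schedule(1, cfg, seed = seed),
                          rl_params(truth[1], truth[2], truth[3]),
                          seed = seed + 1)
    base <- negative_log_likelihood(sim,
                                    rl_params(truth[1], truth[2], truth[3]))
    for (coord in 1:3) {
      pair_sum <- 0
      for (step in c(-0.2, 0.2)) {
        p <- truth
        p[coord] <- p[coord] + step
        if (coord < 3) p[coord] <- min(max(p[coord], 0), 1)
        pair_sum <- pair_sum +
          negative_log_likelihood(sim, rl_params(p[1], p[2], p[3])) - base
      }
      expect_gt(pair_sum, 0)
    }
  }
})
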