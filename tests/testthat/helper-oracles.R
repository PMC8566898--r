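# Independent oracles, deliberately written in a different style from the
# package implementation so they can catch shared mistakes.

# Step-by-step likelihood evaluator: explicit exponential softmax, per-pair
# value lists, data.frame row iteration.
oracle_nll <- function(data, alpha_pos, alpha_neg, beta) {
  q <- list()
  nll <- 0
  for (i in seq_len(nrow(data))) {
    row <- data[i, ]
    if (!(row$valence %in% c("gain", "loss"))) next
    if (is.na(row$choice) || row$choice == "missing") next
    if (is.null(q[[row$pair_id]])) {
      q[[row$pair_id]] <- c(correct = 0, incorrect = 0)
    }
    qq <- q[[row$pair_id]]
    num <- exp(beta * qq[["correct"]])
    den <- num + exp(beta * qq[["incorrect"]])
    p_correct <- num / den
    p <- if (row$choice == "correct") p_correct else 1 - p_correct
    nll <- nll - log(p)
    d <- row$outcome_r - qq[[row$choice]]
    a <- if (d > 0) alpha_pos else alpha_neg
    qq[[row$choice]] <- qq[[row$choice]] + a * d
    q[[row$pair_id]] <- qq
  }
  nll
}

# Single-learning-rate Rescorla-Wagner reference: returns per-trial
# (q_chosen, delta) for financial non-missing trials.
oracle_single_alpha_trace <- function(data, alpha) {
  q <- list()
  out <- NULL
  for (i in seq_len(nrow(data))) {
    row <- data[i, ]
    if (!(row$valence %in% c("gain", "loss"))) next
    if (is.na(row$choice) || row$choice == "missing") next
    if (is.null(q[[row$pair_id]])) {
      q[[row$pair_id]] <- c(correct = 0, incorrect = 0)
    }
    qq <- q[[row$pair_id]]
    d <- row$outcome_r - qq[[row$choice]]
    out <- rbind(out, data.frame(q_chosen = qq[[row$choice]], delta = d))
    q[[row$pair_id]][[row$choice]] <- qq[[row$choice]] + alpha * d
  }
  out
}

# Direct sums-of-squares decomposition for the 2x2 within-subject ANOVA.
oracle_rm_anova <- function(reports) {
  cell <- tapply(reports$rating,
                 list(reports$participant, reports$condition, reports$block),
                 mean)
  ns <- dim(cell)[1]
  grand <- mean(cell)
  s_m <- apply(cell, 1, mean)
  c_m <- apply(cell, 2, mean)
  b_m <- apply(cell, 3, mean)
  sc_m <- apply(cell, c(1, 2), mean)
  sb_m <- apply(cell, c(1, 3), mean)
  cb_m <- apply(cell, c(2, 3), mean)
  ss_c <- 2 * ns * sum((c_m - grand)^2)
  ss_b <- 2 * ns * sum((b_m - grand)^2)
  ss_cb <- ns * sum((cb_m - outer(c_m, rep(1, 2)) -
                       outer(rep(1, 2), b_m) + grand)^2)
  ss_sc <- 2 * sum((sc_m - outer(s_m, rep(1, 2)) -
                      outer(rep(1, ns), c_m) + grand)^2)
  ss_sb <- 2 * sum((sb_m - outer(s_m, rep(1, 2)) -
                      outer(rep(1, ns), b_m) + grand)^2)
  resid <- cell
  for (i in seq_len(ns)) for (j in 1:2) for (k in 1:2) {
    resid[i, j, k] <- cell[i, j, k] - sc_m[i, j] - sb_m[i, k] - cb_m[j, k] +
      s_m[i] + c_m[j] + b_m[k] - grand
  }
  ss_res <- sum(resid^2)
  df_err <- ns - 1
  data.frame(
    effect = c("condition", "block", "condition:block"),
    F = c((ss_c / 1) / (ss_sc / df_err),
          (ss_b / 1) / (ss_sb / df_err),
          (ss_cb / 1) / (ss_res / df_err)),
    pes = c(ss_c / (ss_c + ss_sc), ss_b / (ss_b + ss_sb),
            ss_cb / (ss_cb + ss_res)))
}

# Small task configurations used across tests.
toy_config <- function(presentations = 8, ...) {
  task_config(presentations = presentations, iti_min = 2, iti_max = 2, ...)
}

# A 20-ish-trial single-condition toy dataset for likelihood/oracle checks.
toy_dataset <- function(seed, presentations = 10) {
  sched <- build_schedule(1, toy_config(presentations = presentations),
                          seed = seed)
  sim <- simulate_agent(sched, rl_params(0.4, 0.25, 2.5), seed = seed + 1)
  sim[sim$condition == "control", ]
}

# Session-level cache so expensive fixtures are built once per test run.
.fixture_cache <- new.env(parent = emptyenv())
cached_fixture <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# Per-subject first-level slopes with the generating design reused (the
# generator round-trip used by recovery and power checks).
subject_slope_roundtrip <- function(session, true_slopes, spec, seed,
                                    participant) {
  bold <- generate_roi_bold(session, true_slopes, spec, tr = 2, seed = seed)
  fits <- lapply(bold, function(b) fit_ar1_glm(b$bold, b$design))
  first_level_slopes(fits, participant)
}

# One synthetic cohort's second-level battery under true-parameter traces.
cohort_second_level <- function(spec, seed, tr = 2) {
  coh <- generate_cohort(spec, seed = seed)
  incl <- responder_filter(coh$reports)$included
  set.seed(seed + 77)
  bseeds <- sample.int(.Machine$integer.max - 2L, length(incl))
  rows <- lapply(seq_along(incl), function(k) {
    i <- incl[k]
    subject_slope_roundtrip(coh$sessions[[i]],
                            coh$true_slopes[coh$true_slopes$participant == i, ],
                            spec, bseeds[k], i)
  })
  second_level_tests(do.call(rbind, rows))
}
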