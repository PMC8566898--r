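#' Dual-learning-rate Q-learning parameters
#'
#' The model carries separate learning rates for positive (`alpha_pos`) and
#' negative (`alpha_neg`) prediction errors — allowing asymmetric integration
#' of better- and worse-than-expected outcomes — and an inverse temperature
#' `beta` scaling how deterministically the higher-valued option is chosen
#' (`beta = 0` is random choice).
#'
#' @param alpha_pos Learning rate for positive prediction errors, in `[0, 1]`.
#' @param alpha_neg Learning rate for negative prediction errors, in `[0, 1]`.
#' @param beta Inverse temperature, `>= 0`.
#' @return A list of class `rl_params`.
#' @export
rl_params <- function(alpha_pos, alpha_neg, beta) {
  if (!all(is.finite(c(alpha_pos, alpha_neg, beta)))) {
    stop("All parameters must be finite.")
  }
  if (alpha_pos < 0 || alpha_pos > 1 || alpha_neg < 0 || alpha_neg > 1) {
    stop("Learning rates must lie in [0, 1].")
  }
  if (beta < 0) stop("`beta` must be non-negative.")
  structure(list(alpha_pos = alpha_pos, alpha_neg = alpha_neg, beta = beta),
            class = "rl_params")
}

#' Prediction error
#'
#' The difference between the received reinforcement and the current value of
#' the chosen stimulus: `delta = r - q_chosen`. Positive when the outcome is
#' better than expected.
#'
#' @param r Reinforcement in euro (one of `-0.5`, `0`, `0.5` in the default
#'   task).
#' @param q_chosen Current value of the chosen stimulus.
#' @return The prediction error `r - q_chosen`.
#' @export
prediction_error <- function(r, q_chosen) {
  r - q_chosen
}

#' Value update
#'
#' Rescorla–Wagner update of the chosen stimulus only:
#' `q_next = q + alpha * delta`, with `alpha = alpha_pos` when `delta > 0`
#' and `alpha = alpha_neg` when `delta < 0`. A zero prediction error leaves
#' the value unchanged for any parameters.
#'
#' @param q Current value of the chosen stimulus.
#' @param delta Prediction error for this trial.
#' @param params An [rl_params()] object.
#' @return The updated value.
#' @export
update_value <- function(q, delta, params) {
  if (delta == 0) return(q)
  alpha <- if (delta > 0) params$alpha_pos else params$alpha_neg
  q + alpha * delta
}

#' Softmax choice probability for a two-option pair
#'
#' Logistic softmax: `P(left) = 1 / (1 + exp(-beta * (q_left - q_right)))`.
#' Computed via `plogis`, so extreme `beta * dQ` saturates to 0/1 without
#' overflow; log-probabilities are available exactly through
#' `plogis(log.p = TRUE)` inside the likelihood.
#'
#' @param q_left,q_right Values of the two options.
#' @param beta Inverse temperature, `>= 0`.
#' @return Probability of choosing the left option.
#' @export
choice_probability <- function(q_left, q_right, beta) {
  stopifnot(beta >= 0)
  stats::plogis(beta * (q_left - q_right))
}

# Shared sequential engine. Walks trials in presentation order, holding one
# (Q_correct, Q_incorrect) state per pair (initialized at 0 when the pair is
# introduced). In "simulate" mode it samples choices and outcomes; in
# "replay" mode it consumes observed choices/outcomes. Neutral trials carry
# no financial reinforcement: no update, no trace entry, no likelihood term.
# Per-trial uniforms are pre-drawn in a fixed order (miss, choice, outcome)
# so simulation stays deterministic under a seed.
rl_walk <- function(schedule, params_by_cond, mode = c("simulate", "replay"),
                    config = attr(schedule, "config"), miss_prob = 0,
                    collect_nll = FALSE) {
  mode <- match.arg(mode)
  n <- nrow(schedule)
  valence <- schedule$valence
  condition <- schedule$condition
  pair_i <- as.integer(factor(schedule$pair_id,
                              levels = unique(schedule$pair_id)))
  n_pairs <- max(pair_i)
  qmat <- matrix(0, nrow = n_pairs, ncol = 2)
  choice <- schedule$choice
  outcome <- schedule$outcome_r
  q_chosen <- rep(NA_real_, n)
  delta <- rep(NA_real_, n)
  ap <- vapply(params_by_cond, `[[`, numeric(1), "alpha_pos")
  an <- vapply(params_by_cond, `[[`, numeric(1), "alpha_neg")
  be <- vapply(params_by_cond, `[[`, numeric(1), "beta")
  simulate <- mode == "simulate"
  if (simulate) {
    u_miss <- stats::runif(n)
    u_choice <- stats::runif(n)
    u_out <- stats::runif(n)
    p_good <- config$p_good
    magnitude <- config$magnitude
  }
  nll <- 0
  for (t in seq_len(n)) {
    cond <- condition[t]
    p <- pair_i[t]
    if (simulate) {
      if (miss_prob > 0 && u_miss[t] < miss_prob) {
        choice[t] <- "missing"
        outcome[t] <- NA_real_
        next
      }
      p_correct <- stats::plogis(be[[cond]] * (qmat[p, 1] - qmat[p, 2]))
      ch <- if (u_choice[t] < p_correct) "correct" else "incorrect"
      choice[t] <- ch
      outcome[t] <- if (valence[t] == "neutral") 0 else {
        p_hit <- if ((ch == "correct") == (valence[t] == "gain"))
          p_good else 1 - p_good
        if (u_out[t] < p_hit) {
          if (valence[t] == "gain") magnitude else -magnitude
        } else 0
      }
    } else {
      ch <- choice[t]
      if (is.na(ch) || ch == "missing") {
        if (!is.na(outcome[t])) {
          stop("Data integrity error: outcome recorded on a missing trial (row ",
               t, ").")
        }
        next
      }
    }
    if (valence[t] == "neutral") next
    chosen <- if (ch == "correct") 1L else 2L
    q <- qmat[p, chosen]
    if (collect_nll) {
      dq <- q - qmat[p, 3L - chosen]
      nll <- nll - stats::plogis(be[[cond]] * dq, log.p = TRUE)
    }
    q_chosen[t] <- q
    d <- outcome[t] - q
    delta[t] <- d
    if (d > 0) {
      qmat[p, chosen] <- q + ap[[cond]] * d
    } else if (d < 0) {
      qmat[p, chosen] <- q + an[[cond]] * d
    }
  }
  list(choice = choice, outcome_r = outcome, q_chosen = q_chosen,
       delta = delta, nll = nll)
}

# Preprocessed representation of one dataset for repeated likelihood
# evaluation during optimization: financial non-missing trials only, with
# integer pair/choice codes.
prep_ll_data <- function(data) {
  keep <- data$valence %in% c("gain", "loss") &
    !is.na(data$choice) & data$choice != "missing"
  d <- data[keep, , drop = FALSE]
  list(pair = as.integer(factor(d$pair_id, levels = unique(d$pair_id))),
       chosen = ifelse(d$choice == "correct", 1L, 2L),
       r = d$outcome_r, n = nrow(d))
}

# Tight-loop NLL on a prep_ll_data object under a single parameter set.
nll_prep <- function(prep, alpha_pos, alpha_neg, beta) {
  n <- prep$n
  if (n == 0) return(0)
  pair <- prep$pair
  chosen <- prep$chosen
  r <- prep$r
  qmat <- matrix(0, nrow = max(pair), ncol = 2)
  x <- numeric(n)  # beta * (Q_chosen - Q_unchosen) per trial
  for (t in seq_len(n)) {
    p <- pair[t]
    ch <- chosen[t]
    q <- qmat[p, ch]
    x[t] <- q - qmat[p, 3L - ch]
    d <- r[t] - q
    if (d > 0) {
      qmat[p, ch] <- q + alpha_pos * d
    } else if (d < 0) {
      qmat[p, ch] <- q + alpha_neg * d
    }
  }
  -sum(stats::plogis(beta * x, log.p = TRUE))
}

#' Simulate an agent performing the task
#'
#' Runs the dual-learning-rate model generatively over a schedule: values
#' start at 0 for every new pair, choices are sampled from the softmax over
#' the pair's current values, outcomes from the task contingencies, and
#' values are updated by the signed-learning-rate rule. Neutral trials yield
#' no reinforcement and no update. A per-trial latent trace (`q_chosen` at
#' stimulus time, `delta` at outcome time) is stored on financial trials.
#'
#' @param schedule An `rl_schedule` from [build_schedule()].
#' @param params Either one [rl_params()] (used for both conditions) or a
#'   named list `list(stress = , control = )` of `rl_params`.
#' @param miss_prob Per-trial probability of a missed response (no choice,
#'   no outcome, no update).
#' @param seed Optional integer seed for reproducibility.
#' @return The schedule with `choice`, `outcome_r`, `q_chosen`, `delta`
#'   filled in.
#' @export
simulate_agent <- function(schedule, params, miss_prob = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (inherits(params, "rl_params")) {
    params <- list(stress = params, control = params)
  }
  res <- rl_walk(schedule, params, mode = "simulate",
                 miss_prob = miss_prob)
  schedule$choice <- res$choice
  schedule$outcome_r <- res$outcome_r
  schedule$q_chosen <- res$q_chosen
  schedule$delta <- res$delta
  schedule
}

#' Replay observed choices to extract the latent trace
#'
#' Deterministically replays the learning rule over an observed sequence of
#' choices and outcomes under given parameters, returning the trial-wise
#' `Q_chosen` and prediction error `delta`. Missing trials produce no update
#' and no trace entry; an outcome recorded on a missing trial is a data
#' integrity error.
#'
#' @param schedule Schedule with observed `choice` and `outcome_r` columns.
#' @param params One [rl_params()] or a `list(stress=, control=)` pair.
#' @return A data frame (one row per non-missing financial trial) with the
#'   schedule's metadata plus `q_chosen` and `delta`.
#' @export
trace_from_choices <- function(schedule, params) {
  if (inherits(params, "rl_params")) {
    params <- list(stress = params, control = params)
  }
  res <- rl_walk(schedule, params, mode = "replay")
  schedule$q_chosen <- res$q_chosen
  schedule$delta <- res$delta
  keep <- schedule$valence %in% c("gain", "loss") &
    !is.na(schedule$choice) & schedule$choice != "missing"
  schedule[keep, , drop = FALSE]
}

#' Negative log-likelihood of observed choices
#'
#' Replays the learning rule over the observed sequence and accumulates
#' `-log P(observed choice)` under the softmax, over non-missing financial
#' (gain/loss) trials only. With `beta = 0` this equals `n * log(2)` exactly.
#'
#' @param schedule Schedule with observed `choice` and `outcome_r`; typically
#'   the trials of a single condition (values still evolve per pair in
#'   presentation order).
#' @param params One [rl_params()] or a `list(stress=, control=)` pair.
#' @return Scalar negative log-likelihood (`>= 0`; `Inf` if a zero-probability
#'   choice occurs at extreme `beta`).
#' @export
negative_log_likelihood <- function(schedule, params) {
  if (inherits(params, "rl_params")) {
    params <- list(stress = params, control = params)
  }
  rl_walk(schedule, params, mode = "replay", collect_nll = TRUE)$nll
}
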