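#' Fit the RL model to one subject-condition by multi-start bounded MLE
#'
#' Maximum-likelihood estimation of `(alpha_pos, alpha_neg, beta)` by
#' L-BFGS-B from multiple seeded uniform starting points within the bounds.
#' Multi-start guards against the multimodality of dual-learning-rate
#' likelihood surfaces. Deterministic given `seed`.
#'
#' @param data Trials of one subject and condition (schedule with observed
#'   `choice` and `outcome_r`; must contain at least one non-missing
#'   financial trial).
#' @param n_starts Number of random starts (default 20).
#' @param seed Master seed for the starting points.
#' @param lower,upper Parameter bounds, `(alpha_pos, alpha_neg, beta)`;
#'   defaults `[0,1] x [0,1] x [0,20]`.
#' @return A list of class `fit_result`: `params` ([rl_params()]), `nll`,
#'   `n_starts`, `converged` (TRUE if the best start converged),
#'   `best_start` (index), and `starts` (per-start NLL/convergence table).
#' @export
fit_condition <- function(data, n_starts = 20, seed = NULL,
                          lower = c(0, 0, 0), upper = c(1, 1, 20)) {
  usable <- data$valence %in% c("gain", "loss") &
    !is.na(data$choice) & data$choice != "missing"
  if (!any(usable)) stop("No usable (non-missing financial) trials to fit.")
  if (!is.null(seed)) set.seed(seed)
  prep <- prep_ll_data(data)
  obj <- function(p) {
    v <- nll_prep(prep, p[1], p[2], p[3])
    if (!is.finite(v)) 1e10 else v
  }
  starts <- matrix(stats::runif(3 * n_starts, min = rep(lower, each = n_starts),
                                max = rep(upper, each = n_starts)),
                   ncol = 3)
  res <- vector("list", n_starts)
  for (s in seq_len(n_starts)) {
    res[[s]] <- tryCatch(
      stats::optim(starts[s, ], obj, method = "L-BFGS-B",
                   lower = lower, upper = upper),
      error = function(e) list(par = starts[s, ], value = obj(starts[s, ]),
                               convergence = 99L))
  }
  nlls <- vapply(res, `[[`, numeric(1), "value")
  best <- which.min(nlls)
  par <- pmin(pmax(res[[best]]$par, lower), upper)
  structure(
    list(params = rl_params(par[1], par[2], par[3]),
         nll = nlls[best], n_starts = n_starts,
         converged = res[[best]]$convergence == 0L,
         best_start = best,
         starts = data.frame(start = seq_len(n_starts), nll = nlls,
                             convergence = vapply(res, `[[`, numeric(1),
                                                  "convergence"))),
    class = "fit_result")
}

#' Exhaustive grid evaluation of the likelihood surface
#'
#' Brute-force verification oracle: evaluates the negative log-likelihood on
#' a full parameter grid and returns the argmin together with the whole
#' surface for inspection. Intended to cross-check [fit_condition()] on small
#' datasets.
#'
#' @param data As in [fit_condition()].
#' @param alpha_pos,alpha_neg,beta Grid values for each parameter.
#' @return A list: `best` ([rl_params()] at the grid argmin), `nll` (its
#'   value) and `surface` (data frame of every grid point with its NLL).
#' @export
grid_oracle <- function(data, alpha_pos = seq(0, 1, length.out = 11),
                        alpha_neg = seq(0, 1, length.out = 11),
                        beta = seq(0, 20, length.out = 11)) {
  grid <- expand.grid(alpha_pos = alpha_pos, alpha_neg = alpha_neg,
                      beta = beta, KEEP.OUT.ATTRS = FALSE)
  if (nrow(grid) > 1e5) stop("Grid too large (> 1e5 points).")
  prep <- prep_ll_data(data)
  grid$nll <- vapply(seq_len(nrow(grid)), function(i) {
    nll_prep(prep, grid$alpha_pos[i], grid$alpha_neg[i], grid$beta[i])
  }, numeric(1))
  best <- which.min(grid$nll)
  list(best = rl_params(grid$alpha_pos[best], grid$alpha_neg[best],
                        grid$beta[best]),
       nll = grid$nll[best], surface = grid)
}

#' Parameter-recovery study
#'
#' Standard validation of the estimator: simulate full sessions from known
#' parameters, refit, and summarize per-parameter bias, RMSE and the Spearman
#' rank correlation between true and recovered values.
#'
#' @param design Data frame with one row per synthetic subject x condition:
#'   columns `participant`, `condition` (`"stress"`/`"control"`),
#'   `alpha_pos`, `alpha_neg`, `beta`.
#' @param config A [task_config()] for the simulated sessions.
#' @param n_starts Random starts per fit (default 10 to keep recovery studies
#'   fast; increase for final analyses).
#' @param seed Master seed; per-subject child seeds are derived from it.
#' @return A list: `fits` (true and recovered parameters per row) and
#'   `summary` (bias, RMSE, Spearman rho per parameter).
#' @export
recover_parameters <- function(design, config = task_config(), n_starts = 10,
                               seed = 1L) {
  if (nrow(design) == 0) {
    return(list(fits = design, summary = data.frame()))
  }
  set.seed(seed)
  subjects <- unique(design$participant)
  child <- sample.int(.Machine$integer.max - 1L, length(subjects))
  fits <- vector("list", nrow(design))
  k <- 0L
  for (i in seq_along(subjects)) {
    sid <- subjects[i]
    rows <- design[design$participant == sid, , drop = FALSE]
    pars <- list()
    for (j in seq_len(nrow(rows))) {
      pars[[rows$condition[j]]] <- rl_params(rows$alpha_pos[j],
                                             rows$alpha_neg[j], rows$beta[j])
    }
    if (is.null(pars$stress)) pars$stress <- pars$control
    if (is.null(pars$control)) pars$control <- pars$stress
    sched <- build_schedule(sid, config, seed = child[i])
    sim <- simulate_agent(sched, pars)
    for (j in seq_len(nrow(rows))) {
      cond <- rows$condition[j]
      fit <- fit_condition(sim[sim$condition == cond, , drop = FALSE],
                           n_starts = n_starts, seed = child[i] %% 1000000L + j)
      k <- k + 1L
      fits[[k]] <- data.frame(
        participant = sid, condition = cond,
        alpha_pos_true = rows$alpha_pos[j], alpha_neg_true = rows$alpha_neg[j],
        beta_true = rows$beta[j],
        alpha_pos_hat = fit$params$alpha_pos,
        alpha_neg_hat = fit$params$alpha_neg,
        beta_hat = fit$params$beta, nll = fit$nll,
        converged = fit$converged, stringsAsFactors = FALSE)
    }
  }
  fits <- do.call(rbind, fits[seq_len(k)])
  summ <- do.call(rbind, lapply(c("alpha_pos", "alpha_neg", "beta"), function(p) {
    true <- fits[[paste0(p, "_true")]]
    hat <- fits[[paste0(p, "_hat")]]
    data.frame(parameter = p, bias = mean(hat - true),
               rmse = sqrt(mean((hat - true)^2)),
               spearman = if (stats::sd(true) > 0)
                 stats::cor(true, hat, method = "spearman") else NA_real_)
  }))
  list(fits = fits, summary = summ)
}
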