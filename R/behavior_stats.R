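#' Code trial-wise choices as correct/incorrect
#'
#' On gain trials the correct stimulus is the one winning 0.5 euro with
#' probability 0.75; on loss trials the correct stimulus is the one avoiding
#' the loss with probability 0.75. Neutral trials (no correct response
#' exists) and missing trials are dropped.
#'
#' @param trials One or more participants' schedules with observed choices
#'   (rows may be concatenated across participants).
#' @return A `ChoiceTable` data frame: `participant`, `condition`, `valence`,
#'   `block`, `trial` (presentation count of the pair within its block,
#'   1..24 by default), `correct` (0/1).
#' @export
code_correct <- function(trials) {
  if (!all(trials$valence %in% c("gain", "loss", "neutral"))) {
    stop("Unknown valence label: ",
         paste(setdiff(unique(trials$valence),
                       c("gain", "loss", "neutral")), collapse = ", "))
  }
  keep <- trials$valence %in% c("gain", "loss") &
    !is.na(trials$choice) & trials$choice != "missing"
  t <- trials[keep, , drop = FALSE]
  data.frame(participant = t$participant_id, condition = t$condition,
             valence = t$valence, block = t$block, trial = t$trial_in_pair,
             correct = as.integer(t$choice == "correct"),
             stringsAsFactors = FALSE)
}

#' Responder filter on self-reported stress
#'
#' A participant is a stress responder — and enters the main analyses — iff
#' their mean self-reported stress rating is strictly higher in the stress
#' condition than in the control condition.
#'
#' @param reports A `SelfReportTable`: `participant`, `condition`, `block`,
#'   `rating` (1-9); one rating per participant x condition x block.
#' @return A list: `included` (participant ids with `delta > 0`) and `delta`
#'   (data frame of per-participant mean stress-minus-control differences).
#' @export
responder_filter <- function(reports) {
  for (p in unique(reports$participant)) {
    r <- reports[reports$participant == p, ]
    if (any(is.na(r$rating)) ||
        !all(c("stress", "control") %in% r$condition)) {
      stop("Missing ratings for participant ", p)
    }
  }
  m <- stats::aggregate(rating ~ participant + condition, reports, mean)
  wide <- stats::reshape(m, idvar = "participant", timevar = "condition",
                         direction = "wide")
  delta <- data.frame(participant = wide$participant,
                      delta = wide$rating.stress - wide$rating.control)
  list(included = delta$participant[delta$delta > 0], delta = delta)
}

#' Manipulation-check repeated-measures ANOVA
#'
#' 2 x 2 within-subject ANOVA of self-reported stress ratings with condition
#' (stress/control) and block (1/2) as factors; each factor has two levels so
#' no sphericity correction is required. Effect sizes reported as partial
#' eta-squared (SS_effect / (SS_effect + SS_error)).
#'
#' @param reports Self-report rows of the included participants only, fully
#'   crossed (one rating per participant x condition x block).
#' @return Data frame with one row per effect (`condition`, `block`,
#'   `condition:block`): `F`, `df1`, `df2`, `p`, `pes`.
#' @export
manipulation_anova <- function(reports) {
  counts <- table(reports$participant, reports$condition, reports$block)
  if (any(counts != 1)) {
    stop("Unbalanced design: need exactly one rating per participant x ",
         "condition x block.")
  }
  d <- data.frame(participant = factor(reports$participant),
                  condition = factor(reports$condition),
                  block = factor(reports$block), rating = reports$rating)
  fit <- stats::aov(rating ~ condition * block +
                      Error(participant / (condition * block)), data = d)
  s <- summary(fit)
  out <- lapply(c("condition", "block", "condition:block"), function(eff) {
    stratum <- s[[paste0("Error: participant:", eff)]][[1]]
    row <- trimws(rownames(stratum)) == eff
    err <- trimws(rownames(stratum)) == "Residuals"
    ss_eff <- stratum[row, "Sum Sq"]
    ss_err <- stratum[err, "Sum Sq"]
    Fv <- stratum[row, "F value"]
    pv <- stratum[row, "Pr(>F)"]
    if (ss_eff < 1e-12) {  # exactly null effect: F defined as 0
      Fv <- 0
      pv <- 1
    }
    data.frame(effect = eff, F = Fv, df1 = stratum[row, "Df"],
               df2 = stratum[err, "Df"], p = pv,
               pes = if (ss_eff < 1e-12) 0 else ss_eff / (ss_eff + ss_err))
  })
  do.call(rbind, out)
}

#' Trial-wise mixed-effects logistic regression of choice accuracy
#'
#' Fits `correct ~ condition + valence + block + trial + condition:valence`
#' with a random intercept per participant and a logit link, via
#' `lme4::glmer`. Treatment coding with control and loss as reference
#' levels, so the `conditionstress:valencegain` coefficient is the stress
#' effect on gain accuracy relative to loss; under stress-impaired gain
#' learning it is negative. Block and trial enter as numeric covariates.
#'
#' @param choices A `ChoiceTable` from [code_correct()] with at least two
#'   participants and both conditions and valences present.
#' @return A list of class `glme_result`: `model` (the `glmerMod`),
#'   `coefficients` (estimates with Wald 95% CIs and p-values),
#'   `ranef_var` (random-intercept variance), `separation` flag.
#' @export
performance_glme <- function(choices) {
  if (length(unique(choices$participant)) < 2) {
    stop("Need at least 2 participants for a mixed-effects fit.")
  }
  if (!all(c("stress", "control") %in% choices$condition) ||
      !all(c("gain", "loss") %in% choices$valence)) {
    stop("Both conditions and both valences must be present.")
  }
  d <- data.frame(
    correct = choices$correct,
    condition = factor(choices$condition, levels = c("control", "stress")),
    valence = factor(choices$valence, levels = c("loss", "gain")),
    block = as.numeric(choices$block), trial = as.numeric(choices$trial),
    participant = factor(choices$participant))
  model <- lme4::glmer(
    correct ~ condition + valence + block + trial + condition:valence +
      (1 | participant),
    data = d, family = stats::binomial("logit"),
    control = lme4::glmerControl(calc.derivs = FALSE))
  est <- lme4::fixef(model)
  se <- sqrt(diag(as.matrix(stats::vcov(model))))
  z <- est / se
  coefs <- data.frame(
    term = names(est), estimate = est, se = se, z = z,
    p = 2 * stats::pnorm(-abs(z)),
    ci_lo = est - 1.96 * se, ci_hi = est + 1.96 * se,
    row.names = NULL)
  structure(
    list(model = model, coefficients = coefs,
         ranef_var = unname(lme4::VarCorr(model)$participant[1, 1]),
         separation = any(abs(est) > 10),
         n_obs = nrow(d)),
    class = "glme_result")
}

#' Planned post-hoc contrast: stress vs control within one valence
#'
#' Linear-hypothesis (Wald) test of the simple effect of condition within the
#' given valence, built from the fixed-effect estimates and their covariance
#' — the contrast-matrix approach to post-hoc tests on a fitted mixed model.
#'
#' @param fit A `glme_result` from [performance_glme()].
#' @param valence `"gain"` or `"loss"`.
#' @return Data frame: contrast `estimate` (log-odds stress - control), `F`
#'   (1 numerator df Wald statistic), `df1`, `df2`, `p`.
#' @export
posthoc_contrast <- function(fit, valence = c("gain", "loss")) {
  valence <- match.arg(valence)
  est <- lme4::fixef(fit$model)
  V <- as.matrix(stats::vcov(fit$model))
  cvec <- stats::setNames(numeric(length(est)), names(est))
  cvec["conditionstress"] <- 1
  if (valence == "gain") {
    if (!"conditionstress:valencegain" %in% names(est)) {
      stop("Interaction term absent: contrast inestimable.")
    }
    cvec["conditionstress:valencegain"] <- 1
  }
  effect <- sum(cvec * est)
  v <- drop(t(cvec) %*% V %*% cvec)
  if (v <= 0) stop("Contrast inestimable (non-positive variance).")
  Fstat <- effect^2 / v
  df2 <- fit$n_obs - length(est)
  data.frame(valence = valence, estimate = effect, F = Fstat, df1 = 1,
             df2 = df2, p = stats::pf(Fstat, 1, df2, lower.tail = FALSE))
}

#' Learning curves by condition and valence
#'
#' For each trial index (presentation count of a pair within its block), the
#' fraction of correct choices is first averaged within participant (over
#' blocks), then summarized across participants as mean and SEM.
#'
#' @param choices A `ChoiceTable` from [code_correct()].
#' @return Data frame: `condition`, `valence`, `trial`, `mean_correct`,
#'   `sem`, `n` (participants contributing).
#' @export
learning_curves <- function(choices) {
  if (nrow(choices) == 0) stop("Empty choice table.")
  per_subj <- stats::aggregate(
    correct ~ participant + condition + valence + trial, choices, mean)
  agg <- stats::aggregate(
    correct ~ condition + valence + trial, per_subj,
    function(x) c(mean = mean(x),
                  sem = stats::sd(x) / sqrt(length(x)),
                  n = length(x)))
  data.frame(condition = agg$condition, valence = agg$valence,
             trial = agg$trial, mean_correct = agg$correct[, "mean"],
             sem = agg$correct[, "sem"], n = agg$correct[, "n"],
             stringsAsFactors = FALSE)
}
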