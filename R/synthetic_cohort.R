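#' Effect specification for the synthetic cohort generator
#'
#' Defines the statistical structure of a simulated study: cohort size and
#' responder fraction, the per-condition learning-parameter distributions
#' (stress lowers the positive-error learning rate), self-report means on the
#' 1-9 scale, and the BOLD ground truth — the prediction-error modulation
#' slope per valence in the control condition, the multiplicative blunting
#' factor applied to stress slopes (1 = no blunting, 0 = stress slope
#' removed), between-subject slope variability, AR(1) noise, and an optional
#' coupling that makes blunting increase with a participant's self-reported
#' stress responsivity.
#'
#' @param n_participants Cohort size.
#' @param responder_fraction Fraction of participants whose self-reported
#'   stress is higher under stress than control.
#' @param alpha_pos_control,alpha_pos_stress Mean positive-PE learning rate
#'   per condition.
#' @param alpha_neg Mean negative-PE learning rate (both conditions).
#' @param alpha_sd Between-subject sd of learning rates (clamped to [0, 1]).
#' @param beta_mean,beta_sd Inverse-temperature distribution (clamped to
#'   [0.1, 20]).
#' @param report_control,report_stress Mean self-report ratings (1-9 scale)
#'   in control blocks and — for responders — in stress blocks.
#' @param report_sd Rating noise sd before rounding/clamping to 1..9.
#' @param slope_control_gain,slope_control_loss Ground-truth PE-modulation
#'   slopes (arbitrary units) in the control condition.
#' @param blunting_gain,blunting_loss Stress blunting factors in [0, 1]
#'   multiplying the control slope.
#' @param slope_sd Between-subject sd of control slopes.
#' @param q_slope Ground-truth Q-modulator slope at stimulus onset.
#' @param stim_amp,out_amp Stick amplitudes of stimulus/outcome responses.
#' @param baseline BOLD baseline (intercept) in arbitrary units.
#' @param rho AR(1) coefficient of the BOLD noise.
#' @param noise_sd Innovation sd of the AR(1) noise.
#' @param coupling Strength in [0, 1] of the link between self-reported
#'   stress responsivity and blunting (0 = none).
#' @param blunting_pos,blunting_neg Optional sign-specific stress blunting:
#'   when not `NA`, the stress-condition BOLD response to prediction errors
#'   becomes piecewise linear, scaling the positive-PE part of the (centered)
#'   modulation by `blunting_pos` and the negative part by `blunting_neg`
#'   while the control condition keeps the full linear slope. Overrides
#'   `blunting_gain`/`blunting_loss` for BOLD generation. Defaults `NA`
#'   (ordinary linear blunting).
#' @param miss_prob Per-trial probability of a missed response.
#' @param seed Master seed used when none is passed to the generator.
#' @return A list of class `effect_spec`.
#' @export
effect_spec <- function(n_participants = 37, responder_fraction = 23 / 37,
                        alpha_pos_control = 0.40, alpha_pos_stress = 0.20,
                        alpha_neg = 0.30, alpha_sd = 0.10,
                        beta_mean = 3, beta_sd = 1,
                        report_control = 3, report_stress = 5,
                        report_sd = 1,
                        slope_control_gain = 1.0, slope_control_loss = 1.0,
                        blunting_gain = 0.3, blunting_loss = 0.3,
                        slope_sd = 0.3, q_slope = 0.3,
                        stim_amp = 0.5, out_amp = 1.0, baseline = 100,
                        rho = 0.3, noise_sd = 1.0,
                        coupling = 0, miss_prob = 0.002,
                        blunting_pos = NA_real_, blunting_neg = NA_real_,
                        seed = 1L) {
  if (responder_fraction < 0 || responder_fraction > 1) {
    stop("`responder_fraction` must lie in [0, 1].")
  }
  if (blunting_gain < 0 || blunting_gain > 1 ||
      blunting_loss < 0 || blunting_loss > 1) {
    stop("Blunting factors must lie in [0, 1].")
  }
  if (noise_sd <= 0 || report_sd < 0 || slope_sd < 0 || alpha_sd < 0) {
    stop("Standard deviations must be positive.")
  }
  if (abs(rho) >= 1) stop("`rho` must satisfy |rho| < 1.")
  for (bf in c(blunting_pos, blunting_neg)) {
    if (!is.na(bf) && (bf < 0 || bf > 1)) {
      stop("Sign-specific blunting factors must lie in [0, 1].")
    }
  }
  spec <- as.list(environment())
  structure(spec, class = "effect_spec")
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Generate a synthetic behavioural cohort with self-reports
#'
#' For each participant: a randomized task schedule, per-condition learning
#' parameters drawn around the spec means (stress lowers the mean
#' positive-PE learning rate), choices simulated from the dual-learning-rate
#' model, and block-wise self-report ratings constructed so that exactly
#' `round(responder_fraction * n)` participants have strictly higher mean
#' stress than control ratings. Ground-truth BOLD slopes per condition x
#' valence are drawn here too, so [generate_roi_bold()] and test assertions
#' share one ground truth. Fully deterministic given the seed.
#'
#' @param spec An [effect_spec()].
#' @param config A [task_config()].
#' @param seed Integer seed (defaults to `spec$seed`).
#' @return A list of class `rl_cohort`: `spec`, `config`, `sessions` (list
#'   of simulated schedules), `params` (true RL parameters per participant x
#'   condition), `reports` (self-report table), `responder` (logical by
#'   participant), `true_slopes` (participant x condition x valence BOLD
#'   ground truth), `seed`.
#' @export
generate_cohort <- function(spec = effect_spec(), config = task_config(),
                            seed = spec$seed) {
  set.seed(seed)
  n <- spec$n_participants
  n_resp <- round(spec$responder_fraction * n)
  responder <- rep(FALSE, n)
  responder[sample.int(n, n_resp)] <- TRUE
  child <- sample.int(.Machine$integer.max - 1L, n)
  sessions <- vector("list", n)
  params <- reports <- slopes <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(child[i])
    pars <- list()
    for (cond in c("stress", "control")) {
      ap_mean <- if (cond == "stress") spec$alpha_pos_stress else
        spec$alpha_pos_control
      pars[[cond]] <- rl_params(
        clamp(stats::rnorm(1, ap_mean, spec$alpha_sd), 0, 1),
        clamp(stats::rnorm(1, spec$alpha_neg, spec$alpha_sd), 0, 1),
        clamp(stats::rnorm(1, spec$beta_mean, spec$beta_sd), 0.1, 20))
    }
    sched <- build_schedule(i, config)
    sessions[[i]] <- simulate_agent(sched, pars, miss_prob = spec$miss_prob)
    params[[i]] <- do.call(rbind, lapply(c("stress", "control"), function(cond)
      data.frame(participant = i, condition = cond,
                 alpha_pos = pars[[cond]]$alpha_pos,
                 alpha_neg = pars[[cond]]$alpha_neg,
                 beta = pars[[cond]]$beta)))
    reports[[i]] <- make_reports(i, responder[i], spec)
  }
  reports <- do.call(rbind, reports)
  # ground-truth BOLD slopes; responsivity coupling uses the realized
  # self-report difference
  deltas <- responder_filter(reports)$delta
  for (i in seq_len(n)) {
    set.seed(child[i] + 1L)
    di <- deltas$delta[deltas$participant == i]
    rows <- list()
    for (val in c("gain", "loss")) {
      ctrl <- stats::rnorm(1, spec[[paste0("slope_control_", val)]],
                           spec$slope_sd)
      blunt <- spec[[paste0("blunting_", val)]]
      if (spec$coupling > 0) {
        blunt <- clamp(blunt * (1 - spec$coupling * max(di, 0) / 8), 0, 1)
      }
      rows[[val]] <- data.frame(
        participant = i, valence = val,
        condition = c("control", "stress"),
        slope = c(ctrl, ctrl * blunt))
    }
    slopes[[i]] <- do.call(rbind, rows)
  }
  structure(
    list(spec = spec, config = config, sessions = sessions,
         params = do.call(rbind, params), reports = reports,
         responder = responder, true_slopes = do.call(rbind, slopes),
         seed = seed),
    class = "rl_cohort")
}

# Block-wise 1-9 ratings with the responder status enforced exactly:
# responders end with mean(stress) > mean(control), non-responders with
# mean(stress) <= mean(control), via deterministic fix-ups after sampling.
make_reports <- function(id, is_responder, spec) {
  draw <- function(mu) clamp(round(stats::rnorm(2, mu, spec$report_sd)), 1, 9)
  control <- draw(spec$report_control)
  stress <- draw(if (is_responder) spec$report_stress else spec$report_control)
  if (is_responder) {
    while (mean(stress) <= mean(control)) {
      if (max(stress) < 9) stress[which.min(stress)] <- stress[which.min(stress)] + 1
      else control[which.max(control)] <- control[which.max(control)] - 1
    }
  } else if (mean(stress) > mean(control)) {
    tmp <- stress; stress <- control; control <- tmp
  }
  data.frame(participant = id,
             condition = rep(c("stress", "control"), each = 2),
             block = c(1, 2, 1, 2), rating = c(stress, control))
}

#' Generate ROI BOLD series from a participant's own design
#'
#' Builds the primary design matrix per run from the participant's latent
#' trace and composes `Y = X b + AR(1) noise`, with the ground-truth
#' prediction-error modulator slopes taken per condition x valence from
#' `true_slopes` (stress slopes already carry the blunting factor), fixed
#' stick amplitudes for stimulus/outcome responses, the Q-modulator slope,
#' zero drift, and the baseline on the intercept.
#'
#' @param session A simulated schedule (one participant, trace filled in).
#' @param true_slopes The participant's rows of a cohort's `true_slopes`.
#' @param spec An [effect_spec()].
#' @param tr Repetition time in seconds.
#' @param seed Optional seed for the noise.
#' @return A list with one element per run: `bold` (numeric series),
#'   `design` (the `roi_design` used), `n_scans`.
#' @export
generate_roi_bold <- function(session, true_slopes, spec, tr = 2,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  runs <- sort(unique(session$run))
  out <- vector("list", length(runs))
  for (k in seq_along(runs)) {
    rd <- session[session$run == runs[k], , drop = FALSE]
    des <- build_design(rd, tr = tr, model = "primary")
    b <- stats::setNames(numeric(ncol(des$X)), colnames(des$X))
    b[des$groups$stimulus] <- spec$stim_amp
    b[des$groups$outcome] <- spec$out_amp
    b[des$groups$q_mod] <- spec$q_slope
    sign_split <- !is.na(spec$blunting_pos) || !is.na(spec$blunting_neg)
    extra <- numeric(des$n_scans)
    for (nm in des$groups$pe_mod) {
      parts <- strsplit(nm, "_")[[1]]  # outPE_<cond>_<val>
      cond <- parts[2]; val <- parts[3]
      sl <- true_slopes$slope[true_slopes$condition == cond &
                                true_slopes$valence == val]
      if (length(sl) != 1) stop("Ground-truth slope missing for ", nm)
      if (sign_split && cond == "stress") {
        # piecewise PE response: scale the positive/negative parts of the
        # centered modulation separately, starting from the control slope
        bp <- if (is.na(spec$blunting_pos)) 1 else spec$blunting_pos
        bn <- if (is.na(spec$blunting_neg)) 1 else spec$blunting_neg
        ctrl <- true_slopes$slope[true_slopes$condition == "control" &
                                    true_slopes$valence == val]
        sel <- rd$condition == cond & rd$valence == val &
          !is.na(rd$choice) & rd$choice != "missing"
        dc <- rd$delta[sel] - mean(rd$delta[sel])
        amp <- ctrl * (bp * pmax(dc, 0) + bn * pmin(dc, 0))
        u <- stick_column(rd$outcome_onset[sel], amp, des$n_scans, tr)
        extra <- extra + convolve_hrf(u, canonical_hrf(tr))
        b[nm] <- 0
      } else {
        b[nm] <- sl
      }
    }
    if ("missing" %in% names(b)) b["missing"] <- spec$out_amp / 2
    b["intercept"] <- spec$baseline
    noise <- if (spec$rho == 0) {
      stats::rnorm(des$n_scans, sd = spec$noise_sd)
    } else {
      as.numeric(stats::arima.sim(list(ar = spec$rho), des$n_scans,
                                  sd = spec$noise_sd))
    }
    out[[k]] <- list(bold = as.numeric(des$X %*% b) + extra + noise,
                     design = des, n_scans = des$n_scans)
  }
  out
}

#' Write a self-contained end-to-end fixture to disk
#'
#' Produces one directory the full pipeline can run on: BIDS-style events
#' files and ROI BOLD TSVs per participant and run, a self-report CSV, and a
#' ground-truth JSON (true parameters, slopes, responder status). Regenerated
#' with the same seed, the files are byte-identical.
#'
#' @param dir Output directory.
#' @param spec An [effect_spec()].
#' @param config A [task_config()].
#' @param seed Integer seed.
#' @param tr Repetition time for the BOLD series.
#' @return The cohort object, invisibly; files under `dir`.
#' @export
end_to_end_fixture <- function(dir, spec = effect_spec(),
                               config = task_config(), seed = spec$seed,
                               tr = 2) {
  cohort <- generate_cohort(spec, config, seed)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed + 500000L)
  bold_seeds <- sample.int(.Machine$integer.max - 1L, spec$n_participants)
  for (i in seq_len(spec$n_participants)) {
    prefix <- sprintf("sub-%02d", i)
    write_events(cohort$sessions[[i]], dir, prefix)
    ts <- cohort$true_slopes[cohort$true_slopes$participant == i, ]
    bold <- generate_roi_bold(cohort$sessions[[i]], ts, spec, tr = tr,
                              seed = bold_seeds[i])
    for (k in seq_along(bold)) {
      write_roi_tsv(bold[[k]]$bold,
                    file.path(dir, sprintf("%s_run-%d_roi.tsv", prefix, k)))
    }
  }
  utils::write.csv(cohort$reports, file.path(dir, "self_reports.csv"),
                   row.names = FALSE)
  truth <- list(seed = seed, spec = unclass(spec),
                params = cohort$params, true_slopes = cohort$true_slopes,
                responder = cohort$responder)
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(cohort)
}
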