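#' Pipeline run configuration
#'
#' Bundles everything one reproducible run needs: output directory, master
#' seed (mandatory; per-stage child seeds are derived from it by fixed
#' offsets so stages are independently reproducible), the synthetic-cohort
#' effect specification, task configuration, fitting settings, GLM options
#' and the list of analyses to execute.
#'
#' @param out_dir Output directory for result tables and the config
#'   snapshot.
#' @param seed Master integer seed.
#' @param spec An [effect_spec()].
#' @param config A [task_config()].
#' @param tr Repetition time of the ROI series.
#' @param n_starts Random starts per RL fit.
#' @param analyses Character subset of
#'   `c("behaviour", "rl_fit", "glm", "subsidiary", "responsivity")`; empty
#'   to validate inputs only.
#' @param use_true_params If `TRUE`, the GLM stage uses the generator's true
#'   latent traces; default `FALSE` re-estimates parameters by MLE first, as
#'   the analysed study does.
#' @return A list of class `run_config`.
#' @export
run_config <- function(out_dir, seed, spec = effect_spec(),
                       config = task_config(), tr = 2, n_starts = 10,
                       analyses = c("behaviour", "rl_fit", "glm",
                                    "subsidiary", "responsivity"),
                       use_true_params = FALSE) {
  if (missing(seed) || !is.numeric(seed)) stop("`seed` is mandatory.")
  structure(list(out_dir = out_dir, seed = as.integer(seed), spec = spec,
                 config = config, tr = tr, n_starts = n_starts,
                 analyses = analyses, use_true_params = use_true_params),
            class = "run_config")
}

#' Run the full simulate -> fit -> GLM -> second-level pipeline
#'
#' Executes the analysis stages in order on a synthetic cohort generated
#' under the configuration's effect specification: responder filtering and
#' behavioural statistics, per-subject RL parameter estimation, first-level
#' ROI GLMs with prediction-error modulators and second-level blunting
#' tests, the subsidiary quartile-bin and sign-split models, and the
#' responsivity correlation. Each stage writes a CSV under `out_dir`; a
#' config snapshot is written beside the outputs, and a summary JSON records
#' the three qualitative pattern checks (gain-specific behavioural
#' impairment, prediction-error slope blunting under stress, and a
#' preferentially positive-PE interaction in the sign-split model).
#'
#' @param cfg A [run_config()].
#' @return A list with the stage results (`cohort`, `behaviour`, `fits`,
#'   `slopes`, `second_level`, `bins`, `sign`, `responsivity`, `summary`),
#'   invisibly; files under `cfg$out_dir`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  snapshot <- cfg
  snapshot$spec <- unclass(cfg$spec)
  snapshot$config <- unclass(cfg$config)
  yaml::write_yaml(unclass(snapshot), file.path(cfg$out_dir, "config.yaml"))
  res <- list()
  cohort <- generate_cohort(cfg$spec, cfg$config, cfg$seed)
  res$cohort <- cohort
  filt <- responder_filter(cohort$reports)
  included <- filt$included
  utils::write.csv(filt$delta, file.path(cfg$out_dir, "responders.csv"),
                   row.names = FALSE)
  if (length(cfg$analyses) == 0) {
    return(invisible(res))
  }
  summary <- list(n_total = cfg$spec$n_participants,
                  n_included = length(included))

  if ("behaviour" %in% cfg$analyses) {
    trials <- do.call(rbind, cohort$sessions[included])
    choices <- code_correct(trials)
    anova <- manipulation_anova(
      cohort$reports[cohort$reports$participant %in% included, ])
    glme <- performance_glme(choices)
    gain_c <- posthoc_contrast(glme, "gain")
    loss_c <- posthoc_contrast(glme, "loss")
    curves <- learning_curves(choices)
    utils::write.csv(anova, file.path(cfg$out_dir, "manipulation_anova.csv"),
                     row.names = FALSE)
    utils::write.csv(glme$coefficients,
                     file.path(cfg$out_dir, "glme_coefficients.csv"),
                     row.names = FALSE)
    utils::write.csv(rbind(gain_c, loss_c),
                     file.path(cfg$out_dir, "posthoc_contrasts.csv"),
                     row.names = FALSE)
    utils::write.csv(curves, file.path(cfg$out_dir, "learning_curves.csv"),
                     row.names = FALSE)
    res$behaviour <- list(anova = anova, glme = glme, contrasts =
                            rbind(gain_c, loss_c), curves = curves)
    inter <- glme$coefficients[
      glme$coefficients$term == "conditionstress:valencegain", ]
    summary$behaviour <- list(
      interaction_beta = inter$estimate, interaction_p = inter$p,
      gain_contrast_p = gain_c$p, loss_contrast_p = loss_c$p,
      gain_impaired_selectively =
        gain_c$estimate < 0 && gain_c$p < 0.05 && loss_c$p > 0.05)
  }

  fitted_params <- NULL
  if ("rl_fit" %in% cfg$analyses) {
    set.seed(cfg$seed + 1000L)
    fit_seeds <- sample.int(.Machine$integer.max - 1L, length(included))
    fits <- list()
    for (k in seq_along(included)) {
      i <- included[k]
      for (cond in c("stress", "control")) {
        dat <- cohort$sessions[[i]]
        fit <- fit_condition(dat[dat$condition == cond, , drop = FALSE],
                             n_starts = cfg$n_starts,
                             seed = fit_seeds[k] %% 1000000L +
                               (cond == "stress"))
        n_tr <- sum(dat$condition == cond &
                      dat$valence %in% c("gain", "loss") &
                      dat$choice != "missing")
        fits[[paste(i, cond)]] <- data.frame(
          participant_id = i, condition = cond,
          alpha_pos = fit$params$alpha_pos, alpha_neg = fit$params$alpha_neg,
          beta = fit$params$beta, nll = fit$nll, n_trials = n_tr)
      }
    }
    fitted_params <- do.call(rbind, fits)
    utils::write.csv(fitted_params,
                     file.path(cfg$out_dir, "rl_parameters.csv"),
                     row.names = FALSE)
    res$fits <- fitted_params
  }

  needs_bold <- any(c("glm", "subsidiary", "responsivity") %in% cfg$analyses)
  if (needs_bold) {
    set.seed(cfg$seed + 2000L)
    bold_seeds <- sample.int(.Machine$integer.max - 1L, length(included))
    slope_rows <- list()
    bin_est <- list(); bin_bnd <- list(); sign_est <- list()
    for (k in seq_along(included)) {
      i <- included[k]
      session <- cohort$sessions[[i]]
      ts <- cohort$true_slopes[cohort$true_slopes$participant == i, ]
      bold <- generate_roi_bold(session, ts, cfg$spec, tr = cfg$tr,
                                seed = bold_seeds[k])
      # latent trace for the analysis design: fitted parameters when
      # available (as the analysed study), else the generator's truth
      if (!cfg$use_true_params && !is.null(fitted_params)) {
        pars <- list()
        for (cond in c("stress", "control")) {
          row <- fitted_params[fitted_params$participant_id == i &
                                 fitted_params$condition == cond, ]
          pars[[cond]] <- rl_params(row$alpha_pos, row$alpha_neg, row$beta)
        }
        replay <- trace_from_choices(session, pars)
        session$q_chosen <- NA_real_
        session$delta <- NA_real_
        m <- match(paste(replay$run, replay$stim_onset),
                   paste(session$run, session$stim_onset))
        session$q_chosen[m] <- replay$q_chosen
        session$delta[m] <- replay$delta
      }
      if ("glm" %in% cfg$analyses) {
        runs <- sort(unique(session$run))
        fits_run <- lapply(seq_along(runs), function(r) {
          rd <- session[session$run == runs[r], , drop = FALSE]
          fit_ar1_glm(bold[[r]]$bold, build_design(rd, tr = cfg$tr))
        })
        slope_rows[[k]] <- first_level_slopes(fits_run, participant = i)
      }
      if ("subsidiary" %in% cfg$analyses) {
        bb <- subsidiary_bins(session, lapply(bold, `[[`, "bold"),
                              tr = cfg$tr)
        bb$estimates$participant <- i
        bb$boundaries$participant <- i
        bin_est[[k]] <- bb$estimates
        bin_bnd[[k]] <- bb$boundaries
        se <- subsidiary_sign(session, lapply(bold, `[[`, "bold"),
                              tr = cfg$tr)
        se$participant <- i
        sign_est[[k]] <- se
      }
    }
    if ("glm" %in% cfg$analyses) {
      slopes <- do.call(rbind, slope_rows)
      second <- second_level_tests(slopes)
      utils::write.csv(slopes, file.path(cfg$out_dir, "pe_slopes.csv"),
                       row.names = FALSE)
      utils::write.csv(second, file.path(cfg$out_dir, "second_level.csv"),
                       row.names = FALSE)
      res$slopes <- slopes
      res$second_level <- second
      main <- second[second$test == "main_effect_control_gt_stress", ]
      summary$blunting <- list(
        main_effect_estimate = main$estimate, main_effect_p = main$p,
        blunted = main$estimate > 0 && main$p < 0.05)
      if ("responsivity" %in% cfg$analyses) {
        gs <- slopes[slopes$condition == "stress" & slopes$valence == "gain",
                     c("participant", "slope")]
        resp <- responsivity_correlation(gs, filt$delta)
        utils::write.csv(
          data.frame(rho = resp$rho, p = resp$p, n = resp$n),
          file.path(cfg$out_dir, "responsivity.csv"), row.names = FALSE)
        res$responsivity <- resp
      }
    }
    if ("subsidiary" %in% cfg$analyses) {
      bins <- do.call(rbind, bin_est)
      bnds <- do.call(rbind, bin_bnd)
      signs <- do.call(rbind, sign_est)
      incomplete <- unique(signs$participant[is.na(signs$estimate)])
      if (length(incomplete)) {
        message("Sign-split model: dropping participants with a cell ",
                "lacking one PE sign: ", paste(incomplete, collapse = ", "))
        signs <- signs[!signs$participant %in% incomplete, ]
      }
      sa <- sign_split_anova(signs)
      utils::write.csv(bins, file.path(cfg$out_dir, "bin_estimates.csv"),
                       row.names = FALSE)
      utils::write.csv(bin_boundary_tests(bnds),
                       file.path(cfg$out_dir, "bin_boundaries.csv"),
                       row.names = FALSE)
      utils::write.csv(sa$anova, file.path(cfg$out_dir, "sign_anova.csv"),
                       row.names = FALSE)
      utils::write.csv(sa$paired, file.path(cfg$out_dir, "sign_paired.csv"),
                       row.names = FALSE)
      res$bins <- list(estimates = bins, boundaries = bnds)
      res$sign <- sa
      inter <- sa$anova[sa$anova$effect == "condition:sign", ]
      mean_d <- stats::aggregate(d ~ sign, sa$paired, mean)
      summary$sign_split <- list(
        interaction_F = inter$F, interaction_p = inter$p,
        positive_more_blunted =
          abs(mean_d$d[mean_d$sign == "pos"]) >
          abs(mean_d$d[mean_d$sign == "neg"]))
    }
  }
  res$summary <- summary
  jsonlite::write_json(summary, file.path(cfg$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(res)
}
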