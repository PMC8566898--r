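#' Canonical double-gamma haemodynamic response function
#'
#' The standard difference-of-gammas impulse response (peak near 5 s,
#' undershoot near 15 s, 32-s support): `h(t) = g(t; 6, 1) - g(t; 16, 1)/6`
#' with `g` the gamma density, sampled on the acquisition grid and scaled to
#' unit peak so regression slopes are expressed per unit modulator at the
#' response peak. `h(0) = 0`.
#'
#' @param tr Sampling interval in seconds (the repetition time).
#' @param duration Kernel support in seconds (default 32).
#' @return Numeric vector of kernel samples at `0, tr, 2 tr, ...`.
#' @export
canonical_hrf <- function(tr, duration = 32) {
  stopifnot(tr > 0)
  t <- seq(0, duration, by = tr)
  h <- stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
  h / max(h)
}

#' Discrete-cosine high-pass drift basis
#'
#' Cosine basis functions spanning periods longer than `cutoff` seconds
#' (default 128 s); regressing them out removes low-frequency drift while
#' leaving fast components (e.g. a 20-s oscillation) essentially untouched.
#' The constant (DC) component is excluded — the model intercept carries it.
#'
#' @param n_scans Number of scans (`>= 2`).
#' @param tr Repetition time in seconds.
#' @param cutoff High-pass cutoff period in seconds.
#' @return Matrix `n_scans x K` of cosine regressors (`K` may be 0 for short
#'   runs), columns named `dct1..dctK`.
#' @export
highpass_dct <- function(n_scans, tr, cutoff = 128) {
  stopifnot(n_scans >= 2)
  K <- floor(2 * n_scans * tr / cutoff)
  if (K < 1) {
    return(matrix(numeric(0), nrow = n_scans, ncol = 0))
  }
  n <- n_scans
  X <- vapply(seq_len(K), function(k) {
    sqrt(2 / n) * cos(pi * (2 * seq_len(n) - 1) * k / (2 * n))
  }, numeric(n))
  colnames(X) <- paste0("dct", seq_len(K))
  X
}

# Causal convolution of a scan-gridded event column with the HRF kernel,
# truncated to the run length.
convolve_hrf <- function(u, h) {
  n <- length(u)
  full <- stats::convolve(u, rev(h), type = "open")
  full[seq_len(n)]
}

# Same, for all columns of a matrix at once (single FFT pass).
convolve_hrf_matrix <- function(U, h) {
  n <- nrow(U)
  nfft <- stats::nextn(n + length(h) - 1, 2)
  Hpad <- stats::fft(c(h, numeric(nfft - length(h))))
  Upad <- rbind(U, matrix(0, nfft - n, ncol(U)))
  Y <- Re(stats::mvfft(stats::mvfft(Upad) * Hpad, inverse = TRUE)) / nfft
  Y[seq_len(n), , drop = FALSE]
}

# Map onsets to scan indices (floor alignment to the scan start).
scan_index <- function(onset, tr) floor(onset / tr) + 1L

# Place stick amplitudes on the scan grid (amplitudes sum on collisions).
stick_column <- function(onsets, amplitudes, n_scans, tr) {
  u <- numeric(n_scans)
  idx <- scan_index(onsets, tr)
  for (i in seq_along(idx)) u[idx[i]] <- u[idx[i]] + amplitudes[i]
  u
}

#' Build a first-level design matrix for one run
#'
#' Events are modelled as stick functions on the scan grid and convolved with
#' the canonical HRF. The primary model has one stimulus-onset and one
#' outcome-onset regressor per condition x valence (6 + 6), plus parametric
#' modulators for financial trials: `Q_chosen` at stimulus onset and the
#' prediction error `delta` at outcome onset, separately for gain and loss in
#' each condition. Modulator values are mean-centered within the run and are
#' not orthogonalized against their parent sticks beyond that centering.
#' Missing trials get a no-interest stick regressor. The subsidiary models
#' replace the modulators by splitting financial outcome sticks into
#' quartile bins (`model = "bins"`, labels from [pe_quartile_bins()]) or by
#' prediction-error sign (`model = "sign"`, `delta >= 0` is positive). A
#' discrete-cosine drift basis and an intercept complete the matrix.
#' Event types absent from the run are omitted and recorded in `omitted`.
#'
#' @param run_data One run's rows of a simulated/replayed schedule, with
#'   `choice`, `outcome_r`, `q_chosen`, `delta` filled in.
#' @param tr Repetition time in seconds.
#' @param n_scans Number of scans; default covers the last outcome onset
#'   plus 32 s of HRF support.
#' @param model `"primary"`, `"bins"` or `"sign"`.
#' @param n_bins Number of prediction-error bins for `model = "bins"`.
#' @param cutoff High-pass cutoff in seconds (`NULL` drops the drift basis).
#' @param bin_labels Optional precomputed bin labels (vector aligned to
#'   `run_data` rows) so bins can be defined across runs; default computes
#'   them within the run.
#' @return A list of class `roi_design`: `X` (named matrix), `n_scans`,
#'   `tr`, `groups` (column names by role: stimulus, outcome, q_mod, pe_mod,
#'   nuisance, drift), and `omitted` (names of event types absent from the
#'   run, with constant modulators flagged).
#' @export
build_design <- function(run_data, tr = 2, n_scans = NULL,
                         model = c("primary", "bins", "sign"),
                         n_bins = 4, cutoff = 128, bin_labels = NULL) {
  model <- match.arg(model)
  stopifnot(length(unique(run_data$run)) == 1)
  h <- canonical_hrf(tr)
  if (is.null(n_scans)) {
    n_scans <- ceiling((max(run_data$outcome_onset) + 32) / tr)
  }
  if (any(scan_index(run_data$stim_onset, tr) > n_scans) ||
      any(scan_index(run_data$outcome_onset, tr) > n_scans)) {
    stop("Event onset beyond the end of the run.")
  }
  ok <- !is.na(run_data$choice) & run_data$choice != "missing"
  cols <- list()
  groups <- list(stimulus = character(0), outcome = character(0),
                 q_mod = character(0), pe_mod = character(0),
                 nuisance = character(0), drift = character(0))
  omitted <- character(0)
  add_col <- function(name, u, group) {
    cols[[name]] <<- u
    groups[[group]] <<- c(groups[[group]], name)
  }
  for (cond in c("stress", "control")) {
    for (val in c("gain", "loss", "neutral")) {
      sel <- ok & run_data$condition == cond & run_data$valence == val
      stim_name <- paste("stim", cond, val, sep = "_")
      out_name <- paste("out", cond, val, sep = "_")
      if (!any(sel)) {
        omitted <- c(omitted, stim_name, out_name)
        next
      }
      add_col(stim_name,
              stick_column(run_data$stim_onset[sel], rep(1, sum(sel)),
                           n_scans, tr), "stimulus")
      if (model %in% c("bins", "sign") && val != "neutral") {
        # financial outcome sticks split by bin / PE sign
        if (model == "bins") {
          labels <- if (is.null(bin_labels)) {
            lb <- rep(NA_integer_, nrow(run_data))
            lb[sel] <- pe_quartile_bins(run_data$delta[sel],
                                        seq_len(sum(sel)), n_bins)
            lb
          } else bin_labels
          for (b in seq_len(n_bins)) {
            bsel <- sel & !is.na(labels) & labels == b
            bname <- paste(out_name, "bin", b, sep = "_")
            if (!any(bsel)) { omitted <- c(omitted, bname); next }
            add_col(bname,
                    stick_column(run_data$outcome_onset[bsel],
                                 rep(1, sum(bsel)), n_scans, tr), "outcome")
          }
        } else {
          for (sg in c("pos", "neg")) {
            ssel <- sel & if (sg == "pos") run_data$delta >= 0 else
              run_data$delta < 0
            sname <- paste(out_name, sg, sep = "_")
            if (!any(ssel)) { omitted <- c(omitted, sname); next }
            add_col(sname,
                    stick_column(run_data$outcome_onset[ssel],
                                 rep(1, sum(ssel)), n_scans, tr), "outcome")
          }
        }
      } else {
        add_col(out_name,
                stick_column(run_data$outcome_onset[sel], rep(1, sum(sel)),
                             n_scans, tr), "outcome")
      }
      if (model == "primary" && val != "neutral") {
        q <- run_data$q_chosen[sel]
        d <- run_data$delta[sel]
        qc <- q - mean(q)
        dc <- d - mean(d)
        qname <- paste("stimQ", cond, val, sep = "_")
        dname <- paste("outPE", cond, val, sep = "_")
        if (all(qc == 0)) {
          omitted <- c(omitted, paste0(qname, " (constant modulator)"))
        } else {
          add_col(qname, stick_column(run_data$stim_onset[sel], qc,
                                      n_scans, tr), "q_mod")
        }
        if (all(dc == 0)) {
          omitted <- c(omitted, paste0(dname, " (constant modulator)"))
        } else {
          add_col(dname, stick_column(run_data$outcome_onset[sel], dc,
                                      n_scans, tr), "pe_mod")
        }
      }
    }
  }
  miss <- !is.na(run_data$choice) & run_data$choice == "missing"
  if (any(miss)) {
    add_col("missing", stick_column(run_data$stim_onset[miss],
                                    rep(1, sum(miss)), n_scans, tr),
            "nuisance")
  }
  X <- convolve_hrf_matrix(do.call(cbind, cols), h)
  colnames(X) <- names(cols)
  if (!is.null(cutoff)) {
    D <- highpass_dct(n_scans, tr, cutoff)
    if (ncol(D) > 0) {
      X <- cbind(X, D)
      groups$drift <- colnames(D)
    }
  }
  X <- cbind(X, intercept = 1)
  structure(list(X = X, n_scans = n_scans, tr = tr, groups = groups,
                 omitted = omitted),
            class = "roi_design")
}

#' Quartile bin labels for prediction errors
#'
#' Splits prediction errors into `n_bins` (default 4) bins of equal size, by
#' stable sort on `(delta, trial index)` followed by a contiguous split into
#' groups whose sizes differ by at most one — the deterministic tie-break
#' that keeps bins as equally sized as ties allow. Bin 1 holds the lowest
#' (most negative) prediction errors, bin `n_bins` the highest.
#'
#' @param delta Prediction errors of one condition x valence cell.
#' @param trial_index Tie-breaking index (e.g. order of occurrence).
#' @param n_bins Number of bins.
#' @return Integer bin labels aligned with `delta`.
#' @export
pe_quartile_bins <- function(delta, trial_index = seq_along(delta),
                             n_bins = 4) {
  if (length(delta) < n_bins) {
    stop("Need at least ", n_bins, " trials to form ", n_bins, " bins.")
  }
  ord <- order(delta, trial_index)
  sizes <- rep(length(delta) %/% n_bins, n_bins)
  extra <- length(delta) %% n_bins
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
  labels <- integer(length(delta))
  labels[ord] <- rep(seq_len(n_bins), times = sizes)
  labels
}

#' AR(1) prewhitened GLM for an ROI time series
#'
#' Fits the design by OLS, estimates the lag-1 autocorrelation `rho` from the
#' residuals, prewhitens data and design by the Cochrane-Orcutt transform
#' (first observation rescaled by `sqrt(1 - rho^2)`), and refits. The
#' whitened residuals have approximately zero lag-1 autocorrelation.
#'
#' @param y Numeric BOLD series (one run, arbitrary units).
#' @param design An `roi_design` (or a plain numeric matrix).
#' @return A list of class `roi_glm_fit`: `beta` (named), `se`, `rho`,
#'   `sigma2`, `df`, `resid_white`.
#' @export
fit_ar1_glm <- function(y, design) {
  X <- if (inherits(design, "roi_design")) design$X else design
  n <- length(y)
  stopifnot(n == nrow(X))
  if (n <= ncol(X)) stop("More columns than scans.")
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("Design is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  e <- stats::residuals(stats::lm.fit(X, y))
  rho <- sum(e[-1] * e[-n]) / sum(e^2)
  W <- function(z) {
    zw <- z
    if (is.matrix(z)) {
      zw[1, ] <- sqrt(1 - rho^2) * z[1, ]
      zw[-1, ] <- z[-1, , drop = FALSE] - rho * z[-n, , drop = FALSE]
    } else {
      zw[1] <- sqrt(1 - rho^2) * z[1]
      zw[-1] <- z[-1] - rho * z[-n]
    }
    zw
  }
  Xw <- W(X)
  yw <- W(y)
  fit <- stats::lm.fit(Xw, yw)
  df <- n - ncol(X)
  sigma2 <- sum(fit$residuals^2) / df
  XtXinv <- chol2inv(chol(crossprod(Xw)))
  se <- sqrt(sigma2 * diag(XtXinv))
  beta <- fit$coefficients
  names(se) <- names(beta) <- colnames(X)
  structure(list(beta = beta, se = se, rho = rho, sigma2 = sigma2,
                 df = df, resid_white = fit$residuals),
            class = "roi_glm_fit")
}

#' First-level prediction-error modulation slopes for one subject
#'
#' Extracts the prediction-error modulator slope (and its variance) per
#' condition x valence from each run's fit and combines runs by
#' inverse-variance weighting (equal variances reduce to the simple mean).
#'
#' @param fits List of `roi_glm_fit`, one per run.
#' @param participant Participant id recorded in the output.
#' @return A `SlopeTable` data frame: `participant`, `condition`, `valence`,
#'   `slope`, `var`, `se`. Cells whose modulator column is absent from every
#'   run are flagged with `NA` slope.
#' @export
first_level_slopes <- function(fits, participant = NA_integer_) {
  cells <- expand.grid(condition = c("stress", "control"),
                       valence = c("gain", "loss"),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(cells)), function(i) {
    nm <- paste("outPE", cells$condition[i], cells$valence[i], sep = "_")
    b <- v <- numeric(0)
    for (f in fits) {
      if (nm %in% names(f$beta)) {
        b <- c(b, f$beta[[nm]])
        v <- c(v, f$se[[nm]]^2)
      }
    }
    if (length(b) == 0) {
      return(data.frame(participant = participant,
                        condition = cells$condition[i],
                        valence = cells$valence[i],
                        slope = NA_real_, var = NA_real_, se = NA_real_))
    }
    w <- 1 / v
    slope <- sum(w * b) / sum(w)
    var <- 1 / sum(w)
    data.frame(participant = participant, condition = cells$condition[i],
               valence = cells$valence[i], slope = slope, var = var,
               se = sqrt(var))
  })
  do.call(rbind, out)
}

#' Second-level tests on prediction-error modulation slopes
#'
#' The random-effects battery over subjects: (i) a one-sample t-test against
#' zero per condition x valence cell; (ii) a paired t-test for the main
#' effect of stress — per-subject mean over valences of (control - stress);
#' (iii) a paired t-test for the condition x valence interaction —
#' `(control_gain - stress_gain) - (control_loss - stress_loss)`.
#' Participants with incomplete cells are dropped with a message.
#'
#' @param slopes A `SlopeTable` over participants (rows per participant x
#'   condition x valence).
#' @return Data frame: `test`, `estimate`, `t`, `df`, `p`.
#' @export
second_level_tests <- function(slopes) {
  get_cell <- function(cond, val) {
    x <- slopes$slope[slopes$condition == cond & slopes$valence == val]
    names(x) <- slopes$participant[slopes$condition == cond &
                                     slopes$valence == val]
    x
  }
  sg <- get_cell("stress", "gain"); sl <- get_cell("stress", "loss")
  cg <- get_cell("control", "gain"); cl <- get_cell("control", "loss")
  ids <- Reduce(intersect, list(names(sg), names(sl), names(cg), names(cl)))
  complete <- ids[!is.na(sg[ids]) & !is.na(sl[ids]) & !is.na(cg[ids]) &
                    !is.na(cl[ids])]
  if (length(complete) < length(unique(slopes$participant))) {
    dropped <- setdiff(unique(as.character(slopes$participant)), complete)
    message("Dropping participants with incomplete cells: ",
            paste(dropped, collapse = ", "))
  }
  if (length(complete) < 3) stop("Need at least 3 complete participants.")
  sg <- sg[complete]; sl <- sl[complete]; cg <- cg[complete]; cl <- cl[complete]
  one_sample <- function(x, label) {
    tt <- stats::t.test(x)
    data.frame(test = label, estimate = unname(tt$estimate),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value)
  }
  main_diff <- (cg + cl) / 2 - (sg + sl) / 2
  inter_diff <- (cg - sg) - (cl - sl)
  rbind(
    one_sample(cg, "control_gain_vs_0"),
    one_sample(cl, "control_loss_vs_0"),
    one_sample(sg, "stress_gain_vs_0"),
    one_sample(sl, "stress_loss_vs_0"),
    one_sample(main_diff, "main_effect_control_gt_stress"),
    one_sample(inter_diff, "condition_x_valence_interaction"))
}

#' Subsidiary quartile-bin model for one subject
#'
#' Splits each condition x valence cell's prediction errors into bins of
#' (as near as possible) equal size — quartiles by default — pooling the
#' subject's runs, then fits a no-modulator GLM per run with one outcome
#' regressor per bin and extracts the per-bin BOLD estimates
#' (inverse-variance combined across runs). Also returns the interior bin
#' boundaries per cell for across-condition comparison.
#'
#' @param session The subject's full schedule with trace columns.
#' @param bold List of BOLD series, one per run.
#' @param tr Repetition time.
#' @param n_bins Number of bins (default 4).
#' @return List: `estimates` (`condition`, `valence`, `bin`, `estimate`,
#'   `var`), `boundaries` (`condition`, `valence`, `boundary` index 1..3,
#'   `value`), `degenerate` flag (TRUE when all deltas in some cell are
#'   equal, making boundaries uninformative).
#' @export
subsidiary_bins <- function(session, bold, tr = 2, n_bins = 4) {
  fin <- session$valence %in% c("gain", "loss") &
    !is.na(session$choice) & session$choice != "missing"
  labels <- rep(NA_integer_, nrow(session))
  boundaries <- list()
  degenerate <- FALSE
  for (cond in c("stress", "control")) {
    for (val in c("gain", "loss")) {
      sel <- which(fin & session$condition == cond & session$valence == val)
      if (length(sel) < n_bins) {
        stop("Fewer than ", n_bins, " financial trials in cell ",
             cond, "/", val)
      }
      d <- session$delta[sel]
      if (length(unique(d)) == 1) degenerate <- TRUE
      labels[sel] <- pe_quartile_bins(d, seq_along(sel), n_bins)
      cuts <- vapply(seq_len(n_bins - 1), function(b)
        max(d[labels[sel] == b]), numeric(1))
      boundaries[[paste(cond, val)]] <- data.frame(
        condition = cond, valence = val, boundary = seq_len(n_bins - 1),
        value = cuts)
    }
  }
  runs <- sort(unique(session$run))
  fits <- lapply(runs, function(r) {
    rd <- session[session$run == r, , drop = FALSE]
    des <- build_design(rd, tr = tr, model = "bins", n_bins = n_bins,
                        bin_labels = labels[session$run == r])
    fit_ar1_glm(bold[[which(runs == r)]], des)
  })
  cells <- expand.grid(condition = c("stress", "control"),
                       valence = c("gain", "loss"), bin = seq_len(n_bins),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  est <- lapply(seq_len(nrow(cells)), function(i) {
    nm <- paste("out", cells$condition[i], cells$valence[i], "bin",
                cells$bin[i], sep = "_")
    b <- v <- numeric(0)
    for (f in fits) {
      if (nm %in% names(f$beta)) {
        b <- c(b, f$beta[[nm]]); v <- c(v, f$se[[nm]]^2)
      }
    }
    if (length(b) == 0) {
      return(data.frame(cells[i, ], estimate = NA_real_, var = NA_real_))
    }
    w <- 1 / v
    data.frame(cells[i, ], estimate = sum(w * b) / sum(w), var = 1 / sum(w))
  })
  list(estimates = do.call(rbind, est),
       boundaries = do.call(rbind, boundaries), degenerate = degenerate)
}

#' Paired comparison of bin boundaries across conditions
#'
#' Paired t-tests (across participants) of each interior bin boundary,
#' stress vs control, separately per valence — the check that the bin
#' definitions are comparable between conditions.
#'
#' @param boundaries Row-bound `boundaries` tables from [subsidiary_bins()]
#'   with a `participant` column.
#' @return Data frame: `valence`, `boundary`, `t`, `df`, `p` (NA with a
#'   `degenerate` flag when a boundary has zero variance).
#' @export
bin_boundary_tests <- function(boundaries) {
  out <- list()
  for (val in unique(boundaries$valence)) {
    for (b in unique(boundaries$boundary)) {
      s <- boundaries[boundaries$valence == val & boundaries$boundary == b &
                        boundaries$condition == "stress", ]
      c <- boundaries[boundaries$valence == val & boundaries$boundary == b &
                        boundaries$condition == "control", ]
      m <- merge(s[, c("participant", "value")],
                 c[, c("participant", "value")], by = "participant")
      diff <- m$value.x - m$value.y
      if (stats::sd(diff) == 0) {
        out[[paste(val, b)]] <- data.frame(valence = val, boundary = b,
                                           t = NA_real_, df = NA_real_,
                                           p = NA_real_, degenerate = TRUE)
      } else {
        tt <- stats::t.test(diff)
        out[[paste(val, b)]] <- data.frame(
          valence = val, boundary = b, t = unname(tt$statistic),
          df = unname(tt$parameter), p = tt$p.value, degenerate = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

#' Subsidiary sign-split model for one subject
#'
#' Splits financial outcome events into positive (`delta >= 0`) and negative
#' prediction errors, fits a no-modulator GLM per run with one outcome
#' regressor per condition x valence x sign, and extracts the BOLD
#' estimates (inverse-variance combined across runs).
#'
#' @param session The subject's full schedule with trace columns.
#' @param bold List of BOLD series, one per run.
#' @param tr Repetition time.
#' @return Data frame: `condition`, `valence`, `sign` (`pos`/`neg`),
#'   `estimate`, `var`; cells with no trials of one sign are `NA` (flagged
#'   via attribute `incomplete`).
#' @export
subsidiary_sign <- function(session, bold, tr = 2) {
  runs <- sort(unique(session$run))
  fits <- lapply(runs, function(r) {
    rd <- session[session$run == r, , drop = FALSE]
    des <- build_design(rd, tr = tr, model = "sign")
    fit_ar1_glm(bold[[which(runs == r)]], des)
  })
  cells <- expand.grid(condition = c("stress", "control"),
                       valence = c("gain", "loss"), sign = c("pos", "neg"),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  est <- lapply(seq_len(nrow(cells)), function(i) {
    nm <- paste("out", cells$condition[i], cells$valence[i], cells$sign[i],
                sep = "_")
    b <- v <- numeric(0)
    for (f in fits) {
      if (nm %in% names(f$beta)) {
        b <- c(b, f$beta[[nm]]); v <- c(v, f$se[[nm]]^2)
      }
    }
    if (length(b) == 0) {
      return(data.frame(cells[i, ], estimate = NA_real_, var = NA_real_))
    }
    w <- 1 / v
    data.frame(cells[i, ], estimate = sum(w * b) / sum(w), var = 1 / sum(w))
  })
  out <- do.call(rbind, est)
  attr(out, "incomplete") <- any(is.na(out$estimate))
  out
}

#' Group ANOVA and paired effect sizes for the sign-split model
#'
#' Repeated-measures ANOVA of the sign-split BOLD estimates with
#' within-subject factors condition x PE sign x trial valence, plus paired
#' t-tests (stress - control) with Cohen's d (`mean(diff) / sd(diff)`) per
#' valence x sign cell.
#'
#' @param estimates Row-bound [subsidiary_sign()] outputs with a
#'   `participant` column (complete cells only).
#' @return List: `anova` (effects with `F`, `df1`, `df2`, `p`, `pes`),
#'   `paired` (`valence`, `sign`, `t`, `df`, `p`, `d`; `d` is `NA` when the
#'   paired differences have zero variance).
#' @export
sign_split_anova <- function(estimates) {
  d <- data.frame(participant = factor(estimates$participant),
                  condition = factor(estimates$condition),
                  sign = factor(estimates$sign),
                  valence = factor(estimates$valence),
                  y = estimates$estimate)
  if (any(is.na(d$y))) stop("Incomplete cells; drop flagged participants first.")
  fit <- stats::aov(y ~ condition * sign * valence +
                      Error(participant / (condition * sign * valence)),
                    data = d)
  s <- summary(fit)
  effs <- c("condition", "sign", "valence", "condition:sign",
            "condition:valence", "sign:valence", "condition:sign:valence")
  anova_tab <- do.call(rbind, lapply(effs, function(eff) {
    stratum <- s[[paste0("Error: participant:", eff)]][[1]]
    row <- trimws(rownames(stratum)) == eff
    err <- trimws(rownames(stratum)) == "Residuals"
    data.frame(effect = eff, F = stratum[row, "F value"],
               df1 = stratum[row, "Df"], df2 = stratum[err, "Df"],
               p = stratum[row, "Pr(>F)"],
               pes = stratum[row, "Sum Sq"] /
                 (stratum[row, "Sum Sq"] + stratum[err, "Sum Sq"]))
  }))
  paired <- list()
  for (val in levels(d$valence)) {
    for (sg in levels(d$sign)) {
      cell <- d[d$valence == val & d$sign == sg, ]
      m <- merge(cell[cell$condition == "stress", c("participant", "y")],
                 cell[cell$condition == "control", c("participant", "y")],
                 by = "participant")
      diff <- m$y.x - m$y.y
      if (stats::sd(diff) == 0) {
        paired[[paste(val, sg)]] <- data.frame(
          valence = val, sign = sg, t = NA_real_, df = NA_real_,
          p = NA_real_, d = NA_real_)
      } else {
        tt <- stats::t.test(diff)
        paired[[paste(val, sg)]] <- data.frame(
          valence = val, sign = sg, t = unname(tt$statistic),
          df = unname(tt$parameter), p = tt$p.value,
          d = mean(diff) / stats::sd(diff))
      }
    }
  }
  list(anova = anova_tab, paired = do.call(rbind, paired))
}

#' Spearman correlation between stress responsivity and PE modulation
#'
#' Rank correlation between the gain/stress prediction-error modulation
#' slopes and the per-participant increase in self-reported stress
#' (stress - control), testing whether stronger stress responders show more
#' blunted prediction-error signalling.
#'
#' @param slopes_gain_stress Data frame `participant`, `slope` (the
#'   gain/stress cell of a `SlopeTable`).
#' @param delta_stress Data frame `participant`, `delta` from
#'   [responder_filter()].
#' @return List: `rho`, `p`, `n`, `flagged` (TRUE when an input is constant
#'   and the correlation is undefined).
#' @export
responsivity_correlation <- function(slopes_gain_stress, delta_stress) {
  m <- merge(slopes_gain_stress, delta_stress, by = "participant")
  if (nrow(m) < 4) stop("Need at least 4 paired observations.")
  if (stats::sd(m$slope) == 0 || stats::sd(m$delta) == 0) {
    return(list(rho = NA_real_, p = NA_real_, n = nrow(m), flagged = TRUE))
  }
  ct <- suppressWarnings(stats::cor.test(m$slope, m$delta,
                                         method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value, n = nrow(m),
       flagged = FALSE)
}

#' Read and write ROI time-series TSV files
#'
#' ROI-averaged BOLD series are stored as two-column tab-separated files:
#' `scan` (1-based index) and `value` (arbitrary units).
#'
#' @param y Numeric BOLD series.
#' @param path File path.
#' @return `write_roi_tsv` returns `path` invisibly; `read_roi_tsv` returns
#'   the numeric series.
#' @export
write_roi_tsv <- function(y, path) {
  utils::write.table(data.frame(scan = seq_along(y), value = y), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_roi_tsv
#' @export
read_roi_tsv <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE)
  d$value[order(d$scan)]
}
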