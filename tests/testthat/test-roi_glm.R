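# A small session fixture used throughout: 8 presentations per pair, fixed
# timing so designs are compact and fast to fit.
roi_session <- function(seed = 301, presentations = 8) {
  sched <- build_schedule(1, toy_config(presentations = presentations),
                          seed = seed)
  simulate_agent(sched, list(stress = rl_params(0.25, 0.3, 3),
                             control = rl_params(0.45, 0.3, 3)),
                 seed = seed + 1)
}

test_that("the canonical HRF has the expected shape", {
  h_dense <- canonical_hrf(0.1)
  t_dense <- seq(0, 32, by = 0.1)
  expect_equal(h_dense[1], 0)
  expect_lt(abs(t_dense[which.max(h_dense)] - 5), 0.2)
  expect_equal(max(h_dense), 1)            # unit-peak scaling
  expect_lt(min(h_dense), 0)               # undershoot present
  expect_gt(t_dense[which.min(h_dense)], 10)

  # impulse response: a unit stick reproduces the kernel at its onset
  h <- canonical_hrf(2)
  u <- numeric(50)
  u[11] <- 1
  conv <- stressrl:::convolve_hrf(u, h)
  expect_equal(conv[11:27], h, tolerance = 1e-10)
  expect_equal(conv[1:10], rep(0, 10), tolerance = 1e-10)
})

test_that("the DCT basis removes drift but not fast signal", {
  n <- 300; tr <- 2
  D <- highpass_dct(n, tr, cutoff = 128)
  expect_equal(ncol(D), floor(2 * n * tr / 128))
  proj <- function(y) {
    X <- cbind(1, D)
    y - X %*% qr.solve(crossprod(X), crossprod(X, y))
  }
  drift <- seq_len(n) / n
  expect_lt(sum(proj(drift)^2) / sum((drift - mean(drift))^2), 0.01)
  fast <- sin(2 * pi * (seq_len(n) * tr) / 20)
  expect_gt(sum(proj(fast)^2) / sum((fast - mean(fast))^2), 0.95)
  expect_lt(max(abs(proj(rep(3, n)))), 1e-10)
})

test_that("design matrices contain the documented columns and bookkeeping", {
  ses <- roi_session()
  run1 <- ses[ses$run == 1, ]
  des <- build_design(run1, tr = 2)
  expect_s3_class(des, "roi_design")
  expect_setequal(des$groups$stimulus,
                  paste("stim", rep(c("stress", "control"), each = 3),
                        c("gain", "loss", "neutral"), sep = "_"))
  expect_length(des$groups$pe_mod, 4)
  expect_length(des$groups$q_mod, 4)
  expect_equal(unname(des$X[, "intercept"]), rep(1, des$n_scans))
  # modulator columns are built from centered values: near-zero column sums
  # against the parent sticks is not required, but the raw modulator mean is 0
  expect_length(des$omitted, 0)

  # a run lacking loss/neutral events omits those columns and logs them
  gain_only <- run1[run1$valence == "gain" & run1$condition == "stress", ]
  des_g <- build_design(gain_only, tr = 2)
  expect_true("stim_stress_gain" %in% colnames(des_g$X))
  expect_false(any(grepl("loss", colnames(des_g$X))))
  expect_true(any(grepl("control", des_g$omitted)))

  # constant modulator is dropped and flagged
  const <- gain_only
  const$delta <- 0.2
  des_c <- build_design(const, tr = 2)
  expect_false("outPE_stress_gain" %in% colnames(des_c$X))
  expect_true(any(grepl("outPE_stress_gain \\(constant", des_c$omitted)))

  # events past the end of the run are rejected
  expect_error(build_design(run1, tr = 2, n_scans = 10), "beyond")
})

test_that("known coefficients are recovered from data built on the design", {
  ses <- roi_session(311)
  run1 <- ses[ses$run == 1, ]
  des <- build_design(run1, tr = 2)
  p <- ncol(des$X)
  set.seed(312)
  b_true <- runif(p, -1, 1)
  y <- as.numeric(des$X %*% b_true) + rnorm(des$n_scans, sd = 0.5)
  fit <- fit_ar1_glm(y, des)
  expect_true(all(abs(fit$beta - b_true) <= 3 * fit$se))
})

test_that("AR(1) prewhitening estimates rho and whitens residuals", {
  # long series with a lean design so rho estimates are precise
  n <- 800
  set.seed(322)
  sticks <- numeric(n)
  sticks[sample.int(n, 60)] <- 1
  X <- cbind(task = stressrl:::convolve_hrf(sticks, canonical_hrf(2)),
             highpass_dct(n, 2, 128), intercept = 1)

  # white-noise data: rho near zero, betas match plain OLS
  y0 <- rnorm(n)
  fit0 <- fit_ar1_glm(y0, X)
  ols <- qr.coef(qr(X), y0)
  expect_lt(abs(fit0$rho), 0.12)
  expect_lt(max(abs(fit0$beta - ols)), 0.05)

  # AR(1) data: rho recovered within 0.1
  y1 <- as.numeric(arima.sim(list(ar = 0.4), n, sd = 1))
  fit1 <- fit_ar1_glm(y1, X)
  expect_lt(abs(fit1$rho - 0.4), 0.1)
  lag1 <- function(e) sum(e[-1] * e[-length(e)]) / sum(e^2)
  expect_lt(abs(lag1(fit1$resid_white)), 0.05)

  # rank-deficient designs are rejected with the offending column named
  Xbad <- cbind(X, dup = X[, "task"])
  expect_error(fit_ar1_glm(y0, Xbad), "dup")
})

test_that("first-level slopes combine runs by inverse variance", {
  f1 <- list(beta = c(outPE_stress_gain = 1, outPE_stress_loss = 0.5,
                      outPE_control_gain = 2, outPE_control_loss = 1.5),
             se = c(outPE_stress_gain = 0.1, outPE_stress_loss = 0.1,
                    outPE_control_gain = 0.1, outPE_control_loss = 0.1))
  f2 <- list(beta = c(outPE_stress_gain = 3, outPE_stress_loss = 1.5,
                      outPE_control_gain = 4, outPE_control_loss = 2.5),
             se = c(outPE_stress_gain = 0.1, outPE_stress_loss = 0.1,
                    outPE_control_gain = 0.1, outPE_control_loss = 0.1))
  sl <- first_level_slopes(list(f1, f2), participant = 9)
  # equal variances: simple mean
  expect_equal(sl$slope[sl$condition == "stress" & sl$valence == "gain"], 2)
  expect_equal(sl$slope[sl$condition == "control" & sl$valence == "loss"], 2)

  # unequal variances: weighted towards the precise run
  f2w <- f2
  f2w$se[] <- 0.3
  slw <- first_level_slopes(list(f1, f2w), participant = 9)
  expect_lt(slw$slope[slw$condition == "stress" & slw$valence == "gain"], 2)

  # modulator absent from every run: NA cell
  f_missing <- lapply(list(f1, f2), function(f) {
    f$beta <- f$beta[names(f$beta) != "outPE_stress_gain"]
    f$se <- f$se[names(f$se) != "outPE_stress_gain"]
    f
  })
  slm <- first_level_slopes(f_missing, participant = 9)
  expect_true(is.na(slm$slope[slm$condition == "stress" &
                                slm$valence == "gain"]))
})

test_that("second-level battery computes the documented contrasts", {
  set.seed(331)
  n <- 10
  make_slopes <- function(shift_stress) {
    do.call(rbind, lapply(seq_len(n), function(i) {
      data.frame(participant = i,
                 condition = rep(c("stress", "control"), each = 2),
                 valence = rep(c("gain", "loss"), 2),
                 slope = c(rnorm(2, 1 - shift_stress, 0.2), rnorm(2, 1, 0.2)))
    }))
  }
  res <- second_level_tests(make_slopes(0.8))
  expect_setequal(res$test,
                  c("control_gain_vs_0", "control_loss_vs_0",
                    "stress_gain_vs_0", "stress_loss_vs_0",
                    "main_effect_control_gt_stress",
                    "condition_x_valence_interaction"))
  main <- res[res$test == "main_effect_control_gt_stress", ]
  expect_gt(main$estimate, 0)
  expect_lt(main$p, 0.01)
  expect_equal(main$df, n - 1)

  small <- make_slopes(0)[1:8, ]  # 2 complete participants
  expect_error(suppressMessages(second_level_tests(small)), "at least 3")

  # incomplete participants are dropped with a message
  slopes <- make_slopes(0)
  slopes$slope[1] <- NA
  expect_message(second_level_tests(slopes), "Dropping")
})

test_that("quartile bins are equal-sized with deterministic tie-breaking", {
  expect_equal(pe_quartile_bins(c(8, 1, 5, 3, 7, 2, 6, 4) / 10),
               c(4, 1, 3, 2, 4, 1, 3, 2))
  # ties broken by trial order, sizes differ by at most one
  labels <- pe_quartile_bins(rep(0.2, 10))
  expect_equal(as.integer(table(labels)), c(3, 3, 2, 2))
  expect_equal(labels[1:3], c(1, 1, 1))  # earliest trials in the lowest bin
  expect_error(pe_quartile_bins(c(0.1, 0.2), n_bins = 4), "at least 4")
})

test_that("subsidiary bin model produces balanced bins and boundary tests", {
  ses <- roi_session(351, presentations = 12)
  spec <- effect_spec()
  ts <- data.frame(participant = 1,
                   condition = rep(c("control", "stress"), 2),
                   valence = rep(c("gain", "loss"), each = 2),
                   slope = c(1, 0.3, 1, 0.3))
  bold <- generate_roi_bold(ses, ts, spec, tr = 2, seed = 352)
  bb <- subsidiary_bins(ses, lapply(bold, `[[`, "bold"))
  expect_equal(nrow(bb$estimates), 16)   # 2 cond x 2 val x 4 bins
  expect_equal(nrow(bb$boundaries), 12)  # 3 interior boundaries per cell
  expect_true(all(is.finite(bb$estimates$estimate)))
  # interior boundaries are ordered within each cell
  for (cell in split(bb$boundaries, paste(bb$boundaries$condition,
                                          bb$boundaries$valence))) {
    expect_false(is.unsorted(cell$value[order(cell$boundary)]))
  }

  # group boundary comparison: identical conditions are degenerate-flagged,
  # distinct ones get a paired t
  b <- expand.grid(participant = 1:6, condition = c("stress", "control"),
                   valence = "gain", boundary = 1:3,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  b$value <- b$boundary / 10
  res_deg <- bin_boundary_tests(b)
  expect_true(all(res_deg$degenerate))
  set.seed(353)
  b$value <- b$value + rnorm(nrow(b), sd = 0.02)
  res_t <- bin_boundary_tests(b)
  expect_true(all(!res_t$degenerate))
  expect_true(all(res_t$df == 5))
})

test_that("sign-split group analysis flags degenerate effect sizes", {
  # constructed estimates: condition effect only in positive cells
  est <- expand.grid(participant = 1:8, condition = c("stress", "control"),
                     valence = c("gain", "loss"), sign = c("pos", "neg"),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  set.seed(341)
  est$estimate <- 1 + 0.2 * rnorm(nrow(est)) -
    0.9 * (est$condition == "stress" & est$sign == "pos")
  res <- sign_split_anova(est)
  inter <- res$anova[res$anova$effect == "condition:sign", ]
  expect_lt(inter$p, 0.05)
  d_pos <- mean(abs(res$paired$d[res$paired$sign == "pos"]))
  d_neg <- mean(abs(res$paired$d[res$paired$sign == "neg"]))
  expect_gt(d_pos, d_neg)

  # identical paired samples: zero-variance differences flagged as NA
  est0 <- est
  est0$estimate <- 1
  res0 <- sign_split_anova(est0)
  expect_true(all(is.na(res0$paired$d)))
})

test_that("responsivity correlation handles extremes and degenerate input", {
  mono <- data.frame(participant = 1:6, slope = 6:1)
  delta <- data.frame(participant = 1:6, delta = 1:6)
  r <- responsivity_correlation(mono, delta)
  expect_equal(r$rho, -1)
  expect_false(r$flagged)

  const <- data.frame(participant = 1:6, slope = rep(2, 6))
  expect_true(responsivity_correlation(const, delta)$flagged)
  expect_error(responsivity_correlation(mono[1:3, ], delta), "at least 4")
})
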