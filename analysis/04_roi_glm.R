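#!/usr/bin/env Rscript
# Stage 4 — model-based ROI GLM and second-level tests.
#
# Re-estimates the RL parameters, replays each included participant's
# choices under their fitted parameters to obtain trial-wise Q and
# prediction-error traces, builds the first-level design (stick regressors
# per condition x valence at stimulus and outcome onsets, Q and
# prediction-error parametric modulators, 128-s DCT high-pass), fits it to
# the ROI BOLD series with AR(1) prewhitening, and runs the second-level
# battery on the prediction-error slopes: one-sample tests per cell, the
# control > stress main effect (blunting), the condition x valence
# interaction, the subsidiary quartile-bin and sign-split models, and the
# responsivity correlation.

suppressPackageStartupMessages(library(stressrl))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[[1]]) else 2024L

res <- run_pipeline(run_config(out_dir = "results/roi_glm", seed = seed,
                               analyses = c("rl_fit", "glm", "subsidiary",
                                            "responsivity")))
s <- res$summary
cat("ROI GLM results (results/roi_glm):\n")
cat(sprintf("  control > stress PE-slope main effect: %.3f, p = %.2g (%s)\n",
            s$blunting$main_effect_estimate, s$blunting$main_effect_p,
            if (s$blunting$blunted) "blunting detected" else "no blunting"))
cat(sprintf("  sign-split condition x PE-sign interaction: F = %.2f, p = %.2g\n",
            s$sign_split$interaction_F, s$sign_split$interaction_p))
cat(sprintf("  responsivity correlation (gain/stress slope vs delta stress): rho = %.2f, p = %.2g\n",
            res$responsivity$rho, res$responsivity$p))
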