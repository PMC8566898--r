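#!/usr/bin/env Rscript
# Stage 2 — behavioural analyses.
#
# Runs the behavioural chain on the simulated cohort: responder filter,
# manipulation-check repeated-measures ANOVA on self-reported stress,
# trial-wise mixed-effects logistic regression of correct choice
# (condition + valence + block + trial + condition x valence, random
# intercept per participant), planned stress-vs-control contrasts within
# each valence, and learning curves. Tables land in results/behaviour.

suppressPackageStartupMessages(library(stressrl))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[[1]]) else 2024L

res <- run_pipeline(run_config(out_dir = "results/behaviour", seed = seed,
                               analyses = "behaviour"))
s <- res$summary$behaviour
cat("Behavioural results (results/behaviour):\n")
cat(sprintf("  condition x valence interaction: beta = %.3f, p = %.2g\n",
            s$interaction_beta, s$interaction_p))
cat(sprintf("  stress effect in gain trials:  p = %.2g\n", s$gain_contrast_p))
cat(sprintf("  stress effect in loss trials:  p = %.2g\n", s$loss_contrast_p))
cat(sprintf("  gain-specific impairment under stress: %s\n",
            if (s$gain_impaired_selectively) "yes" else "no"))
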