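#!/usr/bin/env Rscript
# Stage 1 — simulate the study cohort.
#
# Generates the synthetic cohort that stands in for the study's raw data:
# 37 participants, 23 of whom respond to the stress manipulation, each
# completing 2 runs x 2 alternating stress/control blocks of 72 trials
# (3 pairs x 24 presentations, reciprocal 0.75/0.25 contingencies, +/-0.5
# euro). Choices come from the dual-learning-rate Q-learning model with the
# positive-PE learning rate reduced under stress; ROI BOLD is built from
# each participant's own design with the stress prediction-error slope
# blunted. Writes a self-contained fixture directory (events files,
# self-report CSV, ROI time series, ground-truth JSON).

suppressPackageStartupMessages(library(stressrl))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[[1]]) else 2024L

dir <- "results/cohort"
spec <- effect_spec()
cohort <- end_to_end_fixture(dir, spec, seed = seed)

incl <- responder_filter(cohort$reports)$included
n_trials <- sum(vapply(cohort$sessions, nrow, integer(1)))
n_missing <- sum(vapply(cohort$sessions,
                        function(s) sum(s$choice == "missing"), numeric(1)))
cat("Cohort written to", dir, "\n")
cat(sprintf("  participants: %d (%d stress responders enter the analyses)\n",
            spec$n_participants, length(incl)))
cat(sprintf("  trials: %d total, %d missing (%.2f%%)\n",
            n_trials, n_missing, 100 * n_missing / n_trials))
cat(sprintf("  responder-only trials: %d\n",
            sum(vapply(cohort$sessions[incl], nrow, integer(1)))))
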