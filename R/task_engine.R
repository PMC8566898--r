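#' Task configuration for the probabilistic gain/loss learning task
#'
#' Describes the generative structure of the two-run reinforcement-learning
#' task: each run contains one stress and one control block (alternating,
#' counterbalanced across runs), each block introduces three fresh stimulus
#' pairs (gain, loss, neutral) and presents each pair 24 times, so a block has
#' 72 trials. Within a pair the better ("correct") stimulus delivers the good
#' outcome with probability `p_good` and the other stimulus with probability
#' `1 - p_good`; monetary outcomes are `+magnitude` (gain pairs),
#' `-magnitude` (loss pairs) or 0. Trial timing (stimulus-to-outcome delay
#' and inter-trial interval) is configurable; the defaults are typical
#' event-related spacing.
#'
#' @param pairs_per_block Number of stimulus pairs introduced per block.
#'   Pairs take valences `gain`, `loss`, `neutral` in that order, so the
#'   default 3 gives one pair of each valence.
#' @param presentations Presentations of each pair within its block (must be
#'   even so left/right placement of the correct stimulus can be balanced).
#' @param p_good Probability that the correct stimulus of a pair yields the
#'   better outcome; the two stimuli are reciprocal (`p_good`, `1 - p_good`).
#' @param magnitude Money at stake per trial, in euro.
#' @param blocks_per_condition Blocks per condition (stress/control); with 2
#'   runs of 2 alternating blocks the default is 2.
#' @param delay Stimulus-to-outcome delay in seconds.
#' @param iti_min,iti_max Bounds of the uniform inter-trial interval
#'   (outcome offset to next stimulus onset), seconds. Set equal for a fixed
#'   ITI.
#' @return A list of class `task_config`.
#' @export
task_config <- function(pairs_per_block = 3, presentations = 24,
                        p_good = 0.75, magnitude = 0.5,
                        blocks_per_condition = 2,
                        delay = 4, iti_min = 2, iti_max = 6) {
  if (presentations %% 2 != 0) {
    stop("`presentations` must be even: left/right side balance of the ",
         "correct stimulus is impossible with ", presentations,
         " presentations per pair.")
  }
  if (!(p_good > 0.5 && p_good <= 1)) {
    stop("`p_good` must lie in (0.5, 1].")
  }
  if (magnitude <= 0) stop("`magnitude` must be positive.")
  if (delay <= 0 || iti_min <= 0) stop("`delay` and ITI must be positive.")
  if (iti_max < iti_min) stop("`iti_max` must be >= `iti_min`.")
  structure(
    list(pairs_per_block = pairs_per_block, presentations = presentations,
         p_good = p_good, magnitude = magnitude,
         blocks_per_condition = blocks_per_condition,
         delay = delay, iti_min = iti_min, iti_max = iti_max),
    class = "task_config")
}

pair_valences <- function(n_pairs) {
  rep_len(c("gain", "loss", "neutral"), n_pairs)
}

#' Build a randomized trial schedule for one participant
#'
#' Lays out the full session: 2 runs, each with one stress and one control
#' block in alternation. Run 1 starts with stress for even participant ids and
#' control for odd ids (configurable via `first_condition`); run 2 starts with
#' the other condition, so conditions are counterbalanced across runs. Within
#' each block the pair presentation order is a uniform random permutation
#' subject to the presentations-per-pair constraint, and the side on which the
#' correct stimulus appears is balanced (half left, half right) within each
#' pair. Onsets are assigned run-wise via [assign_onsets()].
#'
#' @param participant_id Integer id; also used for default counterbalancing.
#' @param config A [task_config()].
#' @param seed Integer seed; identical seeds give identical schedules.
#' @param first_condition Condition of the first block of run 1, `"stress"`
#'   or `"control"`; default derived from the parity of `participant_id`.
#' @return A data frame of class `rl_schedule`, one row per trial, with
#'   columns `participant_id`, `run`, `condition`, `block` (1 or 2 within
#'   condition), `valence`, `pair_id`, `trial_in_pair`, `side_of_correct`,
#'   `stim_onset`, `outcome_onset`, and empty `choice`/`outcome_r`/
#'   `q_chosen`/`delta` columns filled in by [simulate_agent()].
#' @export
build_schedule <- function(participant_id = 1L, config = task_config(),
                           seed = NULL,
                           first_condition = if (participant_id %% 2 == 0)
                             "stress" else "control") {
  stopifnot(inherits(config, "task_config"))
  first_condition <- match.arg(first_condition, c("stress", "control"))
  if (!is.null(seed)) set.seed(seed)
  other <- setdiff(c("stress", "control"), first_condition)
  n_runs <- config$blocks_per_condition  # one block per condition per run
  rows <- vector("list", n_runs * 2L)
  k <- 0L
  block_count <- c(stress = 0L, control = 0L)
  for (run in seq_len(n_runs)) {
    # conditions alternate within a run; the starting condition alternates
    # across runs (counterbalanced order)
    run_order <- if (run %% 2 == 1) c(first_condition, other)
                 else c(other, first_condition)
    for (cond in run_order) {
      block_count[cond] <- block_count[cond] + 1L
      k <- k + 1L
      rows[[k]] <- build_block(run, cond, block_count[[cond]], config)
    }
  }
  sched <- do.call(rbind, rows)
  sched <- cbind(participant_id = as.integer(participant_id), sched)
  sched$choice <- NA_character_
  sched$outcome_r <- NA_real_
  sched$q_chosen <- NA_real_
  sched$delta <- NA_real_
  sched <- assign_onsets(sched, config)
  class(sched) <- c("rl_schedule", "data.frame")
  attr(sched, "config") <- config
  sched
}

# One block: random presentation order over pairs, side balance within pair.
build_block <- function(run, condition, block, config) {
  n_pairs <- config$pairs_per_block
  valences <- pair_valences(n_pairs)
  pair_ids <- sprintf("r%d_%s%d_%s", run, condition, block, valences)
  n_trials <- n_pairs * config$presentations
  order_idx <- sample(rep(seq_len(n_pairs), each = config$presentations))
  sides <- matrix("", nrow = config$presentations, ncol = n_pairs)
  for (p in seq_len(n_pairs)) {
    sides[, p] <- sample(rep(c("left", "right"), each = config$presentations / 2))
  }
  count <- integer(n_pairs)
  trial_in_pair <- integer(n_trials)
  side_of_correct <- character(n_trials)
  for (t in seq_len(n_trials)) {
    p <- order_idx[t]
    count[p] <- count[p] + 1L
    trial_in_pair[t] <- count[p]
    side_of_correct[t] <- sides[count[p], p]
  }
  data.frame(
    run = run, condition = condition, block = block,
    valence = valences[order_idx], pair_id = pair_ids[order_idx],
    trial_in_pair = trial_in_pair, side_of_correct = side_of_correct,
    stringsAsFactors = FALSE)
}

#' Assign stimulus and outcome onsets to a schedule
#'
#' Onsets accumulate within each run (the clock restarts at 0 for every run):
#' `outcome_onset = stim_onset + delay`, and the next stimulus follows the
#' outcome after an inter-trial interval drawn uniformly from
#' `[iti_min, iti_max]` (fixed when the bounds coincide). Draws come from the
#' current RNG state, so a schedule built under a seed is fully reproducible.
#'
#' @param schedule A schedule data frame (rows ordered as presented).
#' @param config A [task_config()] supplying `delay`, `iti_min`, `iti_max`.
#' @return The schedule with `stim_onset` and `outcome_onset` columns
#'   (strictly increasing within each run).
#' @export
assign_onsets <- function(schedule, config = attr(schedule, "config")) {
  if (config$delay <= 0 || config$iti_min <= 0) {
    stop("`delay` and ITI must be positive.")
  }
  schedule$stim_onset <- NA_real_
  schedule$outcome_onset <- NA_real_
  for (run in unique(schedule$run)) {
    idx <- which(schedule$run == run)
    n <- length(idx)
    iti <- if (config$iti_max > config$iti_min)
      stats::runif(n, config$iti_min, config$iti_max)
    else rep(config$iti_min, n)
    # trial k starts after k-1 full (delay + ITI) cycles
    stim <- cumsum(c(0, (config$delay + iti)[-n]))
    schedule$stim_onset[idx] <- stim
    schedule$outcome_onset[idx] <- stim + config$delay
  }
  schedule
}

#' Sample the monetary outcome of one choice
#'
#' Implements the reciprocal 0.75/0.25 contingencies: on gain trials the
#' correct stimulus wins `+magnitude` with probability `p_good` (the incorrect
#' one with `1 - p_good`), on loss trials the incorrect stimulus loses
#' `-magnitude` with probability `p_good` (the correct one with `1 - p_good`),
#' and neutral trials always yield a financial outcome of 0.
#'
#' @param valence `"gain"`, `"loss"` or `"neutral"`.
#' @param choice `"correct"` or `"incorrect"` (missing choices have no
#'   outcome and raise an error).
#' @param config A [task_config()] giving `p_good` and `magnitude`.
#' @return The outcome in euro: one of `-magnitude`, `0`, `+magnitude`.
#' @export
sample_outcome <- function(valence, choice, config = task_config()) {
  if (is.na(choice) || choice == "missing") {
    stop("No outcome exists for a missing choice.")
  }
  choice <- match.arg(choice, c("correct", "incorrect"))
  valence <- match.arg(valence, c("gain", "loss", "neutral"))
  if (valence == "neutral") return(0)
  p_hit <- if (choice == "correct") {
    if (valence == "gain") config$p_good else 1 - config$p_good
  } else {
    if (valence == "gain") 1 - config$p_good else config$p_good
  }
  hit <- stats::runif(1) < p_hit
  if (valence == "gain") {
    if (hit) config$magnitude else 0
  } else {
    if (hit) -config$magnitude else 0
  }
}

#' Structural audit of a schedule
#'
#' Checks the block-level invariants: expected trial count per block, exact
#' presentations per pair, balanced left/right placement of the correct
#' stimulus within each pair, one pair per valence per block, fresh pair ids
#' per block, alternating conditions within runs, and strictly increasing
#' onsets within runs.
#'
#' @param schedule An `rl_schedule`.
#' @return Invisibly `TRUE`; stops with a message on the first violation.
#' @export
audit_schedule <- function(schedule) {
  config <- attr(schedule, "config")
  n_block <- config$pairs_per_block * config$presentations
  blocks <- split(schedule, interaction(schedule$run, schedule$condition,
                                        schedule$block, drop = TRUE))
  seen_pairs <- character(0)
  for (b in blocks) {
    if (nrow(b) != n_block) stop("Block has ", nrow(b), " trials, expected ", n_block)
    tab <- table(b$pair_id)
    if (any(tab != config$presentations)) stop("Unbalanced pair presentations.")
    if (any(unique(b$pair_id) %in% seen_pairs)) stop("Pair ids reused across blocks.")
    seen_pairs <- c(seen_pairs, unique(b$pair_id))
    vt <- table(unique(b[, c("pair_id", "valence")])$valence)
    expected_val <- table(pair_valences(config$pairs_per_block))
    if (!identical(sort(names(vt)), sort(names(expected_val))) ||
        any(vt[names(expected_val)] != expected_val)) {
      stop("Block valence composition wrong.")
    }
    for (p in unique(b$pair_id)) {
      sides <- table(b$side_of_correct[b$pair_id == p])
      if (length(sides) != 2 || sides[["left"]] != sides[["right"]]) {
        stop("Side of correct stimulus not balanced within pair ", p)
      }
    }
  }
  for (run in unique(schedule$run)) {
    r <- schedule[schedule$run == run, ]
    if (any(diff(r$stim_onset) <= 0)) stop("Onsets not strictly increasing in run ", run)
    if (any(r$outcome_onset <= r$stim_onset)) stop("Outcome before stimulus.")
    conds <- r$condition[!duplicated(paste(r$condition, r$block))]
    if (length(conds) > 1 && any(conds[-1] == conds[-length(conds)])) {
      stop("Conditions do not alternate within run ", run)
    }
  }
  invisible(TRUE)
}

#' Serialize a schedule to BIDS-style events tables
#'
#' Writes one tab-separated events file per run with two rows per trial
#' (stimulus and outcome stick events): columns `onset`, `duration` (0),
#' `trial_type`, `condition`, `valence`, `pair_id`, `choice`, `outcome_r`.
#' Missing trials have only a stimulus row (no outcome was presented).
#'
#' @param schedule An `rl_schedule` with choices filled in.
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix, e.g. `"sub-01"`.
#' @return Paths of the written files, invisibly.
#' @export
write_events <- function(schedule, dir, prefix = sprintf("sub-%02d",
                                                         schedule$participant_id[1])) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (run in sort(unique(schedule$run))) {
    r <- schedule[schedule$run == run, ]
    stim <- data.frame(onset = r$stim_onset, duration = 0,
                       trial_type = "stimulus", condition = r$condition,
                       valence = r$valence, pair_id = r$pair_id,
                       choice = r$choice, outcome_r = NA_real_,
                       stringsAsFactors = FALSE)
    ok <- !is.na(r$choice) & r$choice != "missing"
    out <- data.frame(onset = r$outcome_onset[ok], duration = 0,
                      trial_type = "outcome", condition = r$condition[ok],
                      valence = r$valence[ok], pair_id = r$pair_id[ok],
                      choice = r$choice[ok], outcome_r = r$outcome_r[ok],
                      stringsAsFactors = FALSE)
    ev <- rbind(stim, out)
    ev <- ev[order(ev$onset), ]
    path <- file.path(dir, sprintf("%s_run-%d_events.tsv", prefix, run))
    utils::write.table(ev, path, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Read BIDS-style events files back into a trial table
#'
#' Inverse of [write_events()] at the trial level: stimulus and outcome rows
#' are re-joined on (run, onset order) into one row per trial.
#'
#' @param paths Events file paths, one per run (run index taken from the
#'   `_run-<k>_` token in the file name).
#' @return A trial-level data frame with the schedule columns that the events
#'   dialect preserves (onsets, condition, valence, pair_id, choice,
#'   outcome_r).
#' @export
read_events <- function(paths) {
  runs <- lapply(paths, function(p) {
    run <- as.integer(sub(".*_run-(\\d+)_events\\.tsv$", "\\1", p))
    ev <- utils::read.table(p, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
    stim <- ev[ev$trial_type == "stimulus", ]
    out <- ev[ev$trial_type == "outcome", ]
    stim <- stim[order(stim$onset), ]
    trial <- data.frame(run = run, condition = stim$condition,
                        valence = stim$valence, pair_id = stim$pair_id,
                        choice = stim$choice, stim_onset = stim$onset,
                        outcome_onset = NA_real_, outcome_r = NA_real_,
                        stringsAsFactors = FALSE)
    if (nrow(out)) {
      # each outcome belongs to the nearest preceding stimulus
      j <- findInterval(out$onset, stim$onset)
      trial$outcome_onset[j] <- out$onset
      trial$outcome_r[j] <- out$outcome_r
    }
    trial
  })
  do.call(rbind, runs)
}
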