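#' Design configuration defaults
#'
#' Returns the design parameters of the two-task attention experiment, all
#' overridable: 4 runs per task of 25 trials, 80% cue validity, task-relevant
#' and task-irrelevant matches each present on half of the trials
#' (independently), a stay/switch cue embedded on two-thirds of trials,
#' attention-cue durations drawn from {1.5, 2, 2.5} s with per-run balance,
#' and a fixed 25-value ITI set (truncated-exponential family calibrated to a
#' 6.66 s mean, truncation 9 s) permuted per run.
#'
#' @param ... named overrides of any default.
#' @return a list of design parameters.
#' @export
designConfig <- function(...) {
  cfg <- list(
    trials_per_run = 25L,
    runs_per_task = 4L,
    valid_fraction = 0.8,
    rel_match_rate = 0.5,
    irrel_match_rate = 0.5,
    cue_fraction = 2 / 3,
    task_order = c("memory_guided", "explicit"),
    cue_durations = c(1.5, 2, 2.5),
    iti_target_mean = 6.66,
    iti_truncation = 9,
    iti_tolerance = 0.01,
    probe_max_duration_s = 2.0,
    base_duration_s = 2.0,
    search_duration_s = 1.25,
    gap_s = 0.1,
    n_search = 4L,
    lead_in_s = 2.0,
    default_rt_s = 1.0,
    n_base_sets = 20L
  )
  override <- list(...)
  if (length(override) == 1L && is.list(override[[1]]) &&
      is.null(names(override))) {
    override <- override[[1]]
  }
  unknown <- setdiff(names(override), names(cfg))
  if (length(unknown)) stopf("unknown design options: %s",
                             paste(unknown, collapse = ", "))
  modifyList(cfg, override)
}

#' Stay/switch cue logic
#'
#' Maps the previous trial's attentional state and embedded cue to the state
#' that should be selected on the current trial: a stay cue repeats the
#' previous state, a switch cue flips it, and after a no-cue trial the state
#' is a free choice.
#'
#' @param current_state `"art"` or `"room"`: the previous trial's state.
#' @param cue_type `"stay"`, `"switch"` or `"none"`: the cue embedded in the
#'   previous trial's search set.
#' @param free_choice required iff `cue_type == "none"`: the freely chosen
#'   state.
#' @return `"art"` or `"room"`.
#' @examples
#' deriveNextState("art", "switch")            # "room"
#' deriveNextState("room", "stay")             # "room"
#' deriveNextState("art", "none", "art")       # "art"
#' @export
deriveNextState <- function(current_state, cue_type,
                            free_choice = NULL) {
  current_state <- match.arg(current_state, c("art", "room"))
  cue_type <- match.arg(cue_type, c("stay", "switch", "none"))
  if (cue_type == "none") {
    if (is.null(free_choice)) {
      stopf("cue_type 'none' requires a free_choice state")
    }
    return(match.arg(free_choice, c("art", "room")))
  }
  if (!is.null(free_choice)) {
    stopf("free_choice must only be supplied with cue_type 'none'")
  }
  if (cue_type == "stay") current_state
  else if (current_state == "art") "room" else "art"
}

#' Fixed inter-trial-interval set with per-run seeded orderings
#'
#' Builds one fixed set of `n` ITI durations from a truncated-exponential
#' family and returns seeded random per-run orderings of that same set. The
#' set is constructed by inverse-CDF evaluation at the `n` quantile midpoints
#' with the rate numerically calibrated so the set mean equals
#' `target_mean_s`; only the per-run ordering depends on the seed. Note that a
#' positive-rate exponential truncated at 9 s cannot have a mean above 4.5 s,
#' so means in (T/2, T) are realized with a negative rate (increasing
#' density); the calibration is to the printed mean, not to a particular
#' published construction.
#'
#' @param n number of ITIs per run (>= 1).
#' @param params list with `target_mean_s` (default 6.66), `truncation_s`
#'   (default 9) and `tolerance_s` (default 0.01).
#' @param rng_seed integer seed for the orderings.
#' @param n_runs number of per-run orderings to return.
#' @return numeric matrix `n_runs x n`; each row is a permutation of the same
#'   fixed set. The set itself is in `attr(, "iti_set")`, the calibrated rate
#'   in `attr(, "rate")`.
#' @export
sampleItis <- function(n, params = list(), rng_seed = 0L, n_runs = 1L) {
  if (n < 1L) stopf("n must be >= 1")
  target <- params$target_mean_s %||% 6.66
  Tmax <- params$truncation_s %||% 9
  tol <- params$tolerance_s %||% 0.01
  if (target <= 0 || target >= Tmax) {
    stopf("calibration error: target mean %.3g s unreachable with truncation %.3g s",
          target, Tmax)
  }
  p <- (seq_len(n) - 0.5) / n
  setFor <- function(lam) {
    if (abs(lam) < 1e-9) return(p * Tmax)
    -log(1 - p * (1 - exp(-lam * Tmax))) / lam
  }
  f <- function(lam) mean(setFor(lam)) - target
  interval <- if (target > Tmax / 2) c(-30, -1e-7) else c(1e-7, 30)
  if (abs(target - Tmax / 2) < 1e-9) {
    rate <- 0
  } else {
    root <- tryCatch(uniroot(f, interval, tol = 1e-12),
                     error = function(e) NULL)
    if (is.null(root)) {
      stopf("calibration error: could not reach target mean %.3g s", target)
    }
    rate <- root$root
  }
  iti_set <- setFor(rate)
  if (abs(mean(iti_set) - target) > tol) {
    stopf("calibration error: set mean %.4f s outside tolerance of %.4f s",
          mean(iti_set), target)
  }
  out <- withSeed(childSeed(rng_seed, "itis"), {
    t(vapply(seq_len(n_runs),
             function(r) iti_set[sample.int(n)], numeric(n)))
  })
  attr(out, "iti_set") <- iti_set
  attr(out, "rate") <- rate
  out
}

#' Per-trial event timeline
#'
#' Computes event onsets (seconds from run start) for one trial: initiation
#' screen (until the participant's key press), attention cue (1.5/2/2.5 s),
#' base image (2 s), four search images (1.25 s each, each preceded by a
#' 0.1 s gap), and the probe (0.1 s after the last search offset, up to 2 s).
#' The image-period span (base onset to last search offset) is constant at
#' 7.4 s regardless of the other timing parameters.
#'
#' @param start_s trial start (initiation-screen onset), seconds >= 0.
#' @param initiation_rt_s time until the initiation key press, > 0.
#' @param cue_duration_s attention-cue duration; must be one of
#'   `allowed_cues`.
#' @param config design configuration ([designConfig()]).
#' @param allowed_cues permitted cue durations.
#' @return a one-row data.frame with columns `initiation_onset`, `cue_onset`,
#'   `cue_duration_s`, `base_onset`, `search_onset_1..4`, `probe_onset`,
#'   `probe_max_duration_s`, `image_period_end`.
#' @examples
#' trialTimeline(0, 1, 1.5)$base_onset       # 2.5
#' tl <- trialTimeline(10, 0.8, 2)
#' tl$image_period_end - tl$base_onset       # 7.4
#' @export
trialTimeline <- function(start_s, initiation_rt_s, cue_duration_s,
                          config = designConfig(),
                          allowed_cues = config$cue_durations) {
  if (start_s < 0 || initiation_rt_s < 0) {
    stopf("start_s and initiation_rt_s must be non-negative")
  }
  if (!any(abs(cue_duration_s - allowed_cues) < 1e-9)) {
    stopf("cue_duration_s must be one of {%s}",
          paste(allowed_cues, collapse = ", "))
  }
  gap <- config$gap_s
  cue_onset <- start_s + initiation_rt_s
  base_onset <- cue_onset + cue_duration_s
  search_step <- gap + config$search_duration_s
  search_onsets <- base_onset + config$base_duration_s + gap +
    (seq_len(config$n_search) - 1L) * search_step
  image_end <- search_onsets[config$n_search] + config$search_duration_s
  probe_onset <- image_end + gap
  out <- data.frame(initiation_onset = start_s,
                    cue_onset = cue_onset,
                    cue_duration_s = cue_duration_s,
                    base_onset = base_onset,
                    probe_onset = probe_onset,
                    probe_max_duration_s = config$probe_max_duration_s,
                    image_period_end = image_end)
  for (i in seq_len(config$n_search)) {
    out[[paste0("search_onset_", i)]] <- search_onsets[i]
  }
  out
}

# stratified binary assignment: exactly n_present of the trials get TRUE,
# spread over the supplied cells as equally as possible (seeded tie-breaks)
.balancedBinary <- function(cells, n_present) {
  n <- length(cells)
  stopifnot(n_present <= n)
  out <- logical(n)
  idx_by_cell <- split(seq_len(n), cells)
  base_counts <- vapply(idx_by_cell, function(ix) length(ix) %/% 2L, 0L)
  assigned <- sum(base_counts)
  extra <- n_present - assigned
  cell_names <- names(idx_by_cell)
  odd_cells <- cell_names[vapply(idx_by_cell, length, 0L) %% 2L == 1L]
  grab <- character(0)
  if (extra > 0) {
    pool <- sample(odd_cells)
    grab <- head(pool, extra)
    if (extra > length(pool)) {
      # fall back: top up from random cells with spare capacity
      spare <- rep(cell_names, times = vapply(idx_by_cell, length, 0L) -
                     (base_counts + as.integer(cell_names %in% pool)))
      grab <- c(grab, sample(spare, extra - length(pool)))
    }
  } else if (extra < 0) {
    pool <- sample(cell_names[base_counts > 0])
    drop <- head(pool, -extra)
    base_counts[drop] <- base_counts[drop] - 1L
  }
  for (cn in cell_names) {
    k <- base_counts[[cn]] + sum(grab == cn)
    take <- sample(idx_by_cell[[cn]], min(k, length(idx_by_cell[[cn]])))
    out[take] <- TRUE
  }
  # exact global count (guard against rounding pathologies)
  excess <- sum(out) - n_present
  if (excess > 0) out[sample(which(out), excess)] <- FALSE
  if (excess < 0) out[sample(which(!out), -excess)] <- TRUE
  out
}

# deterministic cue-type counts: floor thirds with the remainder going to
# none, then switch (for the default 2/3 cue fraction and 100 trials this
# gives stay 33, switch 33, none 34)
.cueTypeCounts <- function(n_trials, cue_fraction) {
  n_cued <- round(n_trials * cue_fraction)
  stay <- n_cued %/% 2L
  switch_ <- n_cued - stay
  c(stay = stay, switch = switch_, none = n_trials - n_cued)
}

# greedy free choices that keep art/room counts balanced: at each free slot
# the determined segment until the next free slot is inspected and the choice
# minimizing the cumulative imbalance is taken (seeded tie-break)
.memoryStateChain <- function(cue_seq, free_pos, n_trials) {
  states <- character(n_trials)
  imbalance <- 0L  # art minus room so far
  free_pos <- sort(free_pos)
  for (fi in seq_along(free_pos)) {
    i <- free_pos[fi]
    j_end <- if (fi < length(free_pos)) free_pos[fi + 1L] - 1L else n_trials
    # relative orientation of each segment trial w.r.t. the choice at i
    rel <- integer(j_end - i + 1L)
    rel[1] <- 1L
    if (j_end > i) {
      for (t in (i + 1L):j_end) {
        rel[t - i + 1L] <- if (cue_seq[t - 1L] == "switch") {
          -rel[t - i]
        } else rel[t - i]
      }
    }
    seg_net <- sum(rel)  # art-minus-room if "art" is chosen at i
    d_art <- abs(imbalance + seg_net)
    d_room <- abs(imbalance - seg_net)
    choice <- if (d_art < d_room) "art"
    else if (d_room < d_art) "room"
    else sample(c("art", "room"), 1L)
    seg_states <- ifelse(rel == (if (choice == "art") 1L else -1L),
                         "art", "room")
    states[i:j_end] <- seg_states
    imbalance <- imbalance + sum(seg_states == "art") -
      sum(seg_states == "room")
  }
  states
}

#' Build the two-task trial schedule
#'
#' Deterministically (given a seed) constructs the full experiment plan for
#' both tasks, satisfying the design constraints: each of the 20 base images
#' occurs exactly once in every aligned 20-trial window of a task, no base
#' image repeats on consecutive trials, 80% of trials are valid (probe
#' matches state), task-relevant and task-irrelevant matches are each present
#' on half the trials (independently, spread over design cells as equally as
#' possible), two-thirds of trials embed a stay/switch cue whose dimension
#' matches the trial's state, and in the memory-guided task the state
#' sequence is derivable from the cue sequence via [deriveNextState()] with
#' free choices on the first trial of each run and after no-cue trials (the
#' free choices are made greedily to keep art/room counts balanced). Cue
#' durations are balanced within run; each run reuses the same fixed ITI set
#' in seeded random order. Timelines are finalized with the configured
#' default initiation RT and can be re-finalized per participant with
#' [finalizeTimelines()].
#'
#' @param catalog a [StimulusCatalog-class] (built if missing).
#' @param config design parameters from [designConfig()].
#' @param rng_seed integer seed.
#' @return a [TrialSchedule-class].
#' @export
buildSchedule <- function(catalog = NULL, config = designConfig(),
                          rng_seed = 0L) {
  if (is.null(catalog)) catalog <- buildStimulusSet(rng_seed,
                                                    config$n_base_sets)
  n_run <- config$trials_per_run
  n_runs <- config$runs_per_task
  n_trials <- n_run * n_runs
  n_bs <- nrow(catalog@base_sets)
  if (n_trials %% n_bs != 0L) {
    stopf(paste0("constraint error: trials per task (%d) must be a multiple ",
                 "of the %d base images for aligned windowing"),
          n_trials, n_bs)
  }
  tasks <- config$task_order
  if (!setequal(tasks, c("memory_guided", "explicit"))) {
    stopf("task_order must contain memory_guided and explicit")
  }

  iti_orders <- sampleItis(n_run,
                           list(target_mean_s = config$iti_target_mean,
                                truncation_s = config$iti_truncation,
                                tolerance_s = config$iti_tolerance),
                           rng_seed = childSeed(rng_seed, "iti-order"),
                           n_runs = 2L * n_runs)

  all_tasks <- lapply(seq_along(tasks), function(ti) {
    .buildTaskTrials(catalog, config, tasks[ti],
                     childSeed(rng_seed, "task", tasks[ti]))
  })
  tr <- do.call(rbind, all_tasks)
  # global run index follows task order
  tr$run <- tr$run_in_task +
    (match(tr$task, tasks) - 1L) * n_runs
  tr <- tr[order(tr$run, tr$trial_in_run), ]
  rownames(tr) <- NULL
  tr$iti_s <- as.vector(t(iti_orders))[seq_len(nrow(tr))]

  sched <- new("TrialSchedule", trials = tr,
               runs_per_task = as.integer(n_runs),
               trials_per_run = as.integer(n_run),
               catalog = catalog,
               iti_set = as.numeric(attr(iti_orders, "iti_set")),
               config = config)
  finalizeTimelines(sched, config$default_rt_s)
}

.buildTaskTrials <- function(catalog, config, task, seed) {
  withSeed(seed, {
    n_run <- config$trials_per_run
    n_runs <- config$runs_per_task
    n <- n_run * n_runs
    bs <- catalog@base_sets
    n_bs <- nrow(bs)

    # cue-type sequence
    counts <- .cueTypeCounts(n, config$cue_fraction)
    cue_seq <- sample(rep(c("stay", "switch", "none"), times = counts))

    trial_in_run <- rep(seq_len(n_run) - 1L, n_runs)
    run_in_task <- rep(seq_len(n_runs) - 1L, each = n_run)

    # states
    if (task == "memory_guided") {
      run_starts <- which(trial_in_run == 0L)
      after_none <- which(c(FALSE, head(cue_seq, -1L) == "none"))
      free_pos <- sort(union(run_starts, after_none))
      states <- .memoryStateChain(cue_seq, free_pos, n)
    } else {
      states <- sample(rep(c("art", "room"), length.out = n))
    }

    # validity: exactly round((1 - valid_fraction) * n) invalid trials,
    # spread over state x cue-type cells
    n_invalid <- round((1 - config$valid_fraction) * n)
    invalid <- .balancedBinary(paste(states, cue_seq), n_invalid)
    validity <- ifelse(invalid, "invalid", "valid")
    probe <- ifelse(invalid,
                    ifelse(states == "art", "room", "art"),
                    states)

    # relevant / irrelevant matches (relative to the probe dimension),
    # balanced over state x validity x cue-type cells
    cells <- paste(states, validity, cue_seq)
    rel <- .balancedBinary(cells, round(config$rel_match_rate * n))
    irrel <- .balancedBinary(cells, round(config$irrel_match_rate * n))

    # base sets: aligned non-overlapping windows of n_bs trials, each window
    # a permutation, with no repeats across window boundaries
    n_win <- n %/% n_bs
    base_idx <- integer(0)
    for (w in seq_len(n_win)) {
      repeat {
        perm <- sample.int(n_bs)
        if (!length(base_idx) || perm[1L] != tail(base_idx, 1L)) break
      }
      base_idx <- c(base_idx, perm)
    }
    base_set_id <- bs$base_set_id[base_idx]

    # cue images: dimension equals the trial's state
    cue_imgs <- catalog@images[catalog@images$cue_role != "none", ]
    cue_image <- rep(NA_character_, n)
    for (i in which(cue_seq != "none")) {
      role <- paste0(states[i], "_", cue_seq[i])
      cue_image[i] <- sample(cue_imgs$image_id[cue_imgs$cue_role == role], 1L)
    }

    # search arrays: matches per probe dimension, cue image if any, fill with
    # distractors, shuffle presentation order
    search <- matrix(NA_character_, n, config$n_search)
    for (i in seq_len(n)) {
      row <- bs[base_idx[i], ]
      imgs <- character(0)
      art_present <- if (probe[i] == "art") rel[i] else irrel[i]
      room_present <- if (probe[i] == "room") rel[i] else irrel[i]
      if (art_present) imgs <- c(imgs, row$art_match)
      if (room_present) imgs <- c(imgs, row$room_match)
      if (!is.na(cue_image[i])) imgs <- c(imgs, cue_image[i])
      dpool <- unlist(row[paste0("distractor_", 1:4)], use.names = FALSE)
      imgs <- c(imgs, sample(dpool, config$n_search - length(imgs)))
      search[i, ] <- sample(imgs)
    }

    # cue durations balanced within run
    cue_dur <- numeric(n)
    durs <- config$cue_durations
    for (r in seq_len(n_runs)) {
      ix <- which(run_in_task == r - 1L)
      reps <- rep(durs, length.out = length(ix))
      cue_dur[ix] <- sample(reps)
    }

    prev_cue <- c(NA_character_, head(cue_seq, -1L))
    prev_cue[trial_in_run == 0L] <- NA_character_

    out <- data.frame(task = task,
                      run_in_task = run_in_task,
                      trial_in_run = trial_in_run,
                      trial_index = seq_len(n) - 1L,
                      state = states, probe = probe, validity = validity,
                      cue_type = cue_seq, cue_image = cue_image,
                      prev_cue_type = prev_cue,
                      base_set_id = base_set_id,
                      rel_match = rel, irrel_match = irrel,
                      cue_duration_s = cue_dur,
                      stringsAsFactors = FALSE)
    for (j in seq_len(config$n_search)) {
      out[[paste0("search_", j)]] <- search[, j]
    }
    out
  })
}

#' Finalize per-trial timelines for given initiation response times
#'
#' Recomputes all trial onsets from run start given per-trial initiation
#' response times (e.g., simulated per participant). Trials are laid out
#' sequentially: lead-in, then for each trial initiation screen (RT), cue,
#' base, search images, probe (full maximum duration), ITI.
#'
#' @param schedule a [TrialSchedule-class].
#' @param initiation_rt_s scalar or per-trial vector of initiation RTs (s).
#' @return the schedule with timeline columns updated.
#' @export
finalizeTimelines <- function(schedule, initiation_rt_s = NULL) {
  cfg <- schedule@config
  tr <- schedule@trials
  rts <- initiation_rt_s %||% cfg$default_rt_s
  if (length(rts) == 1L) rts <- rep(rts, nrow(tr))
  if (length(rts) != nrow(tr)) {
    stopf("initiation_rt_s must be scalar or one value per trial")
  }
  if (any(rts < 0)) stopf("initiation RTs must be non-negative")
  gap <- cfg$gap_s
  span <- cfg$base_duration_s +
    cfg$n_search * (gap + cfg$search_duration_s)  # 7.4 s by default
  total <- rts + tr$cue_duration_s + span + gap +
    cfg$probe_max_duration_s + tr$iti_s
  # sequential layout within each run (trials are ordered by run)
  starts <- numeric(nrow(tr))
  for (r in unique(tr$run)) {
    ix <- which(tr$run == r)
    starts[ix] <- cfg$lead_in_s + c(0, cumsum(total[ix][-length(ix)]))
  }
  tr$initiation_onset <- starts
  tr$initiation_rt_s <- rts
  tr$cue_onset <- starts + rts
  tr$base_onset <- tr$cue_onset + tr$cue_duration_s
  for (j in seq_len(cfg$n_search)) {
    tr[[paste0("search_onset_", j)]] <- tr$base_onset +
      cfg$base_duration_s + gap + (j - 1L) * (gap + cfg$search_duration_s)
  }
  tr$image_period_end <- tr$base_onset + span
  tr$probe_onset <- tr$image_period_end + gap
  tr$probe_max_duration_s <- cfg$probe_max_duration_s
  tr$trial_end <- tr$probe_onset + cfg$probe_max_duration_s
  schedule@trials <- tr
  schedule
}

#' Run durations of a schedule
#'
#' @param schedule a [TrialSchedule-class].
#' @return named numeric vector: seconds from run start to the last trial's
#'   end (probe offset), per global run index.
#' @export
runDurations <- function(schedule) {
  tr <- schedule@trials
  vapply(split(tr$trial_end, tr$run), max, numeric(1))
}

#' Write per-run BIDS-style event tables
#'
#' One tab-separated file per run with columns `onset`, `duration`,
#' `trial_type` (orienting / image / probe), `task`, `state`, `probe`,
#' `validity`, `cue_type`, `run` (0-based), in seconds.
#'
#' @param schedule a [TrialSchedule-class] with finalized timelines.
#' @param dir output directory (created if needed).
#' @param participant participant label used in file names.
#' @return invisibly, the paths written.
#' @export
writeEventTables <- function(schedule, dir, participant = "sub-01") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tr <- schedule@trials
  paths <- character(0)
  for (r in sort(unique(tr$run))) {
    sub <- tr[tr$run == r, ]
    ev <- do.call(rbind, lapply(seq_len(nrow(sub)), function(i) {
      x <- sub[i, ]
      data.frame(
        onset = c(x$initiation_onset, x$base_onset, x$probe_onset),
        duration = c(x$cue_onset + x$cue_duration_s - x$initiation_onset,
                     x$image_period_end - x$base_onset,
                     x$probe_max_duration_s),
        trial_type = c("orienting", "image", "probe"),
        task = x$task, state = x$state, probe = x$probe,
        validity = x$validity, cue_type = x$cue_type, run = x$run,
        stringsAsFactors = FALSE)
    }))
    path <- file.path(dir, sprintf("%s_task-%s_run-%02d_events.tsv",
                                   participant, sub$task[1], r))
    write.table(ev, path, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, path)
  }
  invisible(paths)
}
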