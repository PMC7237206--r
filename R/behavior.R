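#' Behavioral participant parameters
#'
#' Ground-truth response parameters for the behavioral simulator. Defaults
#' emulate a well-trained participant: near-ceiling stay/switch decision
#' accuracy, validity-dependent match-detection rates giving above-chance
#' sensitivity on valid trials and chance sensitivity on invalid trials, and
#' ~1 s initiation response times.
#'
#' @param selection_accuracy probability the stay/switch (or no-cue) state
#'   decision is correct in the memory-guided task.
#' @param hit_rate_valid,fa_rate_valid hit / false-alarm rates when the probe
#'   matches the attended state.
#' @param hit_rate_invalid,fa_rate_invalid rates when the probe mismatches
#'   the attended state (equal rates give chance A').
#' @param free_choice_art_prob probability of choosing "art" on free-choice
#'   trials.
#' @param initiation_rt_mean_s,initiation_rt_sd_s mean and SD of the
#'   initiation response time (truncated normal, floor 0.2 s).
#' @return a named list of class `participant_params`.
#' @export
participantParams <- function(selection_accuracy = 0.95,
                              hit_rate_valid = 0.8,
                              fa_rate_valid = 0.2,
                              hit_rate_invalid = 0.5,
                              fa_rate_invalid = 0.5,
                              free_choice_art_prob = 0.5,
                              initiation_rt_mean_s = 1.0,
                              initiation_rt_sd_s = 0.25) {
  p <- list(selection_accuracy = selection_accuracy,
            hit_rate_valid = hit_rate_valid,
            fa_rate_valid = fa_rate_valid,
            hit_rate_invalid = hit_rate_invalid,
            fa_rate_invalid = fa_rate_invalid,
            free_choice_art_prob = free_choice_art_prob,
            initiation_rt_mean_s = initiation_rt_mean_s,
            initiation_rt_sd_s = initiation_rt_sd_s)
  for (nm in setdiff(names(p), c("initiation_rt_mean_s",
                                 "initiation_rt_sd_s"))) {
    assertProb(p[[nm]], nm)
  }
  if (initiation_rt_mean_s <= 0 || initiation_rt_sd_s <= 0) {
    stopf("initiation RT parameters must be positive")
  }
  class(p) <- "participant_params"
  p
}

#' Simulate behavioral responses for one participant
#'
#' Walks the schedule trial by trial. In the memory-guided task the chosen
#' state follows the stay/switch logic applied to the participant's *own*
#' previous choice (so a selection error propagates until the next free
#' choice): the derived state is selected with probability
#' `selection_accuracy`, otherwise it flips; free-choice trials (first of
#' each run, and trials after a no-cue trial) choose art with probability
#' `free_choice_art_prob`. In the explicitly instructed task the chosen state
#' is the scheduled (instructed) one. Match responses are drawn from
#' validity-conditioned hit / false-alarm rates, where experienced validity
#' is `probe == chosen_state`.
#'
#' @param schedule a [TrialSchedule-class].
#' @param participant a [participantParams()] list.
#' @param rng_seed integer seed.
#' @param free_choice `"schedule"` (default): free-choice trials adopt the
#'   schedule's recorded choices, which emulate a participant balancing art
#'   and room as instructed; `"random"`: free choices are drawn anew with
#'   `free_choice_art_prob` (experienced validity then deviates from the
#'   scheduled 80% on those trials, since the probe is unchanged).
#' @return data.frame, one row per trial: `chosen_state`, `validity_exp`
#'   (experienced validity), `match_present` (relative to the probe),
#'   `response` ("present"/"absent"), `correct`, `decision_correct` (NA
#'   except on memory-guided trials following a stay/switch cue),
#'   `initiation_rt_s`, plus the trial keys.
#' @export
simulateBehavior <- function(schedule, participant = participantParams(),
                             rng_seed = 0L,
                             free_choice = c("schedule", "random")) {
  free_choice <- match.arg(free_choice)
  tr <- trials(schedule)
  p <- participant
  withSeed(childSeed(rng_seed, "behavior"), {
    n <- nrow(tr)
    chosen <- character(n)
    decision_correct <- rep(NA, n)
    ord <- order(tr$task, tr$trial_index)
    prev_chosen <- list(memory_guided = NA_character_,
                        explicit = NA_character_)
    for (i in ord) {
      task <- tr$task[i]
      if (task == "explicit") {
        chosen[i] <- tr$state[i]
        next
      }
      first_of_run <- tr$trial_in_run[i] == 0L
      prev_cue <- tr$prev_cue_type[i]
      if (first_of_run || is.na(prev_cue) || prev_cue == "none") {
        # the schedule records this participant's own free choices (made to
        # keep art/room roughly balanced, as instructed); free_choice = "random"
        # draws them anew with free_choice_art_prob instead
        chosen[i] <- if (free_choice == "schedule") tr$state[i]
        else if (runif(1) < p$free_choice_art_prob) "art" else "room"
        if (!first_of_run && !is.na(prev_cue) && prev_cue == "none") {
          decision_correct[i] <- TRUE  # any free choice is acceptable
        }
      } else {
        intended <- deriveNextState(prev_chosen[[task]], prev_cue)
        ok <- runif(1) < p$selection_accuracy
        chosen[i] <- if (ok) intended
        else if (intended == "art") "room" else "art"
        decision_correct[i] <- chosen[i] == intended
      }
      prev_chosen[[task]] <- chosen[i]
    }

    validity_exp <- ifelse(tr$probe == chosen, "valid", "invalid")
    # rel_match is defined relative to the probe dimension at schedule build
    match_present <- tr$rel_match
    hit <- ifelse(validity_exp == "valid", p$hit_rate_valid,
                  p$hit_rate_invalid)
    fa <- ifelse(validity_exp == "valid", p$fa_rate_valid,
                 p$fa_rate_invalid)
    p_present <- ifelse(match_present, hit, fa)
    response <- ifelse(runif(n) < p_present, "present", "absent")
    correct <- (response == "present") == match_present
    rt <- pmax(0.2, rnorm(n, p$initiation_rt_mean_s, p$initiation_rt_sd_s))

    data.frame(task = tr$task, run = tr$run,
               trial_index = tr$trial_index,
               trial_in_run = tr$trial_in_run,
               state = tr$state, probe = tr$probe,
               chosen_state = chosen,
               validity = tr$validity, validity_exp = validity_exp,
               match_present = match_present,
               response = response, correct = correct,
               decision_correct = decision_correct,
               initiation_rt_s = rt,
               stringsAsFactors = FALSE)
  })
}

#' Summarize behavior into signal-detection rates and A'
#'
#' Computes hit and false-alarm rates by task and experienced validity and
#' the corresponding nonparametric sensitivity [aPrime()], plus stay/switch
#' decision accuracy for the memory-guided task.
#'
#' @param behavior output of [simulateBehavior()].
#' @return list with `sdt` (data.frame: task, validity, hit_rate, fa_rate,
#'   a_prime, n_trials) and `decision_accuracy` (scalar).
#' @export
summarizeBehavior <- function(behavior) {
  cells <- split(behavior,
                 list(behavior$task, behavior$validity_exp), drop = TRUE)
  sdt <- do.call(rbind, lapply(cells, function(b) {
    h <- mean(b$response[b$match_present] == "present")
    f <- mean(b$response[!b$match_present] == "present")
    data.frame(task = b$task[1], validity = b$validity_exp[1],
               hit_rate = h, fa_rate = f, a_prime = aPrime(h, f),
               n_trials = nrow(b), stringsAsFactors = FALSE)
  }))
  rownames(sdt) <- NULL
  dec <- behavior$decision_correct[behavior$task == "memory_guided" &
                                     !is.na(behavior$decision_correct)]
  list(sdt = sdt, decision_accuracy = mean(dec))
}
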