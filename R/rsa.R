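# Pearson correlation between rows of A and rows of B (or all row pairs of
# A when B is missing), computed on mean-centered vectors. Two-pass
# summation via the standard centered cross-product; contract: within 1e-10
# of a naive elementwise oracle.
.rowCor <- function(A, B = NULL) {
  As <- A - rowMeans(A)
  As <- As / sqrt(rowSums(As^2))
  if (is.null(B)) {
    tcrossprod(As)
  } else {
    Bs <- B - rowMeans(B)
    Bs <- Bs / sqrt(rowSums(Bs^2))
    tcrossprod(As, Bs)
  }
}

#' Image-period attentional-state pattern similarity
#'
#' Correlates every pair of image-period trial patterns within a task,
#' excluding pairs from the same run (to limit autocorrelation), Fisher
#' transforms the correlations, and averages them separately for same-state
#' pairs (art-art and room-room, each averaged first so the two states
#' weigh equally) and different-state pairs (art-room). Correlations of
#' exactly +/-1 are clipped to +/-(1 - 1e-12) before the transform.
#'
#' @param pp a [PeriodPatternSet-class] of image-period patterns.
#' @param task task to analyze (default: each task present, rbind-ed).
#' @param valid_only use valid trials only (default TRUE).
#' @return data.frame per task: `same_z`, `different_z`, `delta_z` and the
#'   `tanh`-backtransformed `same_r`, `different_r`, `delta_r`, plus pair
#'   counts.
#' @export
imageStateSimilarity <- function(pp, task = NULL, valid_only = TRUE) {
  lab <- patternLabels(pp)
  P <- patterns(pp)
  tasks <- task %||% unique(lab$task)
  out <- lapply(tasks, function(tk) {
    keep <- lab$task == tk
    if (valid_only) keep <- keep & lab$validity == "valid"
    l <- lab[keep, ]
    if (length(unique(l$run)) < 2L) {
      stopf("insufficient-runs error: task %s has <2 runs after filtering",
            tk)
    }
    R <- .rowCor(P[keep, , drop = FALSE])
    z <- fisherZ(clipR(R))
    cross_run <- outer(l$run, l$run, "!=")
    upper <- upper.tri(z)
    use <- upper & cross_run
    same_art <- use & outer(l$state == "art", l$state == "art", "&")
    same_room <- use & outer(l$state == "room", l$state == "room", "&")
    diff_pair <- use & outer(l$state, l$state, "!=")
    same_z <- mean(c(mean(z[same_art]), mean(z[same_room])))
    diff_z <- mean(z[diff_pair])
    data.frame(task = tk, same_z = same_z, different_z = diff_z,
               delta_z = same_z - diff_z,
               same_r = tanh(same_z), different_r = tanh(diff_z),
               delta_r = tanh(same_z) - tanh(diff_z),
               n_same_pairs = sum(same_art) + sum(same_room),
               n_different_pairs = sum(diff_pair),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Build art/room state templates from image-period patterns
#'
#' Averages image-period patterns into one template per attentional state,
#' excluding all trials from `exclude_run` (leave-one-run-out, so a trial is
#' never compared to templates containing trials from its own run).
#' Options: `valid_only` restricts to valid trials (default TRUE);
#' `common_across_tasks` pools both tasks (default TRUE, the main analysis);
#' set it to FALSE and supply `task` for per-task templates.
#'
#' @param pp a [PeriodPatternSet-class] of image-period patterns.
#' @param exclude_run global run index to leave out (NA to use all runs).
#' @param valid_only,common_across_tasks,task template options.
#' @return a [StateTemplates-class].
#' @export
buildTemplates <- function(pp, exclude_run = NA, valid_only = TRUE,
                           common_across_tasks = TRUE, task = NULL) {
  lab <- patternLabels(pp)
  keep <- rep(TRUE, nrow(lab))
  if (!is.na(exclude_run)) keep <- keep & lab$run != exclude_run
  if (valid_only) keep <- keep & lab$validity == "valid"
  if (!common_across_tasks) {
    if (is.null(task)) stopf("per-task templates require a task")
    keep <- keep & lab$task == task
  }
  art_rows <- keep & lab$state == "art"
  room_rows <- keep & lab$state == "room"
  if (!any(art_rows) || !any(room_rows)) {
    stopf("missing-state error: a state has no trials after filtering")
  }
  P <- patterns(pp)
  new("StateTemplates",
      art = colMeans(P[art_rows, , drop = FALSE]),
      room = colMeans(P[room_rows, , drop = FALSE]),
      excluded_run = as.integer(exclude_run),
      options = list(valid_only = valid_only,
                     common_across_tasks = common_across_tasks,
                     task = task))
}

#' Leave-one-run-out template provider
#'
#' Returns a function `f(run, task)` yielding [StateTemplates-class] built
#' from all runs except `run` (cached per run/task).
#'
#' @inheritParams buildTemplates
#' @return a closure providing templates per excluded run.
#' @export
templateProvider <- function(pp, valid_only = TRUE,
                             common_across_tasks = TRUE) {
  cache <- new.env(parent = emptyenv())
  function(run, task = NULL) {
    key <- paste(run, if (common_across_tasks) "common" else task)
    if (!is.null(cache[[key]])) return(cache[[key]])
    tm <- buildTemplates(pp, exclude_run = run, valid_only = valid_only,
                         common_across_tasks = common_across_tasks,
                         task = task)
    cache[[key]] <- tm
    tm
  }
}

# same/different template correlations for a block of patterns, as Fisher z
.templateMatch <- function(P, states, tmpl) {
  R <- .rowCor(P, rbind(tmpl@art, tmpl@room))
  z <- fisherZ(clipR(R))
  is_art <- states == "art"
  cbind(same = ifelse(is_art, z[, 1], z[, 2]),
        different = ifelse(is_art, z[, 2], z[, 1]))
}

#' Orienting-period preparatory attentional-state index
#'
#' For each orienting-period pattern (the first trial of each run is
#' excluded upstream), correlates the pattern with the art and room
#' image-period templates built without that trial's run, and computes the
#' Fisher-z difference `z(corr with same-state template) - z(corr with
#' different-state template)`. Per task, per-trial values are averaged
#' within attentional state and then across the two states, so art and room
#' trials contribute equally. Positive values mean the orienting pattern
#' resembles the *upcoming* state more than the other state.
#'
#' Subsets reproduce the robustness variants: `"all"` uses every analyzed
#' orienting period; `"after_cue_only"` keeps trials whose previous trial
#' embedded a stay or switch cue; `"switch_only"` keeps trials preceded by a
#' switch cue (the retrieval-vs-preparation control: a positive index there
#' means the pattern resembles the upcoming, not the previous, state).
#'
#' @param orient_pp a [PeriodPatternSet-class] of orienting-period patterns
#'   (built with `exclude_first_of_run = TRUE`).
#' @param provider a [templateProvider()] closure (or any
#'   `function(run, task)` returning [StateTemplates-class] excluding that
#'   run).
#' @param subset `"all"`, `"after_cue_only"` or `"switch_only"`.
#' @return list: `per_task` (data.frame task, index_z, index_r, n_trials)
#'   and `per_trial` (data.frame with the per-trial z difference).
#' @export
preparatoryIndex <- function(orient_pp, provider,
                             subset = c("all", "after_cue_only",
                                        "switch_only")) {
  subset <- match.arg(subset)
  lab <- patternLabels(orient_pp)
  P <- patterns(orient_pp)
  keep <- lab$trial_in_run != 0L
  if (subset == "after_cue_only") {
    keep <- keep & !is.na(lab$prev_cue_type) &
      lab$prev_cue_type %in% c("stay", "switch")
  } else if (subset == "switch_only") {
    keep <- keep & !is.na(lab$prev_cue_type) & lab$prev_cue_type == "switch"
  }
  if (!any(keep)) stopf("empty-subset error: no orienting periods remain")
  lab <- lab[keep, , drop = FALSE]
  P <- P[keep, , drop = FALSE]
  per_trial <- lab
  per_trial$z_same <- NA_real_
  per_trial$z_different <- NA_real_
  for (tk in unique(lab$task)) {
    for (r in unique(lab$run[lab$task == tk])) {
      ix <- which(lab$task == tk & lab$run == r)
      tm <- provider(r, tk)
      zz <- .templateMatch(P[ix, , drop = FALSE], lab$state[ix], tm)
      per_trial$z_same[ix] <- zz[, "same"]
      per_trial$z_different[ix] <- zz[, "different"]
    }
  }
  per_trial$delta_z <- per_trial$z_same - per_trial$z_different
  per_task <- do.call(rbind, lapply(unique(lab$task), function(tk) {
    sub <- per_trial[per_trial$task == tk, ]
    by_state <- tapply(sub$delta_z, sub$state, mean)
    idx_z <- mean(by_state)
    zs <- tapply(sub$z_same, sub$state, mean)
    zd <- tapply(sub$z_different, sub$state, mean)
    data.frame(task = tk, index_z = idx_z,
               index_r = mean(tanh(zs)) - mean(tanh(zd)),
               n_trials = nrow(sub), stringsAsFactors = FALSE)
  }))
  list(per_task = per_task, per_trial = per_trial)
}
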