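#' Stimulus catalog for the two-task attention experiment
#'
#' Holds the abstract image catalog (no pixel data): 129 main images plus 12
#' stay/switch cue images, and the 20 base sets of 7 images each used to
#' construct trials. Images are rows of `images` with columns `image_id`,
#' `painting_id`, `room_id` and `cue_role` (one of `"none"`, `"art_stay"`,
#' `"art_switch"`, `"room_stay"`, `"room_switch"`). Base sets are rows of
#' `base_sets` with the base image, its art match, its room match and four
#' distractors.
#'
#' @slot images data.frame of catalog images.
#' @slot base_sets data.frame with columns `base_set_id`, `base`, `art_match`,
#'   `room_match`, `distractor_1` .. `distractor_4`.
#' @slot seed integer seed the catalog was built from.
#' @export
setClass("StimulusCatalog",
         representation(images = "data.frame",
                        base_sets = "data.frame",
                        seed = "integer"))

setValidity("StimulusCatalog", function(object) {
  msgs <- character(0)
  img <- object@images
  if (anyDuplicated(img$image_id)) msgs <- c(msgs, "duplicate image_id")
  ncue <- sum(img$cue_role != "none")
  if (ncue != 12L) {
    msgs <- c(msgs, sprintf("expected 12 cue images, found %d", ncue))
  }
  for (role in c("art_stay", "art_switch", "room_stay", "room_switch")) {
    if (sum(img$cue_role == role) != 3L) {
      msgs <- c(msgs, sprintf("cue role %s must appear in exactly 3 images", role))
    }
  }
  bs <- object@base_sets
  cols <- c("base", "art_match", "room_match", paste0("distractor_", 1:4))
  if (nrow(bs) > 0) {
    for (i in seq_len(nrow(bs))) {
      members <- unlist(bs[i, cols], use.names = FALSE)
      if (length(unique(members)) != 7L) {
        msgs <- c(msgs, sprintf("base set %s does not have 7 distinct members",
                                bs$base_set_id[i]))
      }
    }
    nonbase <- unlist(bs[, setdiff(cols, "base")], use.names = FALSE)
    if (any(bs$base %in% nonbase)) {
      msgs <- c(msgs, "a base image is reused as match/distractor elsewhere")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Full two-task experiment plan
#'
#' One row of `trials` per trial, covering both tasks, with states, cues,
#' validity, probes, search arrays and the per-trial timeline (seconds from
#' run start). Built by [buildSchedule()]; timelines can be re-finalized for
#' participant-specific initiation response times with [finalizeTimelines()].
#'
#' @slot trials data.frame, one row per trial.
#' @slot runs_per_task integer.
#' @slot trials_per_run integer.
#' @slot catalog the [StimulusCatalog-class] the schedule was built from.
#' @slot iti_set numeric vector: the fixed ITI set reused (permuted) per run.
#' @slot config list of the design parameters actually used.
#' @export
setClass("TrialSchedule",
         representation(trials = "data.frame",
                        runs_per_task = "integer",
                        trials_per_run = "integer",
                        catalog = "StimulusCatalog",
                        iti_set = "numeric",
                        config = "list"))

setValidity("TrialSchedule", function(object) {
  tr <- object@trials
  msgs <- character(0)
  if (nrow(tr) != object@runs_per_task * object@trials_per_run * 2L) {
    msgs <- c(msgs, "trial count does not match runs_per_task * trials_per_run * 2 tasks")
  }
  if (!all(tr$validity[tr$probe == tr$state] == "valid") ||
      !all(tr$validity[tr$probe != tr$state] == "invalid")) {
    msgs <- c(msgs, "validity must equal (probe == state)")
  }
  cued <- tr$cue_type != "none"
  if (any(cued)) {
    dim_ok <- substr(tr$cue_image[cued], 1, 3) ==
      ifelse(tr$state[cued] == "art", "art", "roo")
    if (!all(dim_ok, na.rm = TRUE)) {
      msgs <- c(msgs, "cue image dimension must match the trial's state")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' One run's BOLD matrix for a named region
#'
#' Voxels in rows, volumes in columns, after discarding the leading
#' equilibration volumes; volume `k` (0-based) covers
#' `[k * tr_s, (k + 1) * tr_s)` seconds of the run timeline.
#'
#' @slot region character region name.
#' @slot data numeric matrix, voxels x volumes.
#' @slot tr_s repetition time in seconds.
#' @slot run_index 0-based run index within its task.
#' @slot task `"memory_guided"` or `"explicit"`.
#' @slot n_discard number of leading volumes generated then discarded.
#' @export
setClass("BoldRun",
         representation(region = "character",
                        data = "matrix",
                        tr_s = "numeric",
                        run_index = "integer",
                        task = "character",
                        n_discard = "integer"))

setValidity("BoldRun", function(object) {
  msgs <- character(0)
  if (anyNA(object@data)) msgs <- c(msgs, "BOLD data contains missing values")
  if (object@tr_s <= 0) msgs <- c(msgs, "tr_s must be positive")
  if (length(msgs)) msgs else TRUE
})

#' Period-averaged trial patterns for one region
#'
#' One row of `patterns` per analyzed trial (voxels in columns), with aligned
#' trial labels in `labels`: `task`, `run`, `trial_index`, `trial_in_run`,
#' `state`, `validity`, `prev_cue_type`.
#'
#' @slot region character.
#' @slot period `"orienting"`, `"image"` or `"probe"`.
#' @slot patterns numeric matrix, trials x voxels.
#' @slot labels data.frame of trial labels, `nrow(labels) == nrow(patterns)`.
#' @slot trim the boundary-TR trim rule the patterns were built with.
#' @export
setClass("PeriodPatternSet",
         representation(region = "character",
                        period = "character",
                        patterns = "matrix",
                        labels = "data.frame",
                        trim = "character"))

setValidity("PeriodPatternSet", function(object) {
  msgs <- character(0)
  if (nrow(object@patterns) != nrow(object@labels)) {
    msgs <- c(msgs, "patterns and labels disagree on trial count")
  }
  if (!object@period %in% c("orienting", "image", "probe")) {
    msgs <- c(msgs, "period must be orienting, image or probe")
  }
  if (length(msgs)) msgs else TRUE
})

#' Leave-one-run-out attentional-state templates
#'
#' Mean image-period voxel patterns for the art and room states, built from
#' runs other than `excluded_run`, with the trial-selection options recorded.
#'
#' @slot art numeric voxel vector.
#' @slot room numeric voxel vector.
#' @slot excluded_run 0-based run index left out (NA when none).
#' @slot options list: `valid_only`, `common_across_tasks`, `task`.
#' @export
setClass("StateTemplates",
         representation(art = "numeric",
                        room = "numeric",
                        excluded_run = "integer",
                        options = "list"))

setValidity("StateTemplates", function(object) {
  if (length(object@art) != length(object@room)) {
    "art and room templates must have equal length"
  } else TRUE
})

#' Trial-wise attentional-state quality for one region
#'
#' Per-trial same-minus-different template-match scores, with alignment keys
#' (`task`, `run`, `trial_index`) so series from different regions can be
#' correlated trial-by-trial (informational connectivity).
#'
#' @slot region character.
#' @slot scores data.frame with columns `task`, `run`, `trial_index`,
#'   `state`, `quality`.
#' @slot scale `"z"` (Fisher-z difference) or `"r"` (raw correlation difference).
#' @export
setClass("QualitySeries",
         representation(region = "character",
                        scores = "data.frame",
                        scale = "character"))

setValidity("QualitySeries", function(object) {
  keys <- paste(object@scores$task, object@scores$run,
                object@scores$trial_index)
  if (anyDuplicated(keys)) "duplicate trial alignment keys" else TRUE
})

#' @describeIn StimulusCatalog-class number of catalog images and base sets
#' @param object a `StimulusCatalog`
#' @export
setMethod("show", "StimulusCatalog", function(object) {
  cat(sprintf("StimulusCatalog: %d images (%d cue), %d base sets [seed %d]\n",
              nrow(object@images), sum(object@images$cue_role != "none"),
              nrow(object@base_sets), object@seed))
})

#' @describeIn TrialSchedule-class brief summary
#' @param object a `TrialSchedule`
#' @export
setMethod("show", "TrialSchedule", function(object) {
  cat(sprintf(paste0("TrialSchedule: 2 tasks x %d runs x %d trials ",
                     "(%d trials total)\n"),
              object@runs_per_task, object@trials_per_run,
              nrow(object@trials)))
  cat(sprintf("  valid fraction: %.2f; cued fraction: %.2f\n",
              mean(object@trials$validity == "valid"),
              mean(object@trials$cue_type != "none")))
})

#' @describeIn BoldRun-class brief summary
#' @param object a `BoldRun`
#' @export
setMethod("show", "BoldRun", function(object) {
  cat(sprintf("BoldRun: %s / %s run %d: %d voxels x %d volumes (TR %.2g s)\n",
              object@region, object@task, object@run_index,
              nrow(object@data), ncol(object@data), object@tr_s))
})

#' @describeIn PeriodPatternSet-class brief summary
#' @param object a `PeriodPatternSet`
#' @export
setMethod("show", "PeriodPatternSet", function(object) {
  cat(sprintf("PeriodPatternSet: %s %s patterns, %d trials x %d voxels (trim: %s)\n",
              object@region, object@period, nrow(object@patterns),
              ncol(object@patterns), object@trim))
})

#' @describeIn QualitySeries-class brief summary
#' @param object a `QualitySeries`
#' @export
setMethod("show", "QualitySeries", function(object) {
  cat(sprintf("QualitySeries: %s, %d trials (%s scale)\n",
              object@region, nrow(object@scores), object@scale))
})

#' Accessors for prepattn containers
#'
#' `trials()` returns the trial table of a [TrialSchedule-class];
#' `boldData()` the voxels-x-volumes matrix of a [BoldRun-class];
#' `patterns()` and `patternLabels()` the pattern matrix and label table of a
#' [PeriodPatternSet-class]; `qualityScores()` the score table of a
#' [QualitySeries-class].
#'
#' @param x the container object.
#' @return the underlying data (data.frame or matrix).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("trials", function(x) standardGeneric("trials"))
#' @rdname accessors
#' @export
setMethod("trials", "TrialSchedule", function(x) x@trials)

#' @rdname accessors
#' @export
setGeneric("boldData", function(x) standardGeneric("boldData"))
#' @rdname accessors
#' @export
setMethod("boldData", "BoldRun", function(x) x@data)

#' @rdname accessors
#' @export
setGeneric("patterns", function(x) standardGeneric("patterns"))
#' @rdname accessors
#' @export
setMethod("patterns", "PeriodPatternSet", function(x) x@patterns)

#' @rdname accessors
#' @export
setGeneric("patternLabels", function(x) standardGeneric("patternLabels"))
#' @rdname accessors
#' @export
setMethod("patternLabels", "PeriodPatternSet", function(x) x@labels)

#' @rdname accessors
#' @export
setGeneric("qualityScores", function(x) standardGeneric("qualityScores"))
#' @rdname accessors
#' @export
setMethod("qualityScores", "QualitySeries", function(x) x@scores)
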