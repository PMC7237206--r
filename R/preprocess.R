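#' Z-score a run matrix across time, within voxel
#'
#' Standardizes each voxel's time course to mean 0 and unit sample standard
#' deviation, separately per run (each call handles one run matrix).
#' Zero-variance voxels map to all-zeros.
#'
#' @param data numeric matrix, voxels x volumes (>= 2 volumes).
#' @return matrix of the same shape.
#' @examples
#' zscoreRun(rbind(c(1, 2, 3)))  # (-1, 0, 1)
#' @export
zscoreRun <- function(data) {
  if (!is.matrix(data) || ncol(data) < 2L) {
    stopf("degenerate input: a run must have at least 2 volumes")
  }
  m <- rowMeans(data)
  centered <- data - m
  s <- sqrt(rowSums(centered^2) / (ncol(data) - 1L))
  s[s == 0] <- Inf  # zero-variance rows -> all-zeros
  centered / s
}

#' Select the volumes covering a (hemodynamically shifted) trial period
#'
#' A volume `k` (0-based) covers `[k * tr_s, (k + 1) * tr_s)` seconds. After
#' shifting the period interval forward by `shift_s` to account for
#' hemodynamic lag, a volume is selected iff its overlap with the shifted
#' interval is at least `min_overlap * tr_s` (an overlap of exactly half
#' counts as selected). A trim rule then drops boundary volumes: `"image"`
#' drops the first and last selected volume; `"orienting"` drops the last
#' selected volume unless it is the only selected volume overlapping the
#' attention-cue display (`cue_interval_s`, unshifted); `"none"` keeps all.
#'
#' @param interval_s `c(start, end)` of the period, seconds, half-open.
#' @param shift_s hemodynamic shift (default 6 s = 4 TRs).
#' @param tr_s repetition time (default 1.5 s).
#' @param min_overlap minimum fractional overlap (default 0.5, inclusive).
#' @param trim `"none"`, `"image"` or `"orienting"`.
#' @param cue_interval_s required for `trim = "orienting"`: `c(start, end)`
#'   of the attention-cue display, seconds (unshifted).
#' @param n_volumes optional run length; selected indices are clipped to
#'   `[0, n_volumes)`.
#' @param context label used in the empty-period error message.
#' @return integer vector of 0-based volume indices.
#' @examples
#' selectPeriodTrs(c(10, 12.2))                 # 11
#' selectPeriodTrs(c(0, 1.5), shift_s = 0)      # 0
#' @export
selectPeriodTrs <- function(interval_s, shift_s = 6.0, tr_s = 1.5,
                            min_overlap = 0.5, trim = "none",
                            cue_interval_s = NULL, n_volumes = NULL,
                            context = "period") {
  if (interval_s[2] <= interval_s[1]) stopf("interval end must exceed start")
  if (!trim %in% c("none", "image", "orienting")) {
    stopf("trim must be none, image or orienting")
  }
  a <- interval_s[1] + shift_s
  b <- interval_s[2] + shift_s
  k0 <- floor(a / tr_s)
  k1 <- ceiling(b / tr_s) - 1
  ks <- k0:k1
  ov <- pmin.int(b, (ks + 1) * tr_s) - pmax.int(a, ks * tr_s)
  sel <- ks[ov >= min_overlap * tr_s - 1e-9]
  if (!is.null(n_volumes)) sel <- sel[sel >= 0 & sel < n_volumes]
  if (trim == "image") {
    sel <- if (length(sel) > 2L) sel[-c(1L, length(sel))] else integer(0)
  } else if (trim == "orienting") {
    if (is.null(cue_interval_s)) {
      stopf("trim = 'orienting' requires cue_interval_s")
    }
    if (length(sel) > 1L) {
      ca <- cue_interval_s[1] + shift_s
      cb <- cue_interval_s[2] + shift_s
      cue_ov <- pmin(cb, (sel + 1) * tr_s) - pmax(ca, sel * tr_s)
      cue_trs <- sel[cue_ov > 1e-9]
      last <- sel[length(sel)]
      only_cue_tr <- length(cue_trs) == 1L && cue_trs[1] == last
      if (!only_cue_tr) sel <- sel[-length(sel)]
    }
  }
  if (!length(sel)) {
    stopf("empty-period error: no volumes remain for %s", context)
  }
  as.integer(sel)
}

#' Average a z-scored run over selected volumes
#'
#' @param zdata z-scored run matrix (voxels x volumes).
#' @param volume_idx 0-based volume indices from [selectPeriodTrs()].
#' @return numeric voxel vector (elementwise mean over the volumes).
#' @export
periodPattern <- function(zdata, volume_idx) {
  if (!length(volume_idx)) stopf("volume_idx must be nonempty")
  if (any(volume_idx < 0) || any(volume_idx >= ncol(zdata))) {
    stopf("bounds error: volume index outside the run")
  }
  rowMeans(zdata[, volume_idx + 1L, drop = FALSE])
}

# Vectorized volume-range selection for many trials at once. The selection
# rule of selectPeriodTrs() always yields a contiguous 0-based range
# [first, last] per trial; this computes those ranges directly (same
# thresholds, same trim rules) and is verified against the per-trial
# selectPeriodTrs() oracle in the test suite.
.selectRanges <- function(ints, cue_ints, shift_s, tr_s, min_overlap,
                          trim, n_volumes) {
  a <- ints[, 1] + shift_s
  b <- ints[, 2] + shift_s
  thr <- min_overlap * tr_s - 1e-9
  k0 <- floor(a / tr_s)
  k1 <- ceiling(b / tr_s) - 1
  single <- k0 == k1
  first <- k0 + ifelse(single, 0, (k0 + 1) * tr_s - a < thr)
  last <- k1 - ifelse(single, 0, b - k1 * tr_s < thr)
  empty <- single & (b - a < thr)
  first <- pmax(first, 0)
  last <- pmin(last, n_volumes - 1)
  if (trim == "image") {
    len <- last - first + 1
    empty <- empty | len <= 2
    first <- first + 1
    last <- last - 1
  } else if (trim == "orienting") {
    ca <- cue_ints[, 1] + shift_s
    cb <- cue_ints[, 2] + shift_s
    kmin <- floor(ca / tr_s)
    kmin <- kmin + ((kmin + 1) * tr_s - ca <= 1e-9)
    kmax <- ceiling(cb / tr_s) - 1
    kmax <- kmax - (cb - kmax * tr_s <= 1e-9)
    lo <- pmax(first, kmin)
    hi <- pmin(last, kmax)
    only_cue <- lo <= hi & lo == hi & hi == last
    multi <- last > first
    last <- last - as.numeric(multi & !only_cue)
  }
  empty <- empty | last < first
  cbind(first = first, last = last, empty = empty)
}

# period interval (unshifted, seconds) for one trial row
.periodInterval <- function(trial, period) {
  switch(period,
         image = c(trial$base_onset, trial$image_period_end),
         orienting = c(trial$initiation_onset,
                       trial$cue_onset + trial$cue_duration_s),
         probe = c(trial$probe_onset,
                   trial$probe_onset + trial$probe_max_duration_s),
         stopf("unknown period '%s'", period))
}

#' Extract period-averaged trial patterns for one region
#'
#' Applies [zscoreRun()] per run, selects each trial's (shifted) period
#' volumes with [selectPeriodTrs()], and averages them into one voxel
#' pattern per trial. The default trims mirror the conservative
#' orienting-period analysis: `trim = "none"` for the main image-period
#' analysis; `trim = "image"` drops the first and last image-period volume;
#' orienting patterns drop the last volume unless it is the only one
#' covering the attention cue. Labels (state, task, run, validity, previous
#' trial's cue type) travel with the patterns. When a behavior table is
#' supplied, the participant's chosen states replace the scheduled state
#' labels and experienced validity replaces scheduled validity.
#'
#' @param bold list of [BoldRun-class] for one region (e.g. the `runs`
#'   entries of [simulateBold()] for that region), or a single BoldRun.
#' @param schedule the [TrialSchedule-class] the runs were acquired under.
#' @param period `"image"`, `"orienting"` or `"probe"`.
#' @param trim trim rule passed to [selectPeriodTrs()]; defaults to
#'   `"none"` for image and `"orienting"` for orienting periods.
#' @param shift_s hemodynamic shift (default 6 s).
#' @param behavior optional [simulateBehavior()] table.
#' @param exclude_first_of_run drop the first trial of each run (required
#'   for orienting-period analyses; default TRUE for `period="orienting"`).
#' @return a [PeriodPatternSet-class].
#' @export
extractPeriodPatterns <- function(bold, schedule, period = "image",
                                  trim = NULL, shift_s = 6.0,
                                  behavior = NULL,
                                  exclude_first_of_run =
                                    identical(period, "orienting")) {
  sets <- extractPeriodPatternSets(
    bold, schedule,
    specs = list(out = list(period = period, trim = trim,
                            exclude_first_of_run = exclude_first_of_run)),
    shift_s = shift_s, behavior = behavior)
  sets$out
}

# per-run extraction core operating on an already z-scored matrix
.extractFromZ <- function(z, sub, period, trim, shift_s, tr_s, task,
                          run_index) {
  ints <- switch(period,
                 image = cbind(sub$base_onset, sub$image_period_end),
                 orienting = cbind(sub$initiation_onset,
                                   sub$cue_onset + sub$cue_duration_s),
                 probe = cbind(sub$probe_onset,
                               sub$probe_onset + sub$probe_max_duration_s))
  cue_ints <- cbind(sub$cue_onset, sub$cue_onset + sub$cue_duration_s)
  rg <- .selectRanges(ints, cue_ints, shift_s, tr_s, 0.5, trim, ncol(z))
  if (any(rg[, "empty"] > 0)) {
    bad <- sub$trial_index[which(rg[, "empty"] > 0)[1]]
    stopf("empty-period error: no volumes remain for trial %d (%s run %d)",
          bad, task, run_index)
  }
  lens <- rg[, "last"] - rg[, "first"] + 1
  W <- matrix(0, nrow(sub), ncol(z))
  W[cbind(rep(seq_len(nrow(sub)), lens),
          sequence(lens, from = rg[, "first"] + 1))] <- rep(1 / lens, lens)
  tcrossprod(W, z)
}

#' Extract several period/trim pattern sets in one pass
#'
#' Same contract as [extractPeriodPatterns()] but z-scores each run once and
#' extracts every requested period/trim combination from it, which is what
#' the per-participant pipeline needs (untrimmed image patterns, trimmed
#' image patterns for templates, orienting patterns).
#'
#' @inheritParams extractPeriodPatterns
#' @param specs named list; each element a list with `period`, optional
#'   `trim`, optional `exclude_first_of_run`.
#' @param plan optional extraction plan (the `"plan"` attribute of a
#'   previous result for the same schedule/timelines and specs); reuses the
#'   cached volume-averaging weights and labels. Ignored when `behavior` is
#'   supplied, since timelines are then participant-specific.
#' @return named list of [PeriodPatternSet-class], one per spec, with the
#'   reusable plan in `attr(, "plan")`.
#' @export
extractPeriodPatternSets <- function(bold, schedule, specs,
                                     shift_s = 6.0, behavior = NULL,
                                     plan = NULL) {
  if (is(bold, "BoldRun")) bold <- list(bold)
  region <- bold[[1]]@region
  tr <- trials(schedule)
  if (!is.null(behavior)) {
    key <- match(paste(tr$task, tr$trial_index),
                 paste(behavior$task, behavior$trial_index))
    tr$state <- behavior$chosen_state[key]
    tr$validity <- behavior$validity_exp[key]
    plan <- NULL
  }
  specs <- lapply(specs, function(sp) {
    sp$period <- match.arg(sp$period, c("image", "orienting", "probe"))
    sp$trim <- sp$trim %||% switch(sp$period, image = "none",
                                   orienting = "orienting", probe = "none")
    sp$exclude_first_of_run <- sp$exclude_first_of_run %||%
      identical(sp$period, "orienting")
    sp
  })
  lab_cols <- c("task", "run", "run_in_task", "trial_index", "trial_in_run",
                "state", "validity", "cue_type", "prev_cue_type")
  build_plan <- is.null(plan)
  if (build_plan) plan <- list()
  acc <- lapply(specs, function(sp) list(P = list(), lab = list()))
  for (br in bold) {
    stopifnot(is(br, "BoldRun"))
    rkey <- paste(br@task, br@run_index)
    if (build_plan) {
      sub_all <- tr[tr$task == br@task & tr$run_in_task == br@run_index, ]
      if (!nrow(sub_all)) next
      entry <- list()
      for (nm in names(specs)) {
        sp <- specs[[nm]]
        sub <- if (sp$exclude_first_of_run) {
          sub_all[sub_all$trial_in_run != 0L, ]
        } else sub_all
        ints <- switch(sp$period,
                       image = cbind(sub$base_onset, sub$image_period_end),
                       orienting = cbind(sub$initiation_onset,
                                         sub$cue_onset +
                                           sub$cue_duration_s),
                       probe = cbind(sub$probe_onset,
                                     sub$probe_onset +
                                       sub$probe_max_duration_s))
        cue_ints <- cbind(sub$cue_onset, sub$cue_onset + sub$cue_duration_s)
        rgs <- .selectRanges(ints, cue_ints, shift_s, br@tr_s, 0.5,
                             sp$trim, ncol(br@data))
        if (any(rgs[, "empty"] > 0)) {
          bad <- sub$trial_index[which(rgs[, "empty"] > 0)[1]]
          stopf("empty-period error: no volumes remain for trial %d (%s run %d)",
                bad, br@task, br@run_index)
        }
        lens <- rgs[, "last"] - rgs[, "first"] + 1
        W <- matrix(0, nrow(sub), ncol(br@data))
        W[cbind(rep(seq_len(nrow(sub)), lens),
                sequence(lens, from = rgs[, "first"] + 1))] <-
          rep(1 / lens, lens)
        entry[[nm]] <- list(W = W, labels = sub[, lab_cols])
      }
      plan[[rkey]] <- entry
    }
    entry <- plan[[rkey]]
    if (is.null(entry)) next
    if (ncol(entry[[1]]$W) != ncol(br@data)) {
      stopf("extraction plan does not match run %s (volume count)", rkey)
    }
    z <- zscoreRun(br@data)
    for (nm in names(specs)) {
      acc[[nm]]$P[[length(acc[[nm]]$P) + 1L]] <-
        tcrossprod(entry[[nm]]$W, z)
      acc[[nm]]$lab[[length(acc[[nm]]$lab) + 1L]] <- entry[[nm]]$labels
    }
  }
  out <- lapply(names(specs), function(nm) {
    labels <- do.call(rbind, acc[[nm]]$lab)
    rownames(labels) <- NULL
    new("PeriodPatternSet", region = region, period = specs[[nm]]$period,
        patterns = do.call(rbind, acc[[nm]]$P), labels = labels,
        trim = specs[[nm]]$trim)
  })
  names(out) <- names(specs)
  attr(out, "plan") <- plan
  out
}

#' Read a masked 4D BOLD volume into a region matrix
#'
#' Reads a 4D NIfTI time series and a binary 3D mask and returns the
#' voxels-x-volumes matrix for in-mask voxels. Voxel order is the mask's
#' scan (column-major) order and is fixed: the `j`-th row corresponds to the
#' `j`-th nonzero mask voxel in linear array order.
#'
#' @param bold_path path to the 4D NIfTI.
#' @param mask_path path to the binary mask NIfTI (same grid).
#' @param region region name to record.
#' @param tr_s repetition time; taken from the NIfTI header when absent.
#' @param run_index,task metadata for the returned [BoldRun-class].
#' @param n_discard leading volumes already discarded upstream (metadata).
#' @return a [BoldRun-class].
#' @export
readBoldRegion <- function(bold_path, mask_path, region = "roi",
                           tr_s = NULL, run_index = 0L,
                           task = "memory_guided", n_discard = 0L) {
  img <- RNifti::readNifti(bold_path)
  mask <- RNifti::readNifti(mask_path)
  dm <- dim(img)
  if (length(dm) != 4L) stopf("expected a 4D BOLD image")
  if (!all(dim(mask)[1:3] == dm[1:3])) {
    stopf("mask grid does not match the BOLD grid")
  }
  keep <- which(as.array(mask) > 0)
  mat <- matrix(as.array(img), prod(dm[1:3]), dm[4])[keep, , drop = FALSE]
  if (is.null(tr_s)) {
    tr_s <- RNifti::pixdim(img)[4]
    if (!is.finite(tr_s) || tr_s <= 0) tr_s <- 1.5
  }
  new("BoldRun", region = region, data = mat, tr_s = tr_s,
      run_index = as.integer(run_index), task = task,
      n_discard = as.integer(n_discard))
}

#' Write a region matrix as a 4D NIfTI using a mask grid
#'
#' Inverse of [readBoldRegion()]: places each row of the run matrix at the
#' corresponding nonzero mask voxel (mask scan order) and writes a 4D NIfTI,
#' so the synthetic-data path can exercise the real-data reader.
#'
#' @param run a [BoldRun-class].
#' @param mask 3D array (or path) with as many nonzero voxels as the run has
#'   rows.
#' @param path output file path (`.nii` or `.nii.gz`).
#' @return invisibly, `path`.
#' @export
writeBoldNifti <- function(run, mask, path) {
  if (is.character(mask)) mask <- as.array(RNifti::readNifti(mask))
  keep <- which(mask > 0)
  if (length(keep) != nrow(run@data)) {
    stopf("mask has %d nonzero voxels but the run has %d rows",
          length(keep), nrow(run@data))
  }
  arr <- array(0, dim = c(dim(mask), ncol(run@data)))
  flat <- matrix(0, prod(dim(mask)), ncol(run@data))
  flat[keep, ] <- run@data
  arr[] <- flat
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(2, 2, 2, run@tr_s)
  RNifti::writeNifti(img, path)
  invisible(path)
}
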