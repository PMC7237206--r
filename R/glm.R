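#' Build a single-trial design matrix for one run
#'
#' Two modes, mirroring the image-locked and orienting-locked single-trial
#' models. `"image_locked"`: one boxcar regressor per trial spanning the
#' 7.4 s image epoch (base-image onset to last search-image offset), plus
#' one pooled regressor for all orienting periods and one pooled 2 s probe
#' regressor (25 + 1 + 1 = 27 task regressors for a 25-trial run).
#' `"orienting_locked"`: one boxcar per orienting period (initiation-screen
#' onset to attention-cue offset), with the first trial of each run excluded
#' at the design stage, plus pooled image and probe regressors (24 + 2 for a
#' 25-trial run). All task regressors are convolved with the double-gamma
#' HRF on a fine grid and sampled at volume midpoints; nuisance columns
#' (e.g., 6 motion parameters) are appended unconvolved.
#'
#' @param run_trials trial table rows for one run (finalized timelines).
#' @param mode `"image_locked"` or `"orienting_locked"`.
#' @param n_volumes number of volumes in the run.
#' @param tr_s repetition time (default 1.5).
#' @param hrf_params optional [doubleGammaHrf()] overrides.
#' @param nuisance optional volumes x 6 motion-parameter matrix.
#' @param dt_s fine grid step for convolution.
#' @return list of class `design_matrix`: `X` (volumes x regressors),
#'   `names`, `convolved` (logical per regressor), `mode`.
#' @export
buildDesign <- function(run_trials, mode = c("image_locked",
                                             "orienting_locked"),
                        n_volumes, tr_s = 1.5, hrf_params = list(),
                        nuisance = NULL, dt_s = 0.1) {
  mode <- match.arg(mode)
  tr_tab <- run_trials
  epochs <- list()
  nm <- character(0)
  addEpoch <- function(lst, name, start, end) {
    if (any(end <= start)) {
      stopf("zero-duration epoch in regressor '%s'", name)
    }
    lst[[name]] <- cbind(start, end)
    lst
  }
  orient_int <- cbind(tr_tab$initiation_onset,
                      tr_tab$cue_onset + tr_tab$cue_duration_s)
  image_int <- cbind(tr_tab$base_onset, tr_tab$image_period_end)
  probe_int <- cbind(tr_tab$probe_onset,
                     tr_tab$probe_onset + tr_tab$probe_max_duration_s)
  if (mode == "image_locked") {
    for (i in seq_len(nrow(tr_tab))) {
      epochs <- addEpoch(epochs, sprintf("trial_%03d", tr_tab$trial_index[i]),
                         image_int[i, 1], image_int[i, 2])
    }
    epochs[["orienting"]] <- orient_int
    epochs[["probe"]] <- probe_int
  } else {
    keep <- tr_tab$trial_in_run != 0L
    for (i in which(keep)) {
      epochs <- addEpoch(epochs,
                         sprintf("orienting_%03d", tr_tab$trial_index[i]),
                         orient_int[i, 1], orient_int[i, 2])
    }
    epochs[["image"]] <- image_int
    epochs[["probe"]] <- probe_int
  }
  for (nmx in names(epochs)) {
    if (any(epochs[[nmx]][, 2] <= epochs[[nmx]][, 1])) {
      stopf("zero-duration epoch in regressor '%s'", nmx)
    }
  }
  kernel <- .hrfKernel(dt_s, hrf_params = hrf_params)
  L <- ceiling(n_volumes * tr_s / dt_s) + 1L
  mid_idx <- pmin(L, floor(((seq_len(n_volumes) - 1) * tr_s + tr_s / 2) /
                             dt_s) + 1L)
  X <- vapply(names(epochs), function(name) {
    box <- numeric(L)
    iv <- epochs[[name]]
    for (j in seq_len(nrow(iv))) {
      i0 <- min(L, floor(iv[j, 1] / dt_s) + 1L)
      i1 <- min(L, max(i0, floor(iv[j, 2] / dt_s)))
      box[i0:i1] <- box[i0:i1] + 1
    }
    .convolveHrf(box, kernel)[mid_idx]
  }, numeric(n_volumes))
  convolved <- rep(TRUE, ncol(X))
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    if (nrow(nuisance) != n_volumes) {
      stopf("nuisance matrix must have one row per volume")
    }
    colnames(nuisance) <- colnames(nuisance) %||%
      paste0("nuisance_", seq_len(ncol(nuisance)))
    X <- cbind(X, nuisance)
    convolved <- c(convolved, rep(FALSE, ncol(nuisance)))
  }
  if (any(colSums(abs(X)) == 0)) {
    stopf("design contains an all-zero regressor")
  }
  structure(list(X = X, names = colnames(X), convolved = convolved,
                 mode = mode, tr_s = tr_s), class = "design_matrix")
}

#' Discrete-cosine high-pass drift basis
#'
#' DCT-II basis spanning drift periods at or above the cutoff: an intercept
#' plus `floor(2 * n_volumes * tr_s / cutoff_s)` cosine terms, to be
#' projected out of both data and design.
#'
#' @param n_volumes number of volumes (>= 2).
#' @param tr_s repetition time.
#' @param cutoff_s high-pass cutoff in seconds (default 128); must exceed
#'   `2 * tr_s`.
#' @return matrix `n_volumes x (1 + K)`.
#' @export
highpassBasis <- function(n_volumes, tr_s = 1.5, cutoff_s = 128) {
  if (n_volumes < 2L) stopf("need at least 2 volumes")
  if (cutoff_s <= 2 * tr_s) stopf("cutoff must exceed 2 * tr_s")
  K <- floor(2 * n_volumes * tr_s / cutoff_s)
  t_ <- seq_len(n_volumes) - 1
  B <- matrix(1, n_volumes, 1L)
  if (K >= 1L) {
    B <- cbind(B, vapply(seq_len(K), function(k) {
      cos(pi * (t_ + 0.5) * k / n_volumes)
    }, numeric(n_volumes)))
  }
  colnames(B) <- c("intercept", if (K >= 1L) paste0("dct_", seq_len(K)))
  B
}

# residual-forming projection of columns of M against basis B
.projectOut <- function(M, B) {
  M - B %*% qr.coef(qr(B), M)
}

#' Fit a single-run GLM and return ROI-mean estimates
#'
#' Ordinary least squares per voxel (no prewhitening), after projecting the
#' high-pass drift basis out of both the data and the design, then averages
#' the per-voxel parameter estimates across voxels for each regressor. Each
#' run is fit separately; the task contrast (memory-guided minus explicitly
#' instructed single-trial means) is computed downstream across runs and
#' compared across participants.
#'
#' @param Y region matrix, voxels x volumes.
#' @param design a [buildDesign()] result (or a plain matrix).
#' @param highpass logical or a basis matrix from [highpassBasis()];
#'   `TRUE` (default) builds the 128 s basis.
#' @param tr_s repetition time used when building the default basis.
#' @return list: `estimates` (named per-regressor ROI means), `beta`
#'   (regressors x voxels matrix).
#' @export
fitGlmRoi <- function(Y, design, highpass = TRUE, tr_s = NULL) {
  X <- if (inherits(design, "design_matrix")) design$X else as.matrix(design)
  if (ncol(Y) != nrow(X)) {
    stopf("volumes mismatch: Y has %d, design has %d", ncol(Y), nrow(X))
  }
  tr_s <- tr_s %||% (if (inherits(design, "design_matrix")) design$tr_s
                     else 1.5)
  B <- NULL
  if (isTRUE(highpass)) B <- highpassBasis(nrow(X), tr_s)
  else if (is.matrix(highpass)) B <- highpass
  Xr <- X
  Yt <- t(Y)
  if (!is.null(B)) {
    Xr <- .projectOut(X, B)
    Yt <- .projectOut(Yt, B)
  }
  qrx <- qr(Xr)
  if (qrx$rank < ncol(Xr)) {
    bad <- colnames(X)[qrx$pivot[(qrx$rank + 1):ncol(Xr)]]
    stopf("collinearity error: rank-deficient design (offending: %s)",
          paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qrx, Yt)  # regressors x voxels
  est <- rowMeans(beta)
  names(est) <- colnames(X)
  rownames(beta) <- colnames(X)
  list(estimates = est, beta = beta)
}

#' Per-run ROI univariate estimates for a simulated participant
#'
#' Convenience wrapper: builds the requested single-trial design for every
#' run of a region, fits the GLM, and returns the mean single-trial estimate
#' per run (optionally over valid trials only), ready for the
#' memory-guided-minus-explicit task contrast.
#'
#' @param bold list of [BoldRun-class] for one region.
#' @param schedule the [TrialSchedule-class].
#' @param mode passed to [buildDesign()].
#' @param valid_only average only valid trials' estimates (default TRUE).
#' @param hrf_params,highpass passed through.
#' @return data.frame: task, run, mean single-trial estimate.
#' @export
roiUnivariate <- function(bold, schedule, mode = "image_locked",
                          valid_only = TRUE, hrf_params = list(),
                          highpass = TRUE) {
  tr <- trials(schedule)
  rows <- lapply(bold, function(br) {
    sub <- tr[tr$task == br@task & tr$run_in_task == br@run_index, ]
    des <- buildDesign(sub, mode = mode, n_volumes = ncol(br@data),
                       tr_s = br@tr_s, hrf_params = hrf_params)
    fit <- fitGlmRoi(br@data, des, highpass = highpass)
    prefix <- if (mode == "image_locked") "trial_" else "orienting_"
    single <- fit$estimates[startsWith(names(fit$estimates), prefix)]
    idx <- as.integer(sub("^[a-z]+_", "", names(single)))
    keep <- rep(TRUE, length(single))
    if (valid_only) {
      keep <- sub$validity[match(idx, sub$trial_index)] == "valid"
    }
    data.frame(region = br@region, task = br@task, run = br@run_index,
               estimate = mean(single[keep]), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
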