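#' Ground-truth effect parameters for the BOLD simulator
#'
#' Defines the generative effect sizes, in arbitrary BOLD signal units, used
#' by [simulateBold()]. The defaults are a moderate-SNR operating point (see
#' the package vignette): they are free parameters of the simulator, not
#' estimates of any real dataset.
#'
#' @param image_amp strength of the state-specific multivoxel pattern during
#'   image periods (multiplied by the trial fidelity factor).
#' @param prep_amp_memory,prep_amp_explicit strength of the upcoming-state
#'   pattern during orienting periods, per task.
#' @param template_overlap_r0 correlation between the art and room patterns
#'   (constructed exactly; see [makeStatePatterns()]).
#' @param quality_coupling_rho correlation of the latent trial-wise fidelity
#'   factors across regions; scalar, or named per task
#'   (`c(memory_guided = , explicit = )`).
#' @param fidelity_sd log-scale SD of the unit-mean log-normal fidelity
#'   factor.
#' @param noise_sd stationary SD of the AR(1) voxel noise.
#' @param ar1_coef AR(1) coefficient in `[0, 1)`.
#' @param drift_amp amplitude of the sinusoidal slow drift.
#' @param drift_period_s drift period in seconds.
#' @param prep_target `"upcoming"` (default): the orienting-period drive
#'   carries the current trial's (upcoming) state pattern; `"previous"`
#'   emulates retrieval of the preceding trial's state instead (the
#'   switch-trial control's alternative hypothesis).
#' @param baseline constant signal offset.
#' @param tr_s repetition time (default 1.5 s).
#' @param n_discard leading volumes generated then discarded (default 4).
#' @param dt_s fine time grid for neural-drive convolution.
#' @param pad_s seconds of scan continuing after the last trial ends.
#' @return a named list of class `effect_params`.
#' @export
effectParams <- function(image_amp = 0.5,
                         prep_amp_memory = 0.25,
                         prep_amp_explicit = 0.1,
                         template_overlap_r0 = 0,
                         quality_coupling_rho = c(memory_guided = 0.5,
                                                  explicit = 0),
                         fidelity_sd = 0.4,
                         prep_target = "upcoming",
                         noise_sd = 1,
                         ar1_coef = 0.3,
                         drift_amp = 0.5,
                         drift_period_s = 120,
                         baseline = 100,
                         tr_s = 1.5,
                         n_discard = 4L,
                         dt_s = 0.1,
                         pad_s = 9) {
  if (noise_sd < 0) stopf("noise_sd must be non-negative")
  if (ar1_coef < 0 || ar1_coef >= 1) stopf("ar1_coef must be in [0, 1)")
  if (abs(template_overlap_r0) >= 1) {
    stopf("template_overlap_r0 must be in (-1, 1)")
  }
  if (any(quality_coupling_rho < -1 | quality_coupling_rho > 1)) {
    stopf("quality_coupling_rho must be in [-1, 1]")
  }
  if (length(quality_coupling_rho) == 1L && is.null(names(quality_coupling_rho))) {
    quality_coupling_rho <- c(memory_guided = unname(quality_coupling_rho),
                              explicit = unname(quality_coupling_rho))
  }
  prep_target <- match.arg(prep_target, c("upcoming", "previous"))
  e <- list(image_amp = image_amp, prep_amp_memory = prep_amp_memory,
            prep_amp_explicit = prep_amp_explicit,
            template_overlap_r0 = template_overlap_r0,
            quality_coupling_rho = quality_coupling_rho,
            fidelity_sd = fidelity_sd, prep_target = prep_target,
            noise_sd = noise_sd,
            ar1_coef = ar1_coef, drift_amp = drift_amp,
            drift_period_s = drift_period_s, baseline = baseline,
            tr_s = tr_s, n_discard = as.integer(n_discard), dt_s = dt_s,
            pad_s = pad_s)
  class(e) <- "effect_params"
  e
}

#' Construct art/room voxel patterns with exact overlap
#'
#' Builds two unit-norm voxel vectors whose correlation equals `overlap_r0`
#' by construction (Gram-Schmidt), not by sampling. For `n_voxels >= 3` the
#' constant direction is projected out first, so both vectors are zero-mean
#' and their Pearson correlation equals `overlap_r0` exactly; for
#' `n_voxels == 2` centered vectors can only correlate at +/-1, so the
#' contract there is in the inner-product (cosine) sense.
#'
#' @param n_voxels number of voxels (>= 2).
#' @param overlap_r0 target correlation, `|overlap_r0| < 1`.
#' @param rng_seed integer seed.
#' @return list with unit-norm numeric vectors `art` and `room`.
#' @export
makeStatePatterns <- function(n_voxels, overlap_r0 = 0, rng_seed = 0L) {
  if (n_voxels < 2L) stopf("n_voxels must be >= 2")
  if (abs(overlap_r0) >= 1) stopf("|overlap_r0| must be < 1")
  withSeed(childSeed(rng_seed, "patterns"), {
    if (n_voxels == 2L) {
      theta <- runif(1, 0, 2 * pi)
      a <- c(cos(theta), sin(theta))
      phi <- theta + acos(overlap_r0)
      b <- c(cos(phi), sin(phi))
      return(list(art = a, room = b))
    }
    z1 <- rnorm(n_voxels)
    z2 <- rnorm(n_voxels)
    a <- z1 - mean(z1)
    a <- a / sqrt(sum(a^2))
    b0 <- z2 - mean(z2)
    b0 <- b0 - sum(b0 * a) * a
    b0 <- b0 / sqrt(sum(b0^2))
    b <- overlap_r0 * a + sqrt(1 - overlap_r0^2) * b0
    list(art = a, room = b)
  })
}

# correlated unit-mean log-normal fidelity factors: one latent factor shared
# across regions with pairwise correlation rho (per trial)
.fidelityFactors <- function(n_trials, n_regions, rho, sdlog) {
  if (n_regions == 1L || rho == 0) {
    z <- matrix(rnorm(n_trials * n_regions), n_trials, n_regions)
  } else if (rho > 0) {
    shared <- rnorm(n_trials)
    z <- sqrt(rho) * matrix(shared, n_trials, n_regions) +
      sqrt(1 - rho) * matrix(rnorm(n_trials * n_regions), n_trials,
                             n_regions)
  } else if (n_regions == 2L) {
    z1 <- rnorm(n_trials)
    z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n_trials)
    z <- cbind(z1, z2)
  } else {
    stopf("negative quality_coupling_rho requires exactly 2 regions")
  }
  exp(sdlog * z - sdlog^2 / 2)
}

#' Precompute per-trial convolved epoch regressors for a schedule
#'
#' Convolution is linear, so the HRF response of a run's drive (a sum of
#' per-trial boxcars with trial-specific amplitudes) equals the same linear
#' combination of per-trial unit-boxcar responses. This precomputes, per
#' run, the HRF-convolved unit boxcar of every trial's image period and
#' orienting period sampled at volume midpoints, letting [simulateBold()]
#' skip the per-participant convolution when many participants share one
#' schedule. The result is tied to the schedule's finalized timelines and
#' the effect parameters' timing fields (`tr_s`, `dt_s`, `pad_s`).
#'
#' @param schedule a [TrialSchedule-class] with finalized timelines.
#' @param effects an [effectParams()] list (timing fields are used).
#' @param tasks tasks to cover.
#' @param hrf_params optional [doubleGammaHrf()] overrides.
#' @return an opaque list passed to `simulateBold(conv_cache = )`.
#' @export
precomputeConvolvedDesign <- function(schedule, effects = effectParams(),
                                      tasks = c("memory_guided",
                                                "explicit"),
                                      hrf_params = list()) {
  e <- effects
  tr <- trials(schedule)
  tr <- tr[tr$task %in% tasks, ]
  kernel <- .hrfKernel(e$dt_s, hrf_params = hrf_params)
  out <- list()
  for (run in sort(unique(tr$run))) {
    sub <- tr[tr$run == run, ]
    dur <- max(sub$trial_end) + e$pad_s
    n_vol <- ceiling(dur / e$tr_s)
    L <- ceiling(n_vol * e$tr_s / e$dt_s) + 1L
    gi <- function(t) pmin(L, floor(t / e$dt_s) + 1L)
    vol_mid_idx <- gi((seq_len(n_vol) - 1) * e$tr_s + e$tr_s / 2)
    img <- matrix(0, n_vol, nrow(sub))
    prep <- matrix(0, n_vol, nrow(sub))
    for (k in seq_len(nrow(sub))) {
      bi <- numeric(L); bp <- numeric(L)
      bi[gi(sub$base_onset[k]):(gi(sub$image_period_end[k]) - 1L)] <- 1
      bp[gi(sub$initiation_onset[k]):
           (gi(sub$cue_onset[k] + sub$cue_duration_s[k]) - 1L)] <- 1
      cv <- .convolveHrfPair(bi, bp, kernel)
      img[, k] <- cv[[1]][vol_mid_idx]
      prep[, k] <- cv[[2]][vol_mid_idx]
    }
    out[[as.character(run)]] <- list(img = img, prep = prep, n_vol = n_vol,
                                     trial_index = sub$trial_index,
                                     end = max(sub$trial_end))
  }
  attr(out, "timing") <- c(tr_s = e$tr_s, dt_s = e$dt_s, pad_s = e$pad_s)
  out
}

#' Simulate region-wise BOLD runs with known ground truth
#'
#' Forward model matching the analysis assumptions: within each run, the
#' neural drive is `baseline + g_t * image_amp * pattern(state_t)` during
#' each image period and `prep_amp(task) * pattern(state_t)` during each
#' orienting period (the orienting period of a trial carries that trial's
#' upcoming state). The trial fidelity factor `g_t` is a unit-mean log-normal
#' shared across regions with latent correlation `quality_coupling_rho`
#' (per task). The drive is convolved with the double-gamma HRF on a fine
#' grid, sampled at volume midpoints (TR 1.5 s), and AR(1) noise plus a
#' random-phase sinusoidal drift are added. Leading volumes are generated
#' and then discarded, mirroring scanner equilibration handling.
#'
#' @param schedule a [TrialSchedule-class] with finalized timelines.
#' @param regions named integer vector of voxel counts, e.g.
#'   `c(hippocampus = 50, v12 = 50)`.
#' @param effects an [effectParams()] list.
#' @param rng_seed integer seed.
#' @param behavior optional [simulateBehavior()] table; when supplied, the
#'   participant's chosen states drive the signal (selection errors change
#'   the neural state), and its initiation RTs should already have been
#'   applied via [finalizeTimelines()].
#' @param tasks which tasks to simulate (default both).
#' @param hrf_params optional overrides for [doubleGammaHrf()].
#' @param conv_cache optional [precomputeConvolvedDesign()] result for the
#'   same schedule/timelines; replaces the per-call convolution by an exact
#'   linear combination of cached unit responses.
#' @return list with `runs` (list of [BoldRun-class], named
#'   `region.task.run`) and `ground_truth` (state patterns per region,
#'   per-trial fidelity factors, states used).
#' @export
simulateBold <- function(schedule, regions, effects = effectParams(),
                         rng_seed = 0L, behavior = NULL,
                         tasks = c("memory_guided", "explicit"),
                         hrf_params = list(), conv_cache = NULL) {
  if (is.null(names(regions)) || any(!nzchar(names(regions)))) {
    stopf("regions must be a named vector of voxel counts")
  }
  e <- effects
  tr <- trials(schedule)
  tr <- tr[tr$task %in% tasks, ]
  states_use <- if (!is.null(behavior)) {
    b <- behavior[match(paste(tr$task, tr$trial_index),
                        paste(behavior$task, behavior$trial_index)), ]
    b$chosen_state
  } else tr$state

  pats <- lapply(names(regions), function(rg) {
    makeStatePatterns(regions[[rg]], e$template_overlap_r0,
                      childSeed(rng_seed, "pattern", rg))
  })
  names(pats) <- names(regions)

  # fidelity factors per task (coupling can differ by task)
  g <- matrix(NA_real_, nrow(tr), length(regions),
              dimnames = list(NULL, names(regions)))
  withSeed(childSeed(rng_seed, "fidelity"), {
    for (task in unique(tr$task)) {
      ix <- which(tr$task == task)
      rho <- e$quality_coupling_rho[[task]] %||%
        unname(e$quality_coupling_rho[1])
      g[ix, ] <- .fidelityFactors(length(ix), length(regions), rho,
                                  e$fidelity_sd)
    }
  })

  kernel <- if (is.null(conv_cache)) .hrfKernel(e$dt_s,
                                                hrf_params = hrf_params)
  runs <- list()
  for (run in sort(unique(tr$run))) {
    rix <- which(tr$run == run)
    sub <- tr[rix, ]
    task <- sub$task[1]
    dur <- max(sub$trial_end) + e$pad_s
    n_vol <- ceiling(dur / e$tr_s)

    prep_amp <- if (task == "memory_guided") e$prep_amp_memory
    else e$prep_amp_explicit
    st_run <- states_use[rix]
    prep_states <- if (e$prep_target == "upcoming") st_run
    else c(st_run[1], head(st_run, -1))

    ce <- NULL
    if (!is.null(conv_cache)) {
      ce <- conv_cache[[as.character(run)]]
      if (is.null(ce) || ce$n_vol != n_vol ||
          !identical(ce$trial_index, sub$trial_index) ||
          abs(ce$end - max(sub$trial_end)) > 1e-9) {
        stopf("conv_cache does not match the schedule's run %d", run)
      }
    } else {
      L <- ceiling(n_vol * e$tr_s / e$dt_s) + 1L
      tgrid_idx <- function(t) pmin(L, floor(t / e$dt_s) + 1L)
      vol_mid_idx <- tgrid_idx((seq_len(n_vol) - 1) * e$tr_s + e$tr_s / 2)
      img_i0 <- tgrid_idx(sub$base_onset)
      img_i1 <- tgrid_idx(sub$image_period_end) - 1L
      or_i0 <- tgrid_idx(sub$initiation_onset)
      or_i1 <- tgrid_idx(sub$cue_onset + sub$cue_duration_s) - 1L
      img_len <- img_i1 - img_i0 + 1L
      or_len <- or_i1 - or_i0 + 1L
    }
    # event epochs never overlap within a run, so plain indexed assignment
    # into the drive vectors is safe
    driveFor <- function(state, img_amp_per_trial, prep_amp_per_trial) {
      d <- numeric(L)
      ks <- which(st_run == state)
      if (length(ks)) {
        idx <- sequence(img_len[ks], from = img_i0[ks])
        d[idx] <- rep(img_amp_per_trial[ks], img_len[ks])
      }
      kp <- which(prep_states == state)
      if (length(kp)) {
        idx <- sequence(or_len[kp], from = or_i0[kp])
        d[idx] <- d[idx] + rep(prep_amp_per_trial[kp], or_len[kp])
      }
      d
    }

    tvol <- (seq_len(n_vol + e$n_discard) - 1 - e$n_discard) * e$tr_s
    wt <- 2 * pi * tvol / e$drift_period_s
    cos_wt <- cos(wt)
    sin_wt <- sin(wt)

    for (rg in names(regions)) {
      V <- regions[[rg]]
      g_amp <- g[rix, rg] * e$image_amp
      if (is.null(ce)) {
        p_amp <- rep(prep_amp, length(rix))
        conv <- .convolveHrfPair(driveFor("art", g_amp, p_amp),
                                 driveFor("room", g_amp, p_amp), kernel)
        c_art <- conv[[1]][vol_mid_idx]
        c_room <- conv[[2]][vol_mid_idx]
      } else {
        comb <- function(state) {
          ks <- which(st_run == state)
          v <- as.vector(ce$img[, ks, drop = FALSE] %*% g_amp[ks])
          kp <- which(prep_states == state)
          if (prep_amp != 0 && length(kp)) {
            v <- v + prep_amp * rowSums(ce$prep[, kp, drop = FALSE])
          }
          v
        }
        c_art <- comb("art")
        c_room <- comb("room")
      }
      signal <- cbind(pats[[rg]]$art, pats[[rg]]$room) %*%
        rbind(c_art, c_room)

      n_gen <- n_vol + e$n_discard
      data <- withSeed(childSeed(rng_seed, "noise", rg, task, run), {
        .assembleRunData(signal, e$n_discard,
                         e$noise_sd * sqrt(1 - e$ar1_coef^2),
                         e$ar1_coef, e$drift_amp, cos_wt, sin_wt,
                         e$baseline)
      })
      br <- new("BoldRun", region = rg, data = data, tr_s = e$tr_s,
                run_index = as.integer(sub$run_in_task[1]), task = task,
                n_discard = e$n_discard)
      runs[[paste(rg, task, run, sep = ".")]] <- br
    }
  }
  list(runs = runs,
       ground_truth = list(patterns = pats,
                           fidelity = cbind(tr[, c("task", "run",
                                                   "trial_index")],
                                            as.data.frame(g)),
                           states_used = states_use))
}
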