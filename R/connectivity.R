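#' Trial-wise multivariate attentional-state quality
#'
#' For each image-period trial pattern of one region, correlates the pattern
#' with the art and room state templates built without that trial's run and
#' scores the trial's attentional-state "quality" as the same-state minus
#' different-state template correlation. The difference is taken on the
#' Fisher-z scale by default (`scale = "r"` gives raw correlation
#' differences).
#'
#' @param pp a [PeriodPatternSet-class] of image-period patterns for one
#'   region.
#' @param provider a [templateProvider()] closure built on the same region's
#'   image-period patterns.
#' @param valid_only restrict scored trials to valid ones (default TRUE).
#' @param scale `"z"` or `"r"`.
#' @return a [QualitySeries-class].
#' @export
qualitySeries <- function(pp, provider, valid_only = TRUE, scale = "z") {
  scale <- match.arg(scale, c("z", "r"))
  lab <- patternLabels(pp)
  P <- patterns(pp)
  keep <- rep(TRUE, nrow(lab))
  if (valid_only) keep <- keep & lab$validity == "valid"
  lab <- lab[keep, , drop = FALSE]
  P <- P[keep, , drop = FALSE]
  quality <- numeric(nrow(lab))
  for (tk in unique(lab$task)) {
    for (r in unique(lab$run[lab$task == tk])) {
      ix <- which(lab$task == tk & lab$run == r)
      tm <- provider(r, tk)
      zz <- .templateMatch(P[ix, , drop = FALSE], lab$state[ix], tm)
      quality[ix] <- if (scale == "z") {
        zz[, "same"] - zz[, "different"]
      } else {
        tanh(zz[, "same"]) - tanh(zz[, "different"])
      }
    }
  }
  scores <- data.frame(task = lab$task, run = lab$run,
                       trial_index = lab$trial_index, state = lab$state,
                       quality = quality, stringsAsFactors = FALSE)
  new("QualitySeries", region = pp@region, scores = scores, scale = scale)
}

#' Informational (multivariate) connectivity between two regions
#'
#' Correlates the trial-wise attentional-state quality scores of two regions
#' across all trials within a task. The series must align on identical
#' trial keys (task, run, trial index). Group inference is done downstream
#' on the Fisher-z values (one-sample vs 0, paired across tasks).
#'
#' @param qa,qb [QualitySeries-class] objects for the two regions.
#' @param task task(s) to correlate (default: every task present in both).
#' @return data.frame per task: `region_a`, `region_b`, `task`, `r`, `z`,
#'   `n_trials`.
#' @export
multivariateConnectivity <- function(qa, qb, task = NULL) {
  sa <- qualityScores(qa)
  sb <- qualityScores(qb)
  key_a <- paste(sa$task, sa$run, sa$trial_index)
  key_b <- paste(sb$task, sb$run, sb$trial_index)
  if (length(key_a) != length(key_b) || !setequal(key_a, key_b)) {
    stopf("alignment error: quality series have different trial keys")
  }
  sb <- sb[match(key_a, key_b), ]
  tasks <- task %||% unique(sa$task)
  out <- lapply(tasks, function(tk) {
    ix <- sa$task == tk
    if (sum(ix) < 3L) {
      stopf("insufficient-trials error: task %s has <3 aligned trials", tk)
    }
    r <- cor(sa$quality[ix], sb$quality[ix])
    data.frame(region_a = qa@region, region_b = qb@region, task = tk,
               r = r, z = fisherZ(clipR(r)), n_trials = sum(ix),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
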