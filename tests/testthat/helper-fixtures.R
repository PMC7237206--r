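# Shared fixtures, built once per test run (schedule construction is
# deterministic given the seed).
.fix <- new.env()

fixtureSchedule <- function(seed = 42) {
  key <- paste0("sched", seed)
  if (is.null(.fix[[key]])) {
    .fix[[key]] <- buildSchedule(config = designConfig(), rng_seed = seed)
  }
  .fix[[key]]
}

# small two-region simulation shared by several analysis tests
fixtureSim <- function(seed = 42, voxels = 30, effects = effectParams()) {
  key <- paste("sim", seed, voxels, sep = "_")
  if (is.null(.fix[[key]])) {
    s <- fixtureSchedule(seed)
    .fix[[key]] <- simulateBold(s, c(regA = voxels, regB = voxels),
                                effects, rng_seed = seed)
  }
  .fix[[key]]
}

# construct a PeriodPatternSet directly from a matrix + label table
makePatternSet <- function(patterns, labels, region = "toy",
                           period = "image", trim = "none") {
  defaults <- data.frame(
    task = "memory_guided", run = 0L, run_in_task = 0L,
    trial_index = seq_len(nrow(patterns)) - 1L,
    trial_in_run = seq_len(nrow(patterns)) - 1L,
    state = "art", validity = "valid", cue_type = "none",
    prev_cue_type = NA_character_, stringsAsFactors = FALSE)
  for (nm in names(labels)) defaults[[nm]] <- labels[[nm]]
  new("PeriodPatternSet", region = region, period = period,
      patterns = as.matrix(patterns), labels = defaults, trim = trim)
}
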