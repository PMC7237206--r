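test_that("stimulus catalog has the documented composition and reuse structure", {
  ct <- buildStimulusSet(0)
  img <- ct@images
  expect_equal(nrow(img), 141)
  expect_equal(anyDuplicated(img$image_id), 0L)
  expect_equal(sum(img$cue_role != "none"), 12)
  for (role in c("art_stay", "art_switch", "room_stay", "room_switch")) {
    expect_equal(sum(img$cue_role == role), 3)
  }
  expect_equal(nrow(ct@base_sets), 20)

  # art stay and art switch cues share the same 3 background rooms
  bg_stay <- sort(img$room_id[img$cue_role == "art_stay"])
  bg_switch <- sort(img$room_id[img$cue_role == "art_switch"])
  expect_equal(bg_stay, bg_switch)
  # each cue's task-irrelevant half also appears in exactly 2 main images
  main <- img[img$cue_role == "none", ]
  for (r in unique(bg_stay)) {
    expect_equal(sum(main$room_id == r), 2)
  }
  emb <- unique(img$painting_id[img$cue_role == "room_stay"])
  for (p in emb) {
    expect_equal(sum(main$painting_id == p), 2)
  }
})

test_that("base sets have 7 distinct members with correct match structure", {
  ct <- buildStimulusSet(0)
  img <- ct@images
  bs <- ct@base_sets
  cols <- c("base", "art_match", "room_match", paste0("distractor_", 1:4))
  for (i in seq_len(nrow(bs))) {
    members <- unlist(bs[i, cols], use.names = FALSE)
    expect_length(unique(members), 7)
    b <- img[img$image_id == bs$base[i], ]
    am <- img[img$image_id == bs$art_match[i], ]
    rm_ <- img[img$image_id == bs$room_match[i], ]
    expect_equal(am$painting_id, b$painting_id)  # same artist/style
    expect_false(am$room_id == b$room_id)
    expect_equal(rm_$room_id, b$room_id)         # same layout
    expect_false(rm_$painting_id == b$painting_id)
  }
  # bases never reused elsewhere
  nonbase <- unlist(bs[, setdiff(cols, "base")], use.names = FALSE)
  expect_false(any(bs$base %in% nonbase))
})

test_that("catalog generation is seed-reproducible and seed-sensitive", {
  a <- buildStimulusSet(0)
  b <- buildStimulusSet(0)
  c <- buildStimulusSet(1)
  expect_identical(a@images, b@images)
  expect_identical(a@base_sets, b@base_sets)
  expect_equal(nrow(c@images), 141)
  expect_false(identical(a@base_sets, c@base_sets))
})

test_that("stay/switch cue logic maps states correctly", {
  expect_equal(deriveNextState("art", "switch"), "room")
  expect_equal(deriveNextState("room", "switch"), "art")
  expect_equal(deriveNextState("room", "stay"), "room")
  expect_equal(deriveNextState("art", "stay"), "art")
  expect_equal(deriveNextState("art", "none", free_choice = "art"), "art")
  expect_equal(deriveNextState("art", "none", free_choice = "room"), "room")
  expect_error(deriveNextState("art", "none"), "free_choice")
  expect_error(deriveNextState("art", "stay", free_choice = "room"),
               "free_choice")
})

test_that("schedule satisfies the validity, match and cue-rate constraints", {
  s <- fixtureSchedule()
  tr <- trials(s)
  for (tk in c("memory_guided", "explicit")) {
    sub <- tr[tr$task == tk, ]
    expect_equal(nrow(sub), 100)
    expect_equal(mean(sub$validity == "valid"), 0.8)
    expect_equal(sum(sub$validity == "invalid"), round(0.2 * 100))
    expect_equal(sum(sub$rel_match), 50)
    expect_equal(sum(sub$irrel_match), 50)
    counts <- table(sub$cue_type)
    expect_true(all(counts[c("stay", "switch", "none")] %in% 33:34))
    expect_equal(sum(counts), 100)
    # invalid means probe flips state
    expect_true(all((sub$probe != sub$state) ==
                      (sub$validity == "invalid")))
  }
  expect_equal(length(unique(tr$run)), 8)
  expect_true(all(table(tr$run) == 25))
})

test_that("every aligned 20-trial window shows each base image exactly once", {
  s <- fixtureSchedule()
  tr <- trials(s)
  for (tk in unique(tr$task)) {
    sub <- tr[tr$task == tk, ]
    sub <- sub[order(sub$trial_index), ]
    bs <- sub$base_set_id
    # brute-force scan of every aligned window
    for (w in seq_len(length(bs) / 20)) {
      win <- bs[((w - 1) * 20 + 1):(w * 20)]
      expect_length(unique(win), 20)
    }
    # no consecutive repeats (includes window boundaries)
    expect_false(any(bs[-1] == bs[-length(bs)]))
    # each base set -> 5 trials per task (10 overall)
    expect_true(all(table(bs) == 5))
  }
})

test_that("cue images match the trial's state dimension and search arrays are clean", {
  s <- fixtureSchedule()
  tr <- trials(s)
  img <- s@catalog@images
  cued <- tr[tr$cue_type != "none", ]
  roles <- img$cue_role[match(cued$cue_image, img$image_id)]
  expect_true(all(roles == paste0(cued$state, "_", cued$cue_type)))
  search <- as.matrix(tr[, paste0("search_", 1:4)])
  # no duplicates within a trial; at most one cue image
  expect_true(all(apply(search, 1, function(r) length(unique(r)) == 4)))
  cue_ids <- img$image_id[img$cue_role != "none"]
  n_cues_in_search <- apply(search, 1, function(r) sum(r %in% cue_ids))
  expect_true(all(n_cues_in_search <= 1))
  expect_true(all((n_cues_in_search == 1) == (tr$cue_type != "none")))
})

test_that("memory-guided states replay exactly through the cue logic", {
  for (seed in c(42, 7)) {
    s <- fixtureSchedule(seed)
    tr <- trials(s)
    sub <- tr[tr$task == "memory_guided", ]
    sub <- sub[order(sub$trial_index), ]
    for (i in seq_len(nrow(sub))[-1]) {
      if (sub$trial_in_run[i] == 0L) next  # free choice at run start
      st <- deriveNextState(sub$state[i - 1], sub$cue_type[i - 1],
                            free_choice = if (sub$cue_type[i - 1] == "none")
                              sub$state[i])
      expect_identical(st, sub$state[i])
    }
    # art/room counts stay within a small imbalance bound
    expect_lte(abs(sum(sub$state == "art") - sum(sub$state == "room")), 8)
  }
})

test_that("schedule generation is bit-reproducible under a fixed seed", {
  a <- buildSchedule(config = designConfig(), rng_seed = 5)
  b <- buildSchedule(config = designConfig(), rng_seed = 5)
  expect_identical(trials(a), trials(b))
  c <- buildSchedule(config = designConfig(), rng_seed = 6)
  expect_false(identical(trials(a)$base_set_id, trials(c)$base_set_id))
})

test_that("infeasible trial counts raise a constraint error naming the issue", {
  expect_error(
    buildSchedule(config = designConfig(trials_per_run = 23), rng_seed = 0),
    "constraint error")
})

test_that("trial timelines follow the documented component durations", {
  tl <- trialTimeline(0, 1, 1.5)
  expect_equal(tl$base_onset, 2.5)
  expect_equal(tl$image_period_end - tl$base_onset, 7.4)
  expect_equal(tl$probe_onset, tl$image_period_end + 0.1)
  # onsets strictly increasing
  ons <- c(tl$initiation_onset, tl$cue_onset, tl$base_onset,
           tl$search_onset_1, tl$search_onset_2, tl$search_onset_3,
           tl$search_onset_4, tl$probe_onset)
  expect_true(all(diff(ons) > 0))
  # search images 1.25 s apart plus 0.1 s gaps
  expect_equal(tl$search_onset_2 - tl$search_onset_1, 1.35)
  # deterministic
  expect_identical(trialTimeline(3, 0.8, 2), trialTimeline(3, 0.8, 2))
  # span is constant across cue durations / RTs
  tl2 <- trialTimeline(11, 2.3, 2.5)
  expect_equal(tl2$image_period_end - tl2$base_onset, 7.4)
  expect_error(trialTimeline(-1, 1, 1.5), "non-negative")
  expect_error(trialTimeline(0, 1, 1.7), "one of")
})

test_that("the ITI set is truncated, calibrated and reused per run", {
  m <- sampleItis(25, rng_seed = 3, n_runs = 4)
  iti <- attr(m, "iti_set")
  expect_length(iti, 25)
  expect_true(all(iti <= 9.0))
  expect_true(all(iti > 0))
  expect_lt(abs(mean(iti) - 6.66), 0.01)
  # each run is a permutation of the same fixed set
  for (r in 1:4) expect_equal(sort(m[r, ]), sort(iti))
  expect_identical(m, sampleItis(25, rng_seed = 3, n_runs = 4))
  expect_false(identical(m, sampleItis(25, rng_seed = 4, n_runs = 4)))
  # degenerate n = 1: single duration reused identically in every run
  m1 <- sampleItis(1, rng_seed = 0, n_runs = 3)
  expect_length(unique(as.vector(m1)), 1)
  # unreachable target mean
  expect_error(sampleItis(25, params = list(target_mean_s = 10),
                          rng_seed = 0), "calibration error")
})

test_that("event tables are valid BIDS-style TSVs", {
  s <- fixtureSchedule()
  d <- withr::local_tempdir()
  paths <- writeEventTables(s, d, participant = "sub-01")
  expect_length(paths, 8)
  ev <- read.delim(paths[1])
  expect_true(all(c("onset", "duration", "trial_type", "task", "state",
                    "probe", "validity", "cue_type", "run") %in% names(ev)))
  expect_equal(nrow(ev), 25 * 3)
  expect_true(all(diff(ev$onset[ev$trial_type == "orienting"]) > 0))
  expect_true(all(ev$duration > 0))
})
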