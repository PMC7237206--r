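# small labelled pattern set: 2 runs x 4 trials (2 art, 2 room per run)
toyImageSet <- function(P = NULL) {
  labels <- data.frame(
    task = "memory_guided",
    run = rep(0:1, each = 4),
    run_in_task = rep(0:1, each = 4),
    trial_in_run = rep(0:3, 2),
    trial_index = 0:7,
    state = rep(c("art", "art", "room", "room"), 2),
    validity = "valid", cue_type = "none",
    prev_cue_type = NA_character_, stringsAsFactors = FALSE)
  if (is.null(P)) {
    set.seed(10)
    P <- matrix(rnorm(8 * 3), 8, 3)
  }
  makePatternSet(P, labels)
}

test_that("image-period similarity equals an exhaustive all-pairs oracle", {
  pp <- toyImageSet()
  P <- patterns(pp)
  lab <- patternLabels(pp)
  got <- imageStateSimilarity(pp, valid_only = FALSE)
  # brute-force enumeration over all cross-run pairs
  zs_art <- c(); zs_room <- c(); zd <- c()
  for (i in 1:7) for (j in (i + 1):8) {
    if (lab$run[i] == lab$run[j]) next
    z <- atanh(min(1 - 1e-12, max(-1 + 1e-12, cor(P[i, ], P[j, ]))))
    if (lab$state[i] == "art" && lab$state[j] == "art") zs_art <- c(zs_art, z)
    else if (lab$state[i] == "room" && lab$state[j] == "room") {
      zs_room <- c(zs_room, z)
    } else zd <- c(zd, z)
  }
  expect_equal(got$same_z, mean(c(mean(zs_art), mean(zs_room))),
               tolerance = 1e-12)
  expect_equal(got$different_z, mean(zd), tolerance = 1e-12)
  expect_equal(got$delta_z, got$same_z - got$different_z)
  expect_equal(got$n_same_pairs, length(zs_art) + length(zs_room))
  expect_equal(got$n_different_pairs, length(zd))
})

test_that("identical patterns produce capped, zero-difference similarity", {
  pp <- toyImageSet(matrix(rep(c(1, 2, 4), 8), 8, 3, byrow = TRUE))
  got <- imageStateSimilarity(pp, valid_only = FALSE)
  expect_equal(got$same_z, atanh(1 - 1e-12))
  expect_equal(got$delta_z, 0)
})

test_that("similarity requires at least two runs", {
  pp <- toyImageSet()
  pp@labels$run <- 0L
  expect_error(imageStateSimilarity(pp, valid_only = FALSE),
               "insufficient-runs")
})

test_that("state templates honor exclusions and options", {
  pp <- toyImageSet()
  P <- patterns(pp)
  tm <- buildTemplates(pp, exclude_run = 0, valid_only = FALSE)
  expect_equal(tm@art, colMeans(P[5:6, , drop = FALSE]))
  expect_equal(tm@room, colMeans(P[7:8, , drop = FALSE]))
  # one trial per state -> template equals that trial's vector
  one <- toyImageSet()
  one@labels$state <- c("art", "room", "room", "room",
                        "art", "room", "room", "room")
  tm1 <- buildTemplates(one, exclude_run = 1, valid_only = FALSE)
  expect_equal(tm1@art, P[1, ])
  # valid_only toggled on an all-valid set is a no-op
  a <- buildTemplates(pp, exclude_run = 0, valid_only = TRUE)
  b <- buildTemplates(pp, exclude_run = 0, valid_only = FALSE)
  expect_identical(a@art, b@art)
  # per-task vs common templates agree when only one task is present
  ct <- buildTemplates(pp, exclude_run = 0, common_across_tasks = TRUE)
  pt <- buildTemplates(pp, exclude_run = 0, common_across_tasks = FALSE,
                       task = "memory_guided")
  expect_identical(ct@art, pt@art)
  # missing state after filtering
  solo <- toyImageSet()
  solo@labels$state <- "art"
  expect_error(buildTemplates(solo, exclude_run = 0), "missing-state")
})

# orienting set whose patterns are exact copies of chosen templates
orientSetFrom <- function(tmpl_art, tmpl_room, states, prev_cue = "switch") {
  n <- length(states)
  P <- t(vapply(states, function(s) if (s == "art") tmpl_art else tmpl_room,
                numeric(length(tmpl_art))))
  labels <- data.frame(
    task = "memory_guided", run = 2L, run_in_task = 2L,
    trial_in_run = seq_len(n), trial_index = 100 + seq_len(n),
    state = states, validity = "valid", cue_type = "none",
    prev_cue_type = prev_cue, stringsAsFactors = FALSE)
  makePatternSet(P, labels, period = "orienting", trim = "orienting")
}

test_that("preparatory index is maximal for perfect preparation and negative for retrieval", {
  art_t <- c(1, 0, 0, 0); room_t <- c(0, 1, 0, 0)  # orthogonal templates
  provider <- function(run, task = NULL) {
    new("StateTemplates", art = art_t, room = room_t,
        excluded_run = as.integer(run), options = list())
  }
  states <- c("art", "room", "art", "room")
  # orienting pattern == upcoming-state template
  prep <- orientSetFrom(art_t, room_t, states)
  res <- preparatoryIndex(prep, provider)
  expect_equal(res$per_task$index_z,
               atanh(1 - 1e-12) - atanh(cor(art_t, room_t)),
               tolerance = 1e-6)
  expect_true(all(res$per_trial$delta_z > 0))
  # orienting pattern == previous (other) state template on switch trials
  retr <- orientSetFrom(room_t, art_t, states)  # swapped: carries the other state
  res2 <- preparatoryIndex(retr, provider, subset = "switch_only")
  expect_lt(res2$per_task$index_z, 0)
})

test_that("index is antisymmetric under swapping template labels", {
  sim <- fixtureSim()
  s <- fixtureSchedule()
  runs <- Filter(function(b) b@region == "regA", sim$runs)
  img <- extractPeriodPatterns(runs, s, "image", trim = "image")
  orient <- extractPeriodPatterns(runs, s, "orienting")
  prov <- templateProvider(img)
  swapped <- function(run, task = NULL) {
    tm <- prov(run, task)
    new("StateTemplates", art = tm@room, room = tm@art,
        excluded_run = tm@excluded_run, options = tm@options)
  }
  a <- preparatoryIndex(orient, prov)$per_task
  b <- preparatoryIndex(orient, swapped)$per_task
  expect_equal(b$index_z, -a$index_z, tolerance = 1e-12)
})

test_that("summaries are invariant to positive rescaling of all patterns", {
  sim <- fixtureSim()
  s <- fixtureSchedule()
  runs <- Filter(function(b) b@region == "regA", sim$runs)
  img <- extractPeriodPatterns(runs, s, "image")
  scaled <- img
  scaled@patterns <- img@patterns * 7.3
  expect_equal(imageStateSimilarity(img), imageStateSimilarity(scaled),
               tolerance = 1e-10)
})

test_that("all robustness variants run from the same entry point", {
  sim <- fixtureSim()
  s <- fixtureSchedule()
  runs <- Filter(function(b) b@region == "regA", sim$runs)
  img_trim <- extractPeriodPatterns(runs, s, "image", trim = "image")
  orient <- extractPeriodPatterns(runs, s, "orienting")
  orient_last <- extractPeriodPatterns(runs, s, "orienting", trim = "none")
  variants <- list(
    list(pp = orient, valid_only = TRUE, common = TRUE, subset = "all"),
    list(pp = orient, valid_only = TRUE, common = FALSE, subset = "all"),
    list(pp = orient, valid_only = FALSE, common = TRUE, subset = "all"),
    list(pp = orient, valid_only = TRUE, common = TRUE,
         subset = "after_cue_only"),
    list(pp = orient, valid_only = TRUE, common = TRUE,
         subset = "switch_only"),
    list(pp = orient_last, valid_only = TRUE, common = TRUE,
         subset = "all"))
  for (vv in variants) {
    prov <- templateProvider(img_trim, valid_only = vv$valid_only,
                             common_across_tasks = vv$common)
    res <- preparatoryIndex(vv$pp, prov, subset = vv$subset)
    expect_equal(nrow(res$per_task), 2)
    expect_true(all(is.finite(res$per_task$index_z)))
  }
  empty <- orient
  empty@labels$prev_cue_type <- NA_character_
  prov <- templateProvider(img_trim)
  expect_error(preparatoryIndex(empty, prov, subset = "switch_only"),
               "empty-subset")
})

test_that("preparatory signal is recovered when only the memory task carries it", {
  s <- fixtureSchedule()
  e <- effectParams(prep_amp_memory = 0.25, prep_amp_explicit = 0)
  cc <- precomputeConvolvedDesign(s, e)
  wins <- 0
  plan <- NULL
  cfg <- pipelineConfig(regions = c(roi = 30), effects = list(
    prep_amp_memory = 0.25, prep_amp_explicit = 0),
    analyses = "preparatory", simulate_behavior = FALSE)
  for (k in 1:100) {
    r <- analyzeParticipant(s, cfg, childSeed(777, "p", k),
                            conv_cache = cc, extraction_plan = plan)
    plan <- r$extraction_plan
    pt <- r$preparatory
    wins <- wins + (pt$index_z[pt$task == "memory_guided"] >
                      pt$index_z[pt$task == "explicit"])
  }
  expect_gte(wins, 95)
})
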