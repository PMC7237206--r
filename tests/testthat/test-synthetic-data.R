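test_that("a perfect observer makes perfect valid-trial responses", {
  s <- fixtureSchedule()
  p <- participantParams(selection_accuracy = 1, hit_rate_valid = 1,
                         fa_rate_valid = 0, hit_rate_invalid = 1,
                         fa_rate_invalid = 0)
  b <- simulateBehavior(s, p, rng_seed = 1)
  expect_true(all(b$correct))
  sm <- summarizeBehavior(b)
  expect_true(all(sm$sdt$a_prime[sm$sdt$validity == "valid"] == 1))
  expect_equal(sm$decision_accuracy, 1)
})

test_that("equal hit and false-alarm rates give chance sensitivity", {
  s <- fixtureSchedule()
  p <- participantParams(hit_rate_invalid = 0.5, fa_rate_invalid = 0.5)
  ap <- vapply(1:40, function(k) {
    b <- simulateBehavior(s, p, rng_seed = k)
    sm <- summarizeBehavior(b)$sdt
    mean(sm$a_prime[sm$validity == "invalid"])
  }, numeric(1))
  # A' of estimated rates fluctuates around the chance value
  expect_lt(abs(mean(ap) - 0.5), 0.05)
})

test_that("empirical response rates sit inside binomial 99% bounds", {
  s <- fixtureSchedule()
  p <- participantParams(hit_rate_valid = 0.8, fa_rate_valid = 0.2,
                         selection_accuracy = 1)
  b <- simulateBehavior(s, p, rng_seed = 11)
  v <- b[b$validity_exp == "valid", ]
  hits <- v$response[v$match_present] == "present"
  fas <- v$response[!v$match_present] == "present"
  for (x in list(list(k = sum(hits), n = length(hits), p = 0.8),
                 list(k = sum(fas), n = length(fas), p = 0.2))) {
    lo <- qbinom(0.005, x$n, x$p)
    hi <- qbinom(0.995, x$n, x$p)
    expect_gte(x$k, lo)
    expect_lte(x$k, hi)
  }
})

test_that("selection errors propagate through the chosen-state chain", {
  s <- fixtureSchedule()
  p <- participantParams(selection_accuracy = 0.7)
  b <- simulateBehavior(s, p, rng_seed = 2)
  mem <- b[b$task == "memory_guided", ]
  mem <- mem[order(mem$trial_index), ]
  # decision correctness is measured against the chain re-derived from the
  # participant's own previous choice
  for (i in seq_len(nrow(mem))[-1]) {
    prev_cue <- trials(s)$cue_type[trials(s)$task == "memory_guided"][i - 1]
    if (mem$trial_in_run[i] == 0L || prev_cue == "none") next
    intended <- deriveNextState(mem$chosen_state[i - 1], prev_cue)
    expect_identical(mem$decision_correct[i],
                     mem$chosen_state[i] == intended)
  }
  expect_lt(mean(mem$decision_correct, na.rm = TRUE), 0.95)
  expect_gt(mean(mem$decision_correct, na.rm = TRUE), 0.4)
})

test_that("state patterns are unit-norm with exact requested overlap", {
  for (r0 in c(0, 0.5, -0.3)) {
    pat <- makeStatePatterns(100, r0, rng_seed = 1)
    expect_equal(sqrt(sum(pat$art^2)), 1, tolerance = 1e-12)
    expect_equal(sqrt(sum(pat$room^2)), 1, tolerance = 1e-12)
    expect_equal(cor(pat$art, pat$room), r0, tolerance = 1e-6)
  }
  p2 <- makeStatePatterns(2, 0, rng_seed = 1)
  expect_equal(sum(p2$art * p2$room), 0, tolerance = 1e-12)
  expect_error(makeStatePatterns(100, 1), "< 1")
  expect_error(makeStatePatterns(1, 0), ">= 2")
})

test_that("double-gamma HRF has the documented shape", {
  expect_equal(doubleGammaHrf(0), 0)
  grid <- seq(0, 30, by = 0.01)
  h <- doubleGammaHrf(grid)
  expect_lt(abs(grid[which.max(h)] - 6), 0.1)
  expect_equal(max(h), 1, tolerance = 1e-6)   # unit peak
  expect_lt(abs(doubleGammaHrf(30)), 0.01)    # late tail
  # undershoot is negative between the lobes' tails
  expect_lt(doubleGammaHrf(16), 0)
  # configurable peak delay moves the argmax
  h5 <- doubleGammaHrf(grid, peak_delay_s = 5)
  expect_lt(abs(grid[which.max(h5)] - 5), 0.1)
  expect_error(doubleGammaHrf(1, peak_disp_s = 0), "positive")
  expect_error(doubleGammaHrf(-1), "non-negative")
})

test_that("noiseless image periods separate the two states on every trial", {
  s <- fixtureSchedule()
  e <- effectParams(noise_sd = 0, drift_amp = 0, prep_amp_memory = 0,
                    prep_amp_explicit = 0, image_amp = 1, fidelity_sd = 0)
  sim <- simulateBold(s, c(roi = 40), e, rng_seed = 1,
                      tasks = "memory_guided")
  pp <- extractPeriodPatterns(sim$runs, s, "image")
  gt <- sim$ground_truth$patterns$roi
  lab <- patternLabels(pp)
  P <- patterns(pp)
  r_art <- apply(P, 1, cor, y = gt$art)
  r_room <- apply(P, 1, cor, y = gt$room)
  expect_true(all(ifelse(lab$state == "art", r_art > r_room,
                         r_room > r_art)))
})

test_that("with no pattern signal, same-minus-different similarity is null", {
  s <- fixtureSchedule()
  e <- effectParams(image_amp = 0, prep_amp_memory = 0,
                    prep_amp_explicit = 0)
  deltas <- vapply(1:100, function(k) {
    sim <- simulateBold(s, c(roi = 15), e, rng_seed = 1000 + k,
                        tasks = "memory_guided")
    pp <- extractPeriodPatterns(sim$runs, s, "image")
    imageStateSimilarity(pp)$delta_z
  }, numeric(1))
  ci <- mean(deltas) + c(-1, 1) * qt(0.975, 99) * sd(deltas) / 10
  expect_gte(0, ci[1])
  expect_lte(0, ci[2])
})

test_that("BOLD generation is deterministic with the documented shape", {
  s <- fixtureSchedule()
  e <- effectParams()
  a <- simulateBold(s, c(x = 10), e, rng_seed = 9, tasks = "memory_guided")
  b <- simulateBold(s, c(x = 10), e, rng_seed = 9, tasks = "memory_guided")
  expect_identical(a$runs[[1]]@data, b$runs[[1]]@data)
  for (br in a$runs) {
    dur <- runDurations(s)[[as.character(br@run_index)]] + e$pad_s
    expect_equal(ncol(br@data), ceiling(dur / e$tr_s))
    expect_equal(br@n_discard, 4L)
    expect_equal(nrow(br@data), 10)
    expect_false(anyNA(br@data))
  }
  expect_error(effectParams(noise_sd = -1), "non-negative")
})

test_that("fidelity factors are unit-mean and coupled as requested", {
  s <- fixtureSchedule()
  e <- effectParams(quality_coupling_rho = c(memory_guided = 0.6,
                                             explicit = 0))
  sim <- simulateBold(s, c(a = 2, b = 2), e, rng_seed = 3)
  g <- sim$ground_truth$fidelity
  expect_true(all(g$a > 0))
  expect_lt(abs(mean(g$a) - 1), 0.15)
  r_mem <- cor(log(g$a[g$task == "memory_guided"]),
               log(g$b[g$task == "memory_guided"]))
  r_exp <- cor(log(g$a[g$task == "explicit"]),
               log(g$b[g$task == "explicit"]))
  expect_gt(r_mem, 0.3)
  expect_lt(abs(r_exp), 0.3)
})
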