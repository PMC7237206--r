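# labelled pattern matrices over a mask: image patterns carry the state
# pattern, orienting patterns optionally carry a preparatory pattern inside
# a target voxel subset
slPatterns <- function(mask, seed = 1, prep_voxels = NULL,
                       prep_sign = 1, n_runs = 3, trials_per_run = 8,
                       noise = 0.5) {
  set.seed(seed)
  nv <- sum(mask > 0)
  art <- rnorm(nv); art <- art / sqrt(sum(art^2))
  room <- rnorm(nv); room <- room - sum(room * art) * art
  room <- room / sqrt(sum(room^2))
  n <- n_runs * trials_per_run
  states <- rep(rep(c("art", "room"), length.out = trials_per_run), n_runs)
  runs <- rep(seq_len(n_runs) - 1L, each = trials_per_run)
  base <- t(vapply(states, function(s) if (s == "art") art else room,
                   numeric(nv)))
  img <- base + matrix(rnorm(n * nv, sd = noise), n, nv)
  orient <- matrix(rnorm(n * nv, sd = noise), n, nv)
  if (!is.null(prep_voxels)) {
    orient[, prep_voxels] <- orient[, prep_voxels] +
      prep_sign * base[, prep_voxels]
  }
  labels <- data.frame(
    task = "memory_guided", run = runs, run_in_task = runs,
    trial_in_run = rep(seq_len(trials_per_run) - 1L, n_runs),
    trial_index = seq_len(n) - 1L, state = states, validity = "valid",
    cue_type = "none", prev_cue_type = "switch", stringsAsFactors = FALSE)
  list(img = makePatternSet(img, labels, period = "image"),
       orient = makePatternSet(orient, labels, period = "orienting",
                               trim = "orienting"))
}

test_that("cube enumeration finds exactly the interior full cubes", {
  m3 <- array(1, c(3, 3, 3))
  nb <- cubeNeighborhoods(m3)
  expect_equal(length(nb$centers), 1)
  expect_equal(nrow(nb$cols), 27)
  m5 <- array(1, c(5, 5, 5))
  nb5 <- cubeNeighborhoods(m5)
  expect_equal(length(nb5$centers), 27)
  expect_true(all(!is.na(nb5$cols)))
  expect_error(cubeNeighborhoods(array(0, c(3, 3, 3))), "empty")
  expect_warning(cubeNeighborhoods(array(1, c(2, 5, 5))), "no full")
})

test_that("cube enumeration matches a brute-force triple-loop oracle", {
  set.seed(4)
  for (rep in 1:3) {
    dm <- c(sample(4:7, 1), sample(4:7, 1), sample(4:7, 1))
    mask <- array(runif(prod(dm)) < 0.85, dm)
    nb <- tryCatch(suppressWarnings(cubeNeighborhoods(mask)),
                   error = function(e) NULL)
    centers <- integer(0)
    for (i in 2:(dm[1] - 1)) for (j in 2:(dm[2] - 1)) {
      for (k in 2:(dm[3] - 1)) {
        ok <- all(mask[(i - 1):(i + 1), (j - 1):(j + 1),
                       (k - 1):(k + 1)])
        if (ok) {
          centers <- c(centers,
                       i + dm[1] * (j - 1) + dm[1] * dm[2] * (k - 1))
        }
      }
    }
    expect_equal(sort(nb$centers), sort(centers))
  }
})

test_that("a single-cube mask reproduces the ROI pipeline bit-for-bit", {
  mask <- array(1, c(3, 3, 3))
  ps <- slPatterns(mask, seed = 2)
  sl <- searchlightMap(ps$orient, ps$img, mask)
  # ROI route: same patterns, same options, via the ROI entry point
  prov <- templateProvider(ps$img)
  roi <- preparatoryIndex(ps$orient, prov)$per_task
  center_val <- sl$maps$memory_guided[2, 2, 2]
  expect_identical(center_val, roi$index_z)
})

test_that("maps are equivariant under a consistent voxel relabeling", {
  mask <- array(1, c(4, 4, 4))
  ps <- slPatterns(mask, seed = 3)
  sl <- searchlightMap(ps$orient, ps$img, mask)
  # reflect the grid along x: relabel voxels and patterns consistently
  dm <- dim(mask)
  coords <- arrayInd(seq_len(prod(dm)), dm)
  flip <- cbind(dm[1] + 1 - coords[, 1], coords[, 2], coords[, 3])
  perm <- flip[, 1] + dm[1] * (flip[, 2] - 1) + dm[1] * dm[2] * (flip[, 3] - 1)
  reorder <- match(seq_len(prod(dm)), perm)
  ps_f <- ps
  ps_f$img@patterns <- ps$img@patterns[, reorder]
  ps_f$orient@patterns <- ps$orient@patterns[, reorder]
  sl_f <- searchlightMap(ps_f$orient, ps_f$img, mask)
  expect_equal(sl_f$maps$memory_guided[dm[1]:1, , ],
               sl$maps$memory_guided, tolerance = 1e-12)
})

test_that("the preparatory signal localizes to the embedded block", {
  dm <- c(8, 8, 8)
  mask <- array(1, dm)
  block <- array(FALSE, dm)
  block[3:7, 3:7, 3:7] <- TRUE
  hits <- 0
  for (seed in 1:5) {
    ps <- slPatterns(mask, seed = seed, prep_voxels = which(block),
                     noise = 0.4)
    sl <- searchlightMap(ps$orient, ps$img, mask)
    m <- sl$maps$memory_guided
    inside <- mean(m[block & !is.na(m)])
    outside <- mean(m[!block & !is.na(m)])
    expect_gt(inside, outside)
    # dilate the block by one voxel: the peak must fall inside
    dil <- array(FALSE, dm)
    dil[2:8, 2:8, 2:8] <- TRUE
    if (dil[which.max(m)]) hits <- hits + 1
  }
  expect_gte(hits, 4)
})

test_that("group inference survives constants and controls the null", {
  dm <- c(5, 5, 5)
  mask <- array(1, dm)
  nbc <- cubeNeighborhoods(mask)
  template <- array(NA_real_, dm)
  # constant strong positive maps: every defined voxel survives
  maps <- lapply(1:8, function(i) {
    m <- template
    m[nbc$centers] <- 0.5 + 0.01 * i
    m
  })
  g <- groupSearchlight(maps, n_perm = 299, rng_seed = 1)
  expect_equal(g$n_voxels, 27)
  expect_true(all(g$significant_map[nbc$centers] == 1))
  # null maps: no survivors in the large majority of simulations
  clean <- 0
  for (seed in 1:40) {
    set.seed(seed)
    maps0 <- lapply(1:8, function(i) {
      m <- template
      m[nbc$centers] <- rnorm(27)
      m
    })
    g0 <- groupSearchlight(maps0, n_perm = 199, rng_seed = seed)
    if (sum(g0$significant_map[nbc$centers]) == 0) clean <- clean + 1
  }
  expect_gte(clean, 34)  # nominal 95% FWE control, binomial noise allowed
  expect_error(groupSearchlight(maps[1:3]), ">= 5")
  bad <- maps
  bad[[2]] <- array(0, c(4, 4, 4))
  expect_error(groupSearchlight(bad), "alignment")
})

test_that("searchlight maps round-trip through NIfTI", {
  m <- array(NA_real_, c(4, 4, 4))
  m[2:3, 2:3, 2:3] <- rnorm(8)
  d <- withr::local_tempdir()
  p <- file.path(d, "map.nii.gz")
  writeMapNifti(m, p)
  back <- readMapNifti(p)
  expect_equal(back, m, tolerance = 1e-6, ignore_attr = TRUE)
  expect_true(all(is.na(back) == is.na(m)))
})
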