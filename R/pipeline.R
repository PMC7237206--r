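#' Pipeline run configuration
#'
#' Assembles the full configuration for an end-to-end synthetic run:
#' design parameters, participant behavior parameters, generative effect
#' sizes, regions, enabled analyses and analysis-variant flags. Fully
#' serializable (see [writeResultBundle()]); a stored config plus seed
#' reproduces every output.
#'
#' @param seed global seed; all per-stage/per-participant seeds derive from
#'   it via a documented splitting scheme.
#' @param n_participants number of simulated participants.
#' @param regions named vector of voxel counts.
#' @param design,participant,effects lists of overrides for
#'   [designConfig()], [participantParams()], [effectParams()].
#' @param analyses subset of `c("behavior", "similarity", "preparatory",
#'   "connectivity", "univariate")`.
#' @param variants analysis-variant flags: `valid_only`,
#'   `common_across_tasks`, `subset` (`"all"`, `"after_cue_only"`,
#'   `"switch_only"`), `include_last_tr` (keep the last orienting volume),
#'   `quality_scale`.
#' @param connectivity_pair,contrast_pair region name pairs for the
#'   informational-connectivity and univariate-contrast correlation
#'   analyses.
#' @param prep_regions regions to run the preparatory-index analysis for
#'   (default: all).
#' @param tasks tasks to simulate and analyze.
#' @param simulate_behavior simulate behavioral responses (and use chosen
#'   states / RTs downstream); otherwise scheduled states and default RTs
#'   are used.
#' @param schedule_per_participant build a fresh schedule per participant
#'   (default) or share one schedule across participants.
#' @return a list of class `pipeline_config`.
#' @export
pipelineConfig <- function(seed = 1L,
                           n_participants = 12L,
                           regions = c(hippocampus = 50L, vmpfc = 50L,
                                       v12 = 50L),
                           design = list(),
                           participant = list(),
                           effects = list(),
                           analyses = c("behavior", "similarity",
                                        "preparatory", "connectivity",
                                        "univariate"),
                           variants = list(),
                           connectivity_pair = c("hippocampus", "v12"),
                           contrast_pair = c("hippocampus", "vmpfc"),
                           prep_regions = NULL,
                           tasks = c("memory_guided", "explicit"),
                           simulate_behavior = TRUE,
                           schedule_per_participant = TRUE) {
  v <- modifyList(list(valid_only = TRUE, common_across_tasks = TRUE,
                       subset = "all", include_last_tr = FALSE,
                       quality_scale = "z"), variants)
  cfg <- list(seed = as.integer(seed),
              n_participants = as.integer(n_participants),
              regions = regions, design = design,
              participant = participant, effects = effects,
              analyses = analyses, variants = v,
              connectivity_pair = connectivity_pair,
              contrast_pair = contrast_pair,
              prep_regions = prep_regions, tasks = tasks,
              simulate_behavior = simulate_behavior,
              schedule_per_participant = schedule_per_participant)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path YAML (or JSON) document of overrides for [pipelineConfig()].
#' @return a `pipeline_config`.
#' @export
readPipelineConfig <- function(path) {
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (!is.null(raw$regions)) raw$regions <- unlist(raw$regions)
  do.call(pipelineConfig, raw)
}

#' Simulate and analyze a single participant
#'
#' One participant's end-to-end pass: (optionally) behavior simulation with
#' RT-finalized timelines, BOLD simulation for the configured regions, then
#' the enabled analyses: image-period state similarity, orienting-period
#' preparatory index (templates from boundary-trimmed image patterns),
#' informational connectivity between the configured pair, and the
#' single-trial univariate GLM.
#'
#' @param schedule a [TrialSchedule-class].
#' @param config a [pipelineConfig()].
#' @param rng_seed participant-level seed.
#' @param conv_cache optional [precomputeConvolvedDesign()] result; only
#'   valid when behavior simulation is off (timelines shared).
#' @param extraction_plan optional plan list from a previous participant's
#'   `$extraction_plan` (same schedule/timelines); speeds up repeated runs.
#' @return list of per-participant result tables (and the behavior table),
#'   including `$extraction_plan` when timelines are shared.
#' @export
analyzeParticipant <- function(schedule, config, rng_seed,
                               conv_cache = NULL, extraction_plan = NULL) {
  if (is.null(extraction_plan)) extraction_plan <- list()
  v <- config$variants
  eff <- do.call(effectParams, config$effects)
  behavior <- NULL
  if (isTRUE(config$simulate_behavior)) {
    pp <- do.call(participantParams, config$participant)
    behavior <- simulateBehavior(schedule, pp, rng_seed)
    schedule <- finalizeTimelines(schedule, behavior$initiation_rt_s)
    conv_cache <- NULL  # timelines are participant-specific
  }
  sim <- simulateBold(schedule, config$regions, eff, rng_seed,
                      behavior = behavior, tasks = config$tasks,
                      conv_cache = conv_cache)
  by_region <- split(sim$runs,
                     vapply(sim$runs, function(b) b@region, character(1)))

  out <- list(behavior = behavior)
  needs_image <- any(c("similarity", "connectivity") %in% config$analyses)
  specs <- list()
  if (needs_image) specs$image <- list(period = "image", trim = "none")
  if ("preparatory" %in% config$analyses) {
    specs$image_trim <- list(period = "image", trim = "image")
    specs$orienting <- list(
      period = "orienting",
      trim = if (isTRUE(v$include_last_tr)) "none" else "orienting")
  }
  prep_regions <- config$prep_regions %||% names(by_region)
  image_pp <- list(); image_trim_pp <- list(); orient_pp <- list()
  for (rg in names(by_region)) {
    sp_rg <- specs
    if (!rg %in% prep_regions) {
      sp_rg$image_trim <- NULL
      sp_rg$orienting <- NULL
    }
    if (!length(sp_rg)) next
    pkey <- paste(names(sp_rg), collapse = "+")
    sets <- extractPeriodPatternSets(by_region[[rg]], schedule, sp_rg,
                                     behavior = behavior,
                                     plan = extraction_plan[[pkey]])
    if (is.null(behavior)) extraction_plan[[pkey]] <- attr(sets, "plan")
    image_pp[[rg]] <- sets$image
    image_trim_pp[[rg]] <- sets$image_trim
    orient_pp[[rg]] <- sets$orienting
  }
  out$extraction_plan <- if (is.null(behavior)) extraction_plan

  if ("similarity" %in% config$analyses) {
    out$similarity <- do.call(rbind, lapply(names(image_pp), function(rg) {
      cbind(region = rg,
            imageStateSimilarity(image_pp[[rg]], valid_only = v$valid_only))
    }))
  }
  if ("preparatory" %in% config$analyses) {
    out$preparatory <- do.call(rbind, lapply(names(orient_pp), function(rg) {
      prov <- templateProvider(image_trim_pp[[rg]],
                               valid_only = v$valid_only,
                               common_across_tasks = v$common_across_tasks)
      res <- preparatoryIndex(orient_pp[[rg]], prov, subset = v$subset)
      cbind(region = rg, res$per_task)
    }))
  }
  if ("connectivity" %in% config$analyses) {
    pr <- config$connectivity_pair
    if (all(pr %in% names(image_pp))) {
      qs <- lapply(pr, function(rg) {
        prov <- templateProvider(image_pp[[rg]], valid_only = v$valid_only,
                                 common_across_tasks = v$common_across_tasks)
        qualitySeries(image_pp[[rg]], prov, valid_only = v$valid_only,
                      scale = v$quality_scale)
      })
      out$connectivity <- multivariateConnectivity(qs[[1]], qs[[2]])
    }
  }
  if ("univariate" %in% config$analyses) {
    out$univariate <- do.call(rbind, lapply(names(by_region), function(rg) {
      roiUnivariate(by_region[[rg]], schedule, mode = "image_locked",
                    valid_only = v$valid_only)
    }))
  }
  out
}

#' Run the full synthetic-group pipeline
#'
#' Simulates `n_participants` participants (design, behavior, BOLD),
#' analyzes each ([analyzeParticipant()]), and computes the group statistics
#' reported by the corresponding experiment: A' ANOVA over task x validity,
#' same-vs-different image-period similarity tests, preparatory-index
#' one-sample and task-difference tests, connectivity tests, the univariate
#' task contrast and the robust inter-region correlation of its individual
#' differences.
#'
#' @param config a [pipelineConfig()].
#' @return a `result_bundle`: list with `config`, `tables` (named
#'   data.frames with participant-level rows), `group` (named list of test
#'   results), `provenance`.
#' @export
runPipeline <- function(config = pipelineConfig()) {
  design_cfg <- do.call(designConfig, config$design)
  shared_schedule <- NULL
  conv_cache <- NULL
  if (!isTRUE(config$schedule_per_participant)) {
    shared_schedule <- buildSchedule(config = design_cfg,
                                     rng_seed = childSeed(config$seed,
                                                          "design"))
    if (!isTRUE(config$simulate_behavior)) {
      conv_cache <- precomputeConvolvedDesign(
        shared_schedule, do.call(effectParams, config$effects),
        tasks = config$tasks)
    }
  }
  tables <- list()
  addRows <- function(tab, name, id) {
    if (is.null(tab)) return()
    tab <- cbind(participant = id, tab)
    tables[[name]] <<- rbind(tables[[name]], tab)
  }
  plan <- NULL
  for (i in seq_len(config$n_participants)) {
    pseed <- childSeed(config$seed, "participant", i)
    sched <- shared_schedule %||%
      buildSchedule(config = design_cfg, rng_seed = pseed)
    res <- analyzeParticipant(sched, config, pseed,
                              conv_cache = conv_cache,
                              extraction_plan = if (!is.null(shared_schedule))
                                plan)
    if (!is.null(shared_schedule)) plan <- res$extraction_plan %||% plan
    if (!is.null(res$behavior) && "behavior" %in% config$analyses) {
      bs <- summarizeBehavior(res$behavior)
      addRows(bs$sdt, "behavior", i)
      addRows(data.frame(decision_accuracy = bs$decision_accuracy),
              "decision", i)
    }
    addRows(res$similarity, "similarity", i)
    addRows(res$preparatory, "preparatory", i)
    addRows(res$connectivity, "connectivity", i)
    addRows(res$univariate, "univariate", i)
  }
  for (nm in names(tables)) rownames(tables[[nm]]) <- NULL

  group <- .groupStats(tables, config)
  bundle <- list(config = config, tables = tables, group = group,
                 provenance = list(
                   package_version =
                     as.character(utils::packageVersion("prepattn")),
                   config_hash = .hashObject(config),
                   timestamp = format(Sys.time(), tz = "UTC")))
  class(bundle) <- "result_bundle"
  bundle
}

.hashObject <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}

.groupStats <- function(tables, config) {
  g <- list()
  tb <- tables
  if (!is.null(tb$behavior) &&
      length(unique(tb$behavior$participant)) >= 2 &&
      length(config$tasks) == 2) {
    wide <- tryCatch({
      b <- tb$behavior
      long <- data.frame(participant = b$participant, factor_a = b$task,
                         factor_b = b$validity, value = b$a_prime)
      rmAnova2x2(long, factor_names = c("task", "validity"))
    }, error = function(e) NULL)
    g$behavior_anova <- wide
  }
  if (!is.null(tb$similarity)) {
    g$similarity <- do.call(rbind, lapply(
      split(tb$similarity, list(tb$similarity$region, tb$similarity$task),
            drop = TRUE),
      function(s) {
        tt <- oneSampleTTest(s$delta_z)
        data.frame(region = s$region[1], task = s$task[1],
                   mean_delta_z = mean(s$delta_z), t = tt$statistic,
                   dof = tt$dof, p = tt$p, d = tt$effect_size_d)
      }))
    rownames(g$similarity) <- NULL
  }
  if (!is.null(tb$preparatory)) {
    prep <- tb$preparatory
    g$preparatory <- do.call(rbind, lapply(
      split(prep, list(prep$region, prep$task), drop = TRUE),
      function(s) {
        tt <- oneSampleTTest(s$index_z)
        data.frame(region = s$region[1], task = s$task[1],
                   mean_index_z = mean(s$index_z), t = tt$statistic,
                   dof = tt$dof, p = tt$p, d = tt$effect_size_d)
      }))
    rownames(g$preparatory) <- NULL
    if (length(config$tasks) == 2) {
      g$preparatory_task_diff <- do.call(rbind, lapply(
        split(prep, prep$region), function(s) {
          m <- s[s$task == "memory_guided", ]
          e <- s[s$task == "explicit", ]
          e <- e[match(m$participant, e$participant), ]
          tt <- pairedTTest(m$index_z, e$index_z)
          data.frame(region = s$region[1],
                     mean_diff_z = mean(m$index_z - e$index_z),
                     t = tt$statistic, dof = tt$dof, p = tt$p,
                     d = tt$effect_size_d)
        }))
      rownames(g$preparatory_task_diff) <- NULL
    }
  }
  if (!is.null(tb$connectivity)) {
    cn <- tb$connectivity
    g$connectivity <- do.call(rbind, lapply(split(cn, cn$task), function(s) {
      tt <- oneSampleTTest(s$z)
      data.frame(task = s$task[1], mean_r = mean(s$r), mean_z = mean(s$z),
                 t = tt$statistic, dof = tt$dof, p = tt$p,
                 d = tt$effect_size_d)
    }))
    rownames(g$connectivity) <- NULL
    if (length(config$tasks) == 2) {
      m <- cn[cn$task == "memory_guided", ]
      e <- cn[cn$task == "explicit", ]
      e <- e[match(m$participant, e$participant), ]
      tt <- pairedTTest(m$z, e$z)
      g$connectivity_task_diff <- data.frame(
        mean_diff_z = mean(m$z - e$z), t = tt$statistic, dof = tt$dof,
        p = tt$p, d = tt$effect_size_d)
    }
  }
  if (!is.null(tb$univariate) && length(config$tasks) == 2) {
    un <- tb$univariate
    run_means <- stats::aggregate(estimate ~ participant + region + task,
                                  un, mean)
    g$univariate_contrast <- do.call(rbind, lapply(
      split(run_means, run_means$region), function(s) {
        m <- s[s$task == "memory_guided", ]
        e <- s[s$task == "explicit", ]
        e <- e[match(m$participant, e$participant), ]
        tt <- pairedTTest(m$estimate, e$estimate)
        data.frame(region = s$region[1],
                   mean_contrast = mean(m$estimate - e$estimate),
                   t = tt$statistic, dof = tt$dof, p = tt$p,
                   d = tt$effect_size_d)
      }))
    rownames(g$univariate_contrast) <- NULL
    pr <- config$contrast_pair
    if (all(pr %in% run_means$region) &&
        length(unique(run_means$participant)) >= 10) {
      contrasts <- lapply(pr, function(rg) {
        s <- run_means[run_means$region == rg, ]
        m <- s[s$task == "memory_guided", ]
        e <- s[s$task == "explicit", ]
        e <- e[match(m$participant, e$participant), ]
        m$estimate - e$estimate
      })
      g$contrast_correlation <- skippedCorrelation(contrasts[[1]],
                                                   contrasts[[2]],
                                                   rng_seed = config$seed)
    }
  }
  g
}

#' @export
print.result_bundle <- function(x, ...) {
  cat("prepattn result bundle\n")
  cat(sprintf("  participants: %d; tables: %s\n",
              x$config$n_participants,
              paste(names(x$tables), collapse = ", ")))
  cat(sprintf("  config hash: %s\n", x$provenance$config_hash))
  invisible(x)
}

#' Write / read a result bundle
#'
#' `writeResultBundle()` serializes every participant-level table to CSV,
#' the group results and provenance to JSON, and a manifest with MD5
#' checksums. `readResultBundle()` reads it back, verifying the manifest:
#' missing or tampered files raise an integrity error. Optional sections
#' absent from the bundle round-trip as absent.
#'
#' @param bundle a `result_bundle` from [runPipeline()].
#' @param dir output directory.
#' @return `writeResultBundle()`: invisibly, `dir`. `readResultBundle()`:
#'   the restored bundle (numeric values within write precision, ~1e-15
#'   relative).
#' @export
writeResultBundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (nm in names(bundle$tables)) {
    f <- file.path(dir, paste0("table_", nm, ".csv"))
    df <- bundle$tables[[nm]]
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(col) sprintf("%.17g", col))
    write.csv(df, f, row.names = FALSE)
    files <- c(files, basename(f))
  }
  jsonlite::write_json(bundle$group, file.path(dir, "group.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null", force = TRUE)
  jsonlite::write_json(bundle$provenance, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE)
  cfg <- bundle$config
  cfg$regions <- as.list(cfg$regions)
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null", force = TRUE)
  files <- c(files, "group.json", "provenance.json", "config.json")
  md5 <- tools::md5sum(file.path(dir, files))
  manifest <- data.frame(file = files, md5 = unname(md5),
                         stringsAsFactors = FALSE)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname writeResultBundle
#' @export
readResultBundle <- function(dir) {
  mf_path <- file.path(dir, "manifest.csv")
  if (!file.exists(mf_path)) stopf("integrity error: manifest.csv missing")
  manifest <- read.csv(mf_path, stringsAsFactors = FALSE)
  missing <- manifest$file[!file.exists(file.path(dir, manifest$file))]
  if (length(missing)) {
    stopf("integrity error: missing artifacts: %s",
          paste(missing, collapse = ", "))
  }
  md5 <- tools::md5sum(file.path(dir, manifest$file))
  bad <- manifest$file[unname(md5) != manifest$md5]
  if (length(bad)) {
    stopf("integrity error: checksum mismatch: %s",
          paste(bad, collapse = ", "))
  }
  tables <- list()
  for (f in grep("^table_", manifest$file, value = TRUE)) {
    nm <- sub("^table_(.*)\\.csv$", "\\1", f)
    tables[[nm]] <- read.csv(file.path(dir, f), stringsAsFactors = FALSE)
  }
  cfg <- jsonlite::read_json(file.path(dir, "config.json"),
                             simplifyVector = TRUE)
  cfg$regions <- unlist(cfg$regions)
  bundle <- list(config = do.call(pipelineConfig, cfg),
                 tables = tables,
                 group = jsonlite::read_json(file.path(dir, "group.json"),
                                             simplifyVector = TRUE),
                 provenance = jsonlite::read_json(
                   file.path(dir, "provenance.json"), simplifyVector = TRUE))
  class(bundle) <- "result_bundle"
  bundle
}
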