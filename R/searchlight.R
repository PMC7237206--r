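#' Enumerate full 27-voxel cube neighborhoods inside a mask
#'
#' Finds every voxel whose complete 3 x 3 x 3 cube lies inside the mask.
#' Cubes partially outside the mask are skipped entirely (no shrunken
#' neighborhoods), so the searchlight map is defined exactly at interior
#' centers.
#'
#' @param mask 3D array (logical or 0/1).
#' @return list: `centers` (linear array indices of cube centers), `cols`
#'   (27 x n matrix of indices into the mask-voxel order, i.e. columns of a
#'   patterns matrix extracted with that mask), `mask_idx` (linear indices
#'   of in-mask voxels, scan order), `dim`. Zero centers yields a warning.
#' @export
cubeNeighborhoods <- function(mask) {
  mask <- as.array(mask) > 0
  if (length(dim(mask)) != 3L) stopf("mask must be a 3D array")
  if (!any(mask)) stopf("mask is empty")
  dm <- dim(mask)
  mask_idx <- which(mask)
  offsets <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  coords <- arrayInd(mask_idx, dm)
  interior <- coords[, 1] > 1 & coords[, 1] < dm[1] &
    coords[, 2] > 1 & coords[, 2] < dm[2] &
    coords[, 3] > 1 & coords[, 3] < dm[3]
  cand <- which(interior)
  keep <- logical(length(cand))
  cols <- matrix(NA_integer_, 27L, length(cand))
  for (ci in seq_along(cand)) {
    cc <- coords[cand[ci], ]
    neigh <- sweep(offsets, 2L, cc, "+")
    lin <- neigh[, 1] + dm[1] * (neigh[, 2] - 1) +
      dm[1] * dm[2] * (neigh[, 3] - 1)
    pos <- match(lin, mask_idx)
    if (!anyNA(pos)) {
      keep[ci] <- TRUE
      cols[, ci] <- pos
    }
  }
  if (!any(keep)) {
    warning("no full 27-voxel cube fits inside the mask")
  }
  list(centers = mask_idx[cand[keep]],
       cols = cols[, keep, drop = FALSE],
       mask_idx = mask_idx, dim = dm)
}

#' Whole-volume searchlight of the preparatory-state analysis
#'
#' Runs the orienting-period preparatory-index pipeline (identical to the
#' ROI analysis) on every full 27-voxel cube in the mask, assigning each
#' cube's per-task index to its center voxel. Pattern matrices must carry
#' in-mask voxels as columns in mask scan order (as produced by
#' [readBoldRegion()] + [extractPeriodPatterns()] with that mask).
#'
#' @param orient_pp orienting-period [PeriodPatternSet-class] over the whole
#'   mask.
#' @param image_pp image-period [PeriodPatternSet-class] over the same mask
#'   (template source).
#' @param mask 3D array, or the result of [cubeNeighborhoods()].
#' @param subset,valid_only,common_across_tasks analysis options as in
#'   [preparatoryIndex()] / [templateProvider()].
#' @return list: `maps` — named list (per task) of 3D arrays with the index
#'   at defined centers and NA elsewhere; `centers`; `index` — data.frame of
#'   per-center per-task values.
#' @export
searchlightMap <- function(orient_pp, image_pp, mask, subset = "all",
                           valid_only = TRUE, common_across_tasks = TRUE) {
  nb <- if (is.list(mask) && !is.null(mask$cols)) mask
  else cubeNeighborhoods(mask)
  if (ncol(patterns(orient_pp)) != length(nb$mask_idx) ||
      ncol(patterns(image_pp)) != length(nb$mask_idx)) {
    stopf("alignment error: pattern columns do not match the mask voxels")
  }
  n_cent <- ncol(nb$cols)
  task_names <- unique(patternLabels(orient_pp)$task)
  vals <- matrix(NA_real_, n_cent, length(task_names),
                 dimnames = list(NULL, task_names))
  for (ci in seq_len(n_cent)) {
    colsel <- nb$cols[, ci]
    sub_or <- new("PeriodPatternSet", region = orient_pp@region,
                  period = orient_pp@period,
                  patterns = patterns(orient_pp)[, colsel, drop = FALSE],
                  labels = patternLabels(orient_pp), trim = orient_pp@trim)
    sub_im <- new("PeriodPatternSet", region = image_pp@region,
                  period = image_pp@period,
                  patterns = patterns(image_pp)[, colsel, drop = FALSE],
                  labels = patternLabels(image_pp), trim = image_pp@trim)
    prov <- templateProvider(sub_im, valid_only = valid_only,
                             common_across_tasks = common_across_tasks)
    res <- preparatoryIndex(sub_or, prov, subset = subset)$per_task
    vals[ci, res$task] <- res$index_z
  }
  maps <- lapply(task_names, function(tk) {
    m <- array(NA_real_, nb$dim)
    m[nb$centers] <- vals[, tk]
    m
  })
  names(maps) <- task_names
  list(maps = maps, centers = nb$centers,
       index = data.frame(center = rep(nb$centers, length(task_names)),
                          task = rep(task_names, each = n_cent),
                          index_z = as.vector(vals)))
}

#' Group-level searchlight inference with sign-flip FWE correction
#'
#' Stacks per-participant searchlight maps, runs a voxelwise one-sample
#' sign-flip permutation with max-statistic family-wise-error correction
#' (delegating to [signFlipPermutation()]), and thresholds at `alpha`.
#'
#' @param maps list of 3D arrays (one per participant, >= 5) on a common
#'   grid; voxels undefined (NA) in any participant are excluded.
#' @param n_perm number of permutations (default 10000).
#' @param alpha FWE level (default 0.05).
#' @param rng_seed integer seed.
#' @return list: `t_map`, `p_fwe_map`, `significant_map` (3D arrays),
#'   `threshold`, `n_voxels`.
#' @export
groupSearchlight <- function(maps, n_perm = 10000, alpha = 0.05,
                             rng_seed = 0L) {
  if (length(maps) < 5L) stopf("need >= 5 participant maps")
  dm <- dim(maps[[1]])
  if (!all(vapply(maps, function(m) identical(dim(m), dm), logical(1)))) {
    stopf("alignment error: maps are on different grids")
  }
  stack <- do.call(rbind, lapply(maps, as.vector))
  defined <- which(colSums(is.na(stack)) == 0L)
  if (!length(defined)) stopf("no voxel is defined in every participant")
  res <- signFlipPermutation(stack[, defined, drop = FALSE],
                             n_perm = n_perm, mode = "voxelwise_fwe",
                             alpha = alpha, rng_seed = rng_seed)
  mk <- function(v, fill = NA_real_) {
    m <- array(fill, dm)
    m[defined] <- v
    m
  }
  list(t_map = mk(res$statistic), p_fwe_map = mk(res$p_fwe),
       significant_map = mk(as.numeric(res$significant)),
       threshold = res$threshold, n_voxels = length(defined))
}

#' Read or write a searchlight map as 3D NIfTI
#'
#' Maps are stored aligned to the input mask grid; undefined voxels are
#' written as NA-filled (NaN in the file) and restored as NA.
#'
#' @param map 3D numeric array (e.g. an entry of `searchlightMap()$maps`).
#' @param path NIfTI file path (`.nii` or `.nii.gz`).
#' @return `writeMapNifti()`: invisibly, `path`; `readMapNifti()`: the 3D
#'   array with NA at undefined voxels.
#' @export
writeMapNifti <- function(map, path) {
  arr <- map
  arr[is.na(arr)] <- NaN
  RNifti::writeNifti(RNifti::asNifti(arr), path)
  invisible(path)
}

#' @rdname writeMapNifti
#' @export
readMapNifti <- function(path) {
  arr <- as.array(RNifti::readNifti(path))
  arr[is.nan(arr)] <- NA_real_
  arr
}
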