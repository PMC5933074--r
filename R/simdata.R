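#' Canonical double-gamma hemodynamic response function
#'
#' Difference of two gamma densities (response peak minus undershoot),
#' sampled on the TR grid over 32 s and normalized to unit peak height. The
#' peak sits near 5 s after stimulus onset and the kernel starts at ~0.
#'
#' @param tr_seconds repetition time (sampling interval), seconds.
#' @param duration_seconds kernel length, seconds.
#' @return Numeric vector of kernel samples at `t = 0, tr, 2 tr, ...`.
#' @export
canonical_hrf <- function(tr_seconds = 2, duration_seconds = 32) {
  stopifnot(tr_seconds > 0, duration_seconds > 0)
  t <- seq(0, duration_seconds, by = tr_seconds)
  h <- stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
  h / max(h)
}

#' Block-design paradigm
#'
#' Task blocks alternate with rest blocks; every task contributes the same
#' number of blocks and the task order within the run is pseudo-random from
#' the seed. The defaults give the 3-task run used throughout the package:
#' twelve 40 s task blocks (four per task) alternating with twelve 20 s rest
#' blocks at TR = 2 s, i.e. 360 volumes of which 240 are task-labeled.
#'
#' @param n_tasks number of task conditions K.
#' @param blocks_per_task task blocks per condition.
#' @param task_seconds,rest_seconds block lengths (must be multiples of the
#'   TR).
#' @param tr_seconds repetition time.
#' @param order explicit task-block order (overrides the seed), or `NULL`.
#' @param seed seed for the randomized block order.
#' @return A list of class `paradigm` with the block order, per-volume
#'   condition labels (`0` = rest) and timing fields.
#' @export
make_paradigm <- function(n_tasks = 3, blocks_per_task = 4,
                          task_seconds = 40, rest_seconds = 20,
                          tr_seconds = 2, order = NULL, seed = 1L) {
  stopifnot(n_tasks >= 1, blocks_per_task >= 1,
            task_seconds %% tr_seconds == 0, rest_seconds %% tr_seconds == 0)
  if (is.null(order)) {
    order <- withr::with_seed(seed,
      sample(rep(seq_len(n_tasks), blocks_per_task)))
  }
  stopifnot(length(order) == n_tasks * blocks_per_task)
  task_vols <- task_seconds / tr_seconds
  rest_vols <- rest_seconds / tr_seconds
  labels <- unlist(lapply(order, function(task)
    c(rep(task, task_vols), rep(0L, rest_vols))))
  structure(list(n_tasks = as.integer(n_tasks),
                 blocks_per_task = as.integer(blocks_per_task),
                 task_seconds = task_seconds, rest_seconds = rest_seconds,
                 tr_seconds = tr_seconds, order = as.integer(order),
                 volume_labels = as.integer(labels),
                 n_volumes = length(labels),
                 duration_seconds = length(labels) * tr_seconds,
                 seed = seed),
            class = "paradigm")
}

#' @export
print.paradigm <- function(x, ...) {
  cat("<paradigm> ", x$n_tasks, " tasks x ", x$blocks_per_task, " blocks (",
      x$task_seconds, "s task / ", x$rest_seconds, "s rest, TR ",
      x$tr_seconds, "s): ", x$n_volumes, " volumes\n", sep = "")
  invisible(x)
}

# Causal convolution of a volume-sampled time course with the HRF kernel,
# truncated to the input length.
conv_hrf <- function(x, h) {
  n <- length(x)
  out <- stats::convolve(c(x, numeric(length(h))), rev(h), type = "open")
  out[seq_len(n)]
}

#' Spatial source map for the simulator
#'
#' Defines the 27 spatial components of a run on a square voxel grid: one
#' rectangular region of interest (ROI) per task (block amplitude 1.5), one
#' shared rectangular region engaged by every task (amplitude 2), and 23
#' task-unrelated Gaussian blob sources driven by unique events (amplitude
#' 1), over a baseline intensity of 800. ROI positions are specified as grid
#' fractions so maps scale to any grid size. `layout = "shifted"` moves every
#' task ROI sideways by just over half a box width - the cross-decoding
#' geometry, where testing tasks engage nearby but not identical territory
#' (strictly partial overlap with the standard layout).
#'
#' @param grid side length of the square voxel grid.
#' @param layout `"standard"` or `"shifted"` task-ROI placement.
#' @param n_sources total source count (task ROIs + shared + blobs).
#' @param seed seed for the blob placement.
#' @param task_amplitude,shared_amplitude,unique_amplitude,baseline signal
#'   levels.
#' @return A list of class `source_map`; element `sources` holds one
#'   descriptor per component (type, role, center, size, amplitude).
#' @export
default_source_map <- function(grid = 50, layout = c("standard", "shifted"),
                               n_sources = 27, seed = 1L,
                               task_amplitude = 1.5, shared_amplitude = 2,
                               unique_amplitude = 1, baseline = 800) {
  layout <- match.arg(layout)
  stopifnot(grid >= 12, n_sources >= 5)
  # ROI half-width calibrated once so the decoder operating range across
  # CNR 0.08-0.16 matches the published curves (box of ~225 voxels on a
  # 50 x 50 field); "shifted" moves each ROI toward the field center by just
  # over half a box width, giving strictly partial overlap with "standard"
  hw <- max(1, round(0.14 * grid))
  shift <- if (layout == "shifted") hw + 1 else 0
  task_centers <- list(c(0.2, 0.2), c(0.2, 0.8), c(0.8, 0.2))
  sources <- list()
  for (i in 1:3) {
    ctr <- task_centers[[i]] * grid
    dir <- if (ctr[1] < grid / 2) 1 else -1
    sources[[i]] <- list(type = "box", role = "task", task = i,
                         center = c(ctr[1] + dir * shift, ctr[2]),
                         halfwidth = hw, amplitude = task_amplitude)
  }
  sources[[4]] <- list(type = "box", role = "shared", task = NA,
                       center = c(0.8, 0.8) * grid, halfwidth = hw,
                       amplitude = shared_amplitude)
  n_blobs <- n_sources - 4
  blob_xy <- withr::with_seed(seed,
    matrix(runif(2 * n_blobs, 0.05, 0.95), ncol = 2)) * grid
  sigma <- max(1, 0.06 * grid)
  for (b in seq_len(n_blobs)) {
    sources[[4 + b]] <- list(type = "blob", role = "noise", task = NA,
                             center = blob_xy[b, ], sigma = sigma,
                             amplitude = unique_amplitude)
  }
  structure(list(grid = as.integer(grid), layout = layout, sources = sources,
                 baseline = baseline, seed = seed),
            class = "source_map")
}

#' Per-subject source transforms
#'
#' Each source is independently translated (up to ~1 voxel on a 50 grid),
#' rotated about its own center (up to 2 degrees) and scaled (within 2%),
#' emulating intersubject anatomical variability while preserving the
#' relative ROI geometry.
#'
#' @param n_sources number of sources to draw transforms for.
#' @param seed subject-specific seed.
#' @param grid grid side length (translation scales with it).
#' @return A list of per-source transforms (dx, dy, theta, scale).
#' @export
subject_transforms <- function(n_sources, seed = 1L, grid = 50) {
  shift_max <- 0.02 * grid
  withr::with_seed(seed, lapply(seq_len(n_sources), function(s)
    list(dx = runif(1, -shift_max, shift_max),
         dy = runif(1, -shift_max, shift_max),
         theta = runif(1, -2, 2) * pi / 180,
         scale = runif(1, 0.98, 1.02))))
}

# Rasterize one source on the grid after applying its subject transform.
# Returns a length grid^2 vector (voxels in column-major (x, y) order).
rasterize_source <- function(src, grid, xform = NULL) {
  xy <- expand.grid(x = seq_len(grid), y = seq_len(grid))
  dx <- xform$dx %||% 0
  dy <- xform$dy %||% 0
  theta <- xform$theta %||% 0
  sc <- xform$scale %||% 1
  u0 <- xy$x - src$center[1] - dx
  v0 <- xy$y - src$center[2] - dy
  u <- (cos(theta) * u0 + sin(theta) * v0) / sc
  v <- (-sin(theta) * u0 + cos(theta) * v0) / sc
  if (src$type == "box") {
    as.numeric(abs(u) <= src$halfwidth & abs(v) <= src$halfwidth)
  } else {
    w <- exp(-(u^2 + v^2) / (2 * src$sigma^2))
    w[w < 0.01] <- 0                         # sparse, heavy-tailed map
    w
  }
}

# Voxel indices of a task ROI (no transform), used by tests and layouts.
roi_voxels <- function(smap, task) {
  src <- Filter(function(s) s$role == "task" && !is.na(s$task) &&
                  s$task == task, smap$sources)
  which(rasterize_source(src[[1]], smap$grid) > 0)
}

#' Simulate one block-design fMRI run
#'
#' The data are the product of source time courses and spatial maps plus
#' baseline and i.i.d. Gaussian noise. Task ROIs follow their task's box-car
#' convolved with the HRF at amplitude 1.5 (the shared region follows the
#' union of all task blocks at amplitude 2); task-unrelated sources follow
#' HRF-convolved Bernoulli unique events (p = 0.2 per TR) at amplitude 1.
#' The noise standard deviation is set from the contrast-to-noise ratio in
#' the SimTB sense: CNR = temporal standard deviation of a task-ROI voxel's
#' noise-free block response divided by the noise standard deviation.
#' Optionally a small rigid head-motion drift (translation < 2% of the
#' field, rotation < 5 degrees) resamples each volume.
#'
#' @param paradigm a [make_paradigm()].
#' @param source_map a [default_source_map()].
#' @param cnr contrast-to-noise ratio (> 0).
#' @param subject_xform per-source transforms from [subject_transforms()],
#'   or `NULL` for the canonical anatomy.
#' @param seed seed for events and noise.
#' @param noise_sd override the CNR-derived noise SD (e.g. 0 for a noiseless
#'   run); `NULL` derives it from `cnr`.
#' @param motion add the simplified rigid motion drift.
#' @param subject_id,group metadata carried into the result.
#' @return A list of class `simulated_run`: `data` (volumes x voxels),
#'   `volume_labels`, `paradigm`, `cnr`, `noise_sd`, `subject_id`, `seed`,
#'   `group`.
#' @export
generate_run <- function(paradigm, source_map, cnr, subject_xform = NULL,
                         seed = 1L, noise_sd = NULL, motion = FALSE,
                         subject_id = NA_integer_, group = NA_integer_) {
  stopifnot(inherits(paradigm, "paradigm"), inherits(source_map, "source_map"))
  if (is.null(noise_sd) && (!is.numeric(cnr) || cnr <= 0))
    stop("cnr must be a positive number")
  h <- canonical_hrf(paradigm$tr_seconds)
  labs <- paradigm$volume_labels
  tn <- paradigm$n_volumes
  nsrc <- length(source_map$sources)
  grid <- source_map$grid
  # CNR calibration: temporal SD of one task's HRF-convolved block response
  # at a pure ROI voxel (map weight 1), divided by the noise SD
  task_amp <- source_map$sources[[1]]$amplitude
  sigma_s <- stats::sd(task_amp * conv_hrf(as.numeric(labs == 1L), h))
  if (is.null(noise_sd)) noise_sd <- sigma_s / cnr
  event_seeds <- derive_seed(seed, seq_len(nsrc) + 7000L)
  tc <- matrix(0, tn, nsrc)
  for (s in seq_len(nsrc)) {
    src <- source_map$sources[[s]]
    drive <- if (identical(src$role, "task")) {
      as.numeric(labs == src$task)
    } else if (identical(src$role, "shared")) {
      as.numeric(labs > 0)
    } else {
      withr::with_seed(event_seeds[s],
                       as.numeric(runif(tn) < 0.2))
    }
    tc[, s] <- src$amplitude * conv_hrf(drive, h)
  }
  smat <- vapply(seq_len(nsrc), function(s)
    rasterize_source(source_map$sources[[s]], grid,
                     if (!is.null(subject_xform)) subject_xform[[s]]),
    numeric(grid^2))
  signal <- tc %*% t(smat)
  if (motion) signal <- apply_motion(signal, grid, derive_seed(seed, 31L))
  noise <- if (noise_sd > 0) {
    withr::with_seed(derive_seed(seed, 17L),
                     matrix(rnorm(tn * grid^2, sd = noise_sd), tn, grid^2))
  } else 0
  data <- source_map$baseline + signal + noise
  structure(list(data = data, volume_labels = labs, paradigm = paradigm,
                 cnr = cnr, noise_sd = noise_sd, source_map = source_map,
                 subject_id = subject_id, seed = seed, group = group,
                 grid = grid),
            class = "simulated_run")
}

#' @export
print.simulated_run <- function(x, ...) {
  cat("<simulated_run> ", nrow(x$data), " volumes x ", ncol(x$data),
      " voxels (grid ", x$grid, "x", x$grid, "), CNR ", x$cnr,
      ", subject ", x$subject_id, "\n", sep = "")
  invisible(x)
}

# Simplified rigid head motion: a bounded random-walk translation/rotation
# per volume, applied by bilinear resampling. Translation bounded by 2% of
# the field, rotation by 5 degrees.
apply_motion <- function(signal, grid, seed) {
  tn <- nrow(signal)
  tmax <- 0.02 * grid
  rmax <- 5 * pi / 180
  par <- withr::with_seed(seed, {
    step <- matrix(rnorm(3 * tn, sd = c(tmax, tmax, rmax) / 8), ncol = 3,
                   byrow = TRUE)
    drift <- apply(step, 2, cumsum)
    drift[, 1] <- pmin(pmax(drift[, 1], -tmax), tmax)
    drift[, 2] <- pmin(pmax(drift[, 2], -tmax), tmax)
    drift[, 3] <- pmin(pmax(drift[, 3], -rmax), rmax)
    drift
  })
  xy <- expand.grid(x = seq_len(grid), y = seq_len(grid))
  cx <- (grid + 1) / 2
  out <- signal
  for (t in seq_len(tn)) {
    th <- par[t, 3]
    u <- cos(th) * (xy$x - cx) + sin(th) * (xy$y - cx) + cx - par[t, 1]
    v <- -sin(th) * (xy$x - cx) + cos(th) * (xy$y - cx) + cx - par[t, 2]
    u <- pmin(pmax(u, 1), grid)
    v <- pmin(pmax(v, 1), grid)
    u0 <- floor(u); v0 <- floor(v)
    u1 <- pmin(u0 + 1, grid); v1 <- pmin(v0 + 1, grid)
    fu <- u - u0; fv <- v - v0
    frame <- matrix(signal[t, ], grid, grid)
    out[t, ] <- (1 - fu) * (1 - fv) * frame[cbind(u0, v0)] +
      fu * (1 - fv) * frame[cbind(u1, v0)] +
      (1 - fu) * fv * frame[cbind(u0, v1)] +
      fu * fv * frame[cbind(u1, v1)]
  }
  out
}

#' Generate a full simulated dataset collection
#'
#' For every (subject, CNR level) pair, emits one dataset of two runs: run 1
#' for training and run 2 for testing. Group 1 keeps the same task-ROI
#' layout in both runs (same training and testing tasks); group 2 swaps the
#' testing run to the shifted layout, so the testing tasks engage different
#' (partially overlapping) regions - the cross-decoding setting. All
#' subjects at one CNR level share that level's pseudo-random block orders;
#' each subject keeps its own anatomy (source transforms) across runs. The
#' defaults (12 subjects, 9 CNR levels 0.08-0.16) emit 108 datasets.
#'
#' @param group 1 (same tasks) or 2 (cross-decoding).
#' @param n_subjects number of simulated subjects.
#' @param cnr_levels vector of CNR levels.
#' @param seed master seed; the whole collection is a deterministic function
#'   of it.
#' @param grid voxel grid side length.
#' @param motion forwarded to [generate_run()].
#' @return A list of class `sim_collection`; element `datasets` is a list of
#'   `list(subject, cnr, group, train, test)` entries.
#' @export
generate_group <- function(group = 1, n_subjects = 12,
                           cnr_levels = seq(0.08, 0.16, by = 0.01),
                           seed = 1L, grid = 50, motion = FALSE) {
  stopifnot(group %in% c(1, 2), n_subjects >= 1, all(cnr_levels > 0))
  smap_std <- default_source_map(grid, "standard",
                                 seed = derive_seed(seed, 101L))
  smap_alt <- default_source_map(grid, "shifted",
                                 seed = derive_seed(seed, 102L))
  test_map <- if (group == 2) smap_alt else smap_std
  nsrc <- length(smap_std$sources)
  datasets <- vector("list", n_subjects * length(cnr_levels))
  k <- 0L
  for (ci in seq_along(cnr_levels)) {
    cnr <- cnr_levels[ci]
    par_train <- make_paradigm(seed = derive_seed(seed, 1000L + ci))
    par_test <- make_paradigm(seed = derive_seed(seed, 2000L + ci))
    for (subj in seq_len(n_subjects)) {
      xf <- subject_transforms(nsrc, seed = derive_seed(seed, 100L + subj),
                               grid = grid)
      run1 <- generate_run(par_train, smap_std, cnr, xf,
                           seed = derive_seed(seed, 10000L + 100L * ci + subj),
                           motion = motion, subject_id = subj, group = group)
      run2 <- generate_run(par_test, test_map, cnr, xf,
                           seed = derive_seed(seed, 20000L + 100L * ci + subj),
                           motion = motion, subject_id = subj, group = group)
      k <- k + 1L
      datasets[[k]] <- list(subject = subj, cnr = cnr, group = group,
                            train = run1, test = run2)
    }
  }
  structure(list(datasets = datasets, group = group,
                 n_subjects = n_subjects, cnr_levels = cnr_levels,
                 seed = seed, grid = grid),
            class = "sim_collection")
}

#' @export
print.sim_collection <- function(x, ...) {
  cat("<sim_collection> group ", x$group, ": ", length(x$datasets),
      " datasets (", x$n_subjects, " subjects x ", length(x$cnr_levels),
      " CNR levels), grid ", x$grid, "\n", sep = "")
  invisible(x)
}
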