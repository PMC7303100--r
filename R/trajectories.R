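#' Sample a smooth five-step drift trajectory
#'
#' Draws the endpoint shift with a uniformly random direction (axial
#' component compressed by 3.5/5 to respect the shallower axial FOV) and a
#' magnitude uniform in `magnitude_range`; draws a connection point near the
#' trajectory midpoint; and interpolates a per-coordinate natural cubic
#' spline through the three knots. The five shifts are the spline sampled at
#' equally spaced parameters, each relative to the initial position, with the
#' first shift exactly (0, 0, 0).
#'
#' Uses the current R random stream; seed with [set.seed()] for
#' reproducibility.
#'
#' @param magnitude_range interval (mm) for the endpoint shift magnitude.
#' @param conn_sigma_frac std of the isotropic Gaussian perturbation of the
#'   connection point, as a fraction of the endpoint magnitude (truncated at
#'   two sigma).
#' @param axial_scale compression of the axial direction component before
#'   renormalisation; default 3.5/5, the axial-to-lateral FOV ratio.
#' @return An object of class `oct_trajectory`: `shifts` (5 x 3 matrix, mm),
#'   `connection` (3-vector, mm), `magnitude` (mm).
#' @export
sample_trajectory <- function(magnitude_range = c(0.2, 2.4),
                              conn_sigma_frac = 0.15,
                              axial_scale = 3.5 / 5) {
  if (length(magnitude_range) != 2 || any(!is.finite(magnitude_range)) ||
      magnitude_range[1] <= 0 || diff(magnitude_range) < 0)
    stop("magnitude_range must be a positive, non-decreasing interval in mm")

  dir <- stats::rnorm(3)
  dir <- dir / sqrt(sum(dir^2))
  dir[3] <- dir[3] * axial_scale
  dir <- dir / sqrt(sum(dir^2))
  m <- stats::runif(1, magnitude_range[1], magnitude_range[2])
  endpoint <- m * dir

  pert <- stats::rnorm(3) * conn_sigma_frac * m
  pn <- sqrt(sum(pert^2))
  if (pn > 2 * conn_sigma_frac * m)        # truncate at two sigma
    pert <- pert * (2 * conn_sigma_frac * m) / pn
  connection <- endpoint / 2 + pert

  u <- c(0, 0.25, 0.5, 0.75, 1)
  shifts <- vapply(1:3, function(k) {
    sf <- stats::splinefun(c(0, 0.5, 1), c(0, connection[k], endpoint[k]),
                           method = "natural")
    sf(u)
  }, numeric(5))
  shifts[1, ] <- 0   # exact by construction; pin against round-off

  structure(list(shifts = shifts, connection = connection, magnitude = m),
            class = "oct_trajectory")
}

#' Acquire a labelled motion sequence along a trajectory
#'
#' Acquires one volume at each of the five target shifts of `traj`. Labels
#' are carried in mm and round-trip through motor-step space with the given
#' calibration, as on the acquisition rig. Every shift is relative to the
#' initial position, not incremental.
#'
#' @param phantom an `oct_phantom`.
#' @param traj an `oct_trajectory`.
#' @param calibration an `oct_calibration`.
#' @param roi_id integer tag identifying the tissue region.
#' @param origin_mm starting position of the sequence's initial FOV relative
#'   to the phantom reference position (mm). Labels are unaffected: every
#'   shift is relative to the sequence's own initial position.
#' @return An object of class `oct_sequence`: `volumes` (32 x 32 x 32 x 5
#'   array), `shifts` (5 x 3 matrix, mm), `roi_id`, `origin_mm`.
#' @export
make_sequence <- function(phantom, traj, calibration = make_calibration(),
                          roi_id = 0L, origin_mm = c(0, 0, 0)) {
  stopifnot(inherits(traj, "oct_trajectory"))
  shifts <- steps_to_mm(mm_to_steps(traj$shifts, calibration), calibration)
  vols <- array(0, c(fov_voxels(), 5))
  for (i in 1:5)
    vols[, , , i] <- acquire_volume(phantom, origin_mm + shifts[i, ], calibration)
  structure(list(volumes = vols, shifts = shifts, roi_id = as.integer(roi_id),
                 origin_mm = as.numeric(origin_mm)),
            class = "oct_sequence")
}

#' Build a synthetic motion-sequence dataset
#'
#' Generates `n_rois` independent speckle phantoms (one tissue region each)
#' and `n_patterns` motion sequences per region: the full dataset holds
#' `n_rois * n_patterns` sequences and five times as many volumes. The desk
#' profile (8 ROIs x 25 patterns) keeps experiments tractable on one CPU;
#' the full profile is 40 ROIs x 200 patterns.
#'
#' @param n_rois number of tissue regions (>= 3, so a train/val/test split by
#'   region remains possible).
#' @param n_patterns motion sequences per region.
#' @param seed master seed; all phantoms and trajectories derive from it.
#' @param magnitude_range endpoint-magnitude interval in mm, see
#'   [sample_trajectory()].
#' @param profile optional shorthand: `"desk"` = 8 x 25, `"full"` = 40 x 200
#'   (overrides `n_rois`/`n_patterns`).
#' @param start_jitter_mm per-axis half-range (mm) of the uniform jitter of
#'   each pattern's starting FOV position within its region. Jittering the
#'   start keeps the reference volume from being identical across the
#'   patterns of a region, so shift labels can only be inferred by comparing
#'   the volumes of a sequence, never from the content of one volume alone.
#' @param texture_params passed to [make_phantom()].
#' @param calibration an `oct_calibration`.
#' @return An object of class `oct_dataset`: `sequences` (list of
#'   `oct_sequence`), `manifest` (one row per sequence: roi_id, pattern,
#'   phantom seed, the five shifts in mm), `seed`.
#' @export
build_dataset <- function(n_rois = 8, n_patterns = 25, seed = 1,
                          magnitude_range = c(0.2, 2.4), profile = NULL,
                          start_jitter_mm = c(1.2, 1.2, 0.6),
                          texture_params = list(),
                          calibration = make_calibration()) {
  if (!is.null(profile)) {
    profile <- match.arg(profile, c("desk", "full"))
    if (profile == "desk") { n_rois <- 8; n_patterns <- 25 }
    else { n_rois <- 40; n_patterns <- 200 }
  }
  if (n_rois < 3)
    stop("n_rois must be at least 3 to allow a train/val/test split by ROI")

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  roi_seeds <- sample.int(.Machine$integer.max, n_rois)
  traj_seeds <- sample.int(.Machine$integer.max, n_rois)

  sequences <- vector("list", n_rois * n_patterns)
  rows <- vector("list", n_rois * n_patterns)
  k <- 0
  for (r in seq_len(n_rois)) {
    phantom <- make_phantom(roi_seeds[r], texture_params = texture_params)
    set.seed(traj_seeds[r])
    for (p in seq_len(n_patterns)) {
      traj <- sample_trajectory(magnitude_range)
      origin <- stats::runif(3, -start_jitter_mm, start_jitter_mm)
      seq_ <- make_sequence(phantom, traj, calibration, roi_id = r - 1L,
                            origin_mm = origin)
      k <- k + 1
      sequences[[k]] <- seq_
      s <- seq_$shifts
      rows[[k]] <- data.frame(
        roi_id = r - 1L, pattern = p - 1L, phantom_seed = roi_seeds[r],
        magnitude_mm = traj$magnitude,
        t(as.vector(t(s))))
    }
  }
  manifest <- do.call(rbind, rows)
  names(manifest)[5:19] <- as.vector(t(outer(paste0("s", 0:4),
                                             c("x", "y", "z"), paste, sep = "_")))
  rownames(manifest) <- NULL
  structure(list(sequences = sequences, manifest = manifest,
                 seed = as.integer(seed)),
            class = "oct_dataset")
}

#' @export
print.oct_dataset <- function(x, ...) {
  cat(sprintf("<oct_dataset> %d sequences (%d volumes), %d ROIs, seed %d\n",
              length(x$sequences), 5 * length(x$sequences),
              length(unique(x$manifest$roi_id)), x$seed))
  invisible(x)
}

#' Persist or restore a dataset
#'
#' `save_dataset()` writes the volume container (`dataset.rds`) and a
#' plain-text manifest (`manifest.csv`, one row per sequence with its ROI id,
#' phantom seed and the five shifts in mm) into `dir`; `load_dataset()`
#' restores the dataset.
#'
#' @param dataset an `oct_dataset`.
#' @param dir directory to write to / read from (created if missing).
#' @return `save_dataset()` returns `dir` invisibly; `load_dataset()` the
#'   restored `oct_dataset`.
#' @export
save_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "oct_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(dataset$manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  saveRDS(dataset, file.path(dir, "dataset.rds"))
  invisible(dir)
}

#' @rdname save_dataset
#' @export
load_dataset <- function(dir) {
  readRDS(file.path(dir, "dataset.rds"))
}

# Stack the regression targets of a dataset: list of 3 matrices (n x 3, mm)
# for the final shift and the two preceding ones.
dataset_targets <- function(dataset, idx = seq_along(dataset$sequences)) {
  tn  <- t(vapply(dataset$sequences[idx], function(s) s$shifts[5, ], numeric(3)))
  tn1 <- t(vapply(dataset$sequences[idx], function(s) s$shifts[4, ], numeric(3)))
  tn2 <- t(vapply(dataset$sequences[idx], function(s) s$shifts[3, ], numeric(3)))
  list(tn = tn, tn1 = tn1, tn2 = tn2)
}
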