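#' Rotate a motion sequence about the axial axis
#'
#' Applies progressive in-plane rotations to the five volumes of a sequence:
#' volume i (i = 0..4) is rotated by alpha_i = alpha_max / 4 * i about the
#' z (depth) axis, counterclockwise when viewed from +z, about the volume
#' centre, with bilinear resampling and edge replication outside the support.
#'
#' In `"noise"` mode the labels are untouched: the rotation is treated as an
#' image perturbation. In `"motion"` mode the rotation is part of the motion
#' and the lateral label components of shift i are replaced by
#' `R(alpha_i) \%*\% c(sx, sy)` (the axial component is unchanged); for the
#' headline label (i = 4) this is a rotation by `alpha_max`.
#'
#' @param seq an `oct_sequence` (five volumes).
#' @param alpha_max maximal rotation in degrees (>= 0), reached by the last
#'   volume.
#' @param mode `"noise"` or `"motion"`.
#' @return The rotated `oct_sequence`.
#' @export
rotate_sequence <- function(seq, alpha_max, mode = c("noise", "motion")) {
  mode <- match.arg(mode)
  stopifnot(inherits(seq, "oct_sequence"))
  if (dim(seq$volumes)[4] != 5) stop("sequence must hold exactly 5 volumes")
  if (alpha_max < 0) stop("alpha_max must be non-negative")
  angles <- alpha_max / 4 * (0:4)
  for (i in 1:5) {
    if (angles[i] != 0)
      seq$volumes[, , , i] <- rotate_volume_z(seq$volumes[, , , i], angles[i])
    if (mode == "motion") {
      a <- angles[i] * pi / 180
      R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)  # CCW about +z
      seq$shifts[i, 1:2] <- as.vector(R %*% seq$shifts[i, 1:2])
    }
  }
  seq
}

# In-plane (x, y) rotation of a volume about its lateral centre, CCW about +z,
# bilinear resampling, edge replication for out-of-support corners.
rotate_volume_z <- function(vol, angle_deg) {
  d <- dim(vol)
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  cx <- (nx - 1) / 2; cy <- (ny - 1) / 2
  a <- angle_deg * pi / 180
  gx <- rep(0:(nx - 1), times = ny) - cx
  gy <- rep(0:(ny - 1), each = nx) - cy
  # inverse map: source = centre + R(-a) (target - centre)
  sx <- cos(a) * gx + sin(a) * gy + cx
  sy <- -sin(a) * gx + cos(a) * gy + cy
  i0 <- pmin(pmax(floor(sx), 0), nx - 1); fx <- pmin(pmax(sx - i0, 0), 1)
  j0 <- pmin(pmax(floor(sy), 0), ny - 1); fy <- pmin(pmax(sy - j0, 0), 1)
  i1 <- pmin(i0 + 1, nx - 1); j1 <- pmin(j0 + 1, ny - 1)
  idx <- function(i, j) 1 + i + nx * j        # within-slice linear index
  w00 <- (1 - fx) * (1 - fy); w10 <- fx * (1 - fy)
  w01 <- (1 - fx) * fy;       w11 <- fx * fy
  m <- matrix(vol, nx * ny, nz)
  out <- w00 * m[idx(i0, j0), , drop = FALSE] +
         w10 * m[idx(i1, j0), , drop = FALSE] +
         w01 * m[idx(i0, j1), , drop = FALSE] +
         w11 * m[idx(i1, j1), , drop = FALSE]
  array(out, d)
}

#' Apply B-scan motion distortions to a volume
#'
#' Each B-scan (a fixed slow-axis y index, an x-z plane) is independently
#' selected with probability `p_dist`; a selected B-scan is translated by
#' `shift_px` voxels along one uniformly chosen in-plane axis (x or z) with a
#' uniformly chosen sign, vacated voxels filled by edge replication. This
#' emulates the inter-B-scan motion artifacts of slower OCT systems.
#'
#' Uses the current R random stream; seed with [set.seed()] for
#' reproducibility.
#'
#' @param vol a 32^3 volume array.
#' @param p_dist per-B-scan selection probability in [0, 1].
#' @param shift_px shift in voxels, 1 or 2.
#' @return The distorted volume, same shape and intensity range.
#' @export
distort_volume <- function(vol, p_dist, shift_px = 1L) {
  if (!shift_px %in% c(1L, 2L)) stop("shift_px must be 1 or 2")
  if (p_dist < 0 || p_dist > 1) stop("p_dist must lie in [0, 1]")
  d <- dim(vol)
  ny <- d[2]
  sel <- stats::runif(ny) < p_dist
  if (!any(sel)) return(vol)
  axes <- sample(c("x", "z"), ny, replace = TRUE)
  sgn <- sample(c(-1L, 1L), ny, replace = TRUE)
  for (y in which(sel)) {
    b <- vol[, y, ]                      # 32 x 32 B-scan (x along rows, z cols)
    s <- sgn[y] * shift_px
    if (axes[y] == "x") {
      src <- pmin(pmax(seq_len(d[1]) - s, 1L), d[1])
      vol[, y, ] <- b[src, ]
    } else {
      src <- pmin(pmax(seq_len(d[3]) - s, 1L), d[3])
      vol[, y, ] <- b[, src]
    }
  }
  vol
}

#' Random lateral flip/transpose augmentation
#'
#' Applies a random composition of lateral mirror flips (x, y) and an x/y
#' transposition to all five volumes of a sequence, transforming the shift
#' labels consistently (a flipped axis negates that label component; the
#' transposition swaps the lateral components). These are exact symmetries
#' of the translation-estimation problem on an isotropic lateral FOV, and
#' are used as training-time augmentation to discourage region-specific
#' shortcuts. Uses the current R random stream.
#'
#' @param seq an `oct_sequence`.
#' @return The augmented `oct_sequence`.
#' @export
random_flip_sequence <- function(seq) {
  stopifnot(inherits(seq, "oct_sequence"))
  d <- dim(seq$volumes)
  if (stats::runif(1) < 0.5) {                     # mirror x
    seq$volumes <- seq$volumes[d[1]:1, , , , drop = FALSE]
    seq$shifts[, 1] <- -seq$shifts[, 1]
  }
  if (stats::runif(1) < 0.5) {                     # mirror y
    seq$volumes <- seq$volumes[, d[2]:1, , , drop = FALSE]
    seq$shifts[, 2] <- -seq$shifts[, 2]
  }
  if (stats::runif(1) < 0.5) {                     # transpose x/y
    seq$volumes <- aperm(seq$volumes, c(2, 1, 3, 4))
    seq$shifts[, 1:2] <- seq$shifts[, 2:1]
  }
  seq
}

#' @rdname distort_volume
#' @param seq an `oct_sequence`; every volume is distorted independently.
#' @export
distort_sequence <- function(seq, p_dist, shift_px = 1L) {
  stopifnot(inherits(seq, "oct_sequence"))
  for (i in seq_len(dim(seq$volumes)[4]))
    seq$volumes[, , , i] <- distort_volume(seq$volumes[, , , i], p_dist, shift_px)
  seq
}
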