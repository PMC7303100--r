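#' Default OCT field of view, in voxels and millimetres
#'
#' The simulated scanner acquires volumes of 32 x 32 x 32 voxels covering a
#' field of view of approximately 5 mm x 5 mm x 3.5 mm, so one voxel spans
#' (5/32, 5/32, 3.5/32) mm along (x lateral, y lateral, z axial).
#'
#' @return For [fov_voxels()], an integer 3-vector of voxels per axis; for
#'   [fov_mm()], the physical extent in mm; for [fov_pitch_mm()], the
#'   per-axis voxel pitch in mm.
#' @export
fov_voxels <- function() c(32L, 32L, 32L)

#' @rdname fov_voxels
#' @export
fov_mm <- function() c(5, 5, 3.5)

#' @rdname fov_voxels
#' @export
fov_pitch_mm <- function() fov_mm() / fov_voxels()

#' Calibration between stepper-motor space and image space
#'
#' Labels are generated in motor-step space and converted to millimetres by a
#' simple linear calibration, mirroring the galvo/stepper acquisition rig.
#' The default maps 1000 steps to 1 mm on every axis.
#'
#' @param mm_per_voxel per-axis physical voxel size in mm.
#' @param motor_steps_per_mm per-axis linear motor scaling, steps per mm.
#' @return An object of class `oct_calibration`.
#' @export
make_calibration <- function(mm_per_voxel = fov_pitch_mm(),
                             motor_steps_per_mm = c(1000, 1000, 1000)) {
  stopifnot(length(mm_per_voxel) == 3, length(motor_steps_per_mm) == 3)
  if (any(mm_per_voxel <= 0) || any(motor_steps_per_mm <= 0))
    stop("calibration entries must be strictly positive")
  structure(list(mm_per_voxel = as.numeric(mm_per_voxel),
                 motor_steps_per_mm = as.numeric(motor_steps_per_mm)),
            class = "oct_calibration")
}

#' Convert between millimetres and motor steps
#'
#' @param x numeric 3-vector or n x 3 matrix of shifts.
#' @param calibration an `oct_calibration`.
#' @return The converted shifts, same shape as `x`.
#' @export
mm_to_steps <- function(x, calibration = make_calibration()) {
  scale_axes(x, calibration$motor_steps_per_mm)
}

#' @rdname mm_to_steps
#' @export
steps_to_mm <- function(x, calibration = make_calibration()) {
  scale_axes(x, 1 / calibration$motor_steps_per_mm)
}

scale_axes <- function(x, s) {
  if (is.matrix(x)) sweep(x, 2, s, `*`) else x * s
}

default_texture_params <- function() {
  list(
    surface_depth_frac = 0.25,   # mean tissue surface depth, fraction of axial FOV span
    surface_amp_mm     = 0.45,   # std of the smooth surface height variation
    surface_smooth_mm  = 0.8,    # lateral correlation length of the surface
    attenuation_per_mm = 0.6,    # exponential depth attenuation below the surface
    hetero_sigma       = 0.5,    # log-amplitude std of coarse scattering heterogeneity
    hetero_scale_mm    = 0.9,    # correlation length of the heterogeneity (fibres/fascia)
    speckle_sigma      = 0.7,    # log-amplitude std of the multiplicative speckle
    speckle_grain_mm   = 0.16,   # speckle correlation length (~one resolution cell)
    background         = 0.04    # residual amplitude above the surface
  )
}

#' Generate a speckle-textured tissue phantom
#'
#' Builds the master scatter-amplitude grid from which shifted fields of view
#' are sampled. The texture combines a smooth random top surface, exponential
#' attenuation with depth below it, and band-limited log-normal multiplicative
#' speckle, giving the locally distinctive structure that volume-to-volume
#' correspondence needs. Amplitudes are normalised to [0, 1].
#'
#' @param seed integer seed; phantoms are bit-reproducible for a fixed seed.
#' @param grid_size voxels per axis; at least 3 x the 32-voxel FOV (>= 96).
#' @param texture_params list overriding entries of the default texture
#'   parameters (see Details). Units are mm where applicable.
#' @details Texture parameters: `surface_depth_frac` (mean surface depth as a
#'   fraction of the axial extent), `surface_amp_mm` and `surface_smooth_mm`
#'   (height std and lateral correlation length of the surface),
#'   `attenuation_per_mm` (exponential decay below the surface),
#'   `hetero_sigma` and `hetero_scale_mm` (log-amplitude std and correlation
#'   length of coarse scattering heterogeneity, emulating fibrous tissue
#'   structure), `speckle_sigma` and `speckle_grain_mm` (log-amplitude std and
#'   correlation length of the speckle), `background` (amplitude above the
#'   surface).
#' @return An object of class `oct_phantom` with fields `grid` (3D array),
#'   `pitch_mm`, `origin_mm`, `seed`, `texture_params`.
#' @export
make_phantom <- function(seed, grid_size = c(96, 96, 96),
                         texture_params = list()) {
  grid_size <- as.integer(grid_size)
  stopifnot(length(grid_size) == 3)
  if (any(grid_size < 96))
    stop("grid_size must be at least 96 voxels (3x FOV) per axis")
  tp <- utils::modifyList(default_texture_params(), texture_params)
  pitch <- fov_pitch_mm()

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  nx <- grid_size[1]; ny <- grid_size[2]; nz <- grid_size[3]
  depth_mm <- nz * pitch[3]

  # smooth random surface height (mm below the top of the grid)
  h <- matrix(stats::rnorm(nx * ny), nx, ny)
  h <- gauss_smooth_fft(h, tp$surface_smooth_mm / pitch[1:2])
  h <- h / max(stats::sd(h), 1e-12)
  h <- tp$surface_depth_frac * depth_mm + tp$surface_amp_mm * h

  # depth profile: background above the surface, attenuated scattering below
  z_mm <- (seq_len(nz) - 1) * pitch[3]
  zmat <- matrix(z_mm, nx * ny, nz, byrow = TRUE)
  rel <- zmat - as.vector(h)           # depth below the local surface
  amp <- ifelse(rel < 0, tp$background, exp(-tp$attenuation_per_mm * rel))
  amp <- array(amp, grid_size)

  # coarse multiplicative scattering heterogeneity (fibres, fascia): gives the
  # tissue landmarks that survive downsampling, unlike single-cell speckle
  if (tp$hetero_sigma > 0) {
    gh <- array(stats::rnorm(nx * ny * nz), grid_size)
    gh <- gauss_smooth_fft(gh, tp$hetero_scale_mm / pitch)
    gh <- gh / max(stats::sd(gh), 1e-12)
    amp <- amp * exp(tp$hetero_sigma * gh - tp$hetero_sigma^2 / 2)
  }

  # band-limited multiplicative speckle (log-normal, unit mean)
  if (tp$speckle_sigma > 0) {
    g <- array(stats::rnorm(nx * ny * nz), grid_size)
    g <- gauss_smooth_fft(g, tp$speckle_grain_mm / pitch)
    g <- g / max(stats::sd(g), 1e-12)
    amp <- amp * exp(tp$speckle_sigma * g - tp$speckle_sigma^2 / 2)
  }
  amp <- array(amp, grid_size)
  amp <- amp / max(amp)

  structure(list(grid = amp, pitch_mm = pitch, origin_mm = c(0, 0, 0),
                 seed = as.integer(seed), texture_params = tp),
            class = "oct_phantom")
}

#' @export
print.oct_phantom <- function(x, ...) {
  cat(sprintf("<oct_phantom> %s voxels, pitch (%.4f, %.4f, %.4f) mm, seed %d\n",
              paste(dim(x$grid), collapse = " x "),
              x$pitch_mm[1], x$pitch_mm[2], x$pitch_mm[3], x$seed))
  invisible(x)
}

# Gaussian smoothing with periodic boundaries via FFT; sigma in voxels per axis.
gauss_smooth_fft <- function(a, sigma) {
  d <- dim(a)
  sigma <- rep_len(sigma, length(d))
  f <- stats::fft(a)
  for (k in seq_along(d)) {
    n <- d[k]
    freq <- (seq_len(n) - 1) / n
    freq[freq > 0.5] <- freq[freq > 0.5] - 1
    tr <- exp(-2 * pi^2 * sigma[k]^2 * freq^2)
    inner <- if (k == 1) 1 else prod(d[seq_len(k - 1)])
    f <- f * array(rep(tr, each = inner), d)   # recycles over trailing axes
  }
  Re(stats::fft(f, inverse = TRUE)) / prod(d)
}

#' Acquire a 32^3 volume at a sub-voxel FOV shift
#'
#' Crops the field of view from the phantom at the reference position (grid
#' centre, addressed by the crop's minimum corner) displaced by `shift_mm`,
#' resampling with trilinear interpolation for sub-voxel shifts. Positive
#' shifts move the FOV in positive world coordinates.
#'
#' @param phantom an `oct_phantom`.
#' @param shift_mm numeric 3-vector, FOV displacement in mm.
#' @param calibration an `oct_calibration`; its `mm_per_voxel` must match the
#'   phantom pitch.
#' @return A 32 x 32 x 32 array in [0, 1] with attribute `shift_mm`.
#' @export
acquire_volume <- function(phantom, shift_mm, calibration = make_calibration()) {
  stopifnot(inherits(phantom, "oct_phantom"), length(shift_mm) == 3)
  if (max(abs(calibration$mm_per_voxel - phantom$pitch_mm)) > 1e-9)
    stop("calibration voxel pitch does not match the phantom pitch")
  fov <- fov_voxels()
  gd <- dim(phantom$grid)
  ref <- floor((gd - fov) / 2)                      # 0-based minimum corner
  corner <- ref + shift_mm / phantom$pitch_mm       # fractional, 0-based
  eps <- 1e-9
  if (any(corner < -eps) || any(corner + fov - 1 > gd - 1 + eps))
    stop(sprintf(
      "shifted FOV outside phantom: shift (%.3f, %.3f, %.3f) mm exceeds the margin",
      shift_mm[1], shift_mm[2], shift_mm[3]))
  corner <- pmin(pmax(corner, 0), gd - fov)
  i0 <- floor(corner + eps)
  fr <- pmin(pmax(corner - i0, 0), 1)
  i0 <- as.integer(i0)

  out <- array(0, fov)
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- prod(ifelse(c(dx, dy, dz) == 1, fr, 1 - fr))
    if (w == 0) next
    ix <- i0 + c(dx, dy, dz)
    out <- out + w * phantom$grid[ix[1] + 1:fov[1], ix[2] + 1:fov[2],
                                  ix[3] + 1:fov[3], drop = FALSE]
  }
  attr(out, "shift_mm") <- as.numeric(shift_mm)
  out
}

#' Export a volume as a 32-slice multipage TIFF
#'
#' Writes one page per depth slice (z), 32-bit float, for visual inspection in
#' standard image viewers.
#'
#' @param volume a 32^3 array with values in [0, 1].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
export_volume_tiff <- function(volume, path) {
  stopifnot(length(dim(volume)) == 3)
  pages <- lapply(seq_len(dim(volume)[3]), function(z) volume[, , z])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  invisible(path)
}

# Save/restore the global RNG state so generators are pure in `seed`.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
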