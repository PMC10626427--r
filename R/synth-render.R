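## Gaussian-blob rendering of helical filament and microtubule lattices.
##
## All physical coordinates here are Angstrom, with the box corner (voxel
## 0,0,0) at the origin. Blob amplitudes are 1 at the center, so a blob's
## integrated mass is (2*pi)^(3/2) * sigma^3.

# Accumulate isotropic Gaussian blobs into a 3D array. centers: n x 3 (A),
# sigma/amp: scalars or length-n. Each blob only touches +-4 sigma.
.add_blobs3d <- function(grid, apix, centers, sigma, amp = 1) {
  d <- dim(grid)
  n <- nrow(centers)
  sigma <- rep_len(sigma, n)
  amp <- rep_len(amp, n)
  for (i in seq_len(n)) {
    cv <- centers[i, ] / apix            # voxel units, 0-based
    sv <- max(sigma[i] / apix, 0.85)     # blobs below the voxel scale alias
    r <- ceiling(4 * sv)
    ix <- max(0L, floor(cv[1] - r)):min(d[1] - 1L, ceiling(cv[1] + r))
    iy <- max(0L, floor(cv[2] - r)):min(d[2] - 1L, ceiling(cv[2] + r))
    iz <- max(0L, floor(cv[3] - r)):min(d[3] - 1L, ceiling(cv[3] + r))
    if (!length(ix) || !length(iy) || !length(iz)) next
    gx <- exp(-((ix - cv[1])^2) / (2 * sv^2))
    gy <- exp(-((iy - cv[2])^2) / (2 * sv^2))
    gz <- exp(-((iz - cv[3])^2) / (2 * sv^2))
    blob <- amp[i] * (gx %o% gy %o% gz)
    grid[ix + 1L, iy + 1L, iz + 1L] <- grid[ix + 1L, iy + 1L, iz + 1L] + blob
  }
  grid
}

# 2D projection rendering: projecting a 3D Gaussian along x gives a 2D
# Gaussian at (y, z) with amplitude amp * sigma * sqrt(2*pi) (in A, then
# divided by apix to express the projection integral per pixel).
.add_blobs2d <- function(img, apix, centers_yz, sigma, amp = 1) {
  d <- dim(img)
  n <- nrow(centers_yz)
  sigma <- rep_len(sigma, n)
  amp <- rep_len(amp, n)
  for (i in seq_len(n)) {
    cv <- centers_yz[i, ] / apix
    sv <- max(sigma[i] / apix, 0.85)     # blobs below the voxel scale alias
    a2 <- amp[i] * sigma[i] * sqrt(2 * pi) / apix
    r <- ceiling(4 * sv)
    iy <- max(0L, floor(cv[1] - r)):min(d[1] - 1L, ceiling(cv[1] + r))
    iz <- max(0L, floor(cv[2] - r)):min(d[2] - 1L, ceiling(cv[2] + r))
    if (!length(iy) || !length(iz)) next
    gy <- exp(-((iy - cv[1])^2) / (2 * sv^2))
    gz <- exp(-((iz - cv[2])^2) / (2 * sv^2))
    img[iy + 1L, iz + 1L] <- img[iy + 1L, iz + 1L] + a2 * (gy %o% gz)
  }
  img
}

# Blob centers/sigmas/amplitudes for one filament morphology, as a lattice
# of subunits along z through the given axis origin. Returns a list of
# matrices/vectors ready for .add_blobs3d (coordinates in A).
#
# Blob model: each actin subunit is a broad envelope (sigma 25 A) plus a
# compact core (sigma 10 A) at radius 25 A — a single smooth envelope at
# this spacing would erase the lattice periodicity entirely (the 1/rise
# frequency is attenuated by exp(-(2*pi*sigma/rise)^2/2)), while real
# subunits have internal contrast. Cofilin decoration: envelope sigma 15 A
# plus core sigma 8 A at radius 45 A on the subunit azimuth. Plain rod:
# envelope-only blobs on the axis (helically featureless). A small axial
# polarity marker (half-amplitude blob offset +8 A along the axis) makes
# the lattice polar when requested.
.filament_blobs <- function(sym, n_subunits, morphology, phase0 = 0,
                            polar_marker = FALSE, radius = 25) {
  if (morphology == "rod") {
    z <- (seq_len(n_subunits) - 1L) * sym$rise_ang
    centers <- cbind(0, 0, z)
    sigma <- rep(25, n_subunits)
    amp <- rep(1, n_subunits)
  } else {
    lat <- build_subunit_lattice(sym, n_subunits, radius = radius,
                                 phase0 = phase0)
    sub <- as.matrix(lat[, c("x", "y", "z")])
    centers <- rbind(sub, sub)
    sigma <- c(rep(25, n_subunits), rep(10, n_subunits))
    amp <- rep(1, 2L * n_subunits)
    if (morphology == "cofilactin") {
      th <- lat$azimuth_deg * pi / 180
      cof <- cbind(45 * cos(th), 45 * sin(th), lat$z)
      centers <- rbind(centers, cof, cof)
      sigma <- c(sigma, rep(15, n_subunits), rep(8, n_subunits))
      amp <- c(amp, rep(1, 2L * n_subunits))
    }
  }
  if (polar_marker) {
    mk <- centers[seq_len(n_subunits), , drop = FALSE]
    mk[, 3] <- mk[, 3] + 8
    centers <- rbind(centers, mk)
    sigma <- c(sigma, rep(15, n_subunits))
    amp <- c(amp, rep(0.5, n_subunits))
  }
  list(centers = centers, sigma = sigma, amp = amp)
}

#' Render a synthetic helical filament density
#'
#' Builds a noiseless density volume of a single filament along the z axis
#' through the box center, as a lattice of Gaussian subunit blobs with the
#' requested helical symmetry. Morphologies: `"cofilactin"` (actin blobs at
#' 25 A radius plus cofilin decoration blobs at 45 A — decoration widens
#' the filament, as cofilin does), `"factin"` (bare actin lattice) and
#' `"rod"` (straight undecorated rod, apolar and helically featureless).
#'
#' @param sym [helical_symmetry()]; ignored for `"rod"` except for the rise.
#' @param box Box side(s) in voxels: scalar for a cube or length-3 vector.
#' @param apix Voxel size, Angstrom.
#' @param morphology Filament type (see above).
#' @param phase0 Azimuth of subunit 0, degrees.
#' @param polar_marker Add an axial asymmetry (offset half-amplitude blob)
#'   so the lattice is polar.
#' @param radius Subunit-center radius, Angstrom (actin: 25).
#' @param n_subunits Number of subunits; by default as many as fill the
#'   box along z.
#' @return A [density_volume()].
#' @export
render_helical_filament <- function(sym, box = 64, apix = 5.9,
                                    morphology = c("cofilactin", "factin", "rod"),
                                    phase0 = 0, polar_marker = FALSE,
                                    radius = 25, n_subunits = NULL) {
  morphology <- match.arg(morphology)
  box <- rep_len(as.integer(box), 3L)
  zlen <- box[3] * apix
  n_sub <- if (is.null(n_subunits)) max(1L, floor(zlen / sym$rise_ang) + 1L)
           else as.integer(n_subunits)
  b <- .filament_blobs(sym, n_sub, morphology, phase0 = phase0,
                       polar_marker = polar_marker, radius = radius)
  # center the lattice: axis through box center in x/y, fill z
  ctr <- c((box[1] - 1) / 2, (box[2] - 1) / 2, 0) * apix
  z0 <- (zlen - (n_sub - 1L) * sym$rise_ang) / 2
  b$centers <- sweep(b$centers, 2, c(ctr[1], ctr[2], z0), "+")
  grid <- .add_blobs3d(array(0, box), apix, b$centers, b$sigma, b$amp)
  density_volume(grid, apix)
}

#' Render a synthetic microtubule density
#'
#' N protofilaments of tubulin blobs (sigma 20 A) at center radius
#' `N * 50 / (2*pi)` A (50 A lateral spacing), monomer spacing 40.95 A
#' along each protofilament, and an inter-protofilament axial stagger of
#' `3 * 40.95 / N` A (a 3-start approximation of the microtubule lattice;
#' the seam is omitted). This reproduces the N-dependent diameter and
#' moire pattern that protofilament-number classification relies on.
#' Polarity `"minus"` mirrors the lattice through the axial midplane.
#'
#' @param n_pf Protofilament number, one of 12, 13, 14, 15.
#' @param box Box side(s) in voxels.
#' @param apix Voxel size, Angstrom.
#' @param polarity `"plus"` or `"minus"`.
#' @param polar_marker Add the axial asymmetry marker to each monomer.
#' @return A [density_volume()].
#' @export
render_microtubule <- function(n_pf = 13, box = 64, apix = 11.81,
                               polarity = c("plus", "minus"),
                               polar_marker = TRUE) {
  polarity <- match.arg(polarity)
  if (!n_pf %in% 12:15) stop("n_pf must be one of 12, 13, 14, 15")
  box <- rep_len(as.integer(box), 3L)
  mono <- 40.95
  r_mt <- n_pf * 50 / (2 * pi)
  zlen <- box[3] * apix
  n_mono <- max(1L, floor(zlen / mono))
  centers <- NULL
  for (j in seq_len(n_pf) - 1L) {
    th <- 2 * pi * j / n_pf
    z <- (seq_len(n_mono) - 1L) * mono + j * 3 * mono / n_pf
    centers <- rbind(centers,
                     cbind(r_mt * cos(th), r_mt * sin(th), z))
  }
  sigma <- rep(20, nrow(centers))
  amp <- rep(1, nrow(centers))
  if (polar_marker) {
    mk <- centers
    mk[, 3] <- mk[, 3] + 8
    centers <- rbind(centers, mk)
    sigma <- c(sigma, rep(12, nrow(mk)))
    amp <- c(amp, rep(0.5, nrow(mk)))
  }
  if (polarity == "minus") {   # 180-deg rotation about x through the midplane
    centers[, 2] <- -centers[, 2]
    centers[, 3] <- zlen - centers[, 3]
  }
  ctr <- c((box[1] - 1) / 2, (box[2] - 1) / 2, 0) * apix
  centers[, 1] <- centers[, 1] + ctr[1]
  centers[, 2] <- centers[, 2] + ctr[2]
  grid <- .add_blobs3d(array(0, box), apix, centers, sigma, amp)
  density_volume(grid, apix)
}

#' Add white Gaussian noise to a volume
#'
#' Noise standard deviation is `noise_sigma` times the volume's peak value
#' (so `noise_sigma` is a fraction of signal peak). Uses R's RNG stream;
#' set a seed first for reproducibility.
#'
#' @param vol A [density_volume()].
#' @param noise_sigma Fraction of the signal peak.
#' @return A noisy [density_volume()].
#' @export
add_noise <- function(vol, noise_sigma) {
  stopifnot(inherits(vol, "density_volume"))
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (noise_sigma == 0) return(vol)
  peak <- max(abs(vol$grid))
  if (peak == 0) peak <- 1
  vol$grid <- vol$grid + array(stats::rnorm(length(vol$grid),
                                            sd = noise_sigma * peak),
                               dim(vol$grid))
  vol
}

#' Apply a missing-wedge filter to a volume
#'
#' Emulates the anisotropic information loss of single-axis tomography with
#' a limited tilt range: in Fourier space, all frequencies whose angle from
#' the x-y plane (measured in the x-z plane, tilt axis y) exceeds
#' `wedge_halfangle` are zeroed. The mask depends only on |kx| and |kz|, so
#' it is Hermitian-symmetric and the filtered volume stays real.
#'
#' @param vol A [density_volume()].
#' @param wedge_halfangle Half-angle in degrees, in (0, 90]; the tilt range
#'   of the emulated acquisition (default +-60 degrees).
#' @return Filtered [density_volume()].
#' @export
apply_missing_wedge <- function(vol, wedge_halfangle = 60) {
  stopifnot(inherits(vol, "density_volume"))
  if (!(wedge_halfangle > 0 && wedge_halfangle <= 90))
    stop("wedge_halfangle must lie in (0, 90]")
  if (wedge_halfangle == 90) return(vol)
  d <- dim(vol$grid)
  freq_idx <- function(n) { k <- 0:(n - 1); ifelse(k > n / 2, k - n, k) }
  kx <- freq_idx(d[1]) / d[1]
  kz <- freq_idx(d[3]) / d[3]
  tanw <- tan(wedge_halfangle * pi / 180)
  # keep where |kz| <= tan(wedge) * |kx| (plus the kx = kz = 0 line)
  keep_xz <- outer(abs(kx), abs(kz), function(x, z) z <= tanw * x | (z == 0))
  ft <- stats::fft(vol$grid)
  mask <- array(0, d)
  for (iy in seq_len(d[2])) mask[, iy, ] <- keep_xz
  vol$grid <- Re(stats::fft(ft * mask, inverse = TRUE)) / prod(d)
  vol
}
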