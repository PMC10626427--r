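#' Cylindrical Gaussian mask
#'
#' Soft cylinder along a box axis through the box center: 1 inside radius
#' `diameter/2`, Gaussian falloff outside with sigma = radius/4.
#'
#' @param dims Box dimensions (voxels), length 3.
#' @param apix Voxel size, Angstrom.
#' @param diameter Cylinder diameter, Angstrom (the cross-over protocol
#'   uses ~280 A = 28 nm).
#' @param axis Cylinder axis: `"x"`, `"y"` or `"z"`.
#' @return A [density_volume()] holding the mask (values in [0, 1]).
#' @export
cylindrical_gaussian_mask <- function(dims, apix, diameter, axis = "z") {
  dims <- rep_len(as.integer(dims), 3L)
  if (!(diameter > 0)) stop("diameter must be > 0")
  ax <- match(axis, c("x", "y", "z"))
  perp <- setdiff(1:3, ax)
  if (diameter / 2 > min(dims[perp]) * apix / 2)
    stop("mask diameter exceeds the box extent")
  r0 <- diameter / 2
  sg <- r0 / 4
  cc <- (dims - 1) / 2
  u <- (seq_len(dims[perp[1]]) - 1 - cc[perp[1]]) * apix
  v <- (seq_len(dims[perp[2]]) - 1 - cc[perp[2]]) * apix
  r <- sqrt(outer(u^2, v^2, "+"))
  m2 <- ifelse(r <= r0, 1, exp(-(r - r0)^2 / (2 * sg^2)))
  g <- array(rep(m2, dims[ax]), c(dims[perp[1]], dims[perp[2]], dims[ax]))
  density_volume(aperm(g, order(c(perp, ax))), apix)
}

#' Project a volume along an axis
#'
#' @param vol A [density_volume()].
#' @param along Axis to sum over (`"x"`, `"y"` or `"z"`).
#' @return 2D matrix (the remaining two axes, in x<y<z order).
#' @export
project_volume <- function(vol, along = "x") {
  ax <- match(along, c("x", "y", "z"))
  apply(vol$grid, setdiff(1:3, ax), sum)
}

# fftshift for a 2D matrix
.fftshift2 <- function(m) {
  d <- dim(m)
  s1 <- c(((d[1] %/% 2) + 1):d[1], 1:(d[1] %/% 2))
  s2 <- c(((d[2] %/% 2) + 1):d[2], 1:(d[2] %/% 2))
  m[s1, s2]
}

# Center-preserving 2x binning of a shifted power spectrum: binned pixel at
# offset L from the spectrum center covers original offset 2L with (1/4,
# 1/2, 1/4) weights over {2L-1, 2L, 2L+1}. Keeping the DC term at a bin
# center makes the conversion c = box * pixel / L exact on the binned grid.
.bin2_centered <- function(m, bin_to) {
  n <- nrow(m)
  ctr <- n / 2 + 1
  off <- (seq_len(bin_to)) - (bin_to / 2 + 1)
  i0 <- ctr + 2 * off
  cl <- function(i) pmin(pmax(i, 1L), n)
  bin1 <- 0.25 * m[cl(i0 - 1), ] + 0.5 * m[cl(i0), ] + 0.25 * m[cl(i0 + 1), ]
  0.25 * bin1[, cl(i0 - 1)] + 0.5 * bin1[, cl(i0)] + 0.25 * bin1[, cl(i0 + 1)]
}

#' Measure a filament's cross-over distance from its layer line
#'
#' Reproduces the Fourier protocol for cross-over measurement: the volume
#' is masked with a cylindrical Gaussian mask around the filament, a
#' side-view projection is formed (summing along a viewing axis
#' perpendicular to the filament axis), the projection is embedded in an
#' `fft_box`-sized frame and its power spectrum is binned 2x to `bin_to`
#' pixels. The layer line is the strongest off-equator peak of the
#' near-meridian axial-frequency profile (averaged over a +-3 pixel band
#' in the equatorial direction), and the cross-over distance follows from
#' the conversion `c = box size x pixel size / layer-line distance`.
#'
#' @param vol A [density_volume()] containing one filament along `axis`.
#' @param axis Filament axis (`"z"` default).
#' @param diameter Mask diameter, Angstrom (default 280 A = 28 nm).
#' @param fft_box Fourier box size before binning (pixels).
#' @param bin_to Box size after 2x binning (pixels).
#' @param search_band Axial-frequency range (binned pixels from the
#'   equator) searched for the layer line.
#' @param eq_band Half-width (binned pixels from the meridian) of the
#'   equatorial band the layer line is averaged over; the order-2 layer
#'   line of an actin-like filament peaks well off the meridian.
#' @param mask Apply the cylindrical mask (disable if pre-masked).
#' @return List of class `crossover_measurement`: `crossover_nm`,
#'   `L_pixels`, `box`, `pixel_nm`, and the band `profile`.
#' @export
measure_crossover <- function(vol, axis = "z", diameter = 280,
                              fft_box = 512L, bin_to = 256L,
                              search_band = c(3L, 40L), eq_band = 48L,
                              mask = TRUE) {
  stopifnot(inherits(vol, "density_volume"))
  if (mask) {
    mk <- cylindrical_gaussian_mask(dim(vol$grid), vol$apix, diameter, axis = axis)
    vol$grid <- vol$grid * mk$grid
  }
  proj_axis <- switch(axis, z = "x", y = "z", x = "y")
  img <- project_volume(vol, along = proj_axis)
  # orient so that columns run along the filament axis
  if (axis == "x") img <- t(img)
  d <- dim(img)
  if (any(d > fft_box)) stop("projection larger than fft_box")
  frame <- matrix(0, fft_box, fft_box)
  o1 <- (fft_box - d[1]) %/% 2
  o2 <- (fft_box - d[2]) %/% 2
  frame[o1 + seq_len(d[1]), o2 + seq_len(d[2])] <- img - mean(img)
  ps <- Mod(stats::fft(frame))^2
  ps <- .fftshift2(ps)
  hp <- ps[c(2:fft_box, 1), c(2:fft_box, 1)]    # reflect about the center
  ps <- (ps + hp[rev(seq_len(fft_box)), rev(seq_len(fft_box))]) / 2
  ps <- .bin2_centered(ps, bin_to)              # bin_to x bin_to
  ctr <- bin_to / 2 + 1                         # equator/meridian pixel
  # the cross-over layer line of a two-start-appearing helix carries Bessel
  # order 2 and peaks off the meridian, so average over a wide equatorial
  # band rather than the meridian alone
  band_rows <- max(1, ctr - eq_band):min(bin_to, ctr + eq_band)
  profile <- colMeans(ps[band_rows, ])          # axial-frequency profile
  Ls <- search_band[1]:search_band[2]
  vals <- profile[ctr + Ls]
  ipk <- which.max(vals)
  L <- Ls[ipk]
  bg <- stats::median(vals[abs(Ls - L) > 2])
  if (!is.finite(bg) || vals[ipk] < 3 * bg)
    stop("no layer line: no peak above 3x local background in band")
  pixel_nm <- vol$apix / 10
  out <- list(crossover_nm = bin_to * pixel_nm / L, L_pixels = L,
              box = bin_to, pixel_nm = pixel_nm,
              profile = stats::setNames(vals, Ls))
  class(out) <- "crossover_measurement"
  out
}

#' @export
print.crossover_measurement <- function(x, ...) {
  cat(sprintf("cross-over: %.2f nm (layer line at %d px; c = %d x %.4f / %d)\n",
              x$crossover_nm, x$L_pixels, x$box, x$pixel_nm, x$L_pixels))
  invisible(x)
}

## ---- helical symmetry scoring ----------------------------------------------


# Precompute the cylindrical support of a map: integer voxels (1-based)
# within outer_radius of the z axis through the box center. A small inner
# radius (2.5 voxels) is excluded: voxels that close to the axis barely
# move under the trial rotation, so on noisy maps their noise correlates
# with itself through the interpolation kernel and biases the score
# toward rotation-only (small-rise) transforms.
.cyl_support <- function(dims, apix, outer_diameter, inner_voxels = 2.5) {
  cx <- (dims[1] - 1) / 2; cy <- (dims[2] - 1) / 2
  xs <- (seq_len(dims[1]) - 1) - cx
  ys <- (seq_len(dims[2]) - 1) - cy
  r2 <- outer(xs^2, ys^2, "+")
  keep <- which(r2 <= (outer_diameter / 2 / apix)^2 & r2 > inner_voxels^2,
                arr.ind = TRUE)
  if (nrow(keep) == 0L) stop("empty cylindrical support")
  list(ix = keep[, 1], iy = keep[, 2],
       x = xs[keep[, 1]], y = ys[keep[, 2]], cx = cx, cy = cy)
}

# Catmull-Rom cubic-convolution weights for fractional offset t in [0, 1)
# over the 4 taps at offsets -1, 0, 1, 2. Cubic interpolation has a much
# flatter transfer function in t than linear, which matters here: the
# symmetry contrast of smooth filament maps is shallow and linear
# interpolation's t-dependent attenuation biases the score optimum.
.cubic_w <- function(t) {
  list(wm1 = -0.5 * t + t^2 - 0.5 * t^3,
       w0  = 1 - 2.5 * t^2 + 1.5 * t^3,
       w1  = 0.5 * t + 2 * t^2 - 1.5 * t^3,
       w2  = -0.5 * t^2 + 0.5 * t^3)
}

# Resample all z-slices of a map at xy points rotated by twist_deg about
# the central z axis (bicubic). Returns npts x nz matrix.
.rotated_slices <- function(V2d, dims, sup, twist_deg) {
  th <- twist_deg * pi / 180
  xr <- cos(th) * sup$x - sin(th) * sup$y + sup$cx
  yr <- sin(th) * sup$x + cos(th) * sup$y + sup$cy
  ix0 <- pmin(pmax(floor(xr), 1), dims[1] - 3)
  iy0 <- pmin(pmax(floor(yr), 1), dims[2] - 3)
  wx <- .cubic_w(xr - ix0)
  wy <- .cubic_w(yr - iy0)
  wxl <- list(wx$wm1, wx$w0, wx$w1, wx$w2)
  wyl <- list(wy$wm1, wy$w0, wy$w1, wy$w2)
  out <- 0
  for (a in 1:4) for (b in 1:4) {
    idx <- (ix0 + a - 2L) + 1L + (iy0 + b - 2L) * dims[1]
    out <- out + (wxl[[a]] * wyl[[b]]) * V2d[idx, , drop = FALSE]
  }
  out
}

# Symmetry-scoring engine. Numerical design, dictated by how shallow the
# symmetry contrast of smooth filament maps is:
#   - the map is cosine-tapered at its z ends so it is effectively
#     z-periodic, and the rise translation is then applied EXACTLY as a
#     Fourier phase ramp (the Gaussian-blob maps are bandlimited, so the
#     circular shift is exact) — fractional-voxel interpolation along z
#     would otherwise bias the rise optimum by several tenths of an
#     Angstrom;
#   - the twist rotation is split symmetrically (+twist/2 on one copy,
#     -twist/2 on the other, bicubic resampling) so both copies suffer
#     identical in-plane interpolation attenuation and it cancels from
#     the normalized correlation;
#   - the Pearson correlation runs over a fixed central z window
#     (excluding the taper and the largest shift) so the support does not
#     change with the trial rise.
# Returns a function (twists, rises) -> score matrix.
.sym_engine <- function(map, outer_diameter, rise_max, ntaper = 3L,
                        lowpass = NULL) {
  d <- dim(map$grid)
  nz <- d[3]
  grid <- map$grid
  if (!is.null(lowpass)) {
    # Gaussian lowpass at resolution `lowpass` (A): suppresses the white
    # noise beyond the informative frequencies before scoring
    fi <- function(n) { k <- 0:(n - 1); ifelse(k > n / 2, k - n, k) / n }
    kr2 <- outer(outer(fi(d[1])^2, fi(d[2])^2, "+"), fi(d[3])^2, "+") /
      map$apix^2
    grid <- Re(stats::fft(stats::fft(grid) * exp(-kr2 * lowpass^2 / 2),
                          inverse = TRUE)) / prod(d)
  }
  ramp <- 0.5 * (1 - cos(pi * (seq_len(ntaper) - 0.5) / ntaper))
  wz <- rep(1, nz)
  wz[seq_len(ntaper)] <- ramp
  wz[nz + 1L - seq_len(ntaper)] <- ramp
  grid <- sweep(grid, 3, wz, "*")
  sup <- .cyl_support(d, map$apix, outer_diameter)
  V2d <- matrix(grid, d[1] * d[2], nz)
  maxshift <- ceiling(rise_max / map$apix) + 1L
  zlo <- ntaper + maxshift + 1L
  zhi <- nz - ntaper - maxshift
  if (zhi - zlo < 4L) stop("box too short in z for the requested rise range")
  zwin <- zlo:zhi
  kk <- c(0:(nz / 2), -((nz / 2 - 1):1))           # signed frequencies
  function(twists, rises) {
    s <- matrix(NA_real_, length(twists), length(rises),
                dimnames = list(format(twists), format(rises)))
    for (i in seq_along(twists)) {
      Bp <- .rotated_slices(V2d, d, sup, twists[i] / 2)
      Bm <- .rotated_slices(V2d, d, sup, -twists[i] / 2)
      a <- as.vector(t(Bp)[zwin, , drop = FALSE])
      FBm <- stats::mvfft(t(Bm))                   # nz x npts, FFT along z
      for (j in seq_along(rises)) {
        sh <- -rises[j] / map$apix                 # compare B+(z) vs B-(z - rise)
        ph <- exp(2i * pi * kk * sh / nz)
        ph[nz / 2 + 1L] <- cos(pi * sh)            # real Nyquist term
        Am <- Re(stats::mvfft(FBm * ph, inverse = TRUE)) / nz
        b <- as.vector(Am[zwin, , drop = FALSE])
        s[i, j] <- suppressWarnings(stats::cor(a, b))
      }
    }
    s
  }
}

#' Score a helical symmetry against a density map
#'
#' Real-space Pearson correlation, within a cylinder of `outer_diameter`
#' about the central z axis, between the map and the map rotated by the
#' twist about z and translated by the rise along z (z ends are tapered
#' and excluded from the correlation support together with the shift
#' margin). A perfectly symmetric map scores 1 at its generating
#' parameters; twist 0 / rise 0 is the identity transform and scores 1.
#'
#' @param map A [density_volume()] with the helical axis along z through
#'   the box center.
#' @param sym A [helical_symmetry()] (or a plain list with `twist_deg`,
#'   degrees, and `rise_ang`, Angstrom).
#' @param outer_diameter Cylinder diameter, Angstrom (default 120).
#' @return Correlation in [-1, 1].
#' @export
symmetry_score <- function(map, sym, outer_diameter = 120) {
  stopifnot(inherits(map, "density_volume"))
  engine <- .sym_engine(map, outer_diameter, rise_max = max(abs(sym$rise_ang), 1))
  engine(sym$twist_deg, sym$rise_ang)[1, 1]
}

#' Grid search for helical symmetry parameters
#'
#' Coarse-to-fine search of the (twist, rise) plane maximizing
#' [symmetry_score()]: a coarse grid (default 1 degree x 0.5 A) over the
#' full ranges, then a local refinement (default 0.1 degree x 0.1 A)
#' around the coarse optimum. The search is flagged degenerate when the
#' coarse score surface's dynamic range is below 0.05 (featureless maps,
#' e.g. uniform cylinders, correlate equally under every symmetry).
#'
#' @param map A [density_volume()], helical axis z through the box center.
#' @param twist_range Twist search range, degrees (default -200..-100).
#' @param rise_range Rise search range, Angstrom (default 1..40).
#' @param outer_diameter Cylinder diameter, Angstrom (default 120).
#' @param coarse_step `(twist, rise)` coarse steps (degrees, Angstrom).
#' @param fine_step `(twist, rise)` refinement steps.
#' @param exhaustive Evaluate the full fine grid everywhere (slow; for
#'   oracle comparison on small maps).
#' @param lowpass Optional Gaussian lowpass resolution (Angstrom) applied
#'   to the map before scoring; recommended (~15 A) for noisy maps, where
#'   unfiltered white noise drowns the shallow score contrast.
#' @return Object of class `symmetry_search`: `best`
#'   ([helical_symmetry()]), `best_score`, `surface` (coarse score matrix,
#'   twist x rise), `degenerate` flag and the grid spec.
#' @export
symmetry_grid_search <- function(map, twist_range = c(-200, -100),
                                 rise_range = c(1, 40), outer_diameter = 120,
                                 coarse_step = c(1, 0.5),
                                 fine_step = c(0.1, 0.1),
                                 exhaustive = FALSE, lowpass = NULL) {
  stopifnot(inherits(map, "density_volume"))
  if (twist_range[1] >= twist_range[2] || rise_range[1] >= rise_range[2])
    stop("invalid search ranges")
  eval_grid <- .sym_engine(map, outer_diameter, rise_max = rise_range[2],
                           lowpass = lowpass)
  step <- if (exhaustive) fine_step else coarse_step
  tw <- seq(twist_range[1], twist_range[2], by = step[1])
  ri <- seq(rise_range[1], rise_range[2], by = step[2])
  surf <- eval_grid(tw, ri)
  rng <- range(surf, na.rm = TRUE)
  degenerate <- (rng[2] - rng[1]) < 0.05
  bi <- which(surf == rng[2], arr.ind = TRUE)[1, ]
  best_tw <- tw[bi[1]]; best_ri <- ri[bi[2]]; best_sc <- rng[2]
  if (!exhaustive) {
    ftw <- seq(max(twist_range[1], best_tw - coarse_step[1]),
               min(twist_range[2], best_tw + coarse_step[1]), by = fine_step[1])
    fri <- seq(max(rise_range[1], best_ri - coarse_step[2]),
               min(rise_range[2], best_ri + coarse_step[2]), by = fine_step[2])
    fs <- eval_grid(ftw, fri)
    fb <- which(fs == max(fs, na.rm = TRUE), arr.ind = TRUE)[1, ]
    best_tw <- ftw[fb[1]]; best_ri <- fri[fb[2]]
    best_sc <- max(fs, na.rm = TRUE)
  }
  structure(list(best = helical_symmetry(best_tw, best_ri),
                 best_score = best_sc, surface = surf,
                 degenerate = degenerate,
                 grid = list(twist_range = twist_range,
                             rise_range = rise_range,
                             outer_diameter = outer_diameter,
                             coarse_step = coarse_step,
                             fine_step = fine_step)),
            class = "symmetry_search")
}

#' @export
print.symmetry_search <- function(x, ...) {
  cat(sprintf("helical symmetry search: best twist %.2f deg, rise %.2f A (score %.4f)%s\n",
              x$best$twist_deg, x$best$rise_ang, x$best_score,
              if (x$degenerate) " [DEGENERATE surface]" else ""))
  invisible(x)
}

#' @export
plot.symmetry_search <- function(x, ...) {
  tw <- as.numeric(rownames(x$surface))
  ri <- as.numeric(colnames(x$surface))
  graphics::image(tw, ri, x$surface, xlab = "twist (deg)", ylab = "rise (A)",
                  main = "helical symmetry score surface", ...)
  graphics::points(x$best$twist_deg, x$best$rise_ang, pch = 3)
  invisible(x)
}

## ---- Fourier shell correlation ----------------------------------------------

#' Fourier shell correlation of two half-maps
#'
#' Per-shell normalized cross-correlation of the maps' Fourier
#' coefficients, on unit-width radial shells of the 3D frequency grid.
#'
#' @param half1,half2 [density_volume()] objects of identical shape/apix.
#' @return Data.frame with `shell`, `freq` (1/Angstrom, shell center),
#'   `fsc`, `n_voxels`.
#' @export
fsc_curve <- function(half1, half2) {
  stopifnot(inherits(half1, "density_volume"), inherits(half2, "density_volume"))
  if (!identical(dim(half1$grid), dim(half2$grid)))
    stop("half-map shapes differ")
  if (abs(half1$apix - half2$apix) > 1e-6) stop("half-map voxel sizes differ")
  d <- dim(half1$grid)
  f1 <- stats::fft(half1$grid)
  f2 <- stats::fft(half2$grid)
  freq_idx <- function(n) { k <- 0:(n - 1); ifelse(k > n / 2, k - n, k) / n }
  kx <- freq_idx(d[1]); ky <- freq_idx(d[2]); kz <- freq_idx(d[3])
  kr <- sqrt(outer(outer(kx^2, ky^2, "+"), kz^2, "+"))
  nmax <- floor(min(d) / 2)
  shell <- pmin(as.integer(round(kr * min(d))), nmax)
  num <- Re(tapply(f1 * Conj(f2), shell, sum))
  d1 <- tapply(Mod(f1)^2, shell, sum)
  d2 <- tapply(Mod(f2)^2, shell, sum)
  sh <- as.integer(names(num))
  keep <- sh >= 1 & sh <= nmax
  out <- data.frame(shell = sh[keep],
                    freq = sh[keep] / (min(d) * half1$apix),
                    fsc = num[keep] / sqrt(d1[keep] * d2[keep]),
                    n_voxels = as.integer(table(shell)[keep]),
                    row.names = NULL)
  out[order(out$shell), , drop = FALSE]
}

#' Resolution at an FSC threshold
#'
#' Resolution is 1/frequency at the first crossing of the curve below the
#' threshold, linearly interpolated between shells; `NA` when the curve
#' never crosses (e.g. identical maps).
#'
#' @param half1,half2 Half-maps, or `half1` may be a data.frame from
#'   [fsc_curve()].
#' @param threshold FSC criterion (0.143 by the usual half-map convention).
#' @return List with `resolution_ang` (or `NA`) and the `curve`.
#' @export
fsc_resolution <- function(half1, half2 = NULL, threshold = 0.143) {
  curve <- if (is.data.frame(half1)) half1 else fsc_curve(half1, half2)
  below <- which(curve$fsc < threshold)
  if (length(below) == 0L)
    return(list(resolution_ang = NA_real_, curve = curve))
  i <- below[1]
  if (i == 1L) {
    f <- curve$freq[1]
  } else {
    f0 <- curve$freq[i - 1L]; f1 <- curve$freq[i]
    c0 <- curve$fsc[i - 1L]; c1 <- curve$fsc[i]
    f <- f0 + (c0 - threshold) / (c0 - c1) * (f1 - f0)
  }
  list(resolution_ang = 1 / f, curve = curve)
}
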