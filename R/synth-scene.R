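#' Specify a synthetic cryoET scene
#'
#' A scene is a set of microtubules (each an axis trace in nm, a
#' protofilament number in 12..15 and a polarity) and luminal filaments
#' (each hosted by one microtubule over an axial interval, with a helical
#' symmetry, a polarity and a cofilin-decoration flag), plus a noise level
#' and a missing-wedge half-angle.
#'
#' @param microtubules List of lists with elements `trace`
#'   ([filament_trace()], nm), `n_pf` (12..15) and `polarity`
#'   (`"plus"`/`"minus"`).
#' @param luminal_filaments List of lists with elements `host` (index into
#'   `microtubules`), `start_nm`, `end_nm` (arc interval on the host axis),
#'   `sym` ([helical_symmetry()]), `polarity`, `decorated` (logical:
#'   cofilin decoration) and optional `polar_marker` (logical, default
#'   `TRUE`: render the axial asymmetry that makes the lattice polar).
#' @param noise_sigma Additive white-noise s.d. as a fraction of signal peak.
#' @param wedge_halfangle Missing-wedge half-angle, degrees (default 60).
#' @param seed Integer RNG seed used by [render_scene()].
#' @return Object of class `scene_spec`.
#' @export
scene_spec <- function(microtubules = list(), luminal_filaments = list(),
                       noise_sigma = 0, wedge_halfangle = 60, seed = 1L) {
  if (!(wedge_halfangle > 0 && wedge_halfangle <= 90))
    stop("wedge_halfangle must lie in (0, 90]")
  for (mt in microtubules) {
    stopifnot(inherits(mt$trace, "filament_trace"))
    if (!mt$n_pf %in% 12:15) stop("n_pf must be one of 12, 13, 14, 15")
    if (!mt$polarity %in% c("plus", "minus")) stop("bad microtubule polarity")
  }
  for (lf in luminal_filaments) {
    if (!(lf$host >= 1 && lf$host <= length(microtubules)))
      stop("luminal filament host index out of range")
    host_len <- contour_length(microtubules[[lf$host]]$trace)
    if (lf$start_nm < 0 || lf$end_nm > host_len || lf$start_nm >= lf$end_nm)
      stop("luminal filament axial extent must lie within its host microtubule")
    stopifnot(inherits(lf$sym, "helical_symmetry"))
    if (!lf$polarity %in% c("plus", "minus")) stop("bad filament polarity")
  }
  structure(list(microtubules = microtubules,
                 luminal_filaments = luminal_filaments,
                 noise_sigma = noise_sigma,
                 wedge_halfangle = wedge_halfangle,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

# Blob centers (A) for a filament lattice laid along a trace (nm), between
# arc lengths start_nm and end_nm. Local blob coordinates (x,y,z in A, z
# along the axis) are carried through parallel-transported frames.
.blobs_along_trace <- function(trace, start_nm, end_nm, local) {
  n <- nrow(local$centers)
  arc_nm <- start_nm + local$centers[, 3] / 10
  rs <- resample_trace(trace, spacing = max(0.5, (end_nm - start_nm) / 200))
  pos <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    a <- min(max(arc_nm[i], 0), max(rs$arc))
    j <- max(1L, findInterval(a, rs$arc))
    j <- min(j, length(rs$arc) - 1L)
    f <- (a - rs$arc[j]) / (rs$arc[j + 1L] - rs$arc[j])
    p <- rs$positions[j, ] + f * (rs$positions[j + 1L, ] - rs$positions[j, ])
    fr <- rs$frames[[j]]
    pos[i, ] <- p * 10 + as.numeric(fr %*% c(local$centers[i, 1],
                                             local$centers[i, 2], 0))
  }
  pos
}

#' Render a synthetic scene into a density volume
#'
#' Sums Gaussian-blob lattices for every microtubule and luminal filament
#' in the scene, then adds white Gaussian noise and applies the
#' missing-wedge filter. Returns the volume together with per-filament
#' ground truth (the inputs every downstream statistic can be checked
#' against).
#'
#' @param spec A [scene_spec()].
#' @param box Box side(s), voxels.
#' @param apix Voxel size, Angstrom.
#' @param margin_voxels Required clearance between any filament point and
#'   the box faces.
#' @return List with `volume` ([density_volume()]), `microtubules` and
#'   `luminal_filaments` ground-truth data.frames.
#' @export
render_scene <- function(spec, box = 64, apix = 11.81, margin_voxels = 2) {
  stopifnot(inherits(spec, "scene_spec"))
  box <- rep_len(as.integer(box), 3L)
  extent <- box * apix / 10  # nm
  for (mt in spec$microtubules) {
    p <- mt$trace$points
    if (any(p < margin_voxels * apix / 10) ||
        any(sweep(p, 2, extent - margin_voxels * apix / 10) > 0))
      stop("filament outside box (needs >= 2 voxel margin)")
  }
  grid <- array(0, box)
  mt_truth <- NULL
  for (i in seq_along(spec$microtubules)) {
    mt <- spec$microtubules[[i]]
    L_nm <- contour_length(mt$trace)
    mono <- 40.95
    r_mt <- mt$n_pf * 50 / (2 * pi)
    n_mono <- max(1L, floor(L_nm * 10 / mono))
    centers <- NULL
    for (j in seq_len(mt$n_pf) - 1L) {
      th <- 2 * pi * j / mt$n_pf
      z <- (seq_len(n_mono) - 1L) * mono + j * 3 * mono / mt$n_pf
      centers <- rbind(centers, cbind(r_mt * cos(th), r_mt * sin(th), z))
    }
    mk <- centers; mk[, 3] <- mk[, 3] + 8
    local <- list(centers = rbind(centers, mk))
    sigma <- c(rep(20, nrow(centers)), rep(12, nrow(mk)))
    amp <- c(rep(1, nrow(centers)), rep(0.5, nrow(mk)))
    if (mt$polarity == "minus") {
      # 180-degree rotation about x through the lattice's axial midplane
      zext <- (n_mono - 1L) * mono + (mt$n_pf - 1L) * 3 * mono / mt$n_pf
      local$centers[, 2] <- -local$centers[, 2]
      local$centers[, 3] <- zext - local$centers[, 3]
    }
    pos <- .blobs_along_trace(mt$trace, 0, L_nm, local)
    grid <- .add_blobs3d(grid, apix, pos, sigma, amp)
    mt_truth <- rbind(mt_truth, data.frame(
      mt_id = i, n_pf = mt$n_pf, polarity = mt$polarity, length_nm = L_nm))
  }
  lf_truth <- NULL
  for (i in seq_along(spec$luminal_filaments)) {
    lf <- spec$luminal_filaments[[i]]
    host <- spec$microtubules[[lf$host]]
    len_ang <- (lf$end_nm - lf$start_nm) * 10
    n_sub <- max(1L, floor(len_ang / lf$sym$rise_ang) + 1L)
    b <- .filament_blobs(lf$sym, n_sub,
                         morphology = if (isTRUE(lf$decorated)) "cofilactin" else "factin",
                         polar_marker = !isFALSE(lf$polar_marker))
    if (lf$polarity == "minus") {
      # mirror about the lattice midplane (extent (n_sub - 1) * rise), with
      # a y-flip so the flip is a proper rotation
      b$centers[, 2] <- -b$centers[, 2]
      b$centers[, 3] <- (n_sub - 1L) * lf$sym$rise_ang - b$centers[, 3]
    }
    pos <- .blobs_along_trace(host$trace, lf$start_nm, lf$end_nm, b)
    grid <- .add_blobs3d(grid, apix, pos, b$sigma, b$amp)
    lf_truth <- rbind(lf_truth, data.frame(
      filament_id = i, host_mt = lf$host,
      start_nm = lf$start_nm, end_nm = lf$end_nm,
      length_nm = lf$end_nm - lf$start_nm,
      twist_deg = lf$sym$twist_deg, rise_ang = lf$sym$rise_ang,
      polarity = lf$polarity, decorated = isTRUE(lf$decorated)))
  }
  vol <- density_volume(grid, apix)
  if (spec$noise_sigma > 0) {
    set.seed(spec$seed)
    vol <- add_noise(vol, spec$noise_sigma)
  }
  if (spec$wedge_halfangle < 90) vol <- apply_missing_wedge(vol, spec$wedge_halfangle)
  list(volume = vol, microtubules = mt_truth, luminal_filaments = lf_truth)
}

#' Simulate a classification-vote particle table
#'
#' Statistical stand-in for multireference subtomogram classification
#' output: each filament draws a true (protofilament-number, polarity)
#' class from `class_fractions`; each of its particles votes the true class
#' with probability `p_correct`, otherwise uniformly among the remaining
#' classes. Cross-correlation scores come from class-conditional normals
#' (truncated at 0) so that correct votes score higher on average.
#'
#' @param n_filaments Number of filaments.
#' @param particles_per_filament Particles per filament (>= 1).
#' @param class_fractions Named probability vector over class labels such
#'   as `"13:plus"`; must sum to 1 within 1e-9.
#' @param p_correct Probability a particle votes its filament's true class.
#' @param cc_correct,cc_wrong Length-2 `(mean, sd)` of the cc score for
#'   correct / incorrect votes.
#' @param filaments_per_protrusion Grouping of filaments into protrusions.
#' @param seed Integer seed; the table is reproducible from it.
#' @return A data.frame with one row per particle: ids, random Euler
#'   angles, the vote (`class_label`), `cc`, half-set `subset` and the
#'   filament's `true_class`.
#' @export
simulate_vote_table <- function(n_filaments, particles_per_filament,
                                class_fractions,
                                p_correct = 0.85,
                                cc_correct = c(0.15, 0.03),
                                cc_wrong = c(0.10, 0.03),
                                filaments_per_protrusion = 5L,
                                seed = 1L) {
  if (particles_per_filament < 1) stop("particles_per_filament must be >= 1")
  if (is.null(names(class_fractions)) || any(!nzchar(names(class_fractions))))
    stop("class_fractions must be a named vector")
  if (abs(sum(class_fractions) - 1) > 1e-9)
    stop("class_fractions must sum to 1")
  if (p_correct < 0 || p_correct > 1) stop("p_correct must lie in [0, 1]")
  set.seed(seed)
  classes <- names(class_fractions)
  true_class <- sample(classes, n_filaments, replace = TRUE,
                       prob = class_fractions)
  n <- n_filaments * particles_per_filament
  filament_id <- rep(seq_len(n_filaments), each = particles_per_filament)
  tc <- true_class[filament_id]
  correct <- stats::runif(n) < p_correct
  vote <- tc
  if (length(classes) > 1L) {
    wrong_idx <- which(!correct)
    for (i in wrong_idx) vote[i] <- sample(setdiff(classes, tc[i]), 1L)
  }
  rtnorm0 <- function(n, mean, sd) {
    v <- stats::rnorm(n, mean, sd)
    while (any(bad <- v < 0)) v[bad] <- stats::rnorm(sum(bad), mean, sd)
    v
  }
  cc <- numeric(n)
  cc[correct] <- rtnorm0(sum(correct), cc_correct[1], cc_correct[2])
  cc[!correct] <- rtnorm0(sum(!correct), cc_wrong[1], cc_wrong[2])
  data.frame(
    particle_id = seq_len(n),
    filament_id = filament_id,
    protrusion_id = (filament_id - 1L) %/% filaments_per_protrusion + 1L,
    x = 0, y = 0, z = 0,
    rot = stats::runif(n, -180, 180),
    tilt = stats::runif(n, 0, 180),
    psi = stats::runif(n, -180, 180),
    class_label = vote,
    cc = cc,
    subset = (filament_id %% 2L) + 1L,
    true_class = tc,
    stringsAsFactors = FALSE)
}

#' Simulate a set of luminal-filament morphology particles
#'
#' Renders noisy side-view projections of short filament segments with
#' one of three morphologies — cofilactin (twist -161.8 deg, rise 28.5 A,
#' cofilin-decorated), bare f-actin (-167 deg, 27.5 A) or "other" (a
#' straight featureless rod) — at random azimuthal phases.
#'
#' @param n Number of particles; 0 yields an empty set.
#' @param composition Named probability vector over
#'   `c("cofilactin", "factin", "other")`; must sum to 1.
#' @param snr Amplitude signal-to-noise ratio: noise s.d. = peak / snr.
#' @param box Image size `(ny, nz)` in pixels.
#' @param apix Pixel size, Angstrom (bin4 default).
#' @param seed Integer seed.
#' @return List with `images` (array ny x nz x n), `labels` (true
#'   morphology per particle), `apix` and `box`.
#' @export
simulate_morphology_set <- function(n, composition, snr = 20,
                                    box = c(32L, 48L), apix = 11.81,
                                    seed = 1L) {
  comp_names <- c("cofilactin", "factin", "other")
  if (!all(names(composition) %in% comp_names))
    stop("composition must be named over cofilactin/factin/other")
  composition <- composition[comp_names[comp_names %in% names(composition)]]
  if (abs(sum(composition) - 1) > 1e-9) stop("composition must sum to 1")
  box <- rep_len(as.integer(box), 2L)
  if (n == 0)
    return(list(images = array(0, c(box, 0L)), labels = character(),
                apix = apix, box = box))
  set.seed(seed)
  labels <- sample(names(composition), n, replace = TRUE, prob = composition)
  phases <- stats::runif(n, 0, 360)
  images <- array(0, c(box, n))
  for (i in seq_len(n)) {
    img <- .render_morphology_projection(labels[i], phases[i], box, apix)
    if (is.finite(snr)) {
      peak <- max(abs(img)); if (peak == 0) peak <- 1
      img <- img + matrix(stats::rnorm(length(img), sd = peak / snr), box[1], box[2])
    }
    images[, , i] <- img
  }
  list(images = images, labels = labels, apix = apix, box = box)
}

# Noiseless side-view projection of one morphology segment (image rows = y,
# columns = z along the filament axis).
.render_morphology_projection <- function(label, phase0, box, apix) {
  sym <- switch(label,
                cofilactin = helical_symmetry(-161.8, 28.5),
                factin = helical_symmetry(-167, 27.5),
                other = helical_symmetry(-167, 27.5))
  morph <- switch(label, cofilactin = "cofilactin", factin = "factin",
                  other = "rod")
  zlen <- box[2] * apix
  n_sub <- max(1L, floor(zlen / sym$rise_ang) + 1L)
  b <- .filament_blobs(sym, n_sub, morph, phase0 = phase0)
  cy <- (box[1] - 1) / 2 * apix
  z0 <- (zlen - (n_sub - 1L) * sym$rise_ang) / 2
  centers_yz <- cbind(b$centers[, 2] + cy, b$centers[, 3] + z0)
  .add_blobs2d(matrix(0, box[1], box[2]), apix, centers_yz, b$sigma, b$amp)
}
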