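#' Filament trace
#'
#' An ordered polyline of 3D points (nm) tracing a microtubule, a luminal
#' filament or a cytoplasmic filament, as picked in a tomogram.
#'
#' @param points Numeric matrix, n x 3, coordinates in nm; consecutive
#'   points must be distinct.
#' @param id Filament identifier.
#' @param kind One of `"microtubule"`, `"luminal"`, `"cytoplasmic"`.
#' @return Object of class `filament_trace`.
#' @export
filament_trace <- function(points, id = 1L,
                           kind = c("microtubule", "luminal", "cytoplasmic")) {
  kind <- match.arg(kind)
  points <- matrix(as.numeric(points), ncol = 3L)
  if (nrow(points) < 1L) stop("a trace needs at least one point")
  if (nrow(points) > 1L) {
    seglen <- sqrt(rowSums((points[-1L, , drop = FALSE] -
                            points[-nrow(points), , drop = FALSE])^2))
    if (any(seglen == 0)) stop("consecutive trace points must be distinct")
  }
  structure(list(points = points, id = id, kind = kind),
            class = "filament_trace")
}

#' @export
print.filament_trace <- function(x, ...) {
  cat(sprintf("filament trace '%s' (%s): %d points, contour length %.1f nm\n",
              as.character(x$id), x$kind, nrow(x$points), contour_length(x)))
  invisible(x)
}

#' Contour length of a trace
#'
#' Polyline arc length; a single-point trace has length 0.
#'
#' @param t A [filament_trace()].
#' @return Length in nm.
#' @export
contour_length <- function(t) {
  stopifnot(inherits(t, "filament_trace"))
  p <- t$points
  if (nrow(p) < 2L) return(0)
  sum(sqrt(rowSums((p[-1L, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2)))
}

#' Resample a trace into evenly spaced particle positions with frames
#'
#' Positions are placed at arc-length multiples of `spacing` from the first
#' point (including 0). Each position carries an orthonormal frame whose
#' z-axis is the local tangent; the in-plane axes are carried along the
#' trace by parallel transport, so the frame does not roll about the
#' tangent even on curved traces (a Frenet frame would be undefined on
#' straight segments). Traces shorter than `spacing` yield one particle at
#' the trace midpoint.
#'
#' @param t A [filament_trace()].
#' @param spacing Particle spacing in nm (e.g. 8 for microtubules, 6 for
#'   luminal filaments).
#' @return List with `positions` (n x 3, nm), `arc` (nm from the start) and
#'   `frames` (list of 3x3 rotation matrices; column 3 is the tangent).
#' @export
resample_trace <- function(t, spacing) {
  stopifnot(inherits(t, "filament_trace"))
  if (!(is.numeric(spacing) && spacing > 0)) stop("spacing must be > 0")
  p <- t$points
  L <- contour_length(t)
  if (L < spacing) {
    arc <- L / 2
  } else {
    arc <- seq(0, L, by = spacing)
  }
  pos <- .interp_polyline(p, arc)
  tang <- .polyline_tangents(p, arc)
  frames <- vector("list", length(arc))
  frames[[1L]] <- .frame_from_tangent(tang[1L, ])
  if (length(arc) > 1L) {
    for (i in 2L:length(arc)) {
      frames[[i]] <- .transport_frame(frames[[i - 1L]], tang[i, ])
    }
  }
  list(positions = pos, arc = arc, frames = frames)
}

# Linear interpolation of a polyline at given arc lengths.
.interp_polyline <- function(p, arc) {
  if (nrow(p) == 1L) return(matrix(rep(p[1L, ], each = length(arc)), ncol = 3L))
  seg <- sqrt(rowSums((p[-1L, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))
  cum <- c(0, cumsum(seg))
  out <- matrix(0, length(arc), 3L)
  for (i in seq_along(arc)) {
    s <- min(max(arc[i], 0), cum[length(cum)])
    j <- max(1L, findInterval(s, cum, rightmost.closed = TRUE))
    j <- min(j, nrow(p) - 1L)
    f <- if (seg[j] > 0) (s - cum[j]) / seg[j] else 0
    out[i, ] <- p[j, ] + f * (p[j + 1L, ] - p[j, ])
  }
  out
}

.polyline_tangents <- function(p, arc) {
  if (nrow(p) == 1L) return(matrix(rep(c(0, 0, 1), each = length(arc)), ncol = 3L))
  eps <- 1e-3
  L <- sum(sqrt(rowSums((p[-1L, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2)))
  a1 <- pmin(pmax(arc - eps, 0), L)
  a2 <- pmin(pmax(arc + eps, 0), L)
  d <- .interp_polyline(p, a2) - .interp_polyline(p, a1)
  n <- sqrt(rowSums(d^2))
  d / ifelse(n > 0, n, 1)
}

# Build an arbitrary right-handed frame with given z (tangent).
.frame_from_tangent <- function(z) {
  z <- z / sqrt(sum(z^2))
  ref <- if (abs(z[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  x <- ref - sum(ref * z) * z
  x <- x / sqrt(sum(x^2))
  y <- c(z[2] * x[3] - z[3] * x[2], z[3] * x[1] - z[1] * x[3], z[1] * x[2] - z[2] * x[1])
  cbind(x, y, z, deparse.level = 0)
}

# Rotate previous frame by the minimal rotation taking its tangent to the
# new tangent (parallel transport; no roll about the tangent).
.transport_frame <- function(fr, z_new) {
  z_old <- fr[, 3L]
  z_new <- z_new / sqrt(sum(z_new^2))
  c_ <- sum(z_old * z_new)
  v <- c(z_old[2] * z_new[3] - z_old[3] * z_new[2],
         z_old[3] * z_new[1] - z_old[1] * z_new[3],
         z_old[1] * z_new[2] - z_old[2] * z_new[1])
  s <- sqrt(sum(v^2))
  if (s < 1e-12) {
    if (c_ > 0) return(fr)
    # antiparallel: rotate 180 about any axis normal to z_old
    axis <- fr[, 1L]
    R <- 2 * tcrossprod(axis) - diag(3)
    return(R %*% fr)
  }
  vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  R <- diag(3) + vx + vx %*% vx * ((1 - c_) / s^2)
  out <- R %*% fr
  # re-orthonormalize against drift
  out[, 3L] <- z_new
  out[, 1L] <- out[, 1L] - sum(out[, 1L] * z_new) * z_new
  out[, 1L] <- out[, 1L] / sqrt(sum(out[, 1L]^2))
  out[, 2L] <- c(z_new[2] * out[3, 1L] - z_new[3] * out[2, 1L],
                 z_new[3] * out[1, 1L] - z_new[1] * out[3, 1L],
                 z_new[1] * out[2, 1L] - z_new[2] * out[1, 1L])
  out
}

#' Map a luminal filament to its host microtubule
#'
#' Returns the microtubule whose axis polyline has the smallest mean
#' perpendicular distance to the filament's points, provided that mean
#' distance does not exceed `lumen_radius` (the microtubule lumen is only
#' ~15 nm wide, so a generous containment radius of 8 nm is the default).
#'
#' @param f Luminal [filament_trace()].
#' @param mts List of microtubule [filament_trace()] objects.
#' @param lumen_radius Containment radius in nm.
#' @return The host microtubule's `id`, or `NA` if none qualifies.
#' @export
assign_host_microtubule <- function(f, mts, lumen_radius = 8) {
  stopifnot(inherits(f, "filament_trace"))
  if (!(lumen_radius > 0)) stop("lumen_radius must be > 0")
  if (length(mts) == 0L) return(NA)
  dists <- vapply(mts, function(mt) {
    mean(vapply(seq_len(nrow(f$points)), function(i)
      .point_polyline_distance(f$points[i, ], mt$points), 0))
  }, 0)
  best <- which.min(dists)
  if (dists[best] <= lumen_radius) mts[[best]]$id else NA
}

.point_polyline_distance <- function(q, p) {
  if (nrow(p) == 1L) return(sqrt(sum((q - p[1L, ])^2)))
  a <- p[-nrow(p), , drop = FALSE]
  b <- p[-1L, , drop = FALSE]
  ab <- b - a
  aq <- matrix(rep(q, each = nrow(a)), ncol = 3L) - a
  denom <- rowSums(ab^2)
  t_ <- pmin(pmax(rowSums(aq * ab) / ifelse(denom > 0, denom, 1), 0), 1)
  proj <- a + ab * t_
  min(sqrt(rowSums((matrix(rep(q, each = nrow(a)), ncol = 3L) - proj)^2)))
}
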