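#' Helical symmetry parameters
#'
#' A 1-start helical lattice is described by the rotation (twist, degrees)
#' and translation (rise, Angstrom) relating consecutive subunits. All
#' filaments handled here are left-handed genetic helices, so the twist is
#' negative: cofilin-decorated actin (cofilactin) has twist near -161.8 deg
#' and rise near 28.5 A, bare f-actin near -167 deg and 27.5 A.
#'
#' @param twist_deg Signed degrees per subunit about the helix axis;
#'   must lie in (-360, 0).
#' @param rise_ang Rise per subunit along the axis, Angstrom; must be > 0.
#' @return An object of class `helical_symmetry`.
#' @examples
#' cofilactin <- helical_symmetry(-161.8, 28.5)
#' factin     <- helical_symmetry(-167, 27.5)
#' @export
helical_symmetry <- function(twist_deg, rise_ang) {
  stopifnot(is.numeric(twist_deg), length(twist_deg) == 1L,
            is.numeric(rise_ang), length(rise_ang) == 1L)
  if (!(rise_ang > 0)) stop("rise_ang must be > 0")
  if (!(twist_deg > -360 && twist_deg < 0))
    stop("twist_deg must lie in (-360, 0): left-handed genetic helix")
  structure(list(twist_deg = twist_deg, rise_ang = rise_ang),
            class = "helical_symmetry")
}

#' @export
print.helical_symmetry <- function(x, ...) {
  cat(sprintf("helical symmetry: twist %.2f deg / rise %.2f A per subunit\n",
              x$twist_deg, x$rise_ang))
  invisible(x)
}

#' Cross-over distance implied by a helical symmetry
#'
#' For a 1-start helix whose per-subunit twist magnitude lies between 90 and
#' 180 degrees, the filament appears in projection as two long-pitch strands
#' that cross at regular axial intervals. The distance between successive
#' cross-overs is `rise * 180 / (180 - |twist|)`. This closed form is the
#' internal oracle against which Fourier layer-line measurements are checked.
#'
#' @param sym A [helical_symmetry()] object.
#' @return Cross-over distance in Angstrom.
#' @examples
#' crossover_from_symmetry(helical_symmetry(-162, 29))    # 290 A
#' crossover_from_symmetry(helical_symmetry(-161.8, 28.5))
#' @export
crossover_from_symmetry <- function(sym) {
  stopifnot(inherits(sym, "helical_symmetry"))
  at <- abs(sym$twist_deg)
  if (abs(at - 180) < 1e-12)
    stop("strands never cross: |twist| = 180 deg")
  if (at <= 90 || at > 180)
    stop("not a two-start-appearing helix: need 90 < |twist| < 180")
  sym$rise_ang * 180 / (180 - at)
}

#' Build a subunit lattice from a helical symmetry
#'
#' Places `n_subunits` subunit centers on the 1-start helix: subunit k sits
#' at azimuth `phase0 + k * twist` and height `k * rise`, all at the same
#' radius from the axis (the axis is z through the origin).
#'
#' @param sym A [helical_symmetry()] object.
#' @param n_subunits Number of subunits (>= 1).
#' @param radius Radius from the helix axis to the subunit center, Angstrom.
#' @param phase0 Azimuth of subunit 0, degrees.
#' @return A data.frame of class `subunit_lattice` with columns `k`, `x`,
#'   `y`, `z` (Angstrom) and `azimuth_deg`; the symmetry, radius and phase
#'   are kept as attributes.
#' @export
build_subunit_lattice <- function(sym, n_subunits, radius, phase0 = 0) {
  stopifnot(inherits(sym, "helical_symmetry"))
  if (!(is.numeric(n_subunits) && n_subunits >= 1))
    stop("n_subunits must be >= 1")
  if (radius < 0) stop("radius must be >= 0")
  k <- seq_len(n_subunits) - 1L
  az <- phase0 + k * sym$twist_deg
  th <- az * pi / 180
  out <- data.frame(k = k,
                    x = radius * cos(th),
                    y = radius * sin(th),
                    z = k * sym$rise_ang,
                    azimuth_deg = az)
  attr(out, "symmetry") <- sym
  attr(out, "radius") <- radius
  attr(out, "phase0") <- phase0
  class(out) <- c("subunit_lattice", "data.frame")
  out
}

## ---- Euler triplets (intrinsic Z-Y-Z, degrees) ------------------------------

#' Euler triplet in the intrinsic Z-Y-Z convention
#'
#' Orientation is encoded as three angles (rot, tilt, psi) in degrees: first
#' a rotation about z by `rot`, then about the new y by `tilt`, then about
#' the new z by `psi`. Angles are normalized so that tilt lies in [0, 180]
#' and rot, psi in (-180, 180]. This is the convention the subtomogram
#' particle tables use; the "second Euler angle" is tilt.
#'
#' @param rot,tilt,psi Angles in degrees.
#' @return Named numeric vector of class `euler_triplet`.
#' @export
euler_triplet <- function(rot, tilt, psi) {
  m <- euler_to_matrix(c(rot = rot, tilt = tilt, psi = psi))
  matrix_to_euler(m)
}

#' Rotation matrix of a Z-Y-Z Euler triplet
#'
#' @param e Numeric length-3 vector (rot, tilt, psi) in degrees.
#' @return 3x3 rotation matrix (right-handed, column-vector convention).
#' @export
euler_to_matrix <- function(e) {
  e <- as.numeric(e) * pi / 180
  rz <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
  ry <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
  rz(e[1]) %*% ry(e[2]) %*% rz(e[3])
}

#' Extract a canonical Z-Y-Z Euler triplet from a rotation matrix
#'
#' At the gimbal-degenerate orientations (tilt 0 or 180) the in-plane angle
#' is carried entirely by `rot` and `psi` is set to 0.
#'
#' @param m 3x3 rotation matrix.
#' @return Named numeric vector (rot, tilt, psi) of class `euler_triplet`,
#'   with tilt in [0, 180] and rot, psi in (-180, 180].
#' @export
matrix_to_euler <- function(m) {
  stopifnot(is.matrix(m), all(dim(m) == c(3L, 3L)))
  ct <- max(-1, min(1, m[3, 3]))
  tilt <- acos(ct)
  if (sin(tilt) > 1e-9) {
    rot <- atan2(m[2, 3], m[1, 3])
    psi <- atan2(m[3, 2], -m[3, 1])
  } else if (ct > 0) {            # tilt ~ 0: pure z rotation by rot + psi
    rot <- atan2(m[2, 1], m[1, 1])
    psi <- 0
  } else {                        # tilt ~ 180: z rotation by rot - psi
    rot <- atan2(-m[2, 1], -m[1, 1])
    psi <- 0
  }
  deg <- c(rot, tilt, psi) * 180 / pi
  norm180 <- function(a) { a <- (a + 180) %% 360 - 180; ifelse(a == -180, 180, a) }
  out <- c(rot = norm180(deg[1]),
           tilt = max(0, min(180, deg[2])),
           psi = norm180(deg[3]))
  class(out) <- "euler_triplet"
  out
}

#' Direction of a particle's helix axis
#'
#' Image of the +z unit vector under the triplet's rotation: the particle's
#' axial direction in the tomogram frame.
#'
#' @param e Euler triplet (rot, tilt, psi), degrees.
#' @return Unit 3-vector.
#' @export
euler_direction <- function(e) as.numeric(euler_to_matrix(e) %*% c(0, 0, 1))

#' Flip the polarity of a particle orientation
#'
#' Composes the orientation with a 180-degree rotation about the
#' intermediate (second, Y) Euler axis — the operation used to unify
#' filament polarity before averaging — and re-extracts a canonical
#' triplet. The particle's axial direction vector is exactly reversed.
#'
#' @param e Euler triplet (rot, tilt, psi), degrees.
#' @return The flipped `euler_triplet`.
#' @export
flip_polarity <- function(e) {
  e <- as.numeric(e)
  m <- euler_to_matrix(c(e[1], e[2] + 180, e[3]))
  matrix_to_euler(m)
}
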