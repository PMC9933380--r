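## Synthetic time-varying left-atrial cavity phantom.
##
## Coordinate convention: right-handed, millimetres; the LA long axis is +z,
## the mitral annulus center sits at the origin, the roof apex at (0, 0, 2c)
## in the reference state; the interatrial septum normal is +x. The reference
## state (all scale factors 1) is the mitral-closure frame, i.e. the smallest
## cavity of the cycle (LA end-systole).

#' Piecewise-cosine LA volume curve through the cycle's event frames
#'
#' Interpolates smoothly (zero slope at the nodes) from LAVmin at mitral
#' closure up to LAVmax at mitral opening, down to the pre-A volume at the
#' onset of atrial contraction, and back to LAVmin at the cycle wrap —
#' the two-lobed shape of a physiologic LA volume curve with its pre-A
#' shoulder.
#'
#' @param n_phases Number of cardiac phases (frames) per cycle.
#' @param events List with integer frames `mitral_closure`, `mitral_opening`,
#'   `pre_A` (1-based).
#' @param lavmin,lavmax,prea Volumes (mm^3) at the three event frames,
#'   `lavmin <= prea <= lavmax`.
#' @return Numeric vector of length `n_phases` (mm^3).
#' @export
volume_curve <- function(n_phases, events, lavmin, lavmax, prea) {
  stopifnot(lavmin <= prea, prea <= lavmax, lavmin > 0)
  mc <- events$mitral_closure; mo <- events$mitral_opening; pa <- events$pre_A
  stopifnot(mc == 1L, mo > mc, pa > mo, pa <= n_phases)
  nodes_t <- c(mc, mo, pa, n_phases + 1L)
  nodes_v <- c(lavmin, lavmax, prea, lavmin)
  t <- seq_len(n_phases)
  vol <- numeric(n_phases)
  for (s in 1:3) {
    in_seg <- t >= nodes_t[s] & t < nodes_t[s + 1]
    tau <- (t[in_seg] - nodes_t[s]) / (nodes_t[s + 1] - nodes_t[s])
    vol[in_seg] <- nodes_v[s] + (nodes_v[s + 1] - nodes_v[s]) * (1 - cos(pi * tau)) / 2
  }
  vol
}

## Solve the per-phase semi-axis scale factors from a target volume ratio
## g = V(t)/V(reference), distributing the change anisotropically: the
## relative long-axis change is `aniso` (default 1.5) times the relative
## short-axis change, so sx = sy = 1 + d, sz = 1 + aniso*d and
## (1+d)^2 (1+aniso*d) = g. Monotone in d, solved by uniroot.
solve_scales <- function(g, aniso = 1.5) {
  vapply(g, function(gi) {
    if (abs(gi - 1) < 1e-12) return(0)
    uniroot(function(d) (1 + d)^2 * (1 + aniso * d) - gi,
            lower = -0.5, upper = 5, tol = 1e-12)$root
  }, numeric(1))
}

#' Construct a time-varying LA cavity phantom
#'
#' The phantom is a prolate ellipsoid (semi-axes `a`, `b` short, `c` long,
#' long axis +z, annulus at the origin) carrying a per-phase affine
#' deformation about the annulus plus an optional roof "blunting" that
#' attenuates displacement near the pulmonary-vein roof. The LV long axis
#' deviates from the LA long axis by the tilt `theta_deg`; standard
#' (LV-focused) imaging planes are prescribed on that axis and therefore
#' foreshorten the atrium.
#'
#' When `volume_curve_params` prescribes LAVmin, the semi-axes are rescaled
#' isotropically (aspect preserved) so the reference-state closed-form volume
#' (4/3)*pi*a*b*c equals LAVmin exactly; scale factors are then solved so the
#' lambda = 0 closed-form volume passes exactly through LAVmax at mitral
#' opening and the pre-A volume at the pre-A frame.
#'
#' @param a,b,c Reference semi-axes (mm), `c >= max(a, b)`.
#' @param theta_deg Tilt angle between LA and LV long axes, degrees in
#'   \[0, 90).
#' @param volume_curve_params Optional list with `lavmax`, `lavmin`, `prea`
#'   (mm^3). Default: `lavmin` from the semi-axes, `lavmax = (82/38)*lavmin`
#'   and `prea = lavmin + 0.4*(lavmax - lavmin)`.
#' @param lambda Roof-blunting factor in \[0, 1\]; 0 keeps the phantom an
#'   exact affine ellipsoid at every phase.
#' @param n_phases Frames per cardiac cycle (25-30 typical).
#' @param bsa Body surface area (m^2).
#' @param events Optional event-frame list (`mitral_closure`,
#'   `mitral_opening`, `pre_A`); defaults to frames 1, round(0.4 n), and
#'   round(0.85 n).
#' @param mesh_subdiv Icosphere subdivision level for the mesh path.
#' @param tilt_azimuth_deg Azimuth (degrees from the septum normal, in the
#'   annulus plane) of the axis about which the LV axis is tilted; the 45
#'   degree default makes both standard long-axis views oblique to the LA
#'   axis.
#' @return An object of class `la_phantom`.
#' @export
make_phantom <- function(a, b, c, theta_deg = 0,
                         volume_curve_params = NULL,
                         lambda = 0, n_phases = 25L, bsa = 1.88,
                         events = NULL, mesh_subdiv = 4L,
                         tilt_azimuth_deg = 45) {
  ax_a <- a; ax_b <- b; ax_c <- c
  rm(a, b, c)  # free `c` so base::c is visible again below
  stopifnot(ax_a > 0, ax_b > 0, ax_c > 0)
  if (ax_c < max(ax_a, ax_b)) stop("non-prolate axes: c must be the longest semi-axis")
  if (theta_deg < 0 || theta_deg >= 90) stop("tilt angle must lie in [0, 90) degrees")
  if (lambda < 0 || lambda > 1) stop("lambda must lie in [0, 1]")
  n_phases <- as.integer(n_phases)
  stopifnot(n_phases >= 2L)
  if (is.null(events)) {
    events <- list(mitral_closure = 1L,
                   mitral_opening = max(2L, as.integer(round(0.4 * n_phases))),
                   pre_A = as.integer(round(0.85 * n_phases)))
  }
  v_ref <- 4 / 3 * pi * ax_a * ax_b * ax_c
  if (is.null(volume_curve_params)) {
    lavmin <- v_ref
    lavmax <- lavmin * (82 / 38)
    prea <- lavmin + 0.4 * (lavmax - lavmin)
  } else {
    lavmin <- volume_curve_params$lavmin
    lavmax <- volume_curve_params$lavmax
    prea <- if (is.null(volume_curve_params$prea))
      lavmin + 0.4 * (lavmax - lavmin) else volume_curve_params$prea
    if (lavmin > lavmax) stop("LAVmin must not exceed LAVmax")
    if (prea < lavmin || prea > lavmax) stop("pre-A volume must lie in [LAVmin, LAVmax]")
    # rescale the reference ellipsoid so its volume is exactly LAVmin
    k <- (lavmin / v_ref)^(1 / 3)
    ax_a <- ax_a * k; ax_b <- ax_b * k; ax_c <- ax_c * k
  }
  vols <- volume_curve(n_phases, events, lavmin, lavmax, prea)
  d <- solve_scales(vols / lavmin)
  scales <- cbind(sx = 1 + d, sy = 1 + d, sz = 1 + 1.5 * d)

  az <- tilt_azimuth_deg * pi / 180
  tilt_axis <- c(cos(az), sin(az), 0)
  R <- rotation_about(tilt_axis, theta_deg)
  la_axis <- c(0, 0, 1)
  lv_axis <- as.numeric(R %*% la_axis)

  base <- icosphere(mesh_subdiv)
  ref_vertices <- cbind(ax_a * base$vertices[, 1],
                        ax_b * base$vertices[, 2],
                        ax_c * base$vertices[, 3] + ax_c)

  structure(list(
    a = ax_a, b = ax_b, c = ax_c,
    la_axis = la_axis, lv_axis = lv_axis, tilt_deg = theta_deg,
    tilt_rotation = R,
    septum_normal = c(1, 0, 0),
    annulus_center = c(0, 0, 0),
    roof_apex = c(0, 0, 2 * ax_c),
    lambda = lambda, n_phases = n_phases, events = events,
    volumes_affine = vols, scales = scales, bsa = bsa,
    mesh_subdiv = as.integer(mesh_subdiv),
    faces = base$faces, ref_vertices = ref_vertices
  ), class = "la_phantom")
}

#' @export
print.la_phantom <- function(x, ...) {
  cat(sprintf(
    "LA phantom: semi-axes %.1f x %.1f x %.1f mm, tilt %.1f deg, lambda %.2f\n",
    x$a, x$b, x$c, x$tilt_deg, x$lambda))
  cat(sprintf("  %d phases; LAVmin %.1f ml (frame %d), LAVmax %.1f ml (frame %d), pre-A frame %d\n",
              x$n_phases, min(x$volumes_affine) / 1000, x$events$mitral_closure,
              max(x$volumes_affine) / 1000, x$events$mitral_opening, x$events$pre_A))
  invisible(x)
}

#' Roof-blunted displacement of a surface point
#'
#' The affine displacement `u = scaled point - reference point` is attenuated
#' by a weight `w(z') = 1 - lambda * max(0, (z' - 0.5)/0.5)`, where `z'` is
#' the normalized long-axis coordinate from annulus (0) to roof (1): full
#' motion over the annular half, linearly ramping down to `1 - lambda` at the
#' roof apex. This encodes the blunted deformation of the pulmonary-vein roof
#' region.
#'
#' @param phantom An `la_phantom`.
#' @param points n x 3 matrix of reference-surface points (mm).
#' @param phase Frame index in 1..n_phases.
#' @param lambda Blunting factor; defaults to the phantom's.
#' @return n x 3 matrix of displaced points.
#' @export
roof_blunted_displacement <- function(phantom, points, phase, lambda = phantom$lambda) {
  points <- rbind(points)  # tolerate a single point given as a vector
  check_phase(phantom, phase)
  s <- unname(phantom$scales[phase, ])
  scaled <- cbind(points[, 1] * s[1], points[, 2] * s[2], points[, 3] * s[3])
  zp <- points[, 3] / (2 * phantom$c)
  w <- 1 - lambda * pmax(0, (zp - 0.5) / 0.5)
  points + w * (scaled - points)
}

check_phase <- function(phantom, phase) {
  if (length(phase) != 1L || phase < 1L || phase > phantom$n_phases)
    stop(sprintf("phase must lie in 1..%d", phantom$n_phases))
  invisible(TRUE)
}

## Deformed mesh vertices of the phantom at a phase (mm).
phantom_vertices <- function(phantom, phase) {
  roof_blunted_displacement(phantom, phantom$ref_vertices, phase)
}

#' Cavity volume of the phantom at a phase
#'
#' For `lambda = 0` the closed-form affine-ellipsoid volume
#' (4/3) pi a b c sx sy sz; for `lambda > 0` the divergence-theorem volume of
#' the blunted triangle mesh. `method` can force either path (the mesh path
#' on a lambda = 0 phantom is the cross-validation used in the tests).
#'
#' @param phantom An `la_phantom`.
#' @param phase Frame index in 1..n_phases.
#' @param method "auto", "analytic" (lambda = 0 only) or "mesh".
#' @return Volume in mm^3.
#' @export
phantom_volume <- function(phantom, phase, method = c("auto", "analytic", "mesh")) {
  method <- match.arg(method)
  check_phase(phantom, phase)
  if (method == "auto") method <- if (phantom$lambda == 0) "analytic" else "mesh"
  if (method == "analytic") {
    if (phantom$lambda != 0) stop("analytic volume requires lambda = 0")
    s <- phantom$scales[phase, ]
    return(4 / 3 * pi * phantom$a * phantom$b * phantom$c * prod(s))
  }
  mesh_volume(phantom_vertices(phantom, phase), phantom$faces)
}

#' Per-phase ground-truth volume series of a phantom
#'
#' @param phantom An `la_phantom`.
#' @param method Passed to [phantom_volume()].
#' @return Numeric vector of length `n_phases` (mm^3).
#' @export
phantom_volume_series <- function(phantom, method = "auto") {
  vapply(seq_len(phantom$n_phases), function(ph)
    phantom_volume(phantom, ph, method = method), numeric(1))
}
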