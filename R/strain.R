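## Phasic LA strain from contour perimeters.
##
## Feature tracking of cine images is replaced by endocardial global
## longitudinal (perimeter) strain of the sectioned contour: the relative
## perimeter change of the traced border against the mitral-closure
## (ventricular end-diastole) reference frame. Both view sets use the same
## surrogate, so the standard-vs-LA-focused comparison is preserved.

#' Perimeter strain curve
#'
#' `eps(t) = 100 * (P(t) - P_ref) / P_ref` (percent), zero at the reference
#' frame.
#'
#' @param perimeters Per-phase contour perimeters (mm), all positive.
#' @param reference_frame Frame index of the zero-strain reference (mitral
#'   closure).
#' @return Strain in percent, one value per phase.
#' @export
perimeter_strain <- function(perimeters, reference_frame = 1L) {
  if (any(perimeters <= 0)) stop("perimeters must be positive")
  if (reference_frame < 1L || reference_frame > length(perimeters))
    stop("reference frame out of range")
  100 * (perimeters - perimeters[reference_frame]) / perimeters[reference_frame]
}

#' Decompose a strain curve into reservoir, conduit and booster components
#'
#' Reservoir strain `eps_s` is the cycle maximum, booster-pump strain `eps_a`
#' the strain at the onset of atrial contraction (pre-A frame), and conduit
#' strain `eps_e = eps_s - eps_a` the passive-emptying remainder, so
#' `eps_s = eps_e + eps_a` by construction.
#'
#' @param strain Per-phase strain curve (percent), zero at its reference.
#' @param pre_a_frame Pre-A frame index.
#' @return List with `eps_s`, `eps_e`, `eps_a` (percent).
#' @export
phasic_decomposition <- function(strain, pre_a_frame) {
  if (pre_a_frame < 1L || pre_a_frame > length(strain))
    stop("pre-A frame out of range")
  eps_s <- max(strain)
  eps_a <- strain[pre_a_frame]
  list(eps_s = eps_s, eps_e = eps_s - eps_a, eps_a = eps_a)
}

#' View-averaged phasic strain from the 2- and 4-chamber curves
#'
#' Averages the two views' strain curves phase-by-phase and decomposes the
#' mean curve.
#'
#' @param curve_2ch,curve_4ch Per-phase strain curves (percent), equal
#'   length.
#' @param pre_a_frame Pre-A frame index.
#' @return Object of class `la_strain` with the mean curve, per-view curves
#'   and the phasic components.
#' @export
biview_strain <- function(curve_2ch, curve_4ch, pre_a_frame) {
  if (length(curve_2ch) != length(curve_4ch))
    stop("2ch and 4ch curves must have the same number of phases")
  mean_curve <- (curve_2ch + curve_4ch) / 2
  comp <- phasic_decomposition(mean_curve, pre_a_frame)
  structure(c(list(curve = mean_curve, curve_2ch = curve_2ch,
                   curve_4ch = curve_4ch, pre_a_frame = pre_a_frame), comp),
            class = "la_strain")
}

#' @export
print.la_strain <- function(x, ...) {
  cat(sprintf("LA phasic strain: reservoir %.1f%%, conduit %.1f%%, booster %.1f%%\n",
              x$eps_s, x$eps_e, x$eps_a))
  invisible(x)
}

#' Phasic strain of a phantom under a pair of long-axis planes
#'
#' Sections the phantom with the given 2ch/4ch planes at every phase, turns
#' the contour perimeters into strain curves referenced to the
#' mitral-closure frame, and returns the view-averaged phasic decomposition.
#'
#' @param phantom An `la_phantom`.
#' @param planes List of two imaging planes (2ch, 4ch), e.g. from
#'   [prescribe_standard_planes()].
#' @param verts_by_phase Optional list of precomputed deformed vertex
#'   matrices, one per phase (internal speed-up for cohort runs).
#' @return A `la_strain`.
#' @export
phantom_strain <- function(phantom, planes, verts_by_phase = NULL) {
  per <- vapply(seq_len(phantom$n_phases), function(ph) {
    verts <- if (is.null(verts_by_phase)) NULL else verts_by_phase[[ph]]
    c(section_measures(phantom, planes[[1]], ph, verts = verts)$perimeter,
      section_measures(phantom, planes[[2]], ph, verts = verts)$perimeter)
  }, numeric(2))
  ref <- phantom$events$mitral_closure
  biview_strain(perimeter_strain(per[1, ], ref),
                perimeter_strain(per[2, ], ref),
                phantom$events$pre_A)
}
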