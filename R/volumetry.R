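## LA volumetry: biplane area-length, Simpson's disk summation, emptying
## fraction, BSA indexing and dilation-severity categories.
## Volumes are mm^3 internally; 1 ml = 1000 mm^3 at reporting time.

#' Biplane area-length LA volume
#'
#' `V = 0.85 * A_4ch * A_2ch / Lmin`, with `Lmin` the shorter of the two
#' long-axis lengths. The 0.85 constant is the clinical approximation to the
#' exact prolate-ellipsoid factor 8/(3*pi) = 0.8488.
#'
#' @param a_4ch,a_2ch Cross-sectional areas (mm^2) from the 4- and 2-chamber
#'   views.
#' @param l_4ch,l_2ch Long-axis lengths (mm) from the two views.
#' @return Volume in mm^3.
#' @export
biplane_area_length <- function(a_4ch, a_2ch, l_4ch, l_2ch) {
  if (any(c(a_4ch, a_2ch, l_4ch, l_2ch) <= 0))
    stop("areas and lengths must be positive")
  0.85 * a_4ch * a_2ch / pmin(l_4ch, l_2ch)
}

#' Simpson's method of disks
#'
#' Volume as slice thickness times the summed slice areas of a parallel
#' short-axis stack; empty (sentinel) slices contribute zero.
#'
#' @param areas Slice areas (mm^2), `>= 0`.
#' @param thickness Slice thickness (mm).
#' @return Volume in mm^3.
#' @export
disk_volume <- function(areas, thickness) {
  if (length(areas) == 0L) stop("empty slice stack")
  if (thickness <= 0) stop("slice thickness must be positive")
  if (any(areas < 0)) stop("slice areas must be non-negative")
  thickness * sum(areas)
}

#' Select the LAVmax / LAVmin frames of a volume series
#'
#' LAVmax is the largest and LAVmin the smallest per-phase volume; ties are
#' broken toward the earlier frame. For a conforming phantom these coincide
#' with the mitral-opening (frame before mitral-valve opening) and
#' mitral-closure event frames.
#'
#' @param volumes Per-phase volume vector (>= 2 phases).
#' @return List with `max_frame` and `min_frame` (1-based).
#' @export
select_phases <- function(volumes) {
  if (length(volumes) < 2L) stop("need at least two phases")
  list(max_frame = which.max(volumes), min_frame = which.min(volumes))
}

#' LA emptying fraction
#'
#' `LAEF = 100 * (LAVmax - LAVmin) / LAVmax` (percent).
#'
#' @param lavmax,lavmin Maximum and minimum LA volumes (same units).
#' @return LAEF in percent.
#' @export
laef <- function(lavmax, lavmin) {
  if (any(lavmax <= 0)) stop("LAVmax must be positive")
  if (any(lavmin > lavmax)) stop("LAVmin must not exceed LAVmax")
  100 * (lavmax - lavmin) / lavmax
}

#' Index a volume to body surface area
#'
#' @param volume_ml Volume in ml.
#' @param bsa Body surface area in m^2.
#' @return Indexed volume in ml/m^2.
#' @export
index_to_bsa <- function(volume_ml, bsa) {
  if (any(bsa <= 0)) stop("BSA must be positive")
  volume_ml / bsa
}

#' Severity categories of LA dilation
#'
#' Partition of indexed LAVmax (ml/m^2): normal `< 53`, mildly dilated
#' `[53, 63)`, moderately dilated `[63, 73]`, severely dilated `> 73`. The
#' printed clinical ranges (53-62, 63-73) leave the integer edges open; the
#' half-open convention here makes the categories a gap-free partition.
#'
#' @param lavmax_i Indexed LAVmax (ml/m^2), `>= 0`.
#' @return Ordered factor with levels normal < mild < moderate < severe.
#' @export
classify_severity <- function(lavmax_i) {
  if (any(lavmax_i < 0)) stop("indexed volume must be non-negative")
  cut(lavmax_i, breaks = c(-Inf, 53, 63, 73, Inf),
      labels = severity_levels(), right = FALSE,
      # [63, 73] closed on the right per the printed "> 73" for severe:
      include.lowest = TRUE) -> f
  f[lavmax_i == 73] <- "moderate"
  factor(f, levels = severity_levels(), ordered = TRUE)
}

severity_levels <- function() c("normal", "mild", "moderate", "severe")

#' Per-phase volume series with derived quantities
#'
#' Bundles a per-phase volume vector with its LAVmax/LAVmin frames, LAEF,
#' BSA-indexed values and severity category.
#'
#' @param volumes Per-phase volumes (mm^3).
#' @param bsa Body surface area (m^2).
#' @param method Label: "standard", "focused" or "reference".
#' @return Object of class `la_volume_series`.
#' @export
volume_series <- function(volumes, bsa, method = "reference") {
  fr <- select_phases(volumes)
  lavmax_ml <- volumes[fr$max_frame] / 1000
  lavmin_ml <- volumes[fr$min_frame] / 1000
  lavmax_i <- index_to_bsa(lavmax_ml, bsa)
  structure(list(
    volumes = volumes, method = method, bsa = bsa,
    max_frame = fr$max_frame, min_frame = fr$min_frame,
    lavmax_ml = lavmax_ml, lavmin_ml = lavmin_ml,
    lavmax_i = lavmax_i, lavmin_i = index_to_bsa(lavmin_ml, bsa),
    laef = laef(lavmax_ml, lavmin_ml),
    severity = classify_severity(lavmax_i)
  ), class = "la_volume_series")
}

#' @export
print.la_volume_series <- function(x, ...) {
  cat(sprintf(
    "%s volume series: LAVmax %.1f ml (frame %d), LAVmin %.1f ml (frame %d)\n",
    x$method, x$lavmax_ml, x$max_frame, x$lavmin_ml, x$min_frame))
  cat(sprintf("  LAEF %.1f%%; indexed %.1f / %.1f ml/m2; severity: %s\n",
              x$laef, x$lavmax_i, x$lavmin_i, as.character(x$severity)))
  invisible(x)
}
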