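## Imaging-plane prescription and plane-phantom sectioning.
##
## Three acquisition geometries are modelled:
##  * standard long-axis views, prescribed on the LV long axis (which deviates
##    from the LA long axis by the tilt angle, hence foreshortening),
##  * LA-focused long-axis views through the LA roof and the annulus center,
##    the 2-chamber one oriented parallel to the interatrial septum,
##  * a short-axis stack perpendicular to the LA long axis, 6 mm slices,
##    no gap, covering the whole atrium at every phase.

imaging_plane <- function(origin, normal, v_dir, label) {
  normal <- normal / sqrt(sum(normal^2))
  v_dir <- v_dir - sum(v_dir * normal) * normal
  v_dir <- v_dir / sqrt(sum(v_dir^2))
  u_dir <- c(v_dir[2] * normal[3] - v_dir[3] * normal[2],
             v_dir[3] * normal[1] - v_dir[1] * normal[3],
             v_dir[1] * normal[2] - v_dir[2] * normal[1])  # v x n
  structure(list(origin = origin, normal = normal, u = u_dir, v = v_dir,
                 label = label), class = "imaging_plane")
}

#' Prescribe standard (LV-focused) long-axis planes
#'
#' Both planes contain the mitral annulus center and the LV long-axis
#' direction; they are mutually orthogonal about that axis. The 2ch/4ch
#' disambiguation copies the LA-focused convention (2ch parallel to the
#' septum) rotated onto the LV axis, so at zero tilt the standard planes
#' coincide with the focused ones.
#'
#' @param phantom An `la_phantom`.
#' @return List with `standard_2ch` and `standard_4ch` imaging planes.
#' @export
prescribe_standard_planes <- function(phantom) {
  R <- phantom$tilt_rotation
  n2 <- as.numeric(R %*% phantom$septum_normal)
  n4 <- as.numeric(R %*% c(0, 1, 0))
  list(
    standard_2ch = imaging_plane(phantom$annulus_center, n2, phantom$lv_axis, "standard_2ch"),
    standard_4ch = imaging_plane(phantom$annulus_center, n4, phantom$lv_axis, "standard_4ch"))
}

#' Prescribe LA-focused long-axis planes
#'
#' Both planes contain the annulus center and the roof apex (hence the true
#' LA long axis); the 2ch plane is oriented parallel to the interatrial
#' septum, the 4ch plane perpendicular to it about the LA axis.
#'
#' @param phantom An `la_phantom`.
#' @return List with `focused_2ch` and `focused_4ch` imaging planes.
#' @export
prescribe_focused_planes <- function(phantom) {
  n2 <- phantom$septum_normal
  ala <- phantom$la_axis
  if (abs(sum(n2 * ala)) > 1 - 1e-9)
    stop("degenerate geometry: septum normal parallel to the LA long axis")
  n4 <- c(ala[2] * n2[3] - ala[3] * n2[2],
          ala[3] * n2[1] - ala[1] * n2[3],
          ala[1] * n2[2] - ala[2] * n2[1])
  list(
    focused_2ch = imaging_plane(phantom$annulus_center, n2, ala, "focused_2ch"),
    focused_4ch = imaging_plane(phantom$annulus_center, n4, ala, "focused_4ch"))
}

#' Prescribe the short-axis reference stack
#'
#' Parallel planes with normal along the LA long axis, spaced by the slice
#' thickness with no gap, covering the full long-axis extent of the phantom
#' over all phases. Each slice is evaluated at the mid-plane of its slab
#' (midpoint rule).
#'
#' @param phantom An `la_phantom`.
#' @param thickness Slice thickness in mm (default 6, the acquisition value).
#' @return List of `sax_k` imaging planes, proximal (annulus) to distal
#'   (roof).
#' @export
prescribe_short_axis_stack <- function(phantom, thickness = 6) {
  if (thickness <= 0) stop("slice thickness must be positive")
  extent <- 2 * phantom$c * max(phantom$scales[, "sz"])
  n_slices <- ceiling(extent / thickness)
  lapply(seq_len(n_slices), function(k) {
    z_mid <- (k - 0.5) * thickness
    pl <- imaging_plane(c(0, 0, z_mid), phantom$la_axis, c(0, 1, 0),
                        sprintf("sax_%02d", k))
    pl$u <- c(1, 0, 0); pl$v <- c(0, 1, 0)  # fixed in-plane axes for the stack
    pl$thickness <- thickness
    pl
  })
}

#' Intersect the phantom with an imaging plane
#'
#' Returns the closed intersection polygon as a `la_contour` (ordered 2D
#' vertices in plane coordinates, counter-clockwise), or the sentinel
#' [no_section()] when the plane misses the cavity (distal slices beyond the
#' roof). For `lambda = 0` phantoms the exact plane-ellipsoid intersection
#' ellipse is sampled at `n_vertices` points; for `lambda > 0` (or
#' `path = "mesh"`) the triangulated surface is sectioned.
#'
#' @param phantom An `la_phantom`.
#' @param plane An imaging plane.
#' @param phase Frame index in 1..n_phases.
#' @param n_vertices Vertex count for the analytic ellipse polygonization.
#' @param path "auto", "analytic" or "mesh".
#' @return A `la_contour`, or `no_section()`.
#' @export
section <- function(phantom, plane, phase, n_vertices = 512L,
                    path = c("auto", "analytic", "mesh")) {
  path <- match.arg(path)
  check_phase(phantom, phase)
  if (path == "auto") path <- if (phantom$lambda == 0) "analytic" else "mesh"
  if (path == "analytic") {
    if (phantom$lambda != 0) stop("analytic sectioning requires lambda = 0")
    xy <- ellipsoid_plane_ellipse(phantom, plane, phase, n_vertices)
  } else {
    seg <- mesh_plane_segments(phantom_vertices(phantom, phase), phantom$faces,
                               plane$origin, plane$normal, plane$u, plane$v)
    xy <- if (is.null(seg)) NULL else chain_segments(seg)
  }
  if (is.null(xy) || nrow(xy) < 3L) return(no_section(plane$label, phase))
  if (polygon_signed_area(xy) < 0) xy <- xy[rev(seq_len(nrow(xy))), , drop = FALSE]
  landmark <- NULL
  if (grepl("2ch|4ch", plane$label)) {
    d <- phantom$annulus_center - plane$origin
    landmark <- c(sum(d * plane$u), sum(d * plane$v))
  }
  new_contour(xy, plane$label, phase, landmark)
}

## Analytic plane section of the lambda = 0 affine-scaled ellipsoid:
## map to the unit-sphere frame, cut the sphere (a circle), map back, and
## project into plane coordinates. NULL if the plane misses the ellipsoid.
ellipsoid_plane_ellipse <- function(phantom, plane, phase, n_vertices) {
  s <- phantom$scales[phase, ]
  semi <- c(phantom$a * s[1], phantom$b * s[2], phantom$c * s[3])
  ctr <- c(0, 0, phantom$c * s[3])
  np <- plane$normal * semi                   # M^T n, M = diag(semi)
  d <- sum(plane$normal * (plane$origin - ctr))
  delta <- d / sqrt(sum(np^2))
  if (abs(delta) >= 1) return(NULL)
  nh <- np / sqrt(sum(np^2))
  rho <- sqrt(1 - delta^2)
  e1 <- if (abs(nh[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- e1 - sum(e1 * nh) * nh; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(nh[2] * e1[3] - nh[3] * e1[2],
          nh[3] * e1[1] - nh[1] * e1[3],
          nh[1] * e1[2] - nh[2] * e1[1])
  t <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  u_sph <- delta * matrix(nh, n_vertices, 3, byrow = TRUE) +
    rho * (outer(cos(t), e1) + outer(sin(t), e2))
  pts <- sweep(u_sph, 2, semi, "*")
  pts <- sweep(pts, 2, ctr, "+")
  rel <- sweep(pts, 2, plane$origin)
  cbind(rel %*% plane$u, rel %*% plane$v)
}

new_contour <- function(xy, label, phase, landmark = NULL) {
  structure(list(vertices = xy, label = label, phase = phase,
                 landmark = landmark), class = "la_contour")
}

#' Sentinel for an empty plane-phantom intersection
#'
#' Distal short-axis slices beyond the roof intersect nothing; they
#' contribute zero area to disk summation rather than raising an error.
#'
#' @param label Plane label.
#' @param phase Frame index.
#' @return An object of class `la_no_section`.
#' @export
no_section <- function(label = NA_character_, phase = NA_integer_) {
  structure(list(label = label, phase = phase), class = "la_no_section")
}

#' @export
#' @rdname no_section
#' @param x Object to test.
is_no_section <- function(x) inherits(x, "la_no_section")

#' Area, long-axis length and perimeter of a contour
#'
#' Area by the shoelace formula, perimeter as the closed polyline length,
#' and - for long-axis views carrying an annulus landmark - the long-axis
#' length as the maximum distance from the annulus landmark to any contour
#' vertex (the annulus-to-roof length a reader would draw).
#'
#' @param contour A `la_contour` (or the empty-section sentinel, which yields
#'   zero area/perimeter and `NA` length).
#' @return List with `area` (mm^2), `long_axis_length` (mm, `NA` when no
#'   landmark), `perimeter` (mm).
#' @export
measure_contour <- function(contour) {
  if (is_no_section(contour))
    return(list(area = 0, long_axis_length = NA_real_, perimeter = 0))
  xy <- contour$vertices
  if (is.null(xy) || nrow(xy) < 3L) stop("contour needs at least 3 vertices")
  L <- NA_real_
  if (!is.null(contour$landmark)) {
    dx <- xy[, 1] - contour$landmark[1]
    dy <- xy[, 2] - contour$landmark[2]
    L <- sqrt(max(dx^2 + dy^2))
  }
  list(area = abs(polygon_signed_area(xy)),
       long_axis_length = L,
       perimeter = polygon_perimeter(xy))
}

## Fast measurement path used by the study pipeline: area/perimeter/length
## straight from the oriented mesh-plane intersection segments, skipping
## polygon chaining. `verts` lets callers amortize the per-phase deformation.
section_measures <- function(phantom, plane, phase, verts = NULL,
                             n_vertices = 512L) {
  if (phantom$lambda == 0) {
    cont <- section(phantom, plane, phase, n_vertices = n_vertices)
    return(measure_contour(cont))
  }
  if (is.null(verts)) verts <- phantom_vertices(phantom, phase)
  seg <- mesh_plane_segments(verts, phantom$faces,
                             plane$origin, plane$normal, plane$u, plane$v)
  if (is.null(seg)) return(list(area = 0, long_axis_length = NA_real_, perimeter = 0))
  m <- segments_measures(seg)
  L <- NA_real_
  if (grepl("2ch|4ch", plane$label)) {
    d <- phantom$annulus_center - plane$origin
    lm <- c(sum(d * plane$u), sum(d * plane$v))
    L <- sqrt(max((seg$p[, 1] - lm[1])^2 + (seg$p[, 2] - lm[2])^2))
  }
  list(area = m$area, long_axis_length = L, perimeter = m$perimeter)
}

#' Write / read contours as CSV
#'
#' Long format with columns `label, phase, vertex_index, x_mm, y_mm` — also
#' the entry point for user-supplied (manually traced) contours.
#'
#' @param contours A list of `la_contour` objects.
#' @param path CSV file path.
#' @return `write_contours_csv` the path, invisibly; `read_contours_csv` a
#'   list of `la_contour` objects.
#' @export
write_contours_csv <- function(contours, path) {
  if (inherits(contours, "la_contour")) contours <- list(contours)
  rows <- lapply(contours, function(ct) {
    data.frame(label = ct$label, phase = ct$phase,
               vertex_index = seq_len(nrow(ct$vertices)),
               x_mm = ct$vertices[, 1], y_mm = ct$vertices[, 2])
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_contours_csv
#' @export
read_contours_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("label", "phase", "vertex_index", "x_mm", "y_mm")
  if (!all(need %in% names(df))) stop("contour CSV must have columns: ",
                                      paste(need, collapse = ", "))
  keys <- unique(df[, c("label", "phase")])
  lapply(seq_len(nrow(keys)), function(i) {
    sub <- df[df$label == keys$label[i] & df$phase == keys$phase[i], ]
    sub <- sub[order(sub$vertex_index), ]
    new_contour(cbind(sub$x_mm, sub$y_mm), keys$label[i], keys$phase[i])
  })
}
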