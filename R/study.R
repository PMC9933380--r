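## End-to-end simulated method-comparison study: seeded cohort -> three
## measurement protocols per subject -> volumes, strain, agreement and
## reclassification tables mirroring a clinical comparison of standard
## long-axis, LA-focused long-axis and short-axis reference imaging.

#' Study configuration
#'
#' @param cohort A `la_cohort_config` (see [cohort_config()]).
#' @param thickness Short-axis slice thickness, mm.
#' @param n_vertices Polygonization vertex count for analytic sections.
#' @return Object of class `la_study_config`.
#' @export
study_config <- function(cohort = cohort_config(), thickness = 6,
                         n_vertices = 512L) {
  stopifnot(inherits(cohort, "la_cohort_config"), thickness > 0)
  structure(list(cohort = cohort, thickness = thickness,
                 n_vertices = as.integer(n_vertices)),
            class = "la_study_config")
}

#' Measure one phantom with all three protocols
#'
#' Sections the phantom at every phase with the standard and LA-focused
#' long-axis plane pairs (biplane area-length volumes) and with the
#' short-axis stack (Simpson disk volumes), and computes perimeter-strain
#' curves for both long-axis view sets.
#'
#' @param phantom An `la_phantom`.
#' @param thickness Short-axis slice thickness, mm.
#' @param n_vertices Analytic polygonization vertex count.
#' @return List with `la_volume_series` entries `standard`, `focused`,
#'   `reference`, `la_strain` entries `strain_standard`, `strain_focused`,
#'   and the ground-truth series `truth`.
#' @export
measure_phantom <- function(phantom, thickness = 6, n_vertices = 512L) {
  std <- prescribe_standard_planes(phantom)
  foc <- prescribe_focused_planes(phantom)
  stack <- prescribe_short_axis_stack(phantom, thickness)
  np <- phantom$n_phases
  lax_planes <- c(std, foc)

  biplane_vol <- matrix(NA_real_, np, 2, dimnames = list(NULL, c("standard", "focused")))
  perims <- array(NA_real_, c(np, 4),
                  dimnames = list(NULL, c("standard_2ch", "standard_4ch",
                                          "focused_2ch", "focused_4ch")))
  disk_vol <- numeric(np)
  for (ph in seq_len(np)) {
    verts <- if (phantom$lambda > 0) phantom_vertices(phantom, ph) else NULL
    mm <- lapply(lax_planes, section_measures, phantom = phantom, phase = ph,
                 verts = verts, n_vertices = n_vertices)
    biplane_vol[ph, "standard"] <- biplane_area_length(
      mm$standard_4ch$area, mm$standard_2ch$area,
      mm$standard_4ch$long_axis_length, mm$standard_2ch$long_axis_length)
    biplane_vol[ph, "focused"] <- biplane_area_length(
      mm$focused_4ch$area, mm$focused_2ch$area,
      mm$focused_4ch$long_axis_length, mm$focused_2ch$long_axis_length)
    perims[ph, ] <- vapply(mm, `[[`, numeric(1), "perimeter")
    areas <- vapply(stack, function(pl)
      section_measures(phantom, pl, ph, verts = verts,
                       n_vertices = n_vertices)$area, numeric(1))
    disk_vol[ph] <- disk_volume(areas, thickness)
  }
  ref_frame <- phantom$events$mitral_closure
  pre_a <- phantom$events$pre_A
  list(
    standard = volume_series(biplane_vol[, "standard"], phantom$bsa, "standard"),
    focused = volume_series(biplane_vol[, "focused"], phantom$bsa, "focused"),
    reference = volume_series(disk_vol, phantom$bsa, "reference"),
    strain_standard = biview_strain(
      perimeter_strain(perims[, "standard_2ch"], ref_frame),
      perimeter_strain(perims[, "standard_4ch"], ref_frame), pre_a),
    strain_focused = biview_strain(
      perimeter_strain(perims[, "focused_2ch"], ref_frame),
      perimeter_strain(perims[, "focused_4ch"], ref_frame), pre_a),
    truth = phantom_volume_series(phantom)
  )
}

series_row <- function(subject, vs) {
  data.frame(subject = subject, method = vs$method,
             lavmax_ml = vs$lavmax_ml, lavmin_ml = vs$lavmin_ml,
             lavmax_i = vs$lavmax_i, lavmin_i = vs$lavmin_i,
             laef_pct = vs$laef, severity = as.character(vs$severity),
             max_frame = vs$max_frame, min_frame = vs$min_frame)
}

#' Run the full simulated method-comparison study
#'
#' Generates the seeded cohort, measures every phantom with the three
#' protocols, and assembles per-subject, summary, agreement,
#' reclassification and strain-comparison tables. Deterministic under a
#' fixed configuration; any per-subject failure aborts the run with the
#' subject id in the error.
#'
#' @param config A `la_study_config`.
#' @return Object of class `la_study_result`: `subjects`, `volumes`,
#'   `strain`, `summary`, `agreement`, `reclassification` (tables) plus the
#'   `la_reclassification` objects and the config.
#' @export
run_study <- function(config = study_config()) {
  stopifnot(inherits(config, "la_study_config"))
  phantoms <- sample_cohort(config$cohort)
  tab <- attr(phantoms, "table")
  vol_rows <- list(); strain_rows <- list()
  truth_lavmax <- truth_lavmin <- numeric(length(phantoms))
  for (i in seq_along(phantoms)) {
    m <- tryCatch(
      measure_phantom(phantoms[[i]], config$thickness, config$n_vertices),
      error = function(e) stop(sprintf("subject %d: %s", i, conditionMessage(e)),
                               call. = FALSE))
    vol_rows[[i]] <- rbind(series_row(i, m$reference),
                           series_row(i, m$standard),
                           series_row(i, m$focused))
    strain_rows[[i]] <- data.frame(
      subject = i, view_set = c("standard", "focused"),
      eps_s = c(m$strain_standard$eps_s, m$strain_focused$eps_s),
      eps_e = c(m$strain_standard$eps_e, m$strain_focused$eps_e),
      eps_a = c(m$strain_standard$eps_a, m$strain_focused$eps_a))
    truth_lavmax[i] <- max(m$truth) / 1000
    truth_lavmin[i] <- min(m$truth) / 1000
  }
  volumes <- do.call(rbind, vol_rows)
  strain <- do.call(rbind, strain_rows)
  tab$truth_lavmax_ml <- truth_lavmax
  tab$truth_lavmin_ml <- truth_lavmin

  metrics <- c("lavmax_ml", "lavmin_ml", "lavmax_i", "lavmin_i", "laef_pct")
  ref <- volumes[volumes$method == "reference", ]
  agr_rows <- list()
  for (meth in c("standard", "focused")) {
    mdf <- volumes[volumes$method == meth, ]
    for (met in metrics) {
      ba <- bland_altman(mdf[[met]], ref[[met]])
      agr_rows[[paste(meth, met)]] <- data.frame(
        method = meth, metric = met, n = ba$n, bias = ba$bias,
        sd_diff = ba$sd_diff, loa_low = ba$loa_low, loa_high = ba$loa_high,
        pearson_r = ba$pearson_r, r_squared = ba$r_squared)
    }
  }
  agreement <- do.call(rbind, agr_rows)
  rownames(agreement) <- NULL

  recl <- list(
    standard = reclassification(ref$severity,
                                volumes$severity[volumes$method == "standard"]),
    focused = reclassification(ref$severity,
                               volumes$severity[volumes$method == "focused"]))
  recl_tab <- do.call(rbind, lapply(names(recl), function(nm) {
    r <- recl[[nm]]
    data.frame(method = nm, n = r$n, n_changed = r$n_changed,
               pct_changed = r$pct_changed, up_1 = r$up_1,
               up_2plus = r$up_2plus, down_1 = r$down_1,
               down_2plus = r$down_2plus)
  }))

  qfun <- function(x) stats::quantile(x, c(0.5, 0.25, 0.75), names = FALSE)
  summ <- do.call(rbind, lapply(c("reference", "standard", "focused"), function(meth) {
    mdf <- volumes[volumes$method == meth, ]
    do.call(rbind, lapply(metrics, function(met) {
      q <- qfun(mdf[[met]])
      data.frame(method = meth, metric = met, median = q[1],
                 iqr_low = q[2], iqr_high = q[3])
    }))
  }))

  structure(list(subjects = tab, volumes = volumes, strain = strain,
                 summary = summ, agreement = agreement,
                 reclassification = recl_tab,
                 reclassification_objects = recl,
                 config = config),
            class = "la_study_result")
}

#' @export
print.la_study_result <- function(x, ...) {
  cat(sprintf("Simulated LA method-comparison study: n = %d subjects\n",
              x$config$cohort$n_subjects))
  cat("Agreement vs short-axis reference (bias [95% LOA]):\n")
  for (i in seq_len(nrow(x$agreement))) {
    a <- x$agreement[i, ]
    cat(sprintf("  %-8s %-10s %+6.2f [%+6.2f, %+6.2f]\n",
                a$method, a$metric, a$bias, a$loa_low, a$loa_high))
  }
  invisible(x)
}

#' Write study result tables and a manifest
#'
#' Writes `subjects.csv`, `volumes.csv`, `strain.csv`, `summary.csv`,
#' `agreement.csv`, `reclassification.csv` and `manifest.json` (config,
#' seed and per-file MD5 checksums) into `outdir`.
#'
#' @param result A `la_study_result`.
#' @param outdir Output directory (created if missing).
#' @return Invisibly, the named vector of file paths.
#' @export
write_study_outputs <- function(result, outdir) {
  stopifnot(inherits(result, "la_study_result"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(outdir, 2) != 0) stop("output directory is not writable: ", outdir)
  tables <- c("subjects", "volumes", "strain", "summary", "agreement",
              "reclassification")
  paths <- vapply(tables, function(nm) {
    p <- file.path(outdir, paste0(nm, ".csv"))
    utils::write.csv(result[[nm]], p, row.names = FALSE)
    p
  }, character(1))
  manifest <- list(
    package = "laquant",
    version = as.character(utils::packageVersion("laquant")),
    seed = result$config$cohort$seed,
    n_subjects = result$config$cohort$n_subjects,
    thickness_mm = result$config$thickness,
    config = result$config[c("thickness", "n_vertices")],
    cohort_config = unclass(result$config$cohort),
    checksums = as.list(stats::setNames(tools::md5sum(paths), basename(paths)))
  )
  mpath <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(paths, manifest = mpath))
}
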