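## Seeded synthetic cohorts of LA phantoms.
##
## The cohort emulates the statistical structure of a clinical CMR
## population: indexed maximal LA volumes spanning the four dilation-severity
## categories (log-normal around the reference median of 42 ml/m^2), emptying
## fractions around 52%, body surface areas around 1.88 +/- 0.21 m^2, and a
## per-subject tilt between the LV and LA long axes (truncated normal,
## mean 15 deg, SD 5 deg - a modelling choice, as the angular deviation of
## standard views is not reported in the clinical literature).

#' Cohort configuration
#'
#' Distribution parameters for [sample_cohort()]. All tunables live here;
#' identical configurations (including the seed) reproduce identical cohorts
#' bit-for-bit.
#'
#' @param n_subjects Cohort size.
#' @param seed Integer RNG seed.
#' @param tilt Tilt-angle distribution, degrees: `c(mean, sd)`, truncated at
#'   0.
#' @param lavmax_i Indexed LAVmax distribution, ml/m^2: log-normal with
#'   `c(median, sdlog)`.
#' @param laef_pct LAEF distribution, percent: `c(mean, sd)`, truncated to
#'   \[25, 72\].
#' @param bsa Body-surface-area distribution, m^2: `c(mean, sd)`, truncated
#'   at 1.2.
#' @param aspect Long/short semi-axis ratio `c/a`: `c(mean, sd)`, truncated
#'   at 1.15.
#' @param prea_fraction Pre-A volume position within \[LAVmin, LAVmax\]:
#'   `c(mean, sd)`, truncated to \[0.15, 0.65\].
#' @param lambda Roof-blunting factor applied to every subject.
#' @param n_phases Cardiac phases per cycle.
#' @param mesh_subdiv Icosphere subdivision level for subject meshes.
#' @return Object of class `la_cohort_config`.
#' @export
cohort_config <- function(n_subjects = 108L, seed = 1L,
                          tilt = c(mean = 15, sd = 5),
                          lavmax_i = c(median = 42, sdlog = 0.30),
                          laef_pct = c(mean = 52, sd = 9),
                          bsa = c(mean = 1.88, sd = 0.21),
                          aspect = c(mean = 1.6, sd = 0.15),
                          prea_fraction = c(mean = 0.40, sd = 0.05),
                          lambda = 0.5, n_phases = 25L, mesh_subdiv = 4L) {
  stopifnot(n_subjects >= 1L,
            tilt[["sd"]] >= 0, lavmax_i[["median"]] > 0, lavmax_i[["sdlog"]] >= 0,
            laef_pct[["mean"]] > 0, bsa[["mean"]] > 0, aspect[["mean"]] > 1,
            lambda >= 0, lambda <= 1)
  structure(list(n_subjects = as.integer(n_subjects), seed = as.integer(seed),
                 tilt = tilt, lavmax_i = lavmax_i, laef_pct = laef_pct,
                 bsa = bsa, aspect = aspect, prea_fraction = prea_fraction,
                 lambda = lambda, n_phases = as.integer(n_phases),
                 mesh_subdiv = as.integer(mesh_subdiv)),
            class = "la_cohort_config")
}

## Truncated normal via inverse-CDF of a uniform restricted to the
## admissible probability band - exact and deterministic under the seed.
rtrunc_norm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) return(rep(mean, n))
  p_lo <- stats::pnorm(lower, mean, sd)
  p_hi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, p_lo, p_hi), mean, sd)
}

#' Sample the per-subject parameter table of a cohort
#'
#' @param config A `la_cohort_config`.
#' @return data.frame with one row per subject: `subject`, `tilt_deg`,
#'   `lavmax_i`, `laef_pct`, `bsa`, `aspect`, `prea_fraction`, `lavmax_ml`,
#'   `lavmin_ml`, `lambda`, `n_phases`, `seed`.
#' @export
sample_cohort_table <- function(config) {
  stopifnot(inherits(config, "la_cohort_config"))
  n <- config$n_subjects
  set.seed(config$seed)
  tilt <- rtrunc_norm(n, config$tilt[["mean"]], config$tilt[["sd"]], lower = 0)
  lavmax_i <- exp(rtrunc_norm(n, log(config$lavmax_i[["median"]]),
                              config$lavmax_i[["sdlog"]]))
  laef <- rtrunc_norm(n, config$laef_pct[["mean"]], config$laef_pct[["sd"]],
                      lower = 25, upper = 72)
  bsa <- rtrunc_norm(n, config$bsa[["mean"]], config$bsa[["sd"]], lower = 1.2)
  aspect <- rtrunc_norm(n, config$aspect[["mean"]], config$aspect[["sd"]],
                        lower = 1.15)
  prea_f <- rtrunc_norm(n, config$prea_fraction[["mean"]],
                        config$prea_fraction[["sd"]],
                        lower = 0.15, upper = 0.65)
  lavmax_ml <- lavmax_i * bsa
  lavmin_ml <- lavmax_ml * (1 - laef / 100)
  data.frame(subject = seq_len(n), tilt_deg = tilt, lavmax_i = lavmax_i,
             laef_pct = laef, bsa = bsa, aspect = aspect,
             prea_fraction = prea_f, lavmax_ml = lavmax_ml,
             lavmin_ml = lavmin_ml, lambda = config$lambda,
             n_phases = config$n_phases, seed = config$seed)
}

## Phantom for one row of the cohort table.
phantom_from_row <- function(row, mesh_subdiv = 4L) {
  vmin <- row$lavmin_ml * 1000
  vmax <- row$lavmax_ml * 1000
  a <- (3 * vmin / (4 * pi * row$aspect))^(1 / 3)
  make_phantom(
    a = a, b = a, c = row$aspect * a, theta_deg = row$tilt_deg,
    volume_curve_params = list(
      lavmin = vmin, lavmax = vmax,
      prea = vmin + row$prea_fraction * (vmax - vmin)),
    lambda = row$lambda, n_phases = row$n_phases, bsa = row$bsa,
    mesh_subdiv = mesh_subdiv)
}

#' Generate a seeded cohort of LA phantoms
#'
#' A pure function of the configuration: the same config (and seed) yields
#' identical phantoms. Subject geometry is derived from the sampled table:
#' the reference (mitral-closure) ellipsoid volume equals LAVmin, the
#' long/short aspect ratio is sampled, and the volume curve passes through
#' LAVmin, LAVmax and the pre-A volume.
#'
#' @param config A `la_cohort_config`.
#' @return List of `la_phantom` objects with the parameter table attached as
#'   attribute `"table"`.
#' @export
sample_cohort <- function(config) {
  tab <- sample_cohort_table(config)
  phantoms <- lapply(seq_len(nrow(tab)), function(i)
    phantom_from_row(tab[i, ], mesh_subdiv = config$mesh_subdiv))
  attr(phantoms, "table") <- tab
  phantoms
}
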