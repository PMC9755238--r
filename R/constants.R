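# Default study parameters for the synthetic cohort generator.
#
# Values fall into two tiers:
#   * printed values: group means/SDs, age distributions, growth slopes and
#     covariance z-levels reported for the dHCP-based claustrum study the
#     generator emulates;
#   * free defaults: quantities the study does not report (inter-side
#     correlation, within-subject intercept SD, voxel noise, control-region
#     levels); these are labelled "free" below and documented in the
#     methods vignette.

#' Cohort specification
#'
#' Sample sizes and demographic distributions for a two-group
#' (preterm / term) neonatal cohort. Scan and birth ages are in weeks of
#' gestational age (GA).
#'
#' @param n_preterm,n_term subjects per group.
#' @param scan_age_mean,scan_age_sd named numeric (term, preterm), GA weeks.
#' @param birth_age_mean,birth_age_sd named numeric (term, preterm), GA weeks.
#'   Birth ages are truncated to <37 (preterm) and 37--42 (term).
#' @param age_window optional length-2 numeric; scan ages truncated to this
#'   GA window (the matched-comparison analysis window is 37.4--44.9).
#' @param sex_ratio fraction male.
#' @param long_age1_mean,long_age1_sd,long_age2_mean,long_age2_sd first/second
#'   scan-age distributions for the longitudinal generator.
#' @param intercept_sd within-subject random-intercept SD for longitudinal
#'   outcomes, as a fraction of the outcome's marginal SD (free default).
#' @return list of class \code{"cohort_spec"}.
#' @export
cohort_spec <- function(n_preterm = 83L, n_term = 83L,
                        scan_age_mean = c(term = 41.1, preterm = 41.1),
                        scan_age_sd = c(term = 1.7, preterm = 1.7),
                        birth_age_mean = c(term = 40.0, preterm = 32.0),
                        birth_age_sd = c(term = 1.2, preterm = 3.0),
                        age_window = c(37.4, 44.9),
                        sex_ratio = 0.5,
                        long_age1_mean = 34.3, long_age1_sd = 1.9,
                        long_age2_mean = 41.2, long_age2_sd = 1.5,
                        intercept_sd = 0.5) {
  stopifnot(n_preterm >= 0, n_term >= 0,
            all(scan_age_sd >= 0), all(birth_age_sd >= 0),
            sex_ratio >= 0, sex_ratio <= 1, intercept_sd >= 0)
  out <- list(n_preterm = as.integer(n_preterm), n_term = as.integer(n_term),
              scan_age_mean = scan_age_mean, scan_age_sd = scan_age_sd,
              birth_age_mean = birth_age_mean, birth_age_sd = birth_age_sd,
              age_window = age_window, sex_ratio = sex_ratio,
              long_age1_mean = long_age1_mean, long_age1_sd = long_age1_sd,
              long_age2_mean = long_age2_mean, long_age2_sd = long_age2_sd,
              intercept_sd = intercept_sd)
  class(out) <- "cohort_spec"
  out
}

#' Term-spectrum cohort specification
#'
#' Cross-sectional spectrum of term-born neonates (GA 38--45 scan window),
#' used for the context analyses of claustrum development.
#' @param n_term number of term subjects.
#' @return a \code{cohort_spec} with no preterm subjects.
#' @export
term_spectrum_spec <- function(n_term = 377L) {
  cohort_spec(n_preterm = 0L, n_term = n_term, age_window = c(38, 45))
}

#' Longitudinal preterm cohort specification
#' @param n_preterm number of preterm subjects scanned twice.
#' @return a \code{cohort_spec} with no term subjects.
#' @export
longitudinal_spec <- function(n_preterm = 53L) {
  cohort_spec(n_preterm = n_preterm, n_term = 0L, age_window = NULL)
}

#' Define a single generated outcome
#'
#' @param term_mean,term_sd,preterm_mean,preterm_sd group mean and marginal
#'   within-group SD. The SD is interpreted as the total within-group SD;
#'   the generator subtracts the variance explained by the scan-age slope
#'   to obtain the residual SD.
#' @param slope scan-age slope in outcome units per GA week (applies to both
#'   groups).
#' @return list describing the outcome.
#' @export
outcome_def <- function(term_mean, term_sd, preterm_mean, preterm_sd,
                        slope = 0) {
  stopifnot(term_sd >= 0, preterm_sd >= 0)
  list(mean = c(term = term_mean, preterm = preterm_mean),
       sd = c(term = term_sd, preterm = preterm_sd),
       slope = slope)
}

#' Effect parameters of the synthetic cohort
#'
#' Per-outcome group means, marginal SDs and scan-age slopes. Defaults are
#' the printed matched-cohort group values: per-side claustrum volumes
#' (mm^3), MD (10^-3 mm^2/s) and FA, with term-spectrum growth slopes
#' (volume 17.1/12.1 mm^3 per week right/left, MD -0.012/-0.014, FA
#' 0.0050/0.0060). Total brain volume and the control-region outcomes
#' (thalamus/caudate volume, GM MD/FA, insular cortex / lentiform / frame
#' FA) are free defaults at physiologically plausible neonatal levels.
#'
#' @param outcomes named list of \code{\link{outcome_def}}s; paired
#'   \code{*_right}/\code{*_left} outcomes are drawn jointly with inter-side
#'   correlation \code{rho_side}.
#' @param rho_side correlation between right and left values of paired
#'   outcomes (free default 0.85, chosen so the SD of the two-side mean of
#'   claustrum volume reproduces the printed combined SDs of 51/55 mm^3).
#' @return list of class \code{"effect_params"}.
#' @export
effect_params <- function(outcomes = default_outcomes(), rho_side = 0.85) {
  stopifnot(is.list(outcomes), length(names(outcomes)) == length(outcomes),
            abs(rho_side) < 1)
  out <- list(outcomes = outcomes, rho_side = rho_side)
  class(out) <- "effect_params"
  out
}

#' @rdname effect_params
#' @export
default_outcomes <- function() {
  list(
    # printed per-side matched-group values + term-spectrum slopes
    claustrum_volume_right = outcome_def(341, 51, 363, 58, slope = 17.1),
    claustrum_volume_left  = outcome_def(325, 55, 357, 56, slope = 12.1),
    claustrum_md_right     = outcome_def(1.08, 0.04, 1.09, 0.05,
                                         slope = -0.012),
    claustrum_md_left      = outcome_def(1.09, 0.05, 1.10, 0.04,
                                         slope = -0.014),
    claustrum_fa_right     = outcome_def(0.216, 0.026, 0.187, 0.028,
                                         slope = 0.0050),
    claustrum_fa_left      = outcome_def(0.219, 0.027, 0.199, 0.029,
                                         slope = 0.0060),
    # free defaults: TBV consistent with printed relative volumes
    # (sum of sides / relative volume ~ 3.56e5 term, 3.69e5 preterm)
    tbv = outcome_def(356000, 49000, 369000, 47000, slope = 9000),
    # free defaults: control regions (direction of printed group effects)
    thalamus_volume = outcome_def(8600, 900, 8100, 900, slope = 180),
    caudate_volume  = outcome_def(3900, 450, 3750, 450, slope = 80),
    gm_md       = outcome_def(1.15, 0.04, 1.17, 0.04, slope = -0.012),
    gm_fa       = outcome_def(0.150, 0.020, 0.140, 0.020, slope = 0.004),
    insular_fa  = outcome_def(0.160, 0.020, 0.150, 0.020, slope = 0.003),
    lentiform_fa = outcome_def(0.200, 0.025, 0.190, 0.025, slope = 0.004),
    frame_fa    = outcome_def(0.250, 0.030, 0.240, 0.030, slope = 0.005)
  )
}

#' Longitudinal effect parameters
#'
#' Growth slopes for the longitudinal preterm cohort; the mixed-model
#' estimates reported for preterm development (volume 16.6 mm^3/week,
#' relative volume -0.000026/week, MD -0.014, FA 0.0067). Anchor means are
#' the preterm matched-group values at GA 41.1.
#' @return named list of per-outcome slopes.
#' @export
longitudinal_slopes <- function() {
  c(claustrum_volume_right = 17.8, claustrum_volume_left = 15.1,
    claustrum_md_right = -0.014, claustrum_md_left = -0.015,
    claustrum_fa_right = 0.0062, claustrum_fa_left = 0.0071,
    tbv = 11000,
    thalamus_volume = 250, caudate_volume = 110,
    gm_md = -0.014, gm_fa = 0.005, insular_fa = 0.004,
    lentiform_fa = 0.005, frame_fa = 0.006)
}

#' Regional covariance specification
#'
#' Target region-claustrum correlations per tissue class, group and metric
#' for the one-factor regional generator. Default correlation levels are
#' tanh of the printed mean covariance z-scores per tissue class (right
#' claustrum): e.g. term MD cortical GM z = 0.40 -> rho = 0.380.
#'
#' @param regions data.frame(region, class); default
#'   \code{\link{covariance_regions}} (34 cortical GM, 12 subcortical GM,
#'   33 WM).
#' @param z named list \code{z[[metric]][[group]]} of per-class mean z
#'   values (classes cortical_gm, subcortical_gm, wm).
#' @param noise_sd per-region residual noise SD on the standardized scale
#'   (free default 1; the one-factor construction rescales so it does not
#'   affect the correlation).
#' @return list of class \code{"regional_cov_spec"}.
#' @export
regional_cov_spec <- function(regions = covariance_regions(),
                              z = default_cov_z(),
                              noise_sd = 1) {
  stopifnot(!anyDuplicated(regions$region),
            all(regions$class %in% c("cortical_gm", "subcortical_gm", "wm")))
  rho <- lapply(z, function(m) lapply(m, tanh))
  for (m in rho) for (g in m)
    if (any(abs(unlist(g)) >= 1)) stop("|rho| must be < 1")
  out <- list(regions = regions, z = z, rho = rho, noise_sd = noise_sd)
  class(out) <- "regional_cov_spec"
  out
}

#' @rdname regional_cov_spec
#' @export
default_cov_z <- function() {
  list(
    volume = list(
      term    = c(cortical_gm = 0.43, subcortical_gm = 0.59, wm = 0.43),
      preterm = c(cortical_gm = 0.44, subcortical_gm = 0.57, wm = 0.49)),
    relative_volume = list(
      term    = c(cortical_gm = -0.17, subcortical_gm = 0.24, wm = 0.09),
      preterm = c(cortical_gm = -0.15, subcortical_gm = 0.12, wm = 0.20)),
    md = list(
      term    = c(cortical_gm = 0.40, subcortical_gm = 1.03, wm = 0.99),
      preterm = c(cortical_gm = 0.08, subcortical_gm = 0.70, wm = 0.68)),
    fa = list(
      term    = c(cortical_gm = 0.17, subcortical_gm = 0.44, wm = 0.74),
      preterm = c(cortical_gm = 0.61, subcortical_gm = 0.72, wm = 0.89))
  )
}
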