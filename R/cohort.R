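# Synthetic cohort generation.
#
# Outcomes follow a Gaussian model per group:
#   y = group mean + slope * (scan age - group mean age) + residual
# where the residual SD is chosen so the *marginal* within-group SD equals
# the specified SD (slope-explained variance, computed from the realized
# scan-age draw, is subtracted). Right/left pairs of the same outcome are
# drawn jointly with inter-side correlation rho_side.

rtrunc_norm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (n == 0L) return(numeric(0))
  lo <- stats::pnorm(lower, mean, sd)
  hi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, lo, hi), mean, sd)
}

# split outcome names into side pairs (stem_right/stem_left) and singletons
outcome_pairs <- function(nms) {
  stems <- unique(sub("_(left|right)$", "", nms[grepl("_(left|right)$", nms)]))
  pairs <- list()
  for (s in stems) {
    r <- paste0(s, "_right"); l <- paste0(s, "_left")
    if (r %in% nms && l %in% nms) pairs[[s]] <- c(right = r, left = l)
  }
  singles <- setdiff(nms, unlist(pairs))
  list(pairs = pairs, singles = singles)
}

draw_outcome_values <- function(def, group, scan_age, z) {
  mu <- def$mean[[group]]
  sd_tot <- def$sd[[group]]
  age_c <- scan_age - mean(scan_age)
  expl <- def$slope^2 * stats::var(age_c) * (length(age_c) > 1)
  if (is.na(expl)) expl <- 0
  resid_var <- sd_tot^2 - expl
  if (resid_var < 0)
    stop("outcome SD ", sd_tot, " too small for slope ", def$slope,
         " given the scan-age spread (residual variance negative)")
  mu + def$slope * age_c + sqrt(resid_var) * z
}

draw_demographics <- function(spec, group, n) {
  # scan age keeps its printed marginal (truncated to the analysis
  # window); birth age is then drawn conditionally below the scan age
  win <- if (is.null(spec$age_window)) c(-Inf, Inf) else spec$age_window
  sa <- rtrunc_norm(n, spec$scan_age_mean[[group]],
                    spec$scan_age_sd[[group]], win[1], win[2])
  if (group == "preterm") {
    ba <- rtrunc_norm(n, spec$birth_age_mean[["preterm"]],
                      spec$birth_age_sd[["preterm"]], 24,
                      pmin(36.99, sa))
  } else {
    ba <- rtrunc_norm(n, spec$birth_age_mean[["term"]],
                      spec$birth_age_sd[["term"]], 37, pmin(42, sa))
  }
  sex <- ifelse(stats::runif(n) < spec$sex_ratio, "male", "female")
  data.frame(group = group, birth_age = ba, scan_age = sa, sex = sex,
             stringsAsFactors = FALSE)
}

add_derived_columns <- function(df) {
  has <- function(x) x %in% names(df)
  if (has("claustrum_volume_left") && has("claustrum_volume_right")) {
    df$claustrum_volume_mean <- combine_sides(df$claustrum_volume_left,
                                              df$claustrum_volume_right)
    if (has("tbv")) {
      rel <- relative_volume(df$claustrum_volume_left,
                             df$claustrum_volume_right, df$tbv)
      df$relative_volume_left <- rel$left
      df$relative_volume_right <- rel$right
      df$relative_volume_total <- rel$total
    }
  }
  for (m in c("md", "fa")) {
    l <- paste0("claustrum_", m, "_left"); r <- paste0("claustrum_", m, "_right")
    if (has(l) && has(r))
      df[[paste0("claustrum_", m, "_mean")]] <- combine_sides(df[[l]], df[[r]])
  }
  if (has("thalamus_volume") && has("tbv"))
    df$thalamus_relative <- df$thalamus_volume / df$tbv
  if (has("caudate_volume") && has("tbv"))
    df$caudate_relative <- df$caudate_volume / df$tbv
  df
}

draw_group_outcomes <- function(demo, effects) {
  n <- nrow(demo)
  grp <- demo$group[1]
  parts <- outcome_pairs(names(effects$outcomes))
  rho <- effects$rho_side
  out <- list()
  for (stem in names(parts$pairs)) {
    pr <- parts$pairs[[stem]]
    z1 <- stats::rnorm(n)
    z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
    out[[pr[["right"]]]] <- draw_outcome_values(
      effects$outcomes[[pr[["right"]]]], grp, demo$scan_age, z1)
    out[[pr[["left"]]]] <- draw_outcome_values(
      effects$outcomes[[pr[["left"]]]], grp, demo$scan_age, z2)
  }
  for (nm in parts$singles) {
    out[[nm]] <- draw_outcome_values(effects$outcomes[[nm]], grp,
                                     demo$scan_age, stats::rnorm(n))
  }
  cbind(demo, as.data.frame(out))
}

#' Generate a cross-sectional synthetic cohort
#'
#' One row per subject with demographics (group, birth age, scan age, sex)
#' and drawn ROI outcomes. See \code{\link{effect_params}} for the outcome
#' model. Fully deterministic given the seed.
#'
#' @param spec a \code{\link{cohort_spec}}.
#' @param effects an \code{\link{effect_params}}.
#' @param seed integer RNG seed.
#' @return \code{data.frame} with one row per subject.
#' @export
generate_cohort <- function(spec, effects = effect_params(), seed = 1L) {
  set.seed(seed)
  groups <- list()
  if (spec$n_term > 0L)
    groups$term <- draw_group_outcomes(
      draw_demographics(spec, "term", spec$n_term), effects)
  if (spec$n_preterm > 0L)
    groups$preterm <- draw_group_outcomes(
      draw_demographics(spec, "preterm", spec$n_preterm), effects)
  df <- do.call(rbind, groups)
  rownames(df) <- NULL
  df <- cbind(subject_id = sprintf("sub-%04d", seq_len(nrow(df))),
              session_id = "ses-1", df, stringsAsFactors = FALSE)
  df <- add_derived_columns(df)
  stopifnot(all(df$scan_age >= df$birth_age),
            all(df$birth_age[df$group == "preterm"] < 37))
  df
}

#' Generate a longitudinal synthetic cohort
#'
#' Two sessions per preterm subject sharing a subject-level random
#' intercept. Scan ages are drawn from the first/second-scan distributions
#' of \code{spec} (pairs with second age not above the first are resampled,
#' up to 100 retries). Outcomes follow
#' \code{anchor + slope * (age - ref_age) + b_i + e_ij} with
#' \code{sd(b_i) = f * SD} and \code{sd(e) = SD * sqrt(1 - f^2)}, where
#' \code{f = spec$intercept_sd} and SD is the outcome's marginal
#' within-group SD, so the cross-sectional SD at fixed age is preserved.
#'
#' @param spec a \code{\link{cohort_spec}}; \code{n_preterm} subjects are
#'   generated, each scanned twice.
#' @param effects an \code{\link{effect_params}}; preterm means anchor the
#'   trajectories at \code{ref_age}.
#' @param slopes named per-outcome growth slopes (units/week); defaults to
#'   \code{\link{longitudinal_slopes}} where named, else the cross-sectional
#'   slope of \code{effects}.
#' @param ref_age GA week at which the anchor mean applies.
#' @param seed integer RNG seed.
#' @return \code{data.frame}, two rows per subject (sessions 1 and 2).
#' @export
generate_longitudinal_cohort <- function(spec, effects = effect_params(),
                                         slopes = longitudinal_slopes(),
                                         ref_age = 41.1, seed = 1L) {
  set.seed(seed)
  n <- spec$n_preterm
  if (n <= 0L) stop("longitudinal cohort needs n_preterm > 0")
  a1 <- stats::rnorm(n, spec$long_age1_mean, spec$long_age1_sd)
  a2 <- stats::rnorm(n, spec$long_age2_mean, spec$long_age2_sd)
  for (try in 1:100) {
    bad <- which(a2 <= a1)
    if (!length(bad)) break
    a2[bad] <- stats::rnorm(length(bad), spec$long_age2_mean,
                            spec$long_age2_sd)
  }
  if (any(a2 <= a1))
    stop("could not sample second scan ages above first scan ages")
  ba <- rtrunc_norm(n, spec$birth_age_mean[["preterm"]],
                    spec$birth_age_sd[["preterm"]], 24,
                    pmin(36.99, a1))
  sex <- ifelse(stats::runif(n) < spec$sex_ratio, "male", "female")
  f <- spec$intercept_sd
  stopifnot(f >= 0, f < 1)

  subj <- sprintf("sub-%04d", seq_len(n))
  long <- data.frame(
    subject_id = rep(subj, each = 2L),
    session_id = rep(c("ses-1", "ses-2"), times = n),
    session = rep(1:2, times = n),
    group = "preterm",
    birth_age = rep(ba, each = 2L),
    scan_age = as.vector(rbind(a1, a2)),
    sex = rep(sex, each = 2L),
    stringsAsFactors = FALSE)

  for (nm in names(effects$outcomes)) {
    def <- effects$outcomes[[nm]]
    slope <- if (nm %in% names(slopes)) slopes[[nm]] else def$slope
    sd_tot <- def$sd[["preterm"]]
    b <- rep(stats::rnorm(n, 0, f * sd_tot), each = 2L)
    e <- stats::rnorm(2L * n, 0, sd_tot * sqrt(1 - f^2))
    long[[nm]] <- def$mean[["preterm"]] +
      slope * (long$scan_age - ref_age) + b + e
  }
  add_derived_columns(long)
}
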