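# Regional metric tables for structural covariance analysis.
#
# Each region column is built from the (standardized) claustrum column by a
# one-factor model,
#   region = mean + sd * (lambda * z_claustrum + sqrt(1 - lambda^2) * eps),
# with loading lambda equal to the target region-claustrum correlation rho,
# so the population correlation between region and claustrum equals rho.

# cohort column holding the claustrum value for a metric and side
claustrum_column <- function(metric, side) {
  switch(metric,
         volume = paste0("claustrum_volume_", side),
         relative_volume = paste0("relative_volume_", side),
         md = paste0("claustrum_md_", side),
         fa = paste0("claustrum_fa_", side),
         stop("unknown metric: ", metric))
}

# free-default location/scale per metric for region columns (irrelevant to
# the correlation structure)
.region_scale <- list(
  volume = c(mean = 5000, sd = 600),
  relative_volume = c(mean = 0.014, sd = 0.002),
  md = c(mean = 1.20, sd = 0.05),
  fa = c(mean = 0.20, sd = 0.02))

#' Generate a regional metric table
#'
#' Per subject and metric: the claustrum value (copied from the cohort
#' table) plus one column per region, constructed by the one-factor model
#' so each region's population correlation with the claustrum equals the
#' class-level rho of \code{cov_spec} for the subject's group.
#'
#' @param cov_spec a \code{\link{regional_cov_spec}}.
#' @param cohort cohort table from \code{\link{generate_cohort}}.
#' @param metrics metrics to generate (subset of volume, relative_volume,
#'   md, fa).
#' @param side claustrum side the regions covary with.
#' @param seed integer RNG seed.
#' @return \code{data.frame}: subject_id, group, then
#'   \code{claustrum_<metric>} and \code{<region>_<metric>} columns.
#' @export
generate_regional_table <- function(cov_spec, cohort,
                                    metrics = c("volume", "relative_volume",
                                                "md", "fa"),
                                    side = "right", seed = 1L) {
  stopifnot(nrow(cohort) > 0)
  set.seed(seed)
  regions <- cov_spec$regions
  out <- cohort[, c("subject_id", "group")]
  for (metric in metrics) {
    cla <- cohort[[claustrum_column(metric, side)]]
    if (is.null(cla)) stop("cohort lacks claustrum column for ", metric)
    out[[paste0("claustrum_", metric)]] <- cla
    sc <- .region_scale[[metric]]
    vals <- matrix(NA_real_, nrow(cohort), nrow(regions))
    for (g in unique(cohort$group)) {
      idx <- which(cohort$group == g)
      zc <- as.numeric(scale(cla[idx]))
      for (j in seq_len(nrow(regions))) {
        rho <- cov_spec$rho[[metric]][[g]][[regions$class[j]]]
        if (abs(rho) >= 1) stop("|rho| must be < 1")
        eps <- stats::rnorm(length(idx))
        vals[idx, j] <- sc[["mean"]] +
          sc[["sd"]] * (rho * zc + sqrt(1 - rho^2) * eps)
      }
    }
    colnames(vals) <- paste0(regions$region, "_", metric)
    out <- cbind(out, as.data.frame(vals))
  }
  rownames(out) <- NULL
  out
}

#' Region columns of a regional table
#' @param table a regional table.
#' @param metric metric name.
#' @param regions region data.frame (default \code{\link{covariance_regions}}).
#' @return character vector of column names.
#' @export
regional_columns <- function(table, metric,
                             regions = covariance_regions()) {
  cols <- paste0(regions$region, "_", metric)
  cols[cols %in% names(table)]
}
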