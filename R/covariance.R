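#' Fisher r-to-z transformation
#'
#' @param r correlation coefficient(s), |r| < 1.
#' @return z = atanh(r).
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1, na.rm = TRUE))
    stop("|r| must be < 1 for the Fisher transformation")
  atanh(r)
}

# clamp sample correlations away from +/-1 before transforming; returns
# the clamped vector with attribute n_clamped
clamp_r <- function(r, eps = 1e-7) {
  out_of_range <- !is.na(r) & abs(r) >= 1 - eps
  if (any(out_of_range)) {
    warning("clamped ", sum(out_of_range), " correlation(s) to +/-(1-",
            format(eps), ")")
    r[out_of_range] <- sign(r[out_of_range]) * (1 - eps)
  }
  structure(r, n_clamped = sum(out_of_range))
}

#' Per-region Pearson correlations with the claustrum
#'
#' Pearson r between the claustrum column and each region column of a
#' regional table, on pairwise-complete observations. Zero-variance
#' columns yield \code{NA} for that region.
#'
#' @param table regional table (one row per subject).
#' @param metric metric name (selects columns \code{claustrum_<metric>}
#'   and \code{<region>_<metric>}).
#' @param regions region data.frame (region, class).
#' @return named numeric vector of correlations, one per region.
#' @export
region_claustrum_correlations <- function(table, metric,
                                          regions = covariance_regions()) {
  cla <- table[[paste0("claustrum_", metric)]]
  if (is.null(cla)) stop("table lacks column claustrum_", metric)
  if (sum(stats::complete.cases(cla)) < 4L)
    stop("need at least 4 complete subject rows")
  cols <- paste0(regions$region, "_", metric)
  missing_cols <- setdiff(cols, names(table))
  if (length(missing_cols))
    stop("table lacks region column(s): ",
         paste(utils::head(missing_cols, 5), collapse = ", "))
  r <- vapply(cols, function(cn) {
    x <- table[[cn]]
    ok <- !is.na(x) & !is.na(cla)
    if (sum(ok) < 4L || stats::sd(x[ok]) == 0 || stats::sd(cla[ok]) == 0)
      return(NA_real_)
    stats::cor(cla[ok], x[ok])
  }, numeric(1))
  stats::setNames(r, regions$region)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment; order-preserving and never
#' below the raw p-value.
#'
#' @param p_values numeric vector in [0, 1] (NA allowed).
#' @return q-values of the same length.
#' @export
bh_fdr <- function(p_values) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1))
    stop("p-values must lie in [0, 1]")
  q <- p_values
  q[ok] <- stats::p.adjust(p_values[ok], method = "BH")
  q
}

#' Compare structural covariance between groups
#'
#' Per region: Pearson correlation with the claustrum in each group,
#' Fisher r-to-z, two-independent-sample z test
#' \deqn{Z = (z_{PT} - z_{FT}) / \sqrt{1/(n_{PT}-3) + 1/(n_{FT}-3)},}
#' two-sided normal p, and Benjamini-Hochberg q across the regions of this
#' (metric, side) family. Sample correlations are clamped to
#' +/-(1 - 1e-7) before the transformation (with a warning).
#'
#' @param term_table,preterm_table regional tables with identical region
#'   sets (group sizes >= 4).
#' @param metric metric name.
#' @param regions region data.frame (region, class).
#' @param q_threshold significance threshold on q (default 0.05).
#' @return data.frame of class \code{"covariance_comparison"}: region,
#'   class, r and z per group, z-difference statistic, p, q, significant.
#' @export
compare_covariance <- function(term_table, preterm_table, metric,
                               regions = covariance_regions(),
                               q_threshold = 0.05) {
  cols <- function(tab) sort(regional_columns(tab, metric, regions))
  ct <- cols(term_table); cp <- cols(preterm_table)
  if (!identical(ct, cp)) {
    diff <- union(setdiff(ct, cp), setdiff(cp, ct))
    stop("region set mismatch between groups: ",
         paste(utils::head(diff, 10), collapse = ", "))
  }
  n_t <- nrow(term_table); n_p <- nrow(preterm_table)
  if (n_t < 4L || n_p < 4L) stop("need at least 4 subjects per group")
  r_t <- clamp_r(region_claustrum_correlations(term_table, metric, regions))
  r_p <- clamp_r(region_claustrum_correlations(preterm_table, metric,
                                               regions))
  z_t <- fisher_z(as.numeric(r_t))
  z_p <- fisher_z(as.numeric(r_p))
  se <- sqrt(1 / (n_p - 3) + 1 / (n_t - 3))
  zdiff <- (z_p - z_t) / se
  p <- 2 * stats::pnorm(-abs(zdiff))
  q <- bh_fdr(p)
  out <- data.frame(region = regions$region, class = regions$class,
                    metric = metric,
                    r_term = as.numeric(r_t), r_preterm = as.numeric(r_p),
                    z_term = z_t, z_preterm = z_p,
                    z_diff = zdiff, p = p, q = q,
                    significant = !is.na(q) & q < q_threshold,
                    stringsAsFactors = FALSE)
  attr(out, "n_term") <- n_t
  attr(out, "n_preterm") <- n_p
  attr(out, "n_clamped") <- attr(r_t, "n_clamped") +
    attr(r_p, "n_clamped")
  class(out) <- c("covariance_comparison", "data.frame")
  out
}

#' Tissue-class summary of covariance z-scores
#'
#' Per tissue class and group: mean and SD of the Fisher z values across
#' the class's regions, plus the count of regions with significant group
#' differences over the class total (the "n_sig/n_total" convention).
#'
#' @param entries a \code{covariance_comparison} (one metric/side family).
#' @return data.frame: class, group, mean_z, sd_z, n_significant, n_total.
#' @export
tissue_summary <- function(entries) {
  if (any(!entries$class %in% c("cortical_gm", "subcortical_gm", "wm")))
    stop("entries contain regions without a tissue class")
  classes <- unique(entries$class)
  rows <- list()
  for (cl in classes) {
    e <- entries[entries$class == cl, ]
    for (g in c("term", "preterm")) {
      z <- e[[paste0("z_", g)]]
      rows[[paste(cl, g)]] <- data.frame(
        class = cl, group = g, metric = e$metric[1],
        mean_z = mean(z, na.rm = TRUE), sd_z = stats::sd(z),
        n_significant = sum(e$significant, na.rm = TRUE),
        n_total = nrow(e), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
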