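#' Paired t-test between first and second scans
#'
#' Standard paired t-test on within-subject differences (second minus
#' first), two-sided.
#'
#' @param first,second numeric vectors of equal length, paired by subject.
#' @return list of class \code{"paired_test"}: t statistic, df, two-sided
#'   p, mean difference, number of pairs.
#' @export
paired_t <- function(first, second) {
  if (length(first) != length(second))
    stop("first and second must have equal length")
  if (length(first) < 2L) stop("need at least 2 pairs")
  diffs <- second - first
  if (stats::sd(diffs) == 0)
    stop("zero-variance differences; paired t undefined")
  ht <- stats::t.test(second, first, paired = TRUE)
  structure(list(t = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value, mean_difference = unname(ht$estimate),
                 n_pairs = length(first)),
            class = "paired_test")
}

#' @method print paired_test
#' @export
print.paired_test <- function(x, ...) {
  cat(sprintf("paired t-test: t = %.3f, df = %d, p = %.3g, mean diff = %.4g (n = %d pairs)\n",
              x$t, x$df, x$p, x$mean_difference, x$n_pairs))
  invisible(x)
}

#' Random-intercept linear mixed model
#'
#' Linear mixed model with a single random intercept per subject, fitted
#' by restricted maximum likelihood via \pkg{lme4}. Fixed-effect p-values
#' are Wald tests against the standard normal (no small-sample df
#' correction).
#'
#' @param table data.frame in long format.
#' @param outcome outcome column name.
#' @param fixed_terms fixed-effect column names (sex, if present, is coded
#'   female = 0 / male = 1).
#' @param subject_col column identifying subjects.
#' @return list of class \code{"mixed_model"}: fixed-effect table
#'   (estimate, se, t, p), random-intercept SD/variance, residual
#'   SD/variance, n observations, n subjects.
#' @export
fit_random_intercept_model <- function(table, outcome,
                                       fixed_terms = c("scan_age",
                                                       "birth_age", "sex"),
                                       subject_col = "subject_id") {
  need <- c(outcome, fixed_terms, subject_col)
  missing_cols <- setdiff(need, names(table))
  if (length(missing_cols))
    stop("column(s) not in table: ", paste(missing_cols, collapse = ", "))
  dat <- table[stats::complete.cases(table[, need, drop = FALSE]),
               need, drop = FALSE]
  if ("sex" %in% names(dat))
    dat$sex <- code_binary(dat$sex, c("female", "male"))
  fml <- stats::as.formula(paste(outcome, "~",
                                 paste(fixed_terms, collapse = " + "),
                                 "+ (1 |", subject_col, ")"))
  fit <- tryCatch(
    lme4::lmer(fml, data = dat, REML = TRUE,
               control = lme4::lmerControl(
                 check.conv.singular = "ignore",
                 check.nobs.vs.nlev = "ignore",
                 check.nobs.vs.nRE = "ignore")),
    error = function(e) stop("mixed model failed to converge: ",
                             conditionMessage(e)))
  sm <- summary(fit)$coefficients
  vc <- as.data.frame(lme4::VarCorr(fit))
  ri_var <- vc$vcov[vc$grp == subject_col]
  res_var <- vc$vcov[vc$grp == "Residual"]
  fe <- data.frame(term = rownames(sm), estimate = sm[, "Estimate"],
                   se = sm[, "Std. Error"], t = sm[, "t value"],
                   p = 2 * stats::pnorm(-abs(sm[, "t value"])),
                   stringsAsFactors = FALSE)
  rownames(fe) <- NULL
  structure(list(fixed = fe,
                 intercept_sd = sqrt(ri_var), intercept_var = ri_var,
                 residual_sd = sqrt(res_var), residual_var = res_var,
                 n_obs = nrow(dat),
                 n_subjects = length(unique(dat[[subject_col]])),
                 outcome = outcome),
            class = "mixed_model")
}

#' @method print mixed_model
#' @export
print.mixed_model <- function(x, digits = 4, ...) {
  cat("random-intercept model for '", x$outcome, "' (", x$n_obs,
      " obs, ", x$n_subjects, " subjects)\n", sep = "")
  print(format(x$fixed, digits = digits), row.names = FALSE)
  cat(sprintf("random intercept SD = %.4g, residual SD = %.4g\n",
              x$intercept_sd, x$residual_sd))
  invisible(x)
}

#' Match term-born controls to preterm subjects by scan age
#'
#' Greedy minimal scan-age-gap matching: preterm subjects are processed in
#' ascending scan age (ties broken by id); each receives the not yet used
#' term-born subject with the smallest absolute scan-age gap (ties: the
#' smaller term scan age, then the smaller id). Deterministic and
#' independent of input row order; each control is used at most once.
#'
#' @param preterm_rows,term_rows data.frames with columns
#'   \code{subject_id} and \code{scan_age}.
#' @return list of class \code{"match_result"}: \code{pairs} (data.frame
#'   preterm_id, term_id, preterm_age, term_age, gap) and
#'   \code{unmatched_terms}.
#' @export
match_controls <- function(preterm_rows, term_rows) {
  if (nrow(term_rows) < nrow(preterm_rows))
    stop("term pool (", nrow(term_rows), ") smaller than preterm group (",
         nrow(preterm_rows), ")")
  rng <- range(term_rows$scan_age)
  if (any(preterm_rows$scan_age < rng[1] | preterm_rows$scan_age > rng[2]))
    warning("some preterm scan ages lie outside the term scan-age range")
  pt <- preterm_rows[order(preterm_rows$scan_age, preterm_rows$subject_id), ]
  pool <- term_rows[order(term_rows$scan_age, term_rows$subject_id), ]
  used <- rep(FALSE, nrow(pool))
  pairs <- vector("list", nrow(pt))
  for (i in seq_len(nrow(pt))) {
    gap <- abs(pool$scan_age - pt$scan_age[i])
    gap[used] <- Inf
    # smallest gap, ties by smaller term scan age then smaller id: the
    # pool is sorted that way, so the first minimum wins
    j <- which.min(gap)
    used[j] <- TRUE
    pairs[[i]] <- data.frame(preterm_id = pt$subject_id[i],
                             term_id = pool$subject_id[j],
                             preterm_age = pt$scan_age[i],
                             term_age = pool$scan_age[j],
                             gap = gap[j], stringsAsFactors = FALSE)
  }
  structure(list(pairs = do.call(rbind, pairs),
                 unmatched_terms = pool$subject_id[!used]),
            class = "match_result")
}

#' @method print match_result
#' @export
print.match_result <- function(x, ...) {
  cat("matched", nrow(x$pairs), "preterm subjects; mean |gap| =",
      signif(mean(x$pairs$gap), 3), "weeks;",
      length(x$unmatched_terms), "controls unused\n")
  invisible(x)
}
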