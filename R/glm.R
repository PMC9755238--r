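#' Partial eta-squared for a 1-df model term
#'
#' Effect-size share of variance attributable to a single-df term, net of
#' the other terms: t^2 / (t^2 + df), equivalent to
#' SS_term / (SS_term + SS_resid).
#'
#' @param t t statistic of the term.
#' @param df residual degrees of freedom (> 0).
#' @return partial eta-squared in [0, 1].
#' @export
partial_eta_squared <- function(t, df) {
  if (any(df <= 0)) stop("df must be positive")
  t^2 / (t^2 + df)
}

# design coding used throughout: group term = 0, preterm = 1; sex
# female = 0, male = 1
code_binary <- function(x, levels) {
  x <- as.character(x)
  bad <- setdiff(unique(x[!is.na(x)]), levels)
  if (length(bad))
    stop("unexpected level(s): ", paste(bad, collapse = ", "))
  as.numeric(x == levels[2])
}

build_design <- function(table, outcome, group, covariates) {
  preds <- c(if (!is.null(group)) group, covariates)
  if (outcome %in% preds) stop("outcome cannot also be a predictor")
  missing_cols <- setdiff(c(outcome, preds), names(table))
  if (length(missing_cols))
    stop("column(s) not in table: ", paste(missing_cols, collapse = ", "))
  df <- table[, c(outcome, preds), drop = FALSE]
  if (!is.null(group)) df[[group]] <- code_binary(df[[group]],
                                                  c("term", "preterm"))
  if ("sex" %in% names(df)) df$sex <- code_binary(df$sex,
                                                  c("female", "male"))
  keep <- stats::complete.cases(df)
  list(data = df[keep, , drop = FALSE], n_dropped = sum(!keep),
       preds = preds)
}

#' Fit a general linear model with per-term partial eta-squared
#'
#' Ordinary least squares with an optional categorical group term (coded
#' term = 0, preterm = 1) and continuous/binary covariates (sex coded
#' female = 0, male = 1). Rows with missing values in the used columns are
#' dropped with a recorded count. Per-term partial eta-squared is
#' t^2 / (t^2 + df_resid).
#'
#' @param table data.frame of subject rows.
#' @param outcome outcome column name.
#' @param group group column name, or NULL for no group term.
#' @param covariates further predictor column names.
#' @return object of class \code{"claustrum_glm"}: coefficient table
#'   (estimate, se, t, p, partial eta-squared per term), residual df, n,
#'   dropped-row count.
#' @export
fit_glm <- function(table, outcome, group = "group",
                    covariates = c("scan_age", "sex")) {
  d <- build_design(table, outcome, group, covariates)
  dat <- d$data
  p <- length(d$preds) + 1L
  if (nrow(dat) <= p + 1L)
    stop("too few complete rows (", nrow(dat), ") for ", p, " parameters")
  X <- cbind(`(Intercept)` = 1,
             as.matrix(dat[, d$preds, drop = FALSE]))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop_idx <- qrX$pivot[seq(qrX$rank + 1L, ncol(X))]
    stop("rank-deficient design; collinear term(s): ",
         paste(colnames(X)[drop_idx], collapse = ", "))
  }
  fit <- stats::lm.fit(X, dat[[outcome]])
  df_resid <- nrow(dat) - ncol(X)
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / df_resid
  XtXinv <- chol2inv(qr.R(qrX))
  se <- sqrt(diag(XtXinv) * sigma2)
  tval <- fit$coefficients / se
  pval <- 2 * stats::pt(-abs(tval), df_resid)
  coefs <- data.frame(
    term = colnames(X),
    estimate = unname(fit$coefficients),
    se = unname(se), t = unname(tval), p = unname(pval),
    partial_eta2 = unname(partial_eta_squared(tval, df_resid)),
    stringsAsFactors = FALSE)
  structure(list(coefficients = coefs, df_resid = df_resid,
                 n = nrow(dat), n_dropped = d$n_dropped,
                 outcome = outcome, sigma = sqrt(sigma2),
                 rss = rss, fitted = fit$fitted.values,
                 residuals = fit$residuals),
            class = "claustrum_glm")
}

#' @method coef claustrum_glm
#' @export
coef.claustrum_glm <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}

#' @method print claustrum_glm
#' @export
print.claustrum_glm <- function(x, digits = 4, ...) {
  cat("GLM for '", x$outcome, "' (n = ", x$n,
      if (x$n_dropped) paste0(", ", x$n_dropped, " rows dropped"),
      ", residual df = ", x$df_resid, ")\n", sep = "")
  print(format(x$coefficients, digits = digits), row.names = FALSE)
  invisible(x)
}

#' @method summary claustrum_glm
#' @export
summary.claustrum_glm <- function(object, ...) object

# convenience accessor: one term's row from a fitted GLM
glm_term <- function(fit, term) {
  i <- match(term, fit$coefficients$term)
  if (is.na(term) || is.na(i)) stop("term not in model: ", term)
  fit$coefficients[i, ]
}
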