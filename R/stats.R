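#' Pearson product-moment correlation with t-based p-value
#'
#' Implements the product-moment formula directly and converts r to a
#' Student-t statistic, `t = r * sqrt((n-2)/(1-r^2))`, on `n - 2` degrees of
#' freedom. Behavioural validation correlations (e.g. CWF vs #CIU) are
#' conventionally two-tailed; directional tract analyses may request
#' one-tailed (see [partial_correlation()]).
#'
#' @param x,y numeric vectors of equal length (>= 3), neither constant.
#' @param tails `"two"` (default) or `"one"` (one-tailed in the direction of
#'   the observed r).
#' @return object of class `correlation_result`: list with `r`, `n`, `df`,
#'   `p`, `tails`, `controlled` (empty here).
#' @export
pearson <- function(x, y, tails = c("two", "one")) {
  tails <- match.arg(tails)
  if (length(x) != length(y)) stop_invalid("x and y must have equal length")
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop_invalid("need at least 3 complete observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_invalid("undefined correlation: constant input")
  xc <- x - mean(x); yc <- y - mean(y)
  r <- sum(xc * yc) / sqrt(sum(xc^2) * sum(yc^2))
  correlation_result(r, n, n - 2L, tails, character())
}

correlation_result <- function(r, n, df, tails, controlled) {
  r <- max(-1, min(1, r))
  tstat <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  p_one <- stats::pt(abs(tstat), df, lower.tail = FALSE)
  p <- if (tails == "two") 2 * p_one else p_one
  structure(list(r = r, n = n, df = df, p = min(p, 1), tails = tails,
                 controlled = controlled),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  ctl <- if (length(x$controlled))
    paste0(" | ", paste(x$controlled, collapse = ", ")) else ""
  cat(sprintf("r = %.3f%s (n = %d, df = %d, %s-tailed p = %.4g)\n",
              x$r, ctl, x$n, x$df, x$tails, x$p))
  invisible(x)
}

#' Partial correlation by residualization
#'
#' Residualizes `x` and `y` on the covariate matrix (with intercept) by
#' least squares and returns the Pearson correlation of the residuals on
#' `n - 2 - n_covariates` degrees of freedom. With an empty or constant
#' covariate set this reduces exactly to [pearson()].
#'
#' The tract lesion-load analyses default to one-tailed tests in the
#' negative (damage worsens performance) direction: back-computing the t
#' transform from the published tract correlations is consistent with
#' one-tailed, not two-tailed, testing.
#'
#' @param x,y numeric vectors.
#' @param covariates numeric matrix/data.frame (rows aligned with x, y), or
#'   NULL for none.
#' @param tails `"two"` or `"one"`.
#' @return a `correlation_result` with `controlled` set to covariate names.
#' @export
partial_correlation <- function(x, y, covariates = NULL, tails = c("two", "one")) {
  tails <- match.arg(tails)
  if (is.null(covariates) || (is.matrix(covariates) && ncol(covariates) == 0))
    return(pearson(x, y, tails))
  Z <- as.matrix(covariates)
  if (nrow(Z) != length(x) || length(x) != length(y))
    stop_invalid("x, y and covariates must have aligned rows")
  nz <- ncol(Z)
  n <- length(x)
  if (n <= 2 + nz) stop_invalid("need n > 2 + number of covariates")
  qrz <- qr(cbind(1, Z))
  rx <- qr.resid(qrz, x)
  ry <- qr.resid(qrz, y)
  if (sum(rx^2) < 1e-12 || sum(ry^2) < 1e-12)
    stop_invalid("undefined correlation: covariate collinear with x or y")
  r <- sum(rx * ry) / sqrt(sum(rx^2) * sum(ry^2))
  nm <- colnames(Z) %||% paste0("covariate", seq_len(nz))
  correlation_result(r, n, n - 2L - nz, tails, nm)
}

#' Pooled-variance independent-samples t-test
#'
#' Student's t with the pooled variance estimator and
#' `df = n_a + n_b - 2`, two-tailed. The pooled (not Welch) form matches
#' the degrees of freedom convention of classical aphasia-subtype
#' comparisons (e.g. groups of 41 and 17 give df = 56).
#'
#' @param group_a,group_b numeric vectors, each of length >= 2.
#' @return list with `t`, `df`, `p`.
#' @export
pooled_t_test <- function(group_a, group_b) {
  na <- length(group_a); nb <- length(group_b)
  if (na < 2 || nb < 2) stop_invalid("each group needs n >= 2")
  sp2 <- ((na - 1) * stats::var(group_a) + (nb - 1) * stats::var(group_b)) /
    (na + nb - 2)
  if (sp2 <= 0) stop_invalid("undefined statistic: zero pooled variance")
  tstat <- (mean(group_a) - mean(group_b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2L
  list(t = tstat, df = df, p = 2 * stats::pt(abs(tstat), df, lower.tail = FALSE))
}

#' Regress summed item production on psycholinguistic covariates
#'
#' Ordinary least squares of total production counts per checklist item on
#' word class (noun = 0, verb = 1), phoneme length, log frequency and
#' imageability, solved via the QR decomposition (never the normal
#' equations on raw data). Reports per-coefficient t-tests, R-squared and
#' the overall F-test.
#'
#' @param item_totals numeric vector of summed-across-participants counts,
#'   aligned with `checklist$items`.
#' @param checklist a [checklist()] with >= 6 items.
#' @return object of class `regression_result`: `coefficients` (data.frame
#'   estimate/se/t/p), `r_squared`, `f_stat`, `f_p`, `n`.
#' @export
psycholinguistic_regression <- function(item_totals, checklist) {
  items <- checklist$items
  if (length(item_totals) != nrow(items))
    stop_invalid("item_totals must align with checklist items")
  if (nrow(items) < 6) stop_invalid("need at least 6 items")
  X <- cbind(intercept = 1,
             word_class = as.numeric(items$word_class == "verb"),
             length_phonemes = items$length_phonemes,
             frequency = items$frequency,
             imageability = items$imageability)
  y <- as.numeric(item_totals)
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    bad <- colnames(X)[qrx$pivot[seq.int(qrx$rank + 1L, ncol(X))]]
    stop_invalid("singular design; offending columns: ", paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qrx, y)
  res <- qr.resid(qrx, y)
  n <- length(y); p <- ncol(X)
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  sigma2 <- rss / (n - p)
  XtXinv <- chol2inv(qr.R(qrx))
  se <- sqrt(diag(XtXinv) * sigma2)
  tstat <- beta / se
  coef <- data.frame(estimate = beta, se = se, t = tstat,
                     p = 2 * stats::pt(abs(tstat), n - p, lower.tail = FALSE))
  r2 <- 1 - rss / tss
  f <- ((tss - rss) / (p - 1)) / sigma2
  structure(list(coefficients = coef, r_squared = r2, f_stat = f,
                 f_p = stats::pf(f, p - 1, n - p, lower.tail = FALSE), n = n),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("OLS on %d items: R^2 = %.3f, F = %.2f (p = %.4g)\n",
              x$n, x$r_squared, x$f_stat, x$f_p))
  print(round(x$coefficients, 4))
  invisible(x)
}
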