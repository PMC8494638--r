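#' @title Robust inference helpers
#' @description Heteroscedasticity-consistent (HC3) covariance, robust F and
#'   coefficient tests, Mann-Whitney U with exact small-sample inference, and
#'   Benjamini-Hochberg FDR control.
#' @name robust_stats
NULL

# OLS fit with HC3 covariance. X includes the intercept column.
.ols_hc3 <- function(X, y) {
  X <- as.matrix(X)
  fit <- stats::lm.fit(X, y)
  k <- fit$rank
  n <- length(y)
  Xq <- X[, !is.na(fit$coefficients), drop = FALSE]
  b <- fit$coefficients[!is.na(fit$coefficients)]
  e <- y - Xq %*% b
  xtxi <- chol2inv(chol(crossprod(Xq)))
  h <- rowSums((Xq %*% xtxi) * Xq)
  h <- pmin(h, 1 - 1e-10)
  u <- as.numeric(e) / (1 - h)
  meat <- crossprod(Xq * u)
  V <- xtxi %*% meat %*% xtxi
  list(coef = b, vcov = V, resid = as.numeric(e), n = n, k = k,
       fitted = as.numeric(Xq %*% b))
}

#' Heteroscedasticity-robust (HC3) F test
#'
#' Wald F test of the joint nullity of all non-intercept coefficients of an
#' OLS fit, using the HC3 covariance estimator; the reference distribution
#' is F(q, n - k) as in standard robust-regression software.
#'
#' @param X Design matrix including an intercept column.
#' @param y Response.
#' @param which Indices of coefficients tested (default: all but the first).
#' @return List: `F`, `df1`, `df2`, `p`, `coef`, `se` (HC3 standard errors),
#'   `coef_p` (per-coefficient two-sided robust t p-values).
#' @export
hc3_f_test <- function(X, y, which = NULL) {
  f <- .ols_hc3(X, y)
  if (is.null(which)) which <- setdiff(seq_along(f$coef), 1L)
  q <- length(which)
  b <- f$coef[which]
  Vr <- f$vcov[which, which, drop = FALSE]
  W <- tryCatch(as.numeric(t(b) %*% solve(Vr, b)), error = function(e) NA)
  Fstat <- W / q
  df2 <- f$n - f$k
  p <- stats::pf(Fstat, q, df2, lower.tail = FALSE)
  se <- sqrt(diag(f$vcov))
  coef_p <- 2 * stats::pt(abs(f$coef / se), df2, lower.tail = FALSE)
  list(F = Fstat, df1 = q, df2 = df2, p = p,
       coef = f$coef, se = se, coef_p = coef_p)
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test. `U` counts pairs where `x` exceeds `y` (ties
#' count one half). With both groups of size <= 20 and no ties the exact U
#' distribution is used; otherwise the normal approximation with tie
#' correction and continuity correction.
#'
#' @param x,y Numeric samples.
#' @return List: `U`, `p`, `method` (`"exact"` or `"normal"`).
#' @export
mann_whitney <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1 || n2 < 1) stop("both groups must be non-empty")
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(c(x, y)))
  if (max(n1, n2) <= 20 && !ties) {
    p <- if (U > n1 * n2 / 2)
      stats::pwilcox(U - 1, n1, n2, lower.tail = FALSE) * 2
    else stats::pwilcox(U, n1, n2) * 2
    p <- min(1, p)
    return(list(U = U, p = p, method = "exact"))
  }
  N <- n1 + n2
  tie_tab <- table(r)
  sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(tie_tab^3 - tie_tab) /
                              (N * (N - 1)))
  z <- (U - n1 * n2 / 2 - sign(U - n1 * n2 / 2) * 0.5) / sqrt(sigma2)
  list(U = U, p = min(1, 2 * stats::pnorm(-abs(z))), method = "normal")
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR-adjusted q-values (equivalent to
#' `p.adjust(method = "BH")`; kept as a named entry point so batch
#' procedures share a single correction).
#'
#' @param p Numeric vector of p-values.
#' @return q-values, same length and order.
#' @export
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")
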