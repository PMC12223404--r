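#' Welch two-sample t-test
#'
#' Two-tailed unequal-variance t-test (Satterthwaite degrees of freedom),
#' the per-comparison test used for group contrasts of ischemic-burden
#' metrics. Wraps [stats::t.test()] and adds explicit conventions for the
#' degenerate zero-variance case: two identical constant samples give
#' `t = 0, p = 1`; constant samples with different means give `p = 0`
#' flagged `degenerate`.
#'
#' @param a,b Numeric samples, each of length >= 2.
#' @return List: `t_stat`, `df`, `p_two_sided`, `mean_diff` (a - b),
#'   `degenerate`.
#' @export
welch_t_test <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  va <- var(a); vb <- var(b)
  if (va == 0 && vb == 0) {
    if (mean(a) == mean(b))
      return(list(t_stat = 0, df = NA_real_, p_two_sided = 1,
                  mean_diff = 0, degenerate = TRUE))
    return(list(t_stat = sign(mean(a) - mean(b)) * Inf, df = NA_real_,
                p_two_sided = 0, mean_diff = mean(a) - mean(b),
                degenerate = TRUE))
  }
  tt <- t.test(a, b, var.equal = FALSE)
  list(t_stat = unname(tt$statistic), df = unname(tt$parameter),
       p_two_sided = tt$p.value, mean_diff = mean(a) - mean(b),
       degenerate = FALSE)
}

## all permutations of 1..n as an (n! x n) matrix; n <= 8 intended
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 0L
  for (i in seq_len(n)) {
    rest <- seq_len(n)[-i]
    block <- cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
    out[row + seq_len(nrow(sub)), ] <- block
    row <- row + nrow(sub)
  }
  out
}

#' Spearman rank correlation
#'
#' Rank correlation with midranks for ties. The p-value is computed either
#' by full enumeration of all `n!` permutations of one variable (exact,
#' tie-adjusted, two-sided: the proportion of permutations with
#' `|rho| >= |rho_observed|`) or by the usual t-approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))`. The default chooses exact
#' enumeration for n <= 8.
#'
#' @param x,y Numeric samples of equal length >= 3.
#' @param p_method `"auto"`, `"exact_perm"`, or `"t_approx"`.
#' @return List: `rho`, `p`, `method` (the p-value method actually used),
#'   `degenerate` (TRUE when either input is constant; `rho` is `NA`).
#' @export
spearman_corr <- function(x, y, p_method = c("auto", "exact_perm",
                                             "t_approx")) {
  p_method <- match.arg(p_method)
  n <- length(x)
  stopifnot(length(y) == n, n >= 3)
  if (sd(x) == 0 || sd(y) == 0)
    return(list(rho = NA_real_, p = NA_real_, method = p_method,
                degenerate = TRUE))
  rx <- rank(x); ry <- rank(y)
  rho <- cor(rx, ry)
  if (p_method == "auto")
    p_method <- if (n <= 8) "exact_perm" else "t_approx"
  if (p_method == "exact_perm") {
    if (n > 8) stop("exact permutation p is enumerated only for n <= 8")
    perms <- all_permutations(n)
    cx <- rx - mean(rx); cy <- ry - mean(ry)
    denom <- sqrt(sum(cx^2) * sum(cy^2))
    rho_perm <- (matrix(cy[perms], nrow(perms), n) %*% cx) / denom
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
  } else {
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * pt(-abs(tstat), df = n - 2)
    }
  }
  list(rho = rho, p = p, method = p_method, degenerate = FALSE)
}

#' Simple linear regression with intercept confidence interval
#'
#' Ordinary least squares of `y` on `x` via [stats::lm()], reporting the
#' slope, the intercept ("offset" when comparing two %LV metrics) with its
#' 95% t-based confidence interval, and R^2.
#'
#' @param x,y Numeric samples of equal length >= 3; `x` must vary.
#' @return List: `slope`, `intercept`, `r_squared`, `ci95_intercept`
#'   (length-2), `n`.
#' @export
simple_regression <- function(x, y) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 3)
  if (var(x) == 0) stop("x has zero variance; regression undefined")
  fit <- lm(y ~ x)
  ci <- suppressWarnings(confint(fit, "(Intercept)", level = 0.95))
  sse <- sum(fit$residuals^2)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - sse / sst else 1  # flat y fitted exactly
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = r2,
       ci95_intercept = unname(ci[1, ]), n = n)
}
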