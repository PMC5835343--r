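#' Mann-Whitney U test with effect size r
#'
#' Rank-sum test for two independent samples. For pooled sizes of at most
#' `exact_max` the two-sided p-value is computed by exact enumeration of all
#' group assignments of the pooled ranks (valid under ties); otherwise a
#' tie-corrected normal approximation is used. The effect size is
#' `r = |Z| / sqrt(n1 + n2)`.
#'
#' @param a,b Numeric samples.
#' @param exact_max Largest pooled size for exact enumeration (default 12).
#' @return List of class `test_result`: `test`, `U` (for sample `a`), `Z`,
#'   `p_value`, `r`, `n1`, `n2`, `method` ("exact" or "normal").
#' @export
mann_whitney <- function(a, b, exact_max = 12L) {
  if (length(a) == 0L || length(b) == 0L) stop("samples must be non-empty")
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  r_all <- rank(c(a, b))
  U <- sum(r_all[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(r_all)
  tie_term <- sum(ties^3 - ties)
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term / (N * (N - 1)))
  Z <- if (sigma2 > 0) (U - mu) / sqrt(sigma2) else 0
  if (N <= exact_max) {
    combs <- utils::combn(N, n1)
    u_all <- apply(combs, 2L, function(ix) sum(r_all[ix])) - n1 * (n1 + 1) / 2
    p <- mean(abs(u_all - mu) >= abs(U - mu) - 1e-12)
    method <- "exact"
  } else {
    p <- if (sigma2 > 0) 2 * stats::pnorm(-abs(Z)) else 1
    method <- "normal"
  }
  structure(list(test = "Mann-Whitney U", U = U, Z = Z, p_value = p,
                 r = abs(Z) / sqrt(N), n1 = n1, n2 = n2, method = method),
            class = "test_result")
}

#' Wilcoxon signed-rank test with Z statistic
#'
#' Paired-sample test on a vector of differences. Zero differences are
#' dropped; |differences| are ranked with midranks for ties; W is the sum of
#' ranks of the positive differences. For n at most `exact_max` the
#' two-sided p is by exact enumeration of all 2^n sign assignments (valid
#' under ties); otherwise a tie-corrected normal approximation. The Z
#' statistic is sign-antisymmetric: `Z(x) = -Z(-x)`.
#'
#' @param x Numeric vector of paired differences.
#' @param exact_max Largest n for exact enumeration (default 10).
#' @return List of class `test_result`: `test`, `W`, `Z`, `p_value`, `r`
#'   (`|Z|/sqrt(n)`), `n` (nonzero differences), `method`.
#' @export
wilcoxon_signed <- function(x, exact_max = 10L) {
  x <- x[x != 0]
  n <- length(x)
  if (n == 0L) stop("degenerate: all differences are zero")
  rk <- rank(abs(x))
  W <- sum(rk[x > 0])
  mu <- n * (n + 1) / 4
  ties <- table(rk)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  Z <- if (sigma2 > 0) (W - mu) / sqrt(sigma2) else 0
  if (n <= exact_max) {
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    w_all <- as.vector(signs %*% rk)
    p <- mean(abs(w_all - mu) >= abs(W - mu) - 1e-12)
    method <- "exact"
  } else {
    p <- if (sigma2 > 0) 2 * stats::pnorm(-abs(Z)) else 1
    method <- "normal"
  }
  structure(list(test = "Wilcoxon signed-rank", W = W, Z = Z, p_value = p,
                 r = abs(Z) / sqrt(n), n = n, method = method),
            class = "test_result")
}

#' Effect sizes: phi, Cramer's V, Cohen's d
#'
#' `phi_coefficient` and `cramers_v` use the uncorrected chi-squared
#' statistic: phi = sqrt(chi2 / N) for 2x2 tables, V = sqrt(chi2 / (N (k-1)))
#' with k the smaller table dimension. `cohens_d` is the mean difference over
#' the pooled SD.
#'
#' @param tab A contingency table (matrix).
#' @return Numeric effect size.
#' @export
phi_coefficient <- function(tab) {
  stopifnot(all(dim(tab) == c(2L, 2L)))
  chi2 <- suppressWarnings(stats::chisq.test(tab, correct = FALSE)$statistic)
  sqrt(unname(chi2) / sum(tab))
}

#' @rdname phi_coefficient
#' @export
cramers_v <- function(tab) {
  chi2 <- suppressWarnings(stats::chisq.test(tab, correct = FALSE)$statistic)
  k <- min(dim(tab))
  sqrt(unname(chi2) / (sum(tab) * (k - 1)))
}

#' @rdname phi_coefficient
#' @param a,b Numeric samples.
#' @export
cohens_d <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) / (n1 + n2 - 2)
  if (sp2 == 0) stop("zero pooled variance: Cohen's d undefined")
  (mean(a) - mean(b)) / sqrt(sp2)
}

#' Gaussian rank (normal-scores) correlation
#'
#' Robust correlation: the product-moment correlation of the normal scores
#' `qnorm(rank / (n + 1))` of the two variables. Invariant to strictly
#' monotone transformations of either variable; bounded in [-1, 1].
#'
#' @param x,y Numeric vectors of equal length, n >= 3, no missing values.
#' @return Correlation in [-1, 1].
#' @export
gaussian_rank_correlation <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3,
            !anyNA(x), !anyNA(y))
  if (diff(range(x)) == 0 || diff(range(y)) == 0) {
    stop("undefined: constant input")
  }
  n <- length(x)
  stats::cor(stats::qnorm(rank(x) / (n + 1)), stats::qnorm(rank(y) / (n + 1)))
}
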