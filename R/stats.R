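#' @title Comparison statistics
#' @name stats_layer
#' @description
#' The statistical layer, implemented from first principles: mean with
#' standard error, the two-tailed Mann-Whitney U test (exact permutation
#' enumeration for small tie-free samples, otherwise the
#' tie-and-continuity-corrected normal approximation), the Pearson
#' correlation with its t-reference p-value, maximum-likelihood
#' log-normal fits, and percent/fold change metrics.
NULL

#' Mean and standard error of the mean
#'
#' SEM uses the sample standard deviation (n - 1 denominator). For a
#' single value the SEM is reported as 0 with attribute
#' `single_value = TRUE`.
#'
#' @param values numeric vector (length >= 1, no NAs).
#' @return list with `mean`, `sem`, `n`.
#' @export
mean_sem <- function(values) {
  if (length(values) == 0L) stop("mean_sem requires at least one value")
  if (anyNA(values)) stop("mean_sem: values contain NA")
  n <- length(values)
  sem <- if (n == 1L) 0 else stats::sd(values) / sqrt(n)
  out <- list(mean = mean(values), sem = sem, n = n)
  if (n == 1L) attr(out, "single_value") <- TRUE
  out
}

# U statistic of sample a vs b from midranks
u_statistic <- function(a, b) {
  r <- rank(c(a, b))  # midranks for ties
  sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
}

# exact permutation null of U: tail probabilities by full enumeration of
# the C(n1+n2, n1) labelings; tie-free inputs only
exact_u_tails <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  idx <- utils::combn(length(pooled), n1)
  u_obs <- u_statistic(a, b)
  us <- apply(idx, 2, function(i) u_statistic(pooled[i], pooled[-i]))
  eps <- 1e-9
  list(u = u_obs,
       p_lower = mean(us <= u_obs + eps),
       p_upper = mean(us >= u_obs - eps))
}

#' Two-tailed Mann-Whitney U test
#'
#' The U statistic is computed from midranks. In `"auto"` mode the exact
#' permutation null is enumerated when `n1 + n2 <= 16` and the pooled
#' sample is tie-free; otherwise the normal approximation with tie
#' correction and continuity correction is used. The two-tailed p-value
#' doubles the smaller one-sided tail, capped at 1. A pooled sample of
#' identical values returns p = 1 with `degenerate = TRUE`.
#'
#' @param a,b numeric samples (each length >= 1).
#' @param mode `"auto"`, `"exact"` or `"normal"`.
#' @return object of class `mw_test`: `n1`, `n2`, `statistic_U` (for
#'   sample `a`), `p_two_tailed`, `mean_sem_a`, `mean_sem_b`, `method`
#'   (`"exact_enumeration"` or `"normal_approx_tie_corrected"`),
#'   `degenerate`.
#' @export
mann_whitney_u <- function(a, b, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  if (length(a) < 1L || length(b) < 1L)
    stop("both samples must contain at least one value")
  if (anyNA(c(a, b))) stop("samples contain NA")
  n1 <- length(a)
  n2 <- length(b)
  u <- u_statistic(a, b)
  ties <- anyDuplicated(c(a, b)) > 0L
  degenerate <- length(unique(c(a, b))) == 1L
  if (mode == "exact" && ties)
    stop("exact enumeration requires a tie-free pooled sample")
  use_exact <- mode == "exact" ||
    (mode == "auto" && !ties && n1 + n2 <= 16L)
  if (degenerate) {
    p <- 1
    method <- "normal_approx_tie_corrected"
  } else if (use_exact) {
    tails <- exact_u_tails(a, b)
    p <- min(1, 2 * min(tails$p_lower, tails$p_upper))
    method <- "exact_enumeration"
  } else {
    N <- n1 + n2
    mu <- n1 * n2 / 2
    tie_tab <- table(c(a, b))
    tie_term <- sum(tie_tab^3 - tie_tab) / (N * (N - 1))
    sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
      if (abs(u - mu) < 0.5) z <- 0  # continuity correction cannot overshoot
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "normal_approx_tie_corrected"
  }
  structure(list(n1 = n1, n2 = n2, statistic_U = u, p_two_tailed = p,
                 mean_sem_a = mean_sem(a), mean_sem_b = mean_sem(b),
                 method = method, degenerate = degenerate),
            class = "mw_test")
}

#' @export
print.mw_test <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %.4g (n1 = %d, n2 = %d), two-tailed p = %.4g [%s]\n",
              x$statistic_U, x$n1, x$n2, x$p_two_tailed, x$method))
  invisible(x)
}

#' Pearson correlation with t-reference p-value
#'
#' @param x,y numeric vectors of equal length (n >= 3) with nonzero
#'   variance.
#' @return list with `r`, `p_value` (two-sided, from
#'   `t = r * sqrt((n - 2) / (1 - r^2))`), `n`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3) stop("pearson requires n >= 3")
  if (anyNA(x) || anyNA(y)) stop("inputs contain NA")
  sx <- stats::sd(x)
  sy <- stats::sd(y)
  if (sx == 0 || sy == 0) stop("zero variance input")
  r <- sum((x - mean(x)) * (y - mean(y))) / ((n - 1) * sx * sy)
  r <- max(-1, min(1, r))
  p <- if (abs(r) >= 1) 0 else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(t), df = n - 2)
  }
  list(r = r, p_value = p, n = n)
}

#' Maximum-likelihood log-normal fit
#'
#' `logmean` and `logsd` are the ML estimates (moments of the log
#' values, n denominator for the sd). Goodness of fit is a normality
#' test on the logs (Shapiro-Wilk for n < 8, Anderson-Darling
#' otherwise).
#'
#' @param values positive numeric vector, length >= 2.
#' @return object of class `lognormal_fit`: `logmean`, `logsd`, `n`,
#'   `gof_pvalue`.
#' @export
fit_lognormal <- function(values) {
  if (length(values) < 2L) stop("fit_lognormal requires n >= 2")
  if (any(!is.finite(values) | values <= 0))
    stop("all values must be positive and finite")
  l <- log(values)
  logmean <- mean(l)
  logsd <- sqrt(mean((l - logmean)^2))
  gof <- if (stats::sd(l) == 0) NA_real_
         else if (length(l) < 8) stats::shapiro.test(l)$p.value
         else nortest::ad.test(l)$p.value
  structure(list(logmean = logmean, logsd = logsd, n = length(values),
                 gof_pvalue = gof),
            class = "lognormal_fit")
}

#' @export
print.lognormal_fit <- function(x, ...) {
  cat(sprintf("log-normal fit: logmean = %.4g, logsd = %.4g (n = %d), GoF p = %.3g\n",
              x$logmean, x$logsd, x$n, x$gof_pvalue))
  invisible(x)
}

#' Percent and fold change between two values
#'
#' @param before baseline value (> 0).
#' @param after comparison value.
#' @return list with `percent_change` (`100 * (after - before) / before`)
#'   and `fold_change` (`after / before`).
#' @export
change_metrics <- function(before, after) {
  if (!is.finite(before) || before <= 0)
    stop("'before' must be a positive number")
  list(percent_change = 100 * (after - before) / before,
       fold_change = after / before)
}

#' Significance annotation in the conventional star style
#'
#' `ns` for p > 0.05, `*` for p < 0.05, `**` for p < 0.01, `***` for
#' p < 0.001.
#' @param p p-value(s).
#' @return character vector of annotations.
#' @export
significance_stars <- function(p) {
  vapply(p, function(pi) {
    if (is.na(pi)) NA_character_
    else if (pi < 0.001) "***"
    else if (pi < 0.01) "**"
    else if (pi < 0.05) "*"
    else "ns"
  }, character(1))
}
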