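#' Box-Cox power transform toward normality
#'
#' Transforms a positive sample by `(x^lambda - 1) / lambda` (or `ln x` when
#' `lambda = 0`), with `lambda` chosen by profile maximum likelihood unless
#' supplied. Samples containing non-positive values are shifted by
#' `-min(x) + eps` first and the shift recorded.
#'
#' @param values Numeric vector, length >= 3.
#' @param lambda Optional fixed exponent; `NULL` (default) estimates it by ML
#'   over `lambda_grid`.
#' @param lambda_grid Grid over which the profile likelihood is maximized.
#' @param eps Positivity margin used when shifting.
#' @return List with `transformed`, `lambda`, `shift`.
#' @export
boxcox_transform <- function(values, lambda = NULL,
                             lambda_grid = seq(-5, 5, by = 0.01),
                             eps = 1e-6) {
  values <- as.numeric(values)
  if (length(values) < 3) {
    stop("Box-Cox transform needs at least 3 values", call. = FALSE)
  }
  if (anyNA(values)) stop("values contain NA", call. = FALSE)
  shift <- 0
  if (min(values) <= 0) {
    shift <- -min(values) + eps * max(1, diff(range(values)))
    values <- values + shift
  }
  if (is.null(lambda)) {
    if (stats::var(values) == 0) {
      lambda <- 1 # likelihood flat in lambda for a constant sample
    } else {
      prof <- MASS::boxcox(values ~ 1, lambda = lambda_grid, plotit = FALSE)
      lambda <- prof$x[which.max(prof$y)]
    }
  }
  transformed <- if (lambda == 0) log(values) else (values^lambda - 1) / lambda
  list(transformed = transformed, lambda = lambda, shift = shift)
}

#' Pooled two-sample t-test
#'
#' Classical equal-variance two-sample t statistic with
#' `df = n_a + n_b - 2` and a two-tailed p value. Positive `t` means the mean
#' of `a` exceeds the mean of `b`. Two identical degenerate samples give
#' `t = 0, p = 1`; zero pooled variance with unequal means is reported as an
#' infinite statistic with `p = 0` and a `degenerate` flag.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @param welch If `TRUE`, use the Welch unequal-variance form instead.
#' @return List with `t`, `p`, `df`, `degenerate`.
#' @export
two_sample_ttest <- function(a, b, welch = FALSE) {
  a <- as.numeric(a); b <- as.numeric(b)
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) stop("each sample needs at least 2 values", call. = FALSE)
  va <- stats::var(a); vb <- stats::var(b)
  dm <- mean(a) - mean(b)
  if (welch) {
    se2 <- va / na + vb / nb
    if (se2 == 0) {
      if (dm == 0) return(list(t = 0, p = 1, df = na + nb - 2, degenerate = TRUE))
      return(list(t = sign(dm) * Inf, p = 0, df = na + nb - 2, degenerate = TRUE))
    }
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    t <- dm / sqrt(se2)
  } else {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    df <- na + nb - 2
    if (sp2 == 0) {
      if (dm == 0) return(list(t = 0, p = 1, df = df, degenerate = TRUE))
      return(list(t = sign(dm) * Inf, p = 0, df = df, degenerate = TRUE))
    }
    t <- dm / sqrt(sp2 * (1 / na + 1 / nb))
  }
  list(t = t, p = 2 * stats::pt(-abs(t), df), df = df, degenerate = FALSE)
}

#' Bonferroni correction over a family of tests
#'
#' @param pvals Numeric vector of raw p values in `[0, 1]`.
#' @param alpha Family-wise error level.
#' @return A tibble with `p_raw`, `p_adjusted` (`min(1, m * p)`), and
#'   `significant` (`p_raw < alpha / m`, `m` the family size). Empty input
#'   gives an empty table.
#' @export
bonferroni_correct <- function(pvals, alpha = 0.05) {
  if (length(pvals) == 0) {
    return(tibble::tibble(p_raw = numeric(0), p_adjusted = numeric(0),
                          significant = logical(0)))
  }
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) {
    stop("p values must lie in [0, 1]", call. = FALSE)
  }
  m <- length(pvals)
  tibble::tibble(p_raw = pvals,
                 p_adjusted = stats::p.adjust(pvals, method = "bonferroni"),
                 significant = pvals < alpha / m)
}

#' Two-tailed critical t value
#'
#' The value `c` with `P(|T_df| > c) = alpha`; e.g. at `p < 0.001` with 10
#' degrees of freedom the cutoff is 4.587.
#'
#' @param alpha Two-tailed significance level in (0, 1).
#' @param df Degrees of freedom (>= 1).
#' @return The critical value.
#' @export
critical_t <- function(alpha, df) {
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)", call. = FALSE)
  if (df < 1) stop("df must be >= 1", call. = FALSE)
  stats::qt(1 - alpha / 2, df)
}
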