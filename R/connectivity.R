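#' Zero-phase band-pass filter for ROI time series
#'
#' Applies a forward-backward (zero-phase) Butterworth band-pass filter to
#' each region's series. The default band 0.01-0.08 Hz is the conventional
#' resting-state BOLD band, suppressing slow scanner drift below and
#' physiological noise above it.
#'
#' @param series Region x time numeric matrix.
#' @param tr_seconds Sampling interval in seconds.
#' @param low_hz,high_hz Band edges in Hz; must satisfy
#'   `0 < low_hz < high_hz < 1/(2 * tr_seconds)` (the Nyquist frequency).
#' @param order Butterworth order (applied twice by filtering forwards and
#'   backwards).
#' @return Filtered matrix of the same dimensions.
#' @export
bandpass_filter <- function(series, tr_seconds, low_hz = 0.01, high_hz = 0.08,
                            order = 4) {
  stopifnot(is.matrix(series), is.numeric(series), tr_seconds > 0)
  nyquist <- 1 / (2 * tr_seconds)
  if (!(low_hz > 0 && low_hz < high_hz)) {
    stop("band edges must satisfy 0 < low_hz < high_hz", call. = FALSE)
  }
  if (high_hz >= nyquist) {
    stop(sprintf("high_hz (%g Hz) must be below the Nyquist frequency %g Hz",
                 high_hz, nyquist), call. = FALSE)
  }
  if (anyNA(series)) stop("series contains missing values", call. = FALSE)
  bf <- signal::butter(order, c(low_hz, high_hz) / nyquist, type = "pass")
  # filtfilt needs enough samples to settle its edge padding
  warmup <- 3 * (max(length(bf$b), length(bf$a)) - 1)
  if (ncol(series) <= warmup) {
    stop(sprintf("series too short for filtering: %d timepoints, need > %d",
                 ncol(series), warmup), call. = FALSE)
  }
  # remove each region's mean first: the DC component is outside the band by
  # construction, and taking it out keeps the forward-backward pass free of
  # large edge transients
  out <- t(apply(series, 1, function(x) signal::filtfilt(bf, x - mean(x))))
  dimnames(out) <- dimnames(series)
  out
}

#' Regress nuisance covariates out of ROI time series
#'
#' Replaces every region's series by its least-squares residual on an
#' intercept plus the given covariates (e.g. head motion, white matter, CSF
#' or global mean signals). Residuals are orthogonal to every covariate
#' column.
#'
#' @param series Region x time numeric matrix.
#' @param covariates Time x k numeric matrix (or vector) of nuisance signals.
#' @return Residual matrix of the same dimensions as `series`.
#' @export
regress_nuisance <- function(series, covariates) {
  stopifnot(is.matrix(series))
  covariates <- as.matrix(covariates)
  if (nrow(covariates) != ncol(series)) {
    stop("covariates must have one row per timepoint of the series", call. = FALSE)
  }
  x <- cbind(intercept = 1, covariates)
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    stop("nuisance design matrix is rank deficient (collinear covariates)",
         call. = FALSE)
  }
  res <- t(qr.resid(qx, t(series)))
  dimnames(res) <- dimnames(series)
  res
}

#' Pearson correlation matrix with zeroed diagonal
#'
#' Computes the Pearson correlation coefficient between every pair of regional
#' time series. Self-connections carry no information for network analysis, so
#' the diagonal is forced to zero.
#'
#' @param series Region x time numeric matrix with at least 3 timepoints and
#'   no constant rows.
#' @return A `correlation_matrix`: symmetric N x N matrix in `[-1, 1]` with
#'   zero diagonal.
#' @export
correlation_matrix <- function(series) {
  stopifnot(is.matrix(series), is.numeric(series))
  if (ncol(series) < 3) stop("need at least 3 timepoints", call. = FALSE)
  sds <- apply(series, 1, stats::sd)
  if (any(sds == 0)) {
    bad <- which(sds == 0)
    lbl <- if (!is.null(rownames(series))) rownames(series)[bad] else bad
    stop(sprintf("constant (zero-variance) region(s): %s",
                 paste(lbl, collapse = ", ")), call. = FALSE)
  }
  r <- stats::cor(t(series))
  r <- (r + t(r)) / 2 # enforce exact symmetry against rounding
  diag(r) <- 0
  class(r) <- c("correlation_matrix", "matrix", "array")
  r
}

as_correlation_matrix <- function(values) {
  stopifnot(is.matrix(values), nrow(values) == ncol(values))
  if (max(abs(values - t(values))) > 1e-10) {
    stop("correlation matrix must be symmetric", call. = FALSE)
  }
  if (any(abs(values) > 1 + 1e-12)) {
    stop("correlation values must lie in [-1, 1]", call. = FALSE)
  }
  diag(values) <- 0
  class(values) <- c("correlation_matrix", "matrix", "array")
  values
}

#' Binarize a correlation matrix at a threshold
#'
#' An edge joins regions `i != j` whenever the absolute correlation
#' `|r_ij| >= T`; weaker connections are considered non-significant and
#' dropped. Strong negative correlations therefore also produce edges, and no
#' sign is retained.
#'
#' @param corr A [correlation_matrix()] (or any symmetric numeric matrix).
#' @param threshold Threshold `T` in (0, 1).
#' @return A [binary_network()].
#' @export
binarize <- function(corr, threshold) {
  stopifnot(is.matrix(corr), nrow(corr) == ncol(corr))
  if (!(threshold > 0 && threshold < 1)) {
    stop("threshold must lie strictly inside (0, 1)", call. = FALSE)
  }
  a <- (abs(unclass(corr)) >= threshold) * 1
  diag(a) <- 0
  binary_network(a, region_ids = rownames(corr))
}

#' Threshold grid for the binarization sweep
#'
#' @param from,to,by Grid limits and step; defaults give the 14 thresholds
#'   0.225, 0.250, ..., 0.550.
#' @return Strictly increasing numeric vector of thresholds in (0, 1).
#' @export
threshold_grid <- function(from = 0.225, to = 0.550, by = 0.025) {
  stopifnot(from > 0, to < 1, by > 0, from <= to)
  g <- seq(from, to, by = by)
  if (any(diff(g) <= 0)) stop("thresholds must be strictly increasing", call. = FALSE)
  g
}

#' Minimum mean degree for almost-sure connectedness
#'
#' The heuristic bound `K_net >= 2 ln(N)` under which a sparse random graph on
#' `N` nodes is almost surely connected; thresholds whose mean degree falls
#' below it are flagged in the sweep. For the 90-region atlas the bound is
#' `2 ln(90) ~ 9`.
#'
#' @param n Node count (may be non-integer; must be >= 2).
#' @return `2 * log(n)`.
#' @export
connectivity_bound <- function(n) {
  if (!is.numeric(n) || length(n) != 1 || n < 2) {
    stop("n must be a single number >= 2", call. = FALSE)
  }
  2 * log(n)
}
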