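#' Configuration for the synthetic ROI time-series generator
#'
#' Defines a two-group, multi-subject simulation of regional BOLD-like time
#' series with block-modular correlation structure. Each subject is drawn from
#' a multivariate normal with unit variances whose correlation matrix has
#' `within_r` inside each module block and `between_r` across blocks; group B
#' adds `group_effect` to its within-module correlation, which induces a
#' between-group difference in binarized network density. Defaults mirror a
#' typical resting/task fMRI design: 90 regions, 150 retained volumes at
#' TR = 2 s, 11 subjects per group.
#'
#' @param n_subjects Subjects per group.
#' @param n_regions Number of regions (nodes).
#' @param n_timepoints Number of time points per subject.
#' @param tr_seconds Sampling interval in seconds.
#' @param n_modules Number of correlated blocks; module sizes differ by at
#'   most one region.
#' @param within_r Target Pearson correlation inside a module, |within_r| < 1.
#' @param between_r Target correlation across modules, must be below
#'   `within_r`.
#' @param group_effect Additive shift applied to group B's `within_r`.
#' @param ar1 Optional AR(1) coefficient in `[0, 1)` applied identically to
#'   all regions; the lag-0 cross-correlation targets are preserved exactly.
#' @param seed Integer RNG seed.
#' @return A `simulation_config` list, validated (including positive
#'   semi-definiteness of both groups' implied correlation matrices).
#' @export
simulation_config <- function(n_subjects = 11, n_regions = 90,
                              n_timepoints = 150, tr_seconds = 2.0,
                              n_modules = 6, within_r = 0.5, between_r = 0.1,
                              group_effect = 0, ar1 = 0, seed = 1L) {
  stopifnot(n_subjects >= 1, n_regions >= 2, n_timepoints >= 3,
            tr_seconds > 0, n_modules >= 1, n_modules <= n_regions,
            ar1 >= 0, ar1 < 1)
  if (abs(within_r) >= 1 || abs(between_r) >= 1) {
    stop("within_r and between_r must lie strictly inside (-1, 1)", call. = FALSE)
  }
  if (between_r >= within_r) {
    stop("between_r must be smaller than within_r", call. = FALSE)
  }
  if (abs(within_r + group_effect) >= 1) {
    stop("group B within-module correlation (within_r + group_effect) must lie inside (-1, 1)",
         call. = FALSE)
  }
  cfg <- structure(list(
    n_subjects = as.integer(n_subjects), n_regions = as.integer(n_regions),
    n_timepoints = as.integer(n_timepoints), tr_seconds = tr_seconds,
    n_modules = as.integer(n_modules), within_r = within_r,
    between_r = between_r, group_effect = group_effect, ar1 = ar1,
    seed = as.integer(seed)
  ), class = "simulation_config")
  # both groups' correlation matrices must be valid covariances
  check_psd(block_correlation(cfg$n_regions, cfg$n_modules, within_r, between_r),
            within_r, between_r)
  check_psd(block_correlation(cfg$n_regions, cfg$n_modules,
                              within_r + group_effect, between_r),
            within_r + group_effect, between_r)
  cfg
}

check_psd <- function(sigma, within_r, between_r) {
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop(sprintf(
      "implied block covariance is not positive semi-definite for (within_r = %g, between_r = %g)",
      within_r, between_r), call. = FALSE)
  }
  invisible(TRUE)
}

#' Block-modular correlation matrix
#'
#' Unit-diagonal correlation matrix with `within_r` inside each of
#' `n_modules` contiguous blocks and `between_r` elsewhere; block sizes differ
#' by at most one.
#'
#' @param n_regions,n_modules,within_r,between_r See [simulation_config()].
#' @return An `n_regions` x `n_regions` correlation matrix.
#' @export
block_correlation <- function(n_regions, n_modules, within_r, between_r) {
  mod <- module_assignment(n_regions, n_modules)
  sigma <- matrix(between_r, n_regions, n_regions)
  for (m in seq_len(n_modules)) {
    idx <- which(mod == m)
    sigma[idx, idx] <- within_r
  }
  diag(sigma) <- 1
  sigma
}

module_assignment <- function(n_regions, n_modules) {
  sizes <- rep(n_regions %/% n_modules, n_modules)
  extra <- n_regions %% n_modules
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  rep(seq_len(n_modules), times = sizes)
}

#' Generate one group of synthetic ROI time series
#'
#' Draws `n_subjects` independent region-by-time matrices from a multivariate
#' normal with the block correlation structure of `config`. With `ar1 > 0`
#' the innovations are filtered through a common AR(1) recursion and rescaled
#' to unit marginal variance, leaving the lag-0 correlation targets intact.
#'
#' @param config A [simulation_config()].
#' @param group Either `"A"` (within_r as given) or `"B"` (within_r shifted by
#'   `group_effect`).
#' @param label Group label stored on the output; defaults to `group`.
#' @return A `roi_timeseries_set`: list with `group_label`, `subjects` (list of
#'   region x time matrices), `region_ids`, `tr_seconds`.
#' @export
generate_roi_timeseries <- function(config, group = c("A", "B"), label = NULL) {
  group <- match.arg(group)
  stopifnot(inherits(config, "simulation_config"))
  wr <- config$within_r + if (group == "B") config$group_effect else 0
  sigma <- block_correlation(config$n_regions, config$n_modules, wr,
                             config$between_r)
  check_psd(sigma, wr, config$between_r)
  # offset the seed so the two groups use disjoint streams
  set.seed(config$seed + if (group == "B") 104729L else 0L)
  cf <- chol_psd(sigma)
  region_ids <- paste0("R", seq_len(config$n_regions))
  subjects <- lapply(seq_len(config$n_subjects), function(s) {
    x <- draw_subject(cf, config$n_timepoints, config$ar1)
    dimnames(x) <- list(region_ids, NULL)
    x
  })
  structure(list(group_label = if (is.null(label)) group else label,
                 subjects = subjects, region_ids = region_ids,
                 tr_seconds = config$tr_seconds),
            class = "roi_timeseries_set")
}

# Cholesky-like factor tolerant of semidefinite blocks
chol_psd <- function(sigma) {
  ch <- tryCatch(chol(sigma), error = function(e) NULL)
  if (!is.null(ch)) return(ch)
  e <- eigen(sigma, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  t(e$vectors %*% diag(sqrt(ev)))
}

draw_subject <- function(chol_factor, n_timepoints, ar1) {
  n_regions <- ncol(chol_factor)
  z <- matrix(stats::rnorm(n_timepoints * n_regions), n_timepoints, n_regions)
  x <- z %*% chol_factor # time x regions, correlation = sigma
  if (ar1 > 0) {
    # identical AR(1) recursion on every region; rescale to unit variance so
    # cross-correlations at lag 0 stay at their targets
    for (t in 2:n_timepoints) x[t, ] <- ar1 * x[t - 1, ] + sqrt(1 - ar1^2) * x[t, ]
  }
  t(x)
}

#' @export
print.roi_timeseries_set <- function(x, ...) {
  cat(sprintf("roi_timeseries_set '%s': %d subjects, %d regions x %d timepoints, TR = %gs\n",
              x$group_label, length(x$subjects), length(x$region_ids),
              ncol(x$subjects[[1]]), x$tr_seconds))
  invisible(x)
}

#' Generate a matched two-group synthetic dataset
#'
#' Groups A and B share all dimensions; group B's within-module correlation is
#' shifted by `group_effect`, so for `group_effect > 0` its thresholded
#' networks are denser (higher mean degree) at mid-range thresholds.
#'
#' @param config A [simulation_config()].
#' @param labels Length-2 character vector of group labels.
#' @return Named list of two `roi_timeseries_set`s.
#' @export
generate_two_group_dataset <- function(config, labels = c("A", "B")) {
  stopifnot(length(labels) == 2, !anyDuplicated(labels))
  out <- list(generate_roi_timeseries(config, "A", label = labels[1]),
              generate_roi_timeseries(config, "B", label = labels[2]))
  names(out) <- labels
  out
}

#' Number of volumes acquired in a scan
#'
#' @param total_seconds Total scanning time in seconds.
#' @param tr_seconds Repetition time in seconds.
#' @return Integer volume count `floor(total_seconds / tr_seconds)`.
#' @examples
#' scan_volumes(310, 2) # 155
#' @export
scan_volumes <- function(total_seconds, tr_seconds) {
  stopifnot(total_seconds > 0, tr_seconds > 0)
  as.integer(floor(total_seconds / tr_seconds))
}

#' Drop initial volumes from a region x time matrix
#'
#' Discards the first `n` time points, the usual guard against pre-steady-state
#' magnetization at the start of an acquisition.
#'
#' @param series Region x time numeric matrix.
#' @param n Number of leading volumes to drop.
#' @return The truncated matrix.
#' @export
drop_initial_volumes <- function(series, n = 5L) {
  stopifnot(is.matrix(series), n >= 0, ncol(series) > n)
  series[, -seq_len(n), drop = FALSE]
}
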