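#' Read a delimited-text matrix, validated by kind
#'
#' Reads tab/comma/whitespace-delimited numeric matrices and validates them
#' against the target type: `"timeseries"` (any rectangular region x time
#' matrix), `"correlation"` (square, symmetric to 1e-10, entries in
#' `[-1, 1]`, diagonal forced to 0), `"adjacency"` (square, symmetric, 0/1,
#' zero diagonal). An optional first header row and/or first label column of
#' region ids is detected and preserved. Errors name the offending line (and
#' cell where applicable).
#'
#' @param path File path.
#' @param kind One of `"timeseries"`, `"correlation"`, `"adjacency"`.
#' @return A numeric matrix, [correlation_matrix()] or [binary_network()].
#' @export
read_matrix <- function(path, kind = c("timeseries", "correlation", "adjacency")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop(sprintf("%s: empty file", path), call. = FALSE)
  sep <- if (grepl("\t", lines[1])) "\t" else if (grepl(",", lines[1])) "," else "[[:space:]]+"
  tok <- lapply(lines, function(l) strsplit(trimws(l), sep)[[1]])

  is_num <- function(x) !is.na(suppressWarnings(as.numeric(x)))
  col_labels <- NULL
  row_labels <- NULL
  # header row: first line's tokens (beyond a possible corner cell) non-numeric
  first_numeric <- all(is_num(tok[[1]]))
  if (!first_numeric) {
    col_labels <- tok[[1]]
    tok <- tok[-1]
    lines <- lines[-1]
    if (length(tok) == 0) stop(sprintf("%s: header but no data rows", path), call. = FALSE)
  }
  # label column: every remaining line starts with a non-numeric token
  if (all(vapply(tok, function(x) !is_num(x[1]), logical(1)))) {
    row_labels <- vapply(tok, `[`, character(1), 1)
    tok <- lapply(tok, `[`, -1)
    if (!is.null(col_labels) && length(col_labels) == length(tok[[1]]) + 1) {
      col_labels <- col_labels[-1] # drop corner cell
    }
  }
  widths <- vapply(tok, length, integer(1))
  if (length(unique(widths)) != 1) {
    bad <- which(widths != widths[1])[1]
    stop(sprintf("%s: ragged row at line %d (%d fields, expected %d)",
                 path, bad + !is.null(col_labels), widths[bad], widths[1]),
         call. = FALSE)
  }
  vals <- suppressWarnings(lapply(tok, as.numeric))
  for (i in seq_along(vals)) {
    if (anyNA(vals[[i]])) {
      j <- which(is.na(vals[[i]]))[1]
      stop(sprintf("%s: non-numeric cell at line %d, field %d ('%s')",
                   path, i + !is.null(col_labels), j, tok[[i]][j]), call. = FALSE)
    }
  }
  x <- do.call(rbind, vals)
  if (!is.null(row_labels)) rownames(x) <- row_labels
  if (!is.null(col_labels)) {
    if (length(col_labels) != ncol(x)) {
      stop(sprintf("%s: header has %d labels for %d columns", path,
                   length(col_labels), ncol(x)), call. = FALSE)
    }
    colnames(x) <- col_labels
  }

  if (kind == "timeseries") return(x)
  if (nrow(x) != ncol(x)) {
    stop(sprintf("%s: %s matrix must be square, got %d x %d", path, kind,
                 nrow(x), ncol(x)), call. = FALSE)
  }
  if (is.null(rownames(x)) && !is.null(colnames(x))) rownames(x) <- colnames(x)
  asym <- abs(x - t(x))
  if (max(asym) > 1e-10) {
    ij <- sort(which(asym == max(asym), arr.ind = TRUE)[1, ])
    stop(sprintf("%s: asymmetric at cell (%d, %d): %g vs %g", path,
                 ij[1], ij[2], x[ij[1], ij[2]], x[ij[2], ij[1]]), call. = FALSE)
  }
  x <- (x + t(x)) / 2
  if (kind == "correlation") return(as_correlation_matrix(x))
  if (!all(x %in% c(0, 1))) {
    stop(sprintf("%s: adjacency values must be 0 or 1", path), call. = FALSE)
  }
  diag(x) <- 0
  binary_network(x, region_ids = rownames(x))
}

#' Write a matrix as tab-delimited text
#'
#' Deterministic formatting: 15 significant digits, tab separation, an
#' optional header row of column labels. Writing the same matrix twice gives
#' byte-identical files.
#'
#' @param x Numeric matrix (dimnames written when present and
#'   `header = TRUE`).
#' @param path Output path.
#' @param header Write a column-label header row when labels exist.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path, header = !is.null(colnames(x))) {
  x <- unclass(x)
  fmt <- function(v) formatC(v, digits = 15, format = "g")
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (header && !is.null(colnames(x))) {
    writeLines(paste(colnames(x), collapse = "\t"), con)
  }
  for (i in seq_len(nrow(x))) {
    writeLines(paste(fmt(x[i, ]), collapse = "\t"), con)
  }
  invisible(path)
}

#' Write a synthetic time-series set to a directory
#'
#' One tab-delimited file per subject (rows = regions, columns = timepoints)
#' plus a JSON manifest recording the configuration, group label and file
#' list.
#'
#' @param set A `roi_timeseries_set`.
#' @param out_dir Output directory (created if missing).
#' @param config Optional [simulation_config()] recorded in the manifest.
#' @return Character vector of the subject file paths, invisibly.
#' @export
write_timeseries_set <- function(set, out_dir, config = NULL) {
  stopifnot(inherits(set, "roi_timeseries_set"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(seq_along(set$subjects), function(s) {
    p <- file.path(out_dir, sprintf("%s_subject%02d.tsv", set$group_label, s))
    write_matrix(set$subjects[[s]], p, header = FALSE)
    p
  }, character(1))
  manifest <- list(group_label = set$group_label,
                   n_subjects = length(set$subjects),
                   n_regions = length(set$region_ids),
                   n_timepoints = ncol(set$subjects[[1]]),
                   tr_seconds = set$tr_seconds,
                   region_ids = set$region_ids,
                   files = basename(paths),
                   config = config_as_list(config))
  jsonlite::write_json(manifest,
                       file.path(out_dir, sprintf("%s_manifest.json", set$group_label)),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}

config_as_list <- function(config) {
  if (is.null(config)) return(NULL)
  unclass(config)
}

#' Read a time-series set written by [write_timeseries_set()]
#'
#' @param out_dir Directory holding the subject files and manifest.
#' @param group_label Group whose manifest to read.
#' @return A `roi_timeseries_set`.
#' @export
read_timeseries_set <- function(out_dir, group_label) {
  mpath <- file.path(out_dir, sprintf("%s_manifest.json", group_label))
  if (!file.exists(mpath)) stop(sprintf("manifest not found: %s", mpath), call. = FALSE)
  man <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  subjects <- lapply(file.path(out_dir, man$files), read_matrix, kind = "timeseries")
  subjects <- lapply(subjects, function(x) {
    rownames(x) <- man$region_ids
    x
  })
  structure(list(group_label = man$group_label, subjects = subjects,
                 region_ids = man$region_ids, tr_seconds = man$tr_seconds),
            class = "roi_timeseries_set")
}

#' Write result tables with a run manifest
#'
#' Writes each table as a tab-delimited file with deterministic column order
#' and number formatting (12 significant digits), plus `manifest.json`
#' recording the configuration, seeds and an MD5 hash of the serialized
#' configuration. Refuses to overwrite existing files unless `force = TRUE`.
#'
#' @param tables Named list of data frames.
#' @param manifest List of run metadata (configuration, seeds, notes).
#' @param out_dir Output directory (created if missing).
#' @param force Overwrite existing files.
#' @return Character vector of written paths, invisibly.
#' @export
write_results <- function(tables, manifest = list(), out_dir, force = FALSE) {
  stopifnot(is.list(tables), !is.null(names(tables)), all(nzchar(names(tables))))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(out_dir, paste0(names(tables), ".tsv"))
  mpath <- file.path(out_dir, "manifest.json")
  existing <- c(paths, mpath)[file.exists(c(paths, mpath))]
  if (length(existing) > 0 && !force) {
    stop(sprintf("refusing to overwrite existing output (use force = TRUE): %s",
                 paste(basename(existing), collapse = ", ")), call. = FALSE)
  }
  fmt <- function(v) {
    if (is.double(v)) formatC(v, digits = 12, format = "g") else as.character(v)
  }
  for (i in seq_along(tables)) {
    df <- as.data.frame(tables[[i]])
    cols <- lapply(df, fmt)
    con <- file(paths[i], open = "wt")
    writeLines(paste(names(df), collapse = "\t"), con)
    if (nrow(df) > 0) {
      body <- do.call(paste, c(cols, sep = "\t"))
      writeLines(body, con)
    }
    close(con)
  }
  cfg_tmp <- tempfile()
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA), cfg_tmp)
  manifest$config_md5 <- unname(tools::md5sum(cfg_tmp))
  unlink(cfg_tmp)
  manifest$tables <- basename(paths)
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(paths, mpath))
}
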