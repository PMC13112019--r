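# Functional-connectivity construction: time-series cleaning, Fisher-z
# correlation matrices, and the TSV readers/writers for both.

#' Detrend, filter and nuisance-regress ROI time series
#'
#' Applies the standard resting-state cleaning chain to a T x N matrix of
#' region-averaged BOLD signals, in a fixed order: linear detrend, temporal
#' bandpass, then OLS regression of nuisance confounds. Confound columns are
#' detrended and filtered identically before regression so that the
#' regression cannot reintroduce the removed frequency bands.
#'
#' The bandpass is a 4-pole Butterworth (two poles per band edge) applied
#' forward and backward (`signal::filtfilt`) for zero phase distortion.
#'
#' @param ts numeric T x N matrix, one column per region; no missing values.
#' @param confounds optional numeric T x K matrix of nuisance regressors
#'   (e.g. WM/CSF means, motion parameters); `NULL` for none.
#' @param band length-2 numeric, passband in Hz (default `c(0.01, 0.08)`).
#' @param tr sampling interval in seconds (default 2, i.e. TR = 2000 ms).
#' @return cleaned T x N matrix with the column names of `ts`.
#' @export
clean_timeseries <- function(ts, confounds = NULL, band = c(0.01, 0.08), tr = 2) {
  ts <- as.matrix(ts)
  stopifnot(is.numeric(ts), nrow(ts) >= 3)
  if (anyNA(ts)) stop("time series contain missing values")
  nyquist <- 1 / (2 * tr)
  if (length(band) != 2 || band[1] <= 0 || band[1] >= band[2]) {
    stop("band must be (low, high) with 0 < low < high")
  }
  if (band[2] >= nyquist) {
    stop("band high edge ", band[2], " Hz is at or above the Nyquist frequency ",
         nyquist, " Hz for tr = ", tr, " s")
  }
  tt <- nrow(ts)

  detrend <- function(x) {
    design <- cbind(1, seq_len(nrow(x)))
    x - design %*% qr.coef(qr(design), x)
  }
  bw <- signal::butter(2, band / nyquist, type = "pass")
  bandpass <- function(x) apply(x, 2, function(col) signal::filtfilt(bw, col))

  out <- bandpass(detrend(ts))

  if (!is.null(confounds) && NCOL(confounds) > 0) {
    confounds <- as.matrix(confounds)
    if (nrow(confounds) != tt) {
      stop("confounds have ", nrow(confounds), " rows but the series has ", tt)
    }
    conf <- bandpass(detrend(confounds))
    design <- cbind(1, conf)
    qrd <- qr(design)
    if (qrd$rank < ncol(design)) {
      keep <- qrd$pivot[seq_len(qrd$rank)]
      dropped <- setdiff(seq_len(ncol(design)), keep)
      warning("dropping ", length(dropped),
              " linearly dependent confound column(s)")
      design <- design[, keep, drop = FALSE]
      qrd <- qr(design)
    }
    out <- out - design %*% qr.coef(qrd, out)
  }
  dimnames(out) <- dimnames(ts)
  out
}

#' Fisher-z connectivity matrix from ROI time series
#'
#' Pearson correlation between every pair of columns, Fisher z-transformed
#' (`atanh`), with the diagonal set to zero. Correlations at or beyond
#' `1 - 1e-7` in magnitude are clipped before the transform, with a
#' warning, so degenerate inputs do not produce infinities.
#'
#' @param ts numeric T x N matrix, one column per region.
#' @return symmetric N x N Fisher-z matrix, zero diagonal, named like the
#'   columns of `ts`.
#' @export
correlation_matrix <- function(ts) {
  ts <- as.matrix(ts)
  stopifnot(nrow(ts) >= 3)
  sds <- col_sds(ts)
  if (any(sds == 0)) {
    bad <- which(sds == 0)
    labels <- colnames(ts)[bad] %||% bad
    stop("zero-variance region(s): ", paste(labels, collapse = ", "))
  }
  r <- stats::cor(ts)
  clip <- 1 - 1e-7
  off <- abs(r) >= clip & row(r) != col(r)
  if (any(off)) {
    warning(sum(off) / 2, " edge correlation(s) at |r| >= 1 clipped before atanh")
    r[off] <- sign(r[off]) * clip
  }
  z <- atanh(r)
  diag(z) <- 0
  (z + t(z)) / 2
}

# ---- file formats ----------------------------------------------------------

#' Read a TSV of ROI time series
#'
#' Expects T rows x N columns with a header row of region identifiers.
#'
#' @param path file path.
#' @return numeric matrix with region names as column names.
#' @export
read_timeseries_tsv <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE)
  as.matrix(d)
}

#' Write ROI time series as TSV
#' @param ts T x N matrix.
#' @param path output file.
#' @export
write_timeseries_tsv <- function(ts, path) {
  utils::write.table(ts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a square connectivity matrix as TSV
#'
#' The matrix is stored as N rows x N columns with a header of region
#' identifiers; symmetry is validated on read.
#'
#' @param path file path.
#' @return numeric symmetric matrix.
#' @export
read_matrix_tsv <- function(path) {
  m <- as.matrix(utils::read.delim(path, check.names = FALSE))
  rownames(m) <- colnames(m)
  if (nrow(m) != ncol(m)) stop("matrix in ", path, " is not square")
  if (max(abs(m - t(m))) > 1e-8) stop("matrix in ", path, " is not symmetric")
  m
}

#' @rdname read_matrix_tsv
#' @param m symmetric matrix to write.
#' @export
write_matrix_tsv <- function(m, path) {
  utils::write.table(m, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an edge table with explicit 0-based indices
#'
#' One row per edge, columns `i`, `j` (0-based region indices, row-major
#' strict upper triangle — the package-wide edge convention), region names
#' and the edge value.
#'
#' @param values numeric vector over `edges`.
#' @param edges integer vector of edge indices (1-based, into
#'   [edge_index()] order).
#' @param n_regions number of regions.
#' @param path output file.
#' @param atlas optional atlas table for region names.
#' @param value_name column name for `values` (default `"z"`).
#' @export
write_edge_table <- function(values, edges, n_regions, path, atlas = NULL,
                             value_name = "z") {
  idx <- edge_index(n_regions)[edges, , drop = FALSE]
  nm <- if (!is.null(atlas)) atlas$name else as.character(seq_len(n_regions))
  out <- data.frame(i = idx$i - 1L, j = idx$j - 1L,
                    region_i = nm[idx$i], region_j = nm[idx$j])
  out[[value_name]] <- values
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
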