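# Time-series cleaning and Fisher-Z functional connectivity.
#
# Cleaning follows the fixed order detrend -> nuisance regression -> band-pass.
# All steps are linear, and detrending is algebraically absorbed by the
# regression intercept, so the composite is insensitive to the relative order
# of the first two steps; fixing one order keeps outputs deterministic.

#' Remove the least-squares linear trend from each node series
#'
#' @param ts numeric matrix, nodes x timepoints (T >= 3).
#' @return matrix of the same shape; each row is the OLS residual against
#'   intercept + slope * t. Constant rows become all zero.
#' @export
remove_linear_trend <- function(ts) {
  ts <- as.matrix(ts)
  T_ <- ncol(ts)
  stopifnot(T_ >= 3)
  X <- cbind(1, seq_len(T_))
  Q <- qr.Q(qr(X))
  ts - (ts %*% Q) %*% t(Q)
}

#' Expand six motion parameters to the Friston 24-parameter set
#'
#' Rows are ordered in four blocks of six: the parameters m(t), their lag-1
#' versions m(t-1) (zero-padded at t = 1), their squares, and the squared
#' lagged series.
#'
#' @param motion numeric matrix `6 x T`.
#' @return numeric matrix `24 x T`.
#' @export
friston24_expand <- function(motion) {
  motion <- as.matrix(motion)
  if (nrow(motion) != 6L)
    stop("motion must have exactly 6 rows, got ", nrow(motion))
  T_ <- ncol(motion)
  lag1 <- cbind(0, motion[, -T_, drop = FALSE])
  rbind(motion, lag1, motion^2, lag1^2)
}

#' Regress nuisance signals out of node time series
#'
#' Each node series is replaced by its OLS residual against an intercept plus
#' the supplied regressors. With no regressors this demeans each series.
#'
#' @param ts numeric matrix, nodes x timepoints.
#' @param regressors numeric matrix `K x T` (e.g. a Friston-24 set plus tissue
#'   signals), or `NULL`.
#' @return residual matrix, same shape as `ts`.
#' @export
regress_nuisance <- function(ts, regressors = NULL) {
  ts <- as.matrix(ts)
  T_ <- ncol(ts)
  if (is.null(regressors) || nrow(as.matrix(regressors)) == 0L) {
    design <- matrix(1, T_, 1L)
  } else {
    regressors <- as.matrix(regressors)
    if (ncol(regressors) != T_)
      stop("regressors must have as many columns as ts has timepoints")
    if (nrow(regressors) >= T_)
      stop("need fewer regressors than timepoints")
    design <- cbind(1, t(regressors))
  }
  dec <- qr(design)
  if (dec$rank < ncol(design)) {
    dropped <- dec$pivot[(dec$rank + 1L):ncol(design)] - 1L  # 0 = intercept
    stop("rank-deficient nuisance design; collinear regressor rows: ",
         paste(dropped, collapse = ", "))
  }
  Q <- qr.Q(dec)
  ts - (ts %*% Q) %*% t(Q)
}

#' Ideal (rectangular) FFT band-pass filter
#'
#' Zeroes every Fourier coefficient whose frequency lies outside
#' `[low, high]` and inverse-transforms back to a real series. With
#' `low > 0` the DC component is removed. This is the ideal rectangular
#' filter common in resting-state pipelines: exact passthrough in band,
#' exact rejection out of band.
#'
#' @param ts numeric matrix, nodes x timepoints.
#' @param tr repetition time in seconds.
#' @param low,high band edges in Hz; requires `0 <= low < high < 1/(2*tr)`.
#' @return filtered matrix, same shape.
#' @export
bandpass_filter <- function(ts, tr, low = 0.01, high = 0.08) {
  ts <- as.matrix(ts)
  T_ <- ncol(ts)
  nyquist <- 1 / (2 * tr)
  if (!(low >= 0 && low < high)) stop("need 0 <= low < high")
  if (high >= nyquist)
    stop(sprintf("high (%.4f Hz) must be below the Nyquist frequency (%.4f Hz)",
                 high, nyquist))
  freq <- (seq_len(T_) - 1L) / (T_ * tr)
  folded <- pmin(freq, 1 / tr - freq)  # two-sided spectrum
  eps <- 1e-12
  keep <- folded >= low - eps & folded <= high + eps
  co <- stats::mvfft(t(ts))
  co[!keep, ] <- 0
  t(Re(stats::mvfft(co, inverse = TRUE)) / T_)
}

#' Clean node time series
#'
#' Fixed composite: linear detrend, nuisance regression (Friston-24 expansion
#' of the motion parameters plus any extra regressor rows), then band-pass
#' filtering.
#'
#' @param ts numeric matrix, nodes x timepoints.
#' @param tr repetition time in seconds.
#' @param motion optional `6 x T` motion-parameter matrix.
#' @param extra_regressors optional `K x T` matrix (e.g. tissue signals).
#' @param low,high band-pass edges in Hz.
#' @return cleaned matrix, same shape.
#' @export
clean_timeseries <- function(ts, tr, motion = NULL, extra_regressors = NULL,
                             low = 0.01, high = 0.08) {
  out <- remove_linear_trend(ts)
  regs <- NULL
  if (!is.null(motion)) regs <- friston24_expand(motion)
  if (!is.null(extra_regressors)) regs <- rbind(regs, as.matrix(extra_regressors))
  out <- regress_nuisance(out, regs)
  bandpass_filter(out, tr, low, high)
}

#' Fisher-Z functional connectivity matrix
#'
#' Pearson correlation between every pair of node series, clipped to
#' `|r| <= 1 - 1e-7` so the Fisher transform stays finite, then
#' `Z = atanh(r)`. The diagonal is fixed at 0: self-connections are not
#' features.
#'
#' @param ts numeric matrix, nodes x timepoints (T >= 3; every node series
#'   must have nonzero variance).
#' @param subject_id optional id stored as an attribute.
#' @return symmetric `N x N` matrix of Fisher-Z correlations, diagonal 0.
#' @export
pearson_fc <- function(ts, subject_id = NULL) {
  ts <- as.matrix(ts)
  stopifnot(ncol(ts) >= 3)
  v <- apply(ts, 1L, stats::var)
  if (any(v == 0))
    stop("zero-variance node series at index: ",
         paste(which(v == 0), collapse = ", "))
  r <- stats::cor(t(ts))
  clip <- 1 - 1e-7
  r <- pmin(pmax(r, -clip), clip)
  z <- atanh(r)
  z <- (z + t(z)) / 2
  diag(z) <- 0
  if (!is.null(subject_id)) attr(z, "subject_id") <- subject_id
  z
}

#' Vectorize the upper triangle of an FC matrix
#'
#' Flattens the upper triangle in the canonical row-major order
#' (1,2), (1,3), ..., (1,N), (2,3), ... giving the `N(N-1)/2` edge feature
#' vector (7,503 for a 123-node hemisphere network). Named `FC_<i>_<j>`.
#'
#' @param fc symmetric matrix.
#' @return named numeric vector with attribute `n_nodes`.
#' @export
vectorize_edges <- function(fc) {
  n <- nrow(fc)
  ei <- edge_index(n)
  v <- fc[ei]
  names(v) <- edge_feature_ids(n)
  attr(v, "n_nodes") <- n
  v
}

#' Rebuild a symmetric matrix from an edge vector
#'
#' Exact inverse of [vectorize_edges()] (diagonal restored as 0).
#'
#' @param v edge vector of length `N(N-1)/2`.
#' @param n_nodes number of nodes `N`; taken from the vector's attribute if
#'   missing.
#' @return symmetric `N x N` matrix with zero diagonal.
#' @export
devectorize_edges <- function(v, n_nodes = NULL) {
  n <- n_nodes %||% attr(v, "n_nodes")
  if (is.null(n)) stop("n_nodes not supplied and not stored on the vector")
  if (length(v) != n * (n - 1) / 2)
    stop("edge vector length does not match n_nodes")
  ei <- edge_index(n)
  m <- matrix(0, n, n)
  m[ei] <- v
  m[ei[, c(2L, 1L)]] <- v
  m
}

#' FC edge features for a whole cohort
#'
#' Cleans each subject's time series (detrend, optional motion regression,
#' band-pass) and stacks the Fisher-Z edge vectors into a subjects x edges
#' matrix.
#'
#' @param cohort a `cohort` object.
#' @param clean apply [clean_timeseries()] first (default TRUE).
#' @param motion optional list of `6 x T` matrices, one per subject.
#' @param low,high band-pass edges in Hz.
#' @return numeric matrix with rownames = subject ids and edge feature
#'   columns.
#' @export
cohort_fc_features <- function(cohort, clean = TRUE, motion = NULL,
                               low = 0.01, high = 0.08) {
  tr <- cohort$spec$tr_seconds
  rows <- lapply(seq_along(cohort$subjects), function(s) {
    sub <- cohort$subjects[[s]]
    ts <- sub$timeseries
    if (clean) {
      mo <- if (is.null(motion)) NULL else motion[[s]]
      ts <- clean_timeseries(ts, tr, motion = mo, low = low, high = high)
    }
    vectorize_edges(pearson_fc(ts, subject_id = sub$id))
  })
  X <- do.call(rbind, rows)
  rownames(X) <- vapply(cohort$subjects, `[[`, "", "id")
  X
}
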