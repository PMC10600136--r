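COMPONENTS <- c("deoxy", "exc", "oxy", "sat", "total")

as_hb_matrix <- function(x, arg = "series") {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x))
    stop(sprintf("`%s` must be a numeric matrix (frames x voxels)", arg), call. = FALSE)
  storage.mode(x) <- "double"
  x
}

#' Remove per-voxel linear trends from a time series matrix
#'
#' Subtracts, independently for every voxel (column), the least-squares
#' straight line fitted across the time dimension.  Long-term drifts are
#' removed while shorter-scale fluctuations are retained; the residual
#' column means are zero by construction.
#'
#' @param series numeric matrix, `n_frames x n_voxels`.
#' @return matrix of the same shape with each column's linear trend removed.
#' @examples
#' detrend_linear(cbind(1:4, c(0, 1, 0, 1)))
#' @export
detrend_linear <- function(series) {
  series <- as_hb_matrix(series)
  n <- nrow(series)
  if (n < 2L) stop("detrending requires at least 2 time frames", call. = FALSE)
  tt <- seq_len(n) - (n + 1) / 2           # centred time, orthogonal to intercept
  slope <- crossprod(tt, series) / sum(tt^2)
  sweep(series - tcrossprod(tt, drop(slope)), 2L, colMeans(series))
}

#' Build the five-component hemoglobin signal
#'
#' From the two independent components (deviations of oxy- and
#' deoxyhemoglobin about their temporal means) constructs the three
#' dependent ones: total hemoglobin `total = deoxy + oxy`, oxygen exchange
#' `exc = deoxy - oxy`, and oxygen saturation
#' `sat = 100 * ((oxy0 + oxy)/(total0 + total) - oxy0/total0)` (percent),
#' where `oxy0`, `deoxy0` are absolute molar baselines and
#' `total0 = oxy0 + deoxy0`.  All five components are re-referenced to zero
#' temporal mean per voxel after computation, since the state partition is
#' defined relative to temporal means.
#'
#' @param oxy,deoxy numeric matrices (`n_frames x n_voxels`) of molar
#'   deviations about the temporal mean.
#' @param baseline length-2 numeric `c(oxy0, deoxy0)`, absolute molar
#'   baselines; both must be positive.  The default corresponds to a
#'   baseline tissue saturation of 0.7 at total hemoglobin 1e-4 M.
#' @param frame_rate sampling rate in frames per second.
#' @param detrend if `TRUE` (default), [detrend_linear()] is applied to the
#'   independent components before the dependent ones are computed.
#' @return an object of class `hb_series`: a list with elements
#'   `components` (named list of the five matrices), `n_frames`,
#'   `n_voxels`, `frame_rate`, `baseline`.
#' @export
hb_series <- function(oxy, deoxy, baseline = c(oxy0 = 7e-5, deoxy0 = 3e-5),
                      frame_rate = 1.8, detrend = TRUE) {
  oxy <- as_hb_matrix(oxy, "oxy"); deoxy <- as_hb_matrix(deoxy, "deoxy")
  if (!identical(dim(oxy), dim(deoxy)))
    stop("`oxy` and `deoxy` must have identical dimensions", call. = FALSE)
  if (nrow(oxy) < 2L) stop("need at least 2 time frames", call. = FALSE)
  baseline <- as.numeric(baseline)
  if (length(baseline) != 2L || any(!is.finite(baseline)) || any(baseline <= 0))
    stop("`baseline` must be two positive numbers (oxy0, deoxy0)", call. = FALSE)
  oxy0 <- baseline[1L]; deoxy0 <- baseline[2L]; total0 <- oxy0 + deoxy0
  if (detrend) {
    oxy <- detrend_linear(oxy)
    deoxy <- detrend_linear(deoxy)
  }
  total <- deoxy + oxy
  exc <- deoxy - oxy
  denom <- total0 + total
  if (any(denom <= 0)) {
    bad <- which(denom <= 0, arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "degenerate saturation: total0 + dTotal <= 0 at frame %d, voxel %d",
      bad[1L], bad[2L]), call. = FALSE)
  }
  sat <- 100 * ((oxy0 + oxy) / denom - oxy0 / total0)
  comps <- list(deoxy = deoxy, exc = exc, oxy = oxy, sat = sat, total = total)
  # zero-mean re-referencing: state signs are relative to temporal means
  comps <- lapply(comps, function(m) sweep(m, 2L, colMeans(m)))
  structure(list(
    components = comps,
    n_frames = nrow(oxy), n_voxels = ncol(oxy),
    frame_rate = frame_rate,
    baseline = c(oxy0 = oxy0, deoxy0 = deoxy0)
  ), class = "hb_series")
}

#' @export
print.hb_series <- function(x, ...) {
  cat(sprintf(
    "<hb_series> %d frames x %d voxels @ %.3g frames/s (oxy0 = %.3g M, deoxy0 = %.3g M)\n",
    x$n_frames, x$n_voxels, x$frame_rate, x$baseline[["oxy0"]], x$baseline[["deoxy0"]]))
  invisible(x)
}

#' Baseline saturation fraction of an `hb_series`
#' @param series an `hb_series`.
#' @return `oxy0 / (oxy0 + deoxy0)`, dimensionless.
#' @export
baseline_saturation <- function(series) {
  unname(series$baseline[["oxy0"]] / sum(series$baseline))
}
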