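#' Preprocessing configuration
#'
#' Controls the stride-series conditioning pipeline: missing-stride
#' interpolation, session-local moving-average smoothing, baseline
#' referencing and SD normalization. Defaults follow the study protocol:
#' each stride averaged with its two preceding and two subsequent strides
#' within the same session, the late-baseline window strides 81--100 as
#' the zero reference, and the standard deviation of strides 81 to the end
#' as the normalization scale.
#'
#' @param smoothing_half_width non-negative integer; strides averaged with
#'   `half_width` neighbors on each side (default 2, a 5-stride window).
#' @param reference_window length-2 integer vector, the baseline strides
#'   whose mean defines the zero response (default `c(81, 100)`).
#' @param normalization_start first stride of the SD-normalization window,
#'   which runs to the end of the series (default 81).
#' @return object of class `preprocess_config`.
#' @export
preprocess_config <- function(smoothing_half_width = 2L,
                              reference_window = c(81L, 100L),
                              normalization_start = 81L) {
  stopifnot(smoothing_half_width >= 0, length(reference_window) == 2L,
            reference_window[1L] >= 1L,
            reference_window[2L] >= reference_window[1L],
            normalization_start >= 1L)
  structure(list(smoothing_half_width = as.integer(smoothing_half_width),
                 reference_window = as.integer(reference_window),
                 normalization_start = as.integer(normalization_start)),
            class = "preprocess_config")
}

#' Fill missing strides by linear interpolation
#'
#' Interior gaps are filled by linear interpolation against the stride
#' index; leading/trailing gaps are extended with the nearest observed
#' value (interpolation being undefined there). Observed values are left
#' untouched and the missing mask is cleared.
#'
#' @param series a [stride_series()].
#' @return the series with no missing strides.
#' @export
fill_missing <- function(series) {
  stopifnot(inherits(series, "stride_series"))
  miss <- series$missing
  if (!any(miss)) return(series)
  if (all(miss)) stop("all strides are missing; nothing to interpolate")
  v <- series$values
  v[miss] <- NA_real_
  filled <- stats::approx(x = which(!miss), y = v[!miss],
                          xout = seq_along(v), method = "linear",
                          rule = 2)$y   # rule 2: nearest-value extension
  set_values(series, filled)
}

#' Session-local moving-average smoothing
#'
#' Replaces each stride by the mean of the strides within
#' `smoothing_half_width` positions on either side that belong to the same
#' session; windows shrink at session boundaries, so no information bleeds
#' across baseline / intervention / washout transitions.
#'
#' @param series a [stride_series()] with no missing values.
#' @param config a [preprocess_config()].
#' @return the smoothed series.
#' @export
smooth_within_session <- function(series, config = preprocess_config()) {
  stopifnot(inherits(series, "stride_series"))
  if (any(series$missing))
    stop("smoothing requires a complete series; run fill_missing() first")
  h <- config$smoothing_half_width
  if (h == 0L) return(series)
  v <- series$values
  out <- v
  for (sess in unique(series$sessions)) {
    idx <- which(series$sessions == sess)
    m <- length(idx)
    sv <- v[idx]
    cs <- cumsum(c(0, sv))
    pos <- seq_len(m)
    lo <- pmax(pos - h, 1L)
    hi <- pmin(pos + h, m)
    out[idx] <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  }
  set_values(series, out)
}

#' Baseline referencing and SD normalization
#'
#' Subtracts the mean response over the late-baseline reference window
#' (strides 81--100 by default, after which participants are assumed
#' accustomed to the setup) from every stride, then divides by the sample
#' standard deviation of the referenced responses from
#' `normalization_start` to the end. Afterwards the reference-window mean
#' is 0 and the normalization-window SD is 1.
#'
#' @param series a [stride_series()] with no missing values.
#' @param config a [preprocess_config()].
#' @return the referenced, normalized series (dimensionless).
#' @export
reference_and_scale <- function(series, config = preprocess_config()) {
  stopifnot(inherits(series, "stride_series"))
  n <- length(series)
  rw <- config$reference_window
  if (n < rw[2L])
    stop("series too short (", n, " strides) for reference window [",
         rw[1L], ", ", rw[2L], "]")
  if (any(series$sessions[rw[1L]:rw[2L]] != "baseline"))
    stop("reference window must lie within the baseline session")
  v <- series$values - mean(series$values[rw[1L]:rw[2L]])
  s <- stats::sd(v[config$normalization_start:n])
  if (!is.finite(s) || s == 0)
    stop("zero standard deviation over the normalization window; ",
         "cannot scale a constant series")
  set_values(series, v / s)
}

#' Full preprocessing pipeline
#'
#' Composition of [fill_missing()], [smooth_within_session()] and
#' [reference_and_scale()], in that order.
#'
#' @param series a [stride_series()].
#' @param config a [preprocess_config()].
#' @return the conditioned series.
#' @export
preprocess <- function(series, config = preprocess_config()) {
  series |>
    fill_missing() |>
    smooth_within_session(config) |>
    reference_and_scale(config)
}
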