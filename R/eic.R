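#' Extract an ion chromatogram for one target
#'
#' For every MS1 spectrum in the retention-time window, the EIC point is
#' the sum of all centroid intensities whose m/z lies within `ppm_tol`
#' (inclusive, symmetric) of the target m/z, or 0 when none do. Summing
#' in-tolerance centroids (rather than taking the maximum) is robust to
#' centroid splitting. Lookup uses binary search over each spectrum's
#' ascending m/z array.
#'
#' @param run A [ms_run()].
#' @param target One-row data.frame or list with `name`, `mz` (and
#'   optionally `rt`), e.g. one row of a library's `targets`.
#' @param ppm_tol Mass tolerance in ppm (> 0).
#' @param rt_window Length-2 numeric `c(from, to)` in seconds, or `NULL`
#'   for the whole run.
#' @return A `semiq_eic` object with fields `compound_name`, `mz_target`,
#'   `ppm_tol`, `rt`, `intensity` and (initially absent) `smoothed`,
#'   `noise_level`.
#' @export
extract_eic <- function(run, target, ppm_tol = 20, rt_window = NULL) {
  stopifnot(ppm_tol > 0)
  mz0 <- as.numeric(target$mz)
  delta <- mz0 * ppm_tol * 1e-6
  lo <- mz0 - delta
  hi <- mz0 + delta
  is_ms1 <- vapply(run$spectra, function(s) s$ms_level == 1L, logical(1))
  ms1 <- run$spectra[is_ms1]
  rts <- vapply(ms1, `[[`, numeric(1), "rt")
  if (!is.null(rt_window) && !all(is.na(rt_window))) {
    keep <- rts >= rt_window[1] & rts <= rt_window[2]
    if (!any(keep))
      stop("empty EIC: rt window [", rt_window[1], ", ", rt_window[2],
           "] contains no MS1 scans")
    ms1 <- ms1[keep]; rts <- rts[keep]
  }
  intens <- vapply(ms1, function(s) {
    n <- length(s$mz)
    if (n == 0L) return(0)
    i1 <- findInterval(lo, s$mz) + 1L  # first index with mz >= lo
    i2 <- findInterval(hi, s$mz)       # last index with mz <= hi
    if (i1 > i2) 0 else sum(s$intensity[i1:i2])
  }, numeric(1))
  structure(
    list(compound_name = as.character(target$name), mz_target = mz0,
         ppm_tol = ppm_tol, rt = rts, intensity = intens,
         smoothed = NULL, noise_level = NULL, params = list()),
    class = "semiq_eic")
}

#' Smooth an ion chromatogram
#'
#' Fills the `smoothed` field of an EIC using one of four methods:
#' \describe{
#'   \item{moving_mean}{Centred moving average of odd width `window`;
#'     edges are handled by truncating the window to the available
#'     points.}
#'   \item{gaussian}{Convolution with a Gaussian kernel of standard
#'     deviation `sigma` scan units, renormalised over the available
#'     points at the edges.}
#'   \item{savitzky_golay}{Least-squares local polynomial of order
#'     `order` over odd width `window` ([signal::sgolayfilt()]).}
#'   \item{loess}{Local regression against scan index with span `span`.}
#' }
#' Smoothing never changes the trace length and never interpolates
#' missing scans; it operates on the scan grid as acquired. Negative
#' values (possible for the polynomial methods) are clipped to 0.
#'
#' @param eic A `semiq_eic`.
#' @param method One of `"moving_mean"`, `"gaussian"`,
#'   `"savitzky_golay"`, `"loess"`.
#' @param params Named list of method parameters (`window`, `sigma`,
#'   `order`, `span`); missing entries take the defaults of
#'   [default_config()].
#' @return The EIC with `smoothed` filled.
#' @export
smooth_eic <- function(eic, method = c("savitzky_golay", "moving_mean",
                                       "gaussian", "loess"),
                       params = list()) {
  method <- match.arg(method)
  p <- merge_config(default_config()$eic$smoother_params, params)
  x <- eic$intensity
  n <- length(x)
  sm <- switch(method,
    moving_mean = {
      w <- as.integer(p$window)
      if (w %% 2L == 0L) stop("moving_mean window must be odd")
      if (w >= n) stop("smoothing window must be smaller than trace length")
      h <- (w - 1L) %/% 2L
      vapply(seq_len(n), function(i) {
        j <- max(1L, i - h):min(n, i + h)
        mean(x[j])
      }, numeric(1))
    },
    gaussian = {
      sigma <- p$sigma
      if (sigma <= 0) stop("gaussian sigma must be > 0")
      h <- max(1L, ceiling(3 * sigma))
      if (2L * h + 1L >= 2L * n)
        stop("smoothing window must be smaller than trace length")
      k <- stats::dnorm(-h:h, sd = sigma)
      vapply(seq_len(n), function(i) {
        j <- max(1L, i - h):min(n, i + h)
        kv <- k[j - i + h + 1L]
        sum(x[j] * kv) / sum(kv)
      }, numeric(1))
    },
    savitzky_golay = {
      w <- as.integer(p$window)
      if (w %% 2L == 0L) stop("savitzky_golay window must be odd")
      if (w >= n) stop("smoothing window must be smaller than trace length")
      as.numeric(signal::sgolayfilt(x, p = as.integer(p$order), n = w))
    },
    loess = {
      if (p$span <= 0 || p$span > 1) stop("loess span must be in (0, 1]")
      if (ceiling(p$span * n) < 4L)
        stop("loess span too small for trace length")
      idx <- seq_len(n)
      fit <- stats::loess(x ~ idx, span = p$span, degree = 2,
                          family = "gaussian",
                          control = stats::loess.control(surface = "direct"))
      as.numeric(stats::predict(fit, idx))
    })
  sm <- pmax(sm, 0)
  eic$smoothed <- sm
  eic$params$smoother <- method
  eic$params$smoother_params <- p
  eic
}

#' Estimate the noise level of an ion chromatogram
#'
#' Three estimators of the intensity-scale noise used for signal-to-noise
#' screening:
#' \describe{
#'   \item{mad}{`1.4826 * median(|I - median(I)|)` (consistent for a
#'     Gaussian).}
#'   \item{low_percentile}{Mean of all intensities at or below the 50th
#'     percentile (zeros included).}
#'   \item{sliding_window}{Minimum over non-overlapping windows of width
#'     `window` (default 11) of the within-window standard deviation
#'     (disjoint windows keep the minimum from collapsing toward the
#'     extreme order statistics of heavily overlapping windows).}
#' }
#' A floor of 1.0 intensity unit is applied so signal-to-noise ratios are
#' always finite.
#'
#' @param eic A `semiq_eic` of length >= 5.
#' @param method One of `"mad"`, `"low_percentile"`, `"sliding_window"`.
#' @param window Window width for `sliding_window`.
#' @return The EIC with `noise_level` filled.
#' @export
estimate_noise <- function(eic, method = c("mad", "low_percentile",
                                           "sliding_window"),
                           window = 11L) {
  method <- match.arg(method)
  x <- eic$intensity
  if (length(x) < 5L) stop("noise estimation requires a trace of length >= 5")
  noise <- switch(method,
    mad = stats::mad(x, constant = 1.4826),
    low_percentile = {
      thr <- stats::quantile(x, 0.5, names = FALSE)
      mean(x[x <= thr])
    },
    sliding_window = {
      w <- min(as.integer(window), length(x))
      starts <- seq(1L, length(x) - w + 1L, by = w)
      min(vapply(starts, function(i) stats::sd(x[i:(i + w - 1L)]),
                 numeric(1)))
    })
  eic$noise_level <- max(noise, 1.0)
  eic$params$noise_method <- method
  eic
}
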