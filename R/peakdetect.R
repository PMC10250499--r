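#' Select candidate chromatographic peaks on an EIC
#'
#' Three selection methods over the smoothed trace:
#' \describe{
#'   \item{local_max}{Apices are points that are maxima within `+/-k`
#'     scans (`local_max_k`, default 2) and whose smoothed intensity is at
#'     least `snr_min * noise`. Boundaries extend from the apex to the
#'     nearest local minimum, the first point below
#'     `boundary_frac * apex` (default 0.05), or the trace end.}
#'   \item{derivative}{Apices where the first difference changes sign
#'     from positive to negative and the second difference is negative;
#'     boundaries where the absolute first difference falls below
#'     `deriv_eps * apex`.}
#'   \item{cwt}{Mexican-hat continuous wavelet transform at scales
#'     `cwt_scales` (default 2..16 scan units); ridge lines of length
#'     >= 3 linked across scales; the apex sits at the maximum ridge
#'     coefficient and boundaries at `+/- 2 * best_scale`, clipped to
#'     local minima of the smoothed trace.}
#' }
#' All methods require an apex of at least `snr_min * noise`; candidates
#' spanning fewer than 3 scans are dropped. Overlapping candidates (one
#' apex inside another's bounds) are merged keeping the higher apex, ties
#' broken by earlier retention time. Candidates are returned sorted by
#' apex retention time with their areas unset.
#'
#' @param eic A `semiq_eic` with `smoothed` and `noise_level` filled.
#' @param method `"local_max"`, `"derivative"` or `"cwt"`.
#' @param params Named list overriding `peak` defaults of
#'   [default_config()] (`snr_min`, `local_max_k`, `boundary_frac`,
#'   `deriv_eps`, `cwt_scales`).
#' @param file_id Run identifier stamped on the candidates.
#' @return List of candidate peak objects.
#' @export
select_peaks <- function(eic, method = c("local_max", "derivative", "cwt"),
                         params = list(), file_id = "") {
  method <- match.arg(method)
  if (is.null(eic$smoothed) || is.null(eic$noise_level))
    stop("EIC must be smoothed and have a noise estimate before peak selection")
  p <- merge_config(default_config()$peak, params)
  y <- eic$smoothed
  n <- length(y)
  thr <- p$snr_min * eic$noise_level
  apices <- switch(method,
    local_max = local_max_apices(y, as.integer(p$local_max_k), thr),
    derivative = derivative_apices(y, thr),
    cwt = NULL)
  cands <- list()
  if (method == "cwt") {
    ridges <- cwt_ridges(y, as.integer(p$cwt_scales))
    for (r in ridges) {
      i <- r$apex
      if (y[i] < thr) next
      half <- 2L * r$scale
      b <- clip_to_minima(y, i, max(1L, i - half), min(n, i + half))
      cands[[length(cands) + 1L]] <- c(b[1], i, b[2])
    }
  } else {
    for (i in apices) {
      b <- switch(method,
        local_max = walk_bounds(y, i, p$boundary_frac),
        derivative = deriv_bounds(y, i, p$deriv_eps))
      cands[[length(cands) + 1L]] <- c(b[1], i, b[2])
    }
  }
  peaks <- list()
  for (cc in cands) {
    l <- cc[1]; i <- cc[2]; r <- cc[3]
    if (r - l + 1L < 3L) next
    peaks[[length(peaks) + 1L]] <- new_chrom_peak(
      compound_name = eic$compound_name, file_id = file_id,
      rt_start = eic$rt[l], rt_apex = eic$rt[i], rt_end = eic$rt[r],
      apex_intensity = eic$intensity[i], n_points = r - l + 1L)
  }
  merge_overlapping(peaks)
}

local_max_apices <- function(y, k, thr) {
  n <- length(y)
  out <- integer(0)
  for (i in seq_len(n)) {
    if (y[i] < thr) next
    j <- max(1L, i - k):min(n, i + k)
    if (y[i] < max(y[j])) next
    # on a plateau keep only the first point
    if (i > 1L && y[i - 1L] == y[i]) next
    if (y[i] == max(y[j]) && sum(y[j] == y[i]) <= k + 1L)
      out <- c(out, i)
  }
  out
}

derivative_apices <- function(y, thr) {
  n <- length(y)
  if (n < 3L) return(integer(0))
  d <- diff(y)
  out <- integer(0)
  for (i in 2:(n - 1L)) {
    if (d[i - 1L] > 0 && d[i] <= 0 &&
        (y[i + 1L] - 2 * y[i] + y[i - 1L]) < 0 && y[i] >= thr)
      out <- c(out, i)
  }
  out
}

# extend from apex to nearest local minimum, first sub-threshold point,
# or trace end
walk_bounds <- function(y, i, boundary_frac) {
  n <- length(y)
  floor_int <- boundary_frac * y[i]
  l <- i
  while (l > 1L && y[l - 1L] < y[l]) {
    l <- l - 1L
    if (y[l] < floor_int) break
  }
  r <- i
  while (r < n && y[r + 1L] < y[r]) {
    r <- r + 1L
    if (y[r] < floor_int) break
  }
  c(l, r)
}

deriv_bounds <- function(y, i, deriv_eps) {
  n <- length(y)
  eps <- deriv_eps * y[i]
  l <- i
  while (l > 1L && y[l - 1L] < y[l] && abs(y[l] - y[l - 1L]) >= eps)
    l <- l - 1L
  r <- i
  while (r < n && y[r + 1L] < y[r] && abs(y[r + 1L] - y[r]) >= eps)
    r <- r + 1L
  c(l, r)
}

clip_to_minima <- function(y, i, l0, r0) {
  l <- i
  while (l > l0 && y[l - 1L] < y[l]) l <- l - 1L
  r <- i
  while (r < r0 && y[r + 1L] < y[r]) r <- r + 1L
  c(l, r)
}

# Mexican-hat CWT with simple ridge linking across adjacent scales
cwt_ridges <- function(y, scales) {
  n <- length(y)
  scales <- sort(unique(scales))
  scales <- scales[2L * ceiling(4 * scales) + 1L < n]  # kernel must fit
  if (length(scales) < 3L) return(list())
  coef <- matrix(0, nrow = length(scales), ncol = n)
  for (si in seq_along(scales)) {
    a <- scales[si]
    h <- ceiling(4 * a)
    t <- (-h):h
    psi <- (1 - (t / a)^2) * exp(-(t / a)^2 / 2)
    psi <- psi - mean(psi)  # zero-mean so flat traces transform to 0
    cv <- stats::filter(y, rev(psi) / sqrt(a), sides = 2)
    cv[is.na(cv)] <- 0
    coef[si, ] <- as.numeric(cv)
  }
  maxima <- lapply(seq_along(scales), function(si) {
    v <- coef[si, ]
    which(v > 0 &
          v >= c(-Inf, v[-n]) & v >= c(v[-1], -Inf) &
          v == vapply(seq_len(n), function(i)
            max(v[max(1, i - scales[si]):min(n, i + scales[si])]),
            numeric(1)))
  })
  # link maxima from the smallest scale upward; tolerance = current scale
  ridges <- list()
  used <- lapply(maxima, function(m) rep(FALSE, length(m)))
  for (start in seq_along(maxima[[1]])) {
    pos <- maxima[[1]][start]
    if (used[[1]][start]) next
    used[[1]][start] <- TRUE
    line_pos <- pos; line_scale <- 1L
    best_val <- coef[1L, pos]; best_pos <- pos; best_si <- 1L
    cur <- pos
    for (si in seq_along(scales)[-1]) {
      cand <- maxima[[si]]
      if (length(cand) == 0L) break
      d <- abs(cand - cur)
      j <- which.min(d)
      if (d[j] > scales[si]) break
      if (used[[si]][j]) break
      used[[si]][j] <- TRUE
      cur <- cand[j]
      line_pos <- c(line_pos, cur)
      line_scale <- c(line_scale, si)
      if (coef[si, cur] > best_val) {
        best_val <- coef[si, cur]; best_pos <- cur; best_si <- si
      }
    }
    if (length(line_pos) >= 3L)
      ridges[[length(ridges) + 1L]] <-
        list(apex = best_pos, scale = scales[best_si], strength = best_val)
  }
  ridges
}

merge_overlapping <- function(peaks) {
  if (length(peaks) <= 1L) return(order_peaks(peaks))
  peaks <- order_peaks(peaks)
  repeat {
    merged <- FALSE
    for (i in seq_along(peaks)) {
      for (j in seq_along(peaks)) {
        if (i == j) next
        a <- peaks[[i]]; b <- peaks[[j]]
        if (b$rt_apex >= a$rt_start && b$rt_apex <= a$rt_end) {
          # keep the higher apex; ties to the earlier rt
          keep <- if (a$apex_intensity > b$apex_intensity) a
                  else if (b$apex_intensity > a$apex_intensity) b
                  else if (a$rt_apex <= b$rt_apex) a else b
          peaks[[min(i, j)]] <- keep
          peaks[[max(i, j)]] <- NULL
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }
  order_peaks(peaks)
}

order_peaks <- function(peaks) {
  if (length(peaks) <= 1L) return(peaks)
  peaks[order(vapply(peaks, `[[`, numeric(1), "rt_apex"))]
}

#' Integrate a chromatographic peak
#'
#' Two integrators over the raw (unsmoothed) trace between the peak
#' bounds:
#' \describe{
#'   \item{raw_trapezoid}{Trapezoidal sum of the raw intensities.}
#'   \item{baseline_trapezoid}{Raw trapezoid minus the trapezoidal area
#'     of the straight line joining the boundary intensities (a linear
#'     baseline), clipped at 0.}
#' }
#' The signal-to-noise ratio is set here as the raw apex intensity over
#' the EIC noise level.
#'
#' @param eic The `semiq_eic` the peak was detected on (with
#'   `noise_level`).
#' @param peak A candidate peak from [select_peaks()].
#' @param method `"baseline_trapezoid"` or `"raw_trapezoid"`.
#' @return The peak with `area` and `snr` filled.
#' @export
integrate_peak <- function(eic, peak, method = c("baseline_trapezoid",
                                                 "raw_trapezoid")) {
  method <- match.arg(method)
  idx <- which(eic$rt >= peak$rt_start & eic$rt <= peak$rt_end)
  if (length(idx) < 2L ||
      peak$rt_start < eic$rt[1] || peak$rt_end > eic$rt[length(eic$rt)])
    stop("peak bounds outside the EIC retention-time range")
  t <- eic$rt[idx]
  v <- eic$intensity[idx]
  raw <- sum(diff(t) * (v[-length(v)] + v[-1]) / 2)
  area <- if (method == "raw_trapezoid") raw else {
    base <- (v[1] + v[length(v)]) / 2 * (t[length(t)] - t[1])
    max(raw - base, 0)
  }
  peak$area <- area
  if (!is.null(eic$noise_level)) peak$snr <- peak$apex_intensity / eic$noise_level
  peak
}

#' Screen a peak against quality criteria
#'
#' Annotates (never deletes) a peak with the names of the quality
#' criteria it fails, out of five:
#' `snr` (`snr >= snr_min`), `intensity` (`apex_intensity >= int_min`),
#' `rt_deviation` (`|rt_apex - expected_rt| <= rt_tol`), `width`
#' (within `[width_min, width_max]`), `asymmetry` (left/right half-width
#' ratio within `[1/asym_max, asym_max]`). Screening is idempotent and
#' the criteria are independent.
#'
#' @param peak An integrated peak (with `snr`).
#' @param expected_rt Calibrated expected retention time in seconds, or
#'   `NA` to skip the rt criterion.
#' @param params Named list overriding `peak` defaults of
#'   [default_config()].
#' @return The peak with `screen_flags` set.
#' @export
screen_peak <- function(peak, expected_rt = NA_real_, params = list()) {
  p <- merge_config(default_config()$peak, params)
  flags <- character(0)
  if (!is.finite(peak$snr) || peak$snr < p$snr_min) flags <- c(flags, "snr")
  if (peak$apex_intensity < p$int_min) flags <- c(flags, "intensity")
  if (is.finite(expected_rt) && abs(peak$rt_apex - expected_rt) > p$rt_tol)
    flags <- c(flags, "rt_deviation")
  if (peak$width < p$width_min || peak$width > p$width_max)
    flags <- c(flags, "width")
  if (peak$asymmetry < 1 / p$asym_max || peak$asymmetry > p$asym_max)
    flags <- c(flags, "asymmetry")
  peak$screen_flags <- flags
  peak
}
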