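# independent reference implementations ("oracles") used to check the
# package's optimised code paths; deliberately brute-force and kept free
# of any package internals

# O(n*m) EIC: loop over every centroid of every MS1 spectrum
oracle_eic <- function(run, mz0, ppm_tol, rt_window = NULL) {
  out_rt <- numeric(0); out_int <- numeric(0)
  for (s in run$spectra) {
    if (s$ms_level != 1L) next
    if (!is.null(rt_window) &&
        (s$rt < rt_window[1] || s$rt > rt_window[2])) next
    total <- 0
    for (k in seq_along(s$mz)) {
      if (abs(s$mz[k] - mz0) / mz0 * 1e6 <= ppm_tol)
        total <- total + s$intensity[k]
    }
    out_rt <- c(out_rt, s$rt); out_int <- c(out_int, total)
  }
  list(rt = out_rt, intensity = out_int)
}

# trapezoid by explicit interval loop
oracle_trapz <- function(t, v) {
  a <- 0
  for (i in seq_len(length(t) - 1L))
    a <- a + (t[i + 1] - t[i]) * (v[i] + v[i + 1]) / 2
  a
}

# the seven spectral sub-scores computed from scratch: matrix-based
# greedy pairing (smallest |dmz| first, ties to lower reference m/z),
# then direct formulas
oracle_match_scores <- function(qmz, qint, rmz, rint, tol) {
  D <- abs(outer(qmz, rmz, "-"))
  pairs <- NULL
  repeat {
    D2 <- D
    D2[D2 > tol] <- NA
    if (all(is.na(D2))) break
    best <- which(D2 == min(D2, na.rm = TRUE), arr.ind = TRUE)
    if (nrow(best) > 1L)
      best <- best[order(rmz[best[, 2]]), , drop = FALSE]
    qi <- best[1, 1]; ri <- best[1, 2]
    pairs <- rbind(pairs, c(qi, ri, D[qi, ri]))
    D[qi, ] <- Inf; D[, ri] <- Inf
  }
  nm <- if (is.null(pairs)) 0L else nrow(pairs)
  # aligned vectors over the union support
  qi_m <- if (nm) pairs[, 1] else integer(0)
  ri_m <- if (nm) pairs[, 2] else integer(0)
  qi_u <- setdiff(seq_along(qmz), qi_m)
  ri_u <- setdiff(seq_along(rmz), ri_m)
  aq <- c(qint[qi_m], qint[qi_u], rep(0, length(ri_u)))
  ar <- c(rint[ri_m], rep(0, length(qi_u)), rint[ri_u])
  mq <- c(qmz[qi_m], qmz[qi_u], rmz[ri_u])
  mr <- c(rmz[ri_m], qmz[qi_u], rmz[ri_u])
  cos2 <- function(a, b) {
    den <- sum(a^2) * sum(b^2)
    if (den == 0) 0 else sum(a * b)^2 / den
  }
  H <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  pq <- aq / sum(aq); pr <- ar / sum(ar)
  list(
    cosine = cos2(sqrt(aq), sqrt(ar)),
    weighted_cosine = cos2(mq^2 * sqrt(aq), mr^2 * sqrt(ar)),
    entropy_similarity =
      1 - (2 * H((pq + pr) / 2) - H(pq) - H(pr)) / log(4),
    matched_frac_query = nm / length(qmz),
    matched_frac_reference = nm / length(rmz),
    matched_intensity_frac = sum(rint[ri_m]) / sum(rint),
    mz_accuracy = if (nm == 0L) 0
                  else mean(pmax(0, 1 - pairs[, 3] / tol)),
    n_matched = nm)
}

# random small run for EIC equivalence testing
random_run <- function(seed, n_scans = 25, n_centroids = 40) {
  set.seed(seed)
  rts <- sort(stats::runif(n_scans, 0, 300))
  channels <- lapply(rts, function(t) {
    mz <- sort(stats::runif(n_centroids, 100, 500))
    mz <- mz[c(TRUE, diff(mz) > 1e-6)]
    list(mz = mz, intensity = stats::runif(length(mz), 0, 1e4))
  })
  make_run(rts, channels, run_id = paste0("rnd", seed))
}
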