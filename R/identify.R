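# fragment table from either a spectrum or a spectral entry
frag_table <- function(x) {
  if (inherits(x, "semiq_spectral_entry"))
    data.frame(mz = x$fragments$mz, intensity = x$fragments$intensity)
  else
    data.frame(mz = x$mz, intensity = x$intensity)
}

# greedy nearest-m/z fragment pairing within tol; each fragment used at
# most once; ties broken toward the lower-m/z reference fragment.
# Returns a matrix with columns qi, ri, dmz.
pair_fragments <- function(qmz, rmz, tol) {
  cand <- NULL
  for (i in seq_along(qmz)) {
    d <- abs(rmz - qmz[i])
    j <- which(d <= tol)
    if (length(j))
      cand <- rbind(cand, cbind(qi = i, ri = j, dmz = d[j], rmz = rmz[j]))
  }
  if (is.null(cand))
    return(matrix(numeric(0), ncol = 3,
                  dimnames = list(NULL, c("qi", "ri", "dmz"))))
  cand <- cand[order(cand[, "dmz"], cand[, "rmz"]), , drop = FALSE]
  used_q <- rep(FALSE, length(qmz))
  used_r <- rep(FALSE, length(rmz))
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    qi <- cand[k, "qi"]; ri <- cand[k, "ri"]
    if (!used_q[qi] && !used_r[ri]) {
      keep[k] <- TRUE
      used_q[qi] <- TRUE
      used_r[ri] <- TRUE
    }
  }
  cand[keep, c("qi", "ri", "dmz"), drop = FALSE]
}

#' Score the match between a query MS2 spectrum and a reference
#'
#' Computes seven sub-scores, each in \[0, 1\], and their weighted mean.
#' Fragments are paired greedily by nearest m/z within `frag_tol` (Da),
#' each fragment used at most once. The sub-scores are:
#' \describe{
#'   \item{cosine}{Squared normalised dot product on square-root
#'     intensities, with unmatched fragments as zero partners.}
#'   \item{weighted_cosine}{Same on mass-weighted vectors
#'     `mz^2 * sqrt(intensity)` (Stein-Scott style weighting).}
#'   \item{entropy_similarity}{`1 - (2*S_mix - S_q - S_r)/ln 4` where `S`
#'     is the Shannon entropy of the intensity-normalised spectra aligned
#'     on the pairing and `S_mix` that of their average.}
#'   \item{matched_frac_query}{Matched fragments / query fragments.}
#'   \item{matched_frac_reference}{Matched fragments / reference
#'     fragments.}
#'   \item{matched_intensity_frac}{Matched reference intensity / total
#'     reference intensity.}
#'   \item{mz_accuracy}{Mean over matched pairs of
#'     `max(0, 1 - |dmz|/frag_tol)` (0 when nothing matches).}
#' }
#' The combined score is `sum(w_i * s_i) / sum(w_i)`; all weights default
#' to 1 and can be set per score.
#'
#' @param query An MS2 [spectrum()] (or a [spectral_entry()]).
#' @param reference A [spectral_entry()] (or an MS2 spectrum).
#' @param frag_tol Fragment matching tolerance in Da (default 0.02).
#' @param weights Named list/vector of nonnegative weights for the seven
#'   sub-scores; missing names default to 1. Their sum must be > 0.
#' @return A `semiq_match_score` with `sub_scores`, `weights`, `combined`
#'   and `n_matched_fragments`.
#' @export
score_spectrum_match <- function(query, reference, frag_tol = 0.02,
                                 weights = list()) {
  score_names <- c("cosine", "weighted_cosine", "entropy_similarity",
                   "matched_frac_query", "matched_frac_reference",
                   "matched_intensity_frac", "mz_accuracy")
  w <- stats::setNames(rep(1, 7), score_names)
  for (k in intersect(names(weights), score_names)) w[k] <- weights[[k]]
  if (any(w < 0)) stop("score weights must be nonnegative")
  if (sum(w) == 0) stop("score weights sum to zero")
  q <- frag_table(query)
  r <- frag_table(reference)
  if (nrow(q) == 0L || nrow(r) == 0L) {
    warning("empty spectrum in match; all sub-scores set to 0")
    s <- stats::setNames(rep(0, 7), score_names)
    return(structure(list(sub_scores = as.list(s), weights = as.list(w),
                          combined = 0, n_matched_fragments = 0L),
                     class = "semiq_match_score"))
  }
  pairs <- pair_fragments(q$mz, r$mz, frag_tol)
  nm <- nrow(pairs)
  # union support: matched pairs share a bin; unmatched keep their own
  qi_un <- setdiff(seq_len(nrow(q)), pairs[, "qi"])
  ri_un <- setdiff(seq_len(nrow(r)), pairs[, "ri"])
  aq <- c(q$intensity[pairs[, "qi"]], q$intensity[qi_un],
          rep(0, length(ri_un)))
  ar <- c(r$intensity[pairs[, "ri"]], rep(0, length(qi_un)),
          r$intensity[ri_un])
  mzq <- c(q$mz[pairs[, "qi"]], q$mz[qi_un], r$mz[ri_un])
  mzr <- c(r$mz[pairs[, "ri"]], q$mz[qi_un], r$mz[ri_un])
  cos_sq <- function(a, b) {
    num <- sum(a * b)^2
    den <- sum(a^2) * sum(b^2)
    if (den == 0) 0 else num / den
  }
  shannon <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  pq <- aq / sum(aq)
  pr <- ar / sum(ar)
  pm <- (pq + pr) / 2
  s <- c(
    cosine = cos_sq(sqrt(aq), sqrt(ar)),
    weighted_cosine = cos_sq(mzq^2 * sqrt(aq), mzr^2 * sqrt(ar)),
    entropy_similarity =
      1 - (2 * shannon(pm) - shannon(pq) - shannon(pr)) / log(4),
    matched_frac_query = nm / nrow(q),
    matched_frac_reference = nm / nrow(r),
    matched_intensity_frac =
      sum(r$intensity[pairs[, "ri"]]) / sum(r$intensity),
    mz_accuracy =
      if (nm == 0L) 0 else mean(pmax(0, 1 - pairs[, "dmz"] / frag_tol)))
  s <- pmin(pmax(s, 0), 1)
  structure(
    list(sub_scores = as.list(s), weights = as.list(w),
         combined = sum(w * s) / sum(w), n_matched_fragments = nm),
    class = "semiq_match_score")
}

#' @export
print.semiq_match_score <- function(x, ...) {
  cat(sprintf("<semiq_match_score> combined %.3f (%d matched fragments)\n",
              x$combined, x$n_matched_fragments))
  for (k in names(x$sub_scores))
    cat(sprintf("  %-24s %.3f (w=%g)\n", k, x$sub_scores[[k]],
                x$weights[[k]]))
  invisible(x)
}

#' Score the isotope pattern at a peak apex
#'
#' Compares the observed M+1/M intensity ratio at the apex MS1 scan with
#' the ratio expected from a crude carbon-count model: the carbon count
#' is estimated as `mz * 0.0455` (an averaged carbon mass fraction) and
#' the expected ratio is `n_C * 0.0108` (natural 13C abundance per
#' carbon). The score is `max(0, 1 - |r_obs - r_exp| / r_exp)`, clipped
#' to \[0, 1\]. The model requires no molecular formula and is
#' deliberately coarse; it separates plausible envelopes from artefacts
#' rather than validating elemental composition.
#'
#' @param run The [ms_run()] containing the peak.
#' @param peak A detected peak (uses `rt_apex`).
#' @param target The compound target (uses `mz`).
#' @param ppm_tol Mass tolerance in ppm for reading both isotopologues.
#' @return A number in \[0, 1\]; 0 (with attribute `flag`) when the
#'   monoisotopic or M+1 ion is absent at the apex.
#' @export
score_isotope_pattern <- function(run, peak, target, ppm_tol = 20) {
  is_ms1 <- vapply(run$spectra, function(s) s$ms_level == 1L, logical(1))
  ms1 <- run$spectra[is_ms1]
  rts <- vapply(ms1, `[[`, numeric(1), "rt")
  sp <- ms1[[which.min(abs(rts - peak$rt_apex))]]
  read_channel <- function(mz0) {
    delta <- mz0 * ppm_tol * 1e-6
    i1 <- findInterval(mz0 - delta, sp$mz) + 1L
    i2 <- findInterval(mz0 + delta, sp$mz)
    if (i1 > i2) 0 else sum(sp$intensity[i1:i2])
  }
  i0 <- read_channel(target$mz)
  i1 <- read_channel(target$mz + 1.00336)
  if (i0 <= 0)
    return(structure(0, flag = "no_monoisotopic_ion"))
  if (i1 <= 0) return(0)
  r_obs <- i1 / i0
  r_exp <- target$mz * 0.0455 * 0.0108
  min(max(1 - abs(r_obs - r_exp) / r_exp, 0), 1)
}

#' Identify a screened peak
#'
#' Three strategies of increasing stringency, mirroring the matching
#' standards accurate mass, retention time, MS1 spectrum and MS2
#' spectrum:
#' \describe{
#'   \item{mz_rt}{Identified iff the peak carries neither an
#'     `rt_deviation` nor an `snr` screen flag (the mass criterion is
#'     already enforced by the extraction tolerance).}
#'   \item{mz_rt_ms1}{Additionally requires an isotope-pattern score of
#'     at least `iso_min` (default 0.5).}
#'   \item{mz_rt_ms2}{Additionally requires the best combined spectral
#'     match over the reference entries of the same compound, across all
#'     DDA MS2 scans whose precursor lies within `precursor_tol` (Da) of
#'     the target m/z and whose rt falls inside the peak bounds, to reach
#'     `ms2_min` (default 0.7).}
#' }
#'
#' @param peak A screened, integrated peak.
#' @param target The compound target (row of a library's `targets`).
#' @param run The [ms_run()] the peak came from.
#' @param spectral_library List of [spectral_entry()] objects (used by
#'   `mz_rt_ms2`; may be empty).
#' @param strategy One of `"mz_rt"`, `"mz_rt_ms1"`, `"mz_rt_ms2"`.
#' @param params Named list overriding `id` defaults of
#'   [default_config()] (`frag_tol`, `precursor_tol`, `iso_min`,
#'   `ms2_min`, `weights`) plus `ppm_tol` for the isotope read-out.
#' @return An identification result: list with `strategy`,
#'   `matched_properties`, `isotope_score`, `spectral_match`,
#'   `best_reference`, `identified` and (when not identified) `reason`.
#' @export
identify_peak <- function(peak, target, run, spectral_library = list(),
                          strategy = c("mz_rt", "mz_rt_ms1", "mz_rt_ms2"),
                          params = list()) {
  strategy <- match.arg(strategy)
  p <- merge_config(default_config()$id, params)
  ppm_tol <- params$ppm_tol %||% default_config()$eic$ppm_tol
  ok_base <- !any(c("rt_deviation", "snr") %in% peak$screen_flags)
  res <- list(strategy = strategy,
              matched_properties = character(0),
              isotope_score = NULL, spectral_match = NULL,
              best_reference = NULL, identified = FALSE, reason = NULL)
  if (!ok_base) {
    res$reason <- "screen_flags"
    return(res)
  }
  res$matched_properties <- c("accurate_mass", "rt")
  if (strategy == "mz_rt") {
    res$identified <- TRUE
    return(res)
  }
  if (strategy == "mz_rt_ms1") {
    iso <- score_isotope_pattern(run, peak, target, ppm_tol = ppm_tol)
    res$isotope_score <- as.numeric(iso)
    if (res$isotope_score >= p$iso_min) {
      res$matched_properties <- c(res$matched_properties, "ms1_spectrum")
      res$identified <- TRUE
    } else res$reason <- "isotope_pattern"
    return(res)
  }
  # mz_rt_ms2
  refs <- Filter(function(e) e$compound_name == target$name,
                 spectral_library)
  if (length(refs) == 0L) {
    res$reason <- "no_reference"
    return(res)
  }
  scans <- Filter(function(s)
    s$ms_level == 2L && is.finite(s$precursor_mz) &&
      abs(s$precursor_mz - target$mz) <= p$precursor_tol &&
      s$rt >= peak$rt_start && s$rt <= peak$rt_end,
    run$spectra)
  if (length(scans) == 0L) {
    res$reason <- "no_ms2_in_peak"
    return(res)
  }
  best <- NULL; best_ref <- NULL
  for (s in scans) for (e in refs) {
    ms <- score_spectrum_match(s, e, frag_tol = p$frag_tol,
                               weights = p$weights)
    if (is.null(best) || ms$combined > best$combined) {
      best <- ms; best_ref <- e
    }
  }
  res$spectral_match <- best
  res$best_reference <- entry_id(best_ref)
  if (best$combined >= p$ms2_min) {
    res$matched_properties <- c(res$matched_properties, "ms2_spectrum")
    res$identified <- TRUE
  } else res$reason <- "ms2_score_below_threshold"
  res
}
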