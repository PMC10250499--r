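test_that("a spectrum matched against itself scores 1 everywhere", {
  e <- random_entry(1)
  ms <- score_spectrum_match(entry_as_ms2(e), e)
  for (k in names(ms$sub_scores))
    expect_equal(ms$sub_scores[[k]], 1.0, tolerance = 1e-12, label = k)
  expect_equal(ms$combined, 1.0, tolerance = 1e-12)
  expect_equal(ms$n_matched_fragments, nrow(e$fragments))
})

test_that("disjoint spectra score 0 everywhere", {
  a <- random_entry(2, mz_range = c(60, 200))
  b <- random_entry(3, mz_range = c(300, 500))
  ms <- score_spectrum_match(entry_as_ms2(a), b)
  for (k in names(ms$sub_scores))
    expect_equal(ms$sub_scores[[k]], 0, label = k)
  expect_equal(ms$combined, 0)
})

test_that("match fractions follow hand counts on a partial overlap", {
  ref <- spectral_entry("X", 250,
                        data.frame(mz = c(100.00, 200.00),
                                   intensity = c(50, 50)))
  qry <- spectrum(2L, 10, 100.00, 50, precursor_mz = 250)
  ms <- score_spectrum_match(qry, ref, frag_tol = 0.02)
  expect_equal(ms$sub_scores$matched_frac_reference, 0.5)
  expect_equal(ms$sub_scores$matched_frac_query, 1.0)
  expect_equal(ms$sub_scores$matched_intensity_frac, 0.5)
  orc <- oracle_match_scores(100.00, 50, c(100.00, 200.00), c(50, 50), 0.02)
  expect_equal(ms$sub_scores$cosine, orc$cosine, tolerance = 1e-12)
  expect_equal(ms$sub_scores$entropy_similarity, orc$entropy_similarity,
               tolerance = 1e-12)
})

test_that("sub-scores agree with the independent oracle on random pairs", {
  for (seed in 1:20) {
    a <- random_entry(seed, n = 5 + seed %% 6, mz_range = c(60, 300))
    b <- random_entry(seed + 500, n = 5 + (seed + 3) %% 6,
                      mz_range = c(60, 300))
    tol <- c(0.02, 0.5, 5)[1 + seed %% 3]  # include sloppy tolerances
    ms <- score_spectrum_match(entry_as_ms2(a), b, frag_tol = tol)
    orc <- oracle_match_scores(a$fragments$mz, a$fragments$intensity,
                               b$fragments$mz, b$fragments$intensity, tol)
    for (k in names(ms$sub_scores))
      expect_equal(ms$sub_scores[[k]], orc[[k]], tolerance = 1e-9,
                   label = paste(k, "seed", seed))
    expect_equal(ms$n_matched_fragments, orc$n_matched)
  }
})

test_that("matching is symmetric where the scores are symmetric", {
  for (seed in 41:50) {
    a <- random_entry(seed, mz_range = c(60, 300))
    b <- random_entry(seed + 100, mz_range = c(60, 300))
    ab <- score_spectrum_match(entry_as_ms2(a), b)
    ba <- score_spectrum_match(entry_as_ms2(b), a)
    expect_equal(ab$sub_scores$cosine, ba$sub_scores$cosine,
                 tolerance = 1e-9)
    expect_equal(ab$sub_scores$entropy_similarity,
                 ba$sub_scores$entropy_similarity, tolerance = 1e-9)
    expect_equal(ab$sub_scores$matched_frac_query,
                 ba$sub_scores$matched_frac_reference, tolerance = 1e-12)
    expect_equal(ab$sub_scores$matched_frac_reference,
                 ba$sub_scores$matched_frac_query, tolerance = 1e-12)
  }
})

test_that("the combined score is the weighted mean of the sub-scores", {
  a <- random_entry(7)
  b <- random_entry(8, mz_range = c(60, 480))
  w <- list(cosine = 2, entropy_similarity = 0.5, mz_accuracy = 0)
  ms <- score_spectrum_match(entry_as_ms2(a), b, weights = w)
  s <- unlist(ms$sub_scores)
  wv <- unlist(ms$weights)
  expect_equal(ms$combined, sum(s * wv) / sum(wv), tolerance = 1e-12)
  expect_gte(ms$combined, min(s))
  expect_lte(ms$combined, max(s))
  expect_error(score_spectrum_match(entry_as_ms2(a), b,
                                    weights = as.list(stats::setNames(
                                      rep(0, 7), names(ms$sub_scores)))),
               "zero")
})

test_that("empty spectra score 0 with a warning", {
  a <- random_entry(9)
  empty <- structure(list(ms_level = 2L, rt = 1, mz = numeric(0),
                          intensity = numeric(0), precursor_mz = 100,
                          precursor_charge = 1L, scan_id = "e"),
                     class = "semiq_spectrum")
  expect_warning(ms <- score_spectrum_match(empty, a), "empty")
  expect_equal(ms$combined, 0)
})

iso_run_for <- function(mz0, ratio_scale = 1, rt = 50) {
  r_exp <- mz0 * 0.0455 * 0.0108
  make_run(rts = rt,
           channels = list(list(
             mz = c(mz0, mz0 + 1.00336),
             intensity = c(1e5, 1e5 * r_exp * ratio_scale))))
}

test_that("isotope scoring rewards the modelled envelope", {
  tgt <- list(name = "X", mz = 300.1)
  pk <- list(rt_apex = 50)
  expect_gte(score_isotope_pattern(iso_run_for(300.1), pk, tgt), 0.95)
  # M+1 absent
  run0 <- make_run(rts = 50, channels = list(list(mz = 300.1,
                                                  intensity = 1e5)))
  expect_equal(as.numeric(score_isotope_pattern(run0, pk, tgt)), 0)
  # observed ratio twice the expectation: 1 - |2r - r|/r = 0
  expect_equal(score_isotope_pattern(iso_run_for(300.1, 2), pk, tgt), 0)
  # monoisotopic ion missing entirely
  far <- make_run(rts = 50, channels = list(list(mz = 500, intensity = 1)))
  s <- score_isotope_pattern(far, pk, tgt)
  expect_equal(as.numeric(s), 0)
  expect_identical(attr(s, "flag"), "no_monoisotopic_ion")
})

planted_ms2_case <- function(seed = 31) {
  cp <- data.frame(name = "X", mz = 350.2, rt_true = 80, peak_sigma = 4,
                   abundance = 2e5)
  frag <- list(X = data.frame(mz = c(91.05, 120.08, 175.12, 230.1),
                              rel_intensity = c(100, 60, 40, 20)))
  d <- synthetic_design(cp, fragments = frag, run_length = 160,
                        dda_top_n = 2, dda_min_intensity = 1000,
                        noise_sigma = 20, baseline = 50, seed = seed)
  sim <- simulate_run(d)
  eic <- extract_eic(sim$run, cp, ppm_tol = 20)
  eic <- estimate_noise(smooth_eic(eic, "savitzky_golay"), "mad")
  pk <- select_peaks(eic, "local_max", file_id = sim$run$run_id)[[1]]
  pk <- screen_peak(integrate_peak(eic, pk), expected_rt = 80)
  ref <- spectral_entry("X", 350.2,
                        data.frame(mz = frag$X$mz,
                                   intensity = frag$X$rel_intensity),
                        file_source = "lib", rt = 80)
  list(run = sim$run, pk = pk, target = cp, ref = ref)
}

test_that("a planted compound identifies under all three strategies", {
  cs <- planted_ms2_case()
  for (st in c("mz_rt", "mz_rt_ms1", "mz_rt_ms2")) {
    res <- identify_peak(cs$pk, cs$target, cs$run, list(cs$ref),
                         strategy = st)
    expect_true(res$identified, label = st)
  }
  res <- identify_peak(cs$pk, cs$target, cs$run, list(cs$ref),
                       strategy = "mz_rt_ms2")
  expect_identical(res$best_reference, entry_id(cs$ref))
  expect_setequal(res$matched_properties,
                  c("accurate_mass", "rt", "ms2_spectrum"))
})

test_that("MS2 identification fails cleanly without spectra or references", {
  cs <- planted_ms2_case()
  # empty library
  res <- identify_peak(cs$pk, cs$target, cs$run, list(),
                       strategy = "mz_rt_ms2")
  expect_false(res$identified)
  expect_identical(res$reason, "no_reference")
  # no MS2 scans triggered inside the peak bounds
  ms1_only <- cs$run
  ms1_only$spectra <- Filter(function(s) s$ms_level == 1L, ms1_only$spectra)
  res2 <- identify_peak(cs$pk, cs$target, ms1_only, list(cs$ref),
                        strategy = "mz_rt_ms2")
  expect_false(res2$identified)
  expect_identical(res2$reason, "no_ms2_in_peak")
})

test_that("decoy spectra are rejected by the MS2 strategy", {
  cs <- planted_ms2_case()
  rejected <- 0L
  for (seed in 1:50) {
    set.seed(seed)
    decoy_frag <- data.frame(
      mz = sort(stats::runif(nrow(cs$ref$fragments), 60, 330)),
      intensity = cs$ref$fragments$intensity)
    decoy <- spectral_entry("X", 350.2, decoy_frag, file_source = "decoy",
                            rt = 80)
    res <- identify_peak(cs$pk, cs$target, cs$run, list(decoy),
                         strategy = "mz_rt_ms2")
    if (!res$identified) rejected <- rejected + 1L
  }
  expect_gte(rejected, 45L)  # >= 90 percent of 50 decoys
  # while the same peak passes the plain mz+rt strategy
  expect_true(identify_peak(cs$pk, cs$target, cs$run, list(),
                            strategy = "mz_rt")$identified)
})
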