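test_that("RT calibration interpolates, extrapolates and pools violators", {
  cal <- rt_calibration(c(100, 200), c(110, 210))
  expect_equal(predict(cal, 150), 160)
  expect_equal(predict(cal, 100), 110)
  # slope-1 extrapolation beyond the anchors
  expect_equal(predict(cal, 50), 60)
  expect_equal(predict(cal, 260), 270)
  # no anchors: identity
  id <- rt_calibration()
  expect_equal(predict(id, c(0, 123.4)), c(0, 123.4))
  expect_warning(one <- rt_calibration(100, 140), "identity")
  expect_equal(predict(one, 100), 100)
  # monotone violator pooled by PAVA: both observed become 125
  viol <- rt_calibration(c(100, 200), c(130, 120))
  expect_equal(viol$anchors$observed, c(125, 125))
  x <- seq(0, 400, by = 10)
  expect_true(all(diff(predict(viol, x)) >= 0))
})

test_that("the RT mapping is monotone for random anchor sets", {
  for (seed in 1:25) {
    set.seed(seed)
    k <- sample(2:8, 1)
    expected <- sort(stats::runif(k, 0, 600))
    observed <- expected + stats::rnorm(k, 0, 25)  # may violate order
    cal <- rt_calibration(expected, observed)
    x <- seq(-50, 700, length.out = 300)
    expect_true(all(diff(predict(cal, x)) >= -1e-9), label = paste(seed))
  }
})

fake_peak <- function(name, rt_apex, snr = 50, flags = character(0),
                      rt_start = rt_apex - 10, rt_end = rt_apex + 10,
                      area = 1000, file_id = "f") {
  structure(
    list(compound_name = name, file_id = file_id, rt_start = rt_start,
         rt_apex = rt_apex, rt_end = rt_end, apex_intensity = snr * 100,
         area = area, snr = snr, width = rt_end - rt_start,
         asymmetry = 1, n_points = 11L, screen_flags = flags,
         status = "unknown", identification = NULL),
    class = "semiq_peak")
}

test_that("calibrate_rt builds per-file mappings from IS peaks", {
  is_lib <- compound_library("is", "internal_standard",
                             data.frame(name = c("IS1", "IS2"),
                                        mz = c(200, 400),
                                        rt = c(100, 200)))
  per_file <- list(
    fileA = list(fake_peak("IS1", 110), fake_peak("IS2", 210)),
    fileB = list(fake_peak("IS1", 100),
                 fake_peak("IS2", 195, flags = c("snr"))))  # excluded
  cals <- calibrate_rt(is_lib, per_file)
  expect_equal(predict(cals$fileA, 150), 160)
  # fileB keeps only one eligible anchor -> identity
  expect_equal(predict(cals$fileB, 150), 150)
})

test_that("cross-file alignment re-selects toward the consensus", {
  # 4 files agree near 300 s; the 5th file's top-snr candidate sits at
  # 350 s but a weaker candidate exists at 302 s
  cands <- list(
    f1 = list(fake_peak("X", 299)),
    f2 = list(fake_peak("X", 300)),
    f3 = list(fake_peak("X", 301)),
    f4 = list(fake_peak("X", 300.5)),
    f5 = list(fake_peak("X", 350, snr = 90), fake_peak("X", 302, snr = 15)))
  al <- align_eics(cands, rt_tol = 30)
  expect_equal(al$consensus_rt, 300.5)
  expect_equal(al$selection$f5$idx, 2)  # the 302 s candidate
  expect_true(al$selection$f5$consistent)
  expect_true(all(vapply(al$selection[1:4], `[[`, logical(1),
                         "consistent")))
})

test_that("alignment of a single file keeps its own best selection", {
  cands <- list(f1 = list(fake_peak("X", 120, snr = 10),
                          fake_peak("X", 180, snr = 80)))
  al <- align_eics(cands)
  expect_equal(al$consensus_rt, 180)
  expect_equal(al$selection$f1$idx, 2)
  # no candidates anywhere
  al0 <- align_eics(list(f1 = list(), f2 = list()))
  expect_true(is.na(al0$consensus_rt))
  expect_true(all(is.na(vapply(al0$selection, `[[`, integer(1), "idx"))))
  # a file whose only candidate is far from the consensus is inconsistent
  far <- align_eics(list(f1 = list(fake_peak("X", 100)),
                         f2 = list(fake_peak("X", 101)),
                         f3 = list(fake_peak("X", 300))), rt_tol = 30)
  expect_false(far$selection$f3$consistent)
})

# peak table with a uniform +15 s drift; compound "C4" mis-selected at
# -40 s relative shift while a correct candidate sits at +14 s
drift_table <- function() {
  lib <- compound_library("l", "analyte",
                          data.frame(name = paste0("C", 1:6),
                                     mz = 200 + 1:6,
                                     rt = c(100, 130, 160, 190, 220, 250)))
  pt <- list()
  for (i in 1:6) {
    nm <- paste0("C", i)
    exp_rt <- lib$targets$rt[i]
    cands <- list(fake_peak(nm, exp_rt + 15))
    sel <- 1L
    if (nm == "C4") {
      cands <- list(fake_peak(nm, exp_rt - 40), fake_peak(nm, exp_rt + 14))
      sel <- 1L
    }
    pt[[nm]] <- list(fileA = list(candidates = cands, selected_idx = sel,
                                  consistent = TRUE,
                                  expected_rt_cal = exp_rt,
                                  demoted = FALSE, rt_refined = FALSE,
                                  status = "unknown",
                                  identification = NULL))
  }
  list(lib = lib, pt = pt)
}

test_that("RT-pattern refinement corrects a drift outlier idempotently", {
  d <- drift_table()
  out <- refine_by_rt_pattern(d$lib, d$pt, neighbor_window = 120,
                              dev_max = 20)
  expect_equal(out$C4$fileA$selected_idx, 2)  # the +14 s candidate
  expect_true(out$C4$fileA$rt_refined)
  for (nm in paste0("C", c(1:3, 5:6)))
    expect_equal(out[[nm]]$fileA$selected_idx, 1)
  # second application is a no-op
  again <- refine_by_rt_pattern(d$lib, out, neighbor_window = 120,
                                dev_max = 20)
  expect_equal(lapply(again, function(r) r$fileA$selected_idx),
               lapply(out, function(r) r$fileA$selected_idx))
})

test_that("refinement demotes when no candidate fits the local shift", {
  d <- drift_table()
  d$pt$C4$fileA$candidates <- list(fake_peak("C4", d$lib$targets$rt[4] - 40))
  out <- refine_by_rt_pattern(d$lib, d$pt)
  expect_true(out$C4$fileA$demoted)
})

test_that("refinement falls back to the global shift with few neighbours", {
  lib <- compound_library("l", "analyte",
                          data.frame(name = c("A", "B"), mz = c(200, 300),
                                     rt = c(100, 500)))  # no neighbours
  pt <- list(
    A = list(f = list(candidates = list(fake_peak("A", 110)),
                      selected_idx = 1L, consistent = TRUE,
                      expected_rt_cal = 100, demoted = FALSE,
                      rt_refined = FALSE, status = "unknown",
                      identification = NULL)),
    B = list(f = list(candidates = list(fake_peak("B", 510)),
                      selected_idx = 1L, consistent = TRUE,
                      expected_rt_cal = 500, demoted = FALSE,
                      rt_refined = FALSE, status = "unknown",
                      identification = NULL)))
  out <- refine_by_rt_pattern(lib, pt)
  # both shifts agree with the global median (+10 s): nothing changes
  expect_equal(out$A$f$selected_idx, 1)
  expect_false(out$A$f$demoted)
  expect_false(out$B$f$demoted)
})

test_that("the full chain passes planted compounds and isolates absences", {
  pb <- make_planted_batch(n_runs = 3, n_compounds = 10, seed = 11)
  # one library entry that is absent from every run
  targets <- rbind(pb$library$targets,
                   data.frame(name = "Absent", mz = 777.77, rt = 200,
                              adduct = NA, group = NA))
  lib <- compound_library("planted+absent", "analyte", targets)
  ov <- run_semi_targeted(pb$runs, lib, created_at = "fixed")
  st <- sapply(ov$peak_table, function(row)
    vapply(row, `[[`, character(1), "status"))
  planted <- st[, colnames(st) != "Absent", drop = FALSE]
  expect_true(all(planted == "pass"))
  expect_true(all(st[, "Absent"] == "fail"))
})

test_that("identical inputs give byte-identical Overview JSON", {
  pb <- make_planted_batch(n_runs = 2, n_compounds = 6, seed = 13)
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  ov1 <- run_semi_targeted(pb$runs, pb$library, seed = 99,
                           created_at = "2026-01-01T00:00:00")
  ov2 <- run_semi_targeted(pb$runs, pb$library, seed = 99,
                           created_at = "2026-01-01T00:00:00")
  write_overview(ov1, p1)
  write_overview(ov2, p2)
  expect_identical(readBin(p1, "raw", file.size(p1) + 10),
                   readBin(p2, "raw", file.size(p2) + 10))
})

test_that("IS-based calibration corrects a drifted run end to end", {
  pb <- make_planted_batch(n_runs = 2, n_compounds = 8, seed = 17,
                           drifts = c(0, 25))
  # use 3 compounds as internal standards, the rest as analytes
  tg <- pb$library$targets
  is_lib <- compound_library("is", "internal_standard", tg[c(1, 4, 8), ])
  an_lib <- compound_library("an", "analyte", tg[c(2, 3, 5, 6, 7), ])
  ov <- run_semi_targeted(pb$runs, an_lib, is_library = is_lib,
                          created_at = "fixed")
  st <- sapply(ov$peak_table, function(row)
    vapply(row, `[[`, character(1), "status"))
  expect_true(all(st == "pass"))
  # calibrated expectations track the drift in run2
  cells <- lapply(ov$peak_table, function(row) row$run2)
  shifts <- vapply(cells, function(cl) cl$expected_rt_cal, numeric(1)) -
    an_lib$targets$rt
  expect_true(all(shifts > 15))
})
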