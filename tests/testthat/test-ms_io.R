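test_that("mzML write/read round-trips a simulated DDA run", {
  cp <- data.frame(name = "X", mz = 300.15, rt_true = 60, peak_sigma = 4,
                   abundance = 5e4)
  frag <- list(X = data.frame(mz = c(120.1, 180.2), rel_intensity = c(80, 40)))
  d <- synthetic_design(cp, fragments = frag, run_length = 120,
                        dda_top_n = 2, dda_min_intensity = 500, seed = 3)
  sim <- simulate_run(d)
  path <- withr::local_tempfile(fileext = ".mzML")
  write_run(sim$run, path)
  back <- read_run(path)
  expect_equal(length(back$spectra), length(sim$run$spectra))
  expect_equal(vapply(back$spectra, `[[`, numeric(1), "rt"),
               vapply(sim$run$spectra, `[[`, numeric(1), "rt"),
               tolerance = 1e-9)
  expect_equal(vapply(back$spectra, `[[`, integer(1), "ms_level"),
               vapply(sim$run$spectra, `[[`, integer(1), "ms_level"))
  i <- which(vapply(sim$run$spectra, `[[`, integer(1), "ms_level") == 1L)[30]
  expect_equal(back$spectra[[i]]$mz, sim$run$spectra[[i]]$mz,
               tolerance = 1e-10)
  expect_equal(back$spectra[[i]]$intensity, sim$run$spectra[[i]]$intensity,
               tolerance = 1e-6)
  j <- which(vapply(back$spectra, `[[`, integer(1), "ms_level") == 2L)[1]
  expect_false(is.na(back$spectra[[j]]$precursor_mz))
  expect_identical(back$polarity, "positive")
  expect_false(is.unsorted(vapply(back$spectra, `[[`, numeric(1), "rt")))
})

test_that("retention times recorded in minutes are converted to seconds", {
  path <- withr::local_tempfile(fileext = ".mzML")
  write_minimal_mzml(path, rt_value = 2.5, rt_unit = "minute")
  run <- read_run(path)
  expect_equal(run$spectra[[1]]$rt, 150)
  path2 <- withr::local_tempfile(fileext = ".mzML")
  write_minimal_mzml(path2, rt_value = 42, rt_unit = "second")
  expect_equal(read_run(path2)$spectra[[1]]$rt, 42)
})

test_that("degenerate and profile-mode mzML inputs are rejected", {
  expect_error(read_run(file.path(tempdir(), "does-not-exist.mzML")),
               "not found")
  empty <- withr::local_tempfile(fileext = ".mzML")
  write_minimal_mzml(empty, mode = "empty")
  expect_error(read_run(empty), "no spectra|no MS1")
  prof <- withr::local_tempfile(fileext = ".mzML")
  write_minimal_mzml(prof, mode = "profile")
  expect_error(read_run(prof), "centroid required")
})

test_that("compound library CSV reading converts units and validates", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("name,mz,rt,adduct",
               "Alanine,90.0550,1.2,[M+H]+",
               "Valine,118.0863,2.5,[M+H]+",
               "Leucine,132.1019,4.0,[M+H]+"), path)
  lib <- read_compound_library(path, "analyte", rt_unit = "minutes")
  expect_equal(nrow(lib$targets), 3)
  expect_equal(lib$targets$rt[lib$targets$name == "Valine"], 150)

  dup <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("name,mz,rt", "Alanine,90.1,10", "Alanine,90.1,20"), dup)
  expect_error(read_compound_library(dup), "Alanine")

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("name,mz,rt", "Alanine,90.1,10", "Valine,oops,20"), bad)
  expect_error(read_compound_library(bad), "line.*3")
})

test_that("MSP write/read round-trips fragments and metadata", {
  e1 <- spectral_entry("Valine", 118.0863,
                       data.frame(mz = c(55.0545, 72.0808, 101.1073),
                                  intensity = c(30, 100, 12.5)),
                       instrument_type = "QTOF",
                       collision_energy = "35 eV",
                       ionization_mode = "positive",
                       file_source = "runA", rt = 150.25, approved = TRUE)
  e2 <- spectral_entry("Alanine", 90.0550,
                       data.frame(mz = c(44.0495), intensity = c(100)),
                       file_source = "runB", rt = 72)
  path <- withr::local_tempfile(fileext = ".msp")
  write_msp(list(e1, e2), path)
  back <- read_msp(path)
  # deterministic ordering: by compound name
  expect_identical(vapply(back, `[[`, character(1), "compound_name"),
                   c("Alanine", "Valine"))
  v <- back[[2]]
  expect_equal(v$fragments$mz, e1$fragments$mz, tolerance = 1e-6)
  expect_equal(v$fragments$intensity, e1$fragments$intensity,
               tolerance = 1e-4)
  expect_identical(v$collision_energy, "35 eV")
  expect_identical(v$instrument_type, "QTOF")
  expect_identical(v$file_source, "runA")
  expect_true(v$approved)
  # byte-stable output for a fixed entry set, order-independent input
  path2 <- withr::local_tempfile(fileext = ".msp")
  write_msp(list(e2, e1), path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("MSP records with inconsistent Num Peaks are rejected", {
  path <- withr::local_tempfile(fileext = ".msp")
  writeLines(c("Name: Broken", "PrecursorMZ: 100.0", "Num Peaks: 5",
               "50.0 10", "60.0 20", "70.0 30", "80.0 40", ""), path)
  expect_error(read_msp(path), "Num Peaks")
})

test_that("MGF export writes one block per entry with formatted m/z", {
  e <- spectral_entry("Glutamine", 147.0764,
                      data.frame(mz = c(84.0444, 101.0709, 147.0764),
                                 intensity = c(100, 45, 20)),
                      file_source = "runA", rt = 210)
  path <- withr::local_tempfile(fileext = ".mgf")
  export_mgf(list(e), path)
  lines <- readLines(path)
  expect_equal(sum(lines == "BEGIN IONS"), 1)
  expect_equal(sum(lines == "END IONS"), 1)
  ion_lines <- grep("^[0-9]+\\.[0-9]+ ", lines, value = TRUE)
  expect_length(ion_lines, 3)
  expect_true(startsWith(ion_lines[3], "147.0764"))
  expect_warning(export_mgf(list(), withr::local_tempfile(fileext = ".mgf")),
                 "empty")
})
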