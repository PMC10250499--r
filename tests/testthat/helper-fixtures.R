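# fixture builders shared across test files; everything is generated in
# code, nothing is stored on disk

# a tiny in-memory run: one MS1 scan per rt with the given channels
make_run <- function(rts, channels, run_id = "t",
                     polarity = "positive") {
  spectra <- lapply(seq_along(rts), function(i) {
    ch <- channels[[i]]
    semiq::spectrum(1L, rts[i], ch$mz, ch$intensity,
                    scan_id = paste0("scan=", i))
  })
  semiq::ms_run(run_id, polarity, spectra)
}

# a run holding a single Gaussian elution profile on one m/z channel
make_gaussian_run <- function(mz0 = 300.2, apex = 1e5, rt0 = 100,
                              sigma = 4, noise = 0, baseline = 0,
                              rt_step = 1, run_length = 200, seed = 1) {
  set.seed(seed)
  rts <- seq(0, run_length, by = rt_step)
  channels <- lapply(rts, function(t) {
    v <- max(apex * exp(-(t - rt0)^2 / (2 * sigma^2)) + baseline +
               stats::rnorm(1, 0, noise), 0)
    list(mz = mz0, intensity = v)
  })
  make_run(rts, channels)
}

# prepared EIC (smoothed + noise) from a numeric trace
make_eic <- function(intensity, rt = seq_along(intensity) - 1,
                     name = "X", mz = 300, smooth = TRUE) {
  eic <- structure(
    list(compound_name = name, mz_target = mz, ppm_tol = 20,
         rt = rt, intensity = as.numeric(intensity),
         smoothed = NULL, noise_level = NULL, params = list()),
    class = "semiq_eic")
  if (smooth) {
    eic$smoothed <- as.numeric(intensity)
    eic$noise_level <- 1.0
  }
  eic
}

# candidate peak covering eic indices [l, r] with apex at index a
new_peak_for_test <- function(eic, l, a, r, name = "X", file_id = "t") {
  structure(
    list(compound_name = name, file_id = file_id,
         rt_start = eic$rt[l], rt_apex = eic$rt[a], rt_end = eic$rt[r],
         apex_intensity = eic$intensity[a],
         area = NA_real_, snr = NA_real_,
         width = eic$rt[r] - eic$rt[l],
         asymmetry = (eic$rt[a] - eic$rt[l]) /
           max(eic$rt[r] - eic$rt[a], 1e-12),
         n_points = r - l + 1L, screen_flags = character(0),
         status = "unknown", identification = NULL),
    class = "semiq_peak")
}

# small random MS2 spectrum as a spectral entry
random_entry <- function(seed, compound = "X", n = 8, mz_range = c(60, 500),
                         file_source = "f1") {
  set.seed(seed)
  mz <- sort(stats::runif(n, mz_range[1], mz_range[2]))
  semiq::spectral_entry(compound, precursor_mz = max(mz) + 50,
                        fragments = data.frame(
                          mz = mz, intensity = stats::runif(n, 5, 100)),
                        file_source = file_source, rt = 100)
}

entry_as_ms2 <- function(entry, rt = 100) {
  semiq::spectrum(2L, rt, entry$fragments$mz, entry$fragments$intensity,
                  precursor_mz = entry$precursor_mz, scan_id = "q")
}

# minimal hand-written mzML (uncompressed 64-bit) used to probe reader
# behaviour that the packaged writer cannot produce (minute rt units,
# profile-mode flags, zero spectra)
write_minimal_mzml <- function(path, rt_value = 2.5, rt_unit = "minute",
                               mz = c(100.5, 200.25),
                               intensity = c(10, 20),
                               mode = c("centroid", "profile", "empty")) {
  mode <- match.arg(mode)
  enc <- function(x) jsonlite::base64_enc(writeBin(as.numeric(x), raw(),
                                                   size = 8,
                                                   endian = "little"))
  unit_acc <- if (rt_unit == "minute") "UO:0000031" else "UO:0000010"
  mode_acc <- if (mode == "profile") "MS:1000128" else "MS:1000127"
  mode_name <- if (mode == "profile") "profile spectrum"
               else "centroid spectrum"
  spec <- sprintf('
      <spectrum index="0" id="scan=1" defaultArrayLength="%d">
        <cvParam cvRef="MS" accession="MS:1000511" name="ms level" value="1"/>
        <cvParam cvRef="MS" accession="%s" name="%s" value=""/>
        <cvParam cvRef="MS" accession="MS:1000130" name="positive scan" value=""/>
        <scanList count="1"><scan>
          <cvParam cvRef="MS" accession="MS:1000016" name="scan start time" value="%s" unitCvRef="UO" unitAccession="%s" unitName="%s"/>
        </scan></scanList>
        <binaryDataArrayList count="2">
          <binaryDataArray encodedLength="%d">
            <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>
            <cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>
            <cvParam cvRef="MS" accession="MS:1000514" name="m/z array" value="" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>
            <binary>%s</binary>
          </binaryDataArray>
          <binaryDataArray encodedLength="%d">
            <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>
            <cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>
            <cvParam cvRef="MS" accession="MS:1000515" name="intensity array" value="" unitCvRef="MS" unitAccession="MS:1000131" unitName="number of detector counts"/>
            <binary>%s</binary>
          </binaryDataArray>
        </binaryDataArrayList>
      </spectrum>',
    length(mz), mode_acc, mode_name, format(rt_value), unit_acc, rt_unit,
    nchar(enc(mz)), enc(mz), nchar(enc(intensity)), enc(intensity))
  body <- if (mode == "empty")
    '<spectrumList count="0">\n    </spectrumList>'
  else sprintf('<spectrumList count="1">%s\n    </spectrumList>', spec)
  xml <- sprintf('<?xml version="1.0" encoding="utf-8"?>
<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">
  <cvList count="2">
    <cv id="MS" fullName="PSI-MS" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/>
    <cv id="UO" fullName="Unit Ontology" URI="https://unit-ontology.obo"/>
  </cvList>
  <fileDescription><fileContent>
    <cvParam cvRef="MS" accession="MS:1000579" name="MS1 spectrum" value=""/>
  </fileContent></fileDescription>
  <run id="r1">
    %s
  </run>
</mzML>', body)
  writeLines(xml, path)
  path
}

# small planted-compound multi-run scenario used by batch + curation
# tests: every compound is a clean Gaussian present in every run
make_planted_batch <- function(n_runs = 3, n_compounds = 10, seed = 11,
                               dda_top_n = 2, run_length = 420,
                               drifts = NULL) {
  set.seed(seed)
  mz <- sort(sample(seq(150, 850, by = 2), n_compounds)) +
    stats::runif(n_compounds, -0.1, 0.1)
  cp <- data.frame(
    name = sprintf("C%02d", seq_len(n_compounds)), mz = mz,
    rt_true = seq(60, run_length - 60, length.out = n_compounds),
    peak_sigma = stats::runif(n_compounds, 3, 5),
    abundance = stats::runif(n_compounds, 1e5, 5e5))
  fragments <- stats::setNames(lapply(seq_len(n_compounds), function(i) {
    k <- sample(4:7, 1)
    data.frame(mz = sort(stats::runif(k, 50, mz[i] - 30)),
               rel_intensity = stats::runif(k, 10, 100))
  }), cp$name)
  if (is.null(drifts)) drifts <- rep(0, n_runs)
  runs <- lapply(seq_len(n_runs), function(i) {
    d <- semiq::synthetic_design(
      cp, fragments = fragments, run_length = run_length,
      dda_top_n = dda_top_n, noise_sigma = 30, baseline = 80,
      rt_drift = drifts[i], seed = seed * 100 + i)
    r <- semiq::simulate_run(d)$run
    r$run_id <- sprintf("run%d", i)
    r
  })
  lib <- semiq::compound_library("planted", "analyte",
                                 data.frame(name = cp$name, mz = cp$mz,
                                            rt = cp$rt_true))
  list(runs = runs, library = lib, compounds = cp, fragments = fragments)
}
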