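#' Read a centroided DDA run from mzML
#'
#' Loads all MS1 and MS2 spectra of an mzML file into a [ms_run()] object.
#' Retention times are always expressed in seconds internally, regardless
#' of the unit used in the file (the mzML reader normalises minutes).
#' Profile-mode data are rejected: the engine operates on centroids only.
#'
#' @param path Path to an mzML file.
#' @return A `semiq_run`.
#' @export
read_run <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  fh <- mzR::openMSfile(path, backend = "pwiz")
  on.exit(mzR::close(fh), add = TRUE)
  hdr <- mzR::header(fh)
  if (nrow(hdr) == 0L) stop("validation error: mzML file contains no spectra")
  if (any(hdr$centroided %in% FALSE))
    stop("centroid required: file contains profile-mode spectra")
  if (!any(hdr$msLevel == 1L))
    stop("validation error: mzML file contains no MS1 spectra")
  pk <- mzR::peaks(fh)
  if (is.matrix(pk)) pk <- list(pk)
  spectra <- vector("list", nrow(hdr))
  for (i in seq_len(nrow(hdr))) {
    m <- pk[[i]]
    mz <- m[, 1]; it <- m[, 2]
    # guard against duplicated centroid m/z from upstream writers
    if (length(mz) > 1L && any(diff(mz) <= 0)) {
      o <- order(mz); mz <- mz[o]; it <- it[o]
      keep <- c(TRUE, diff(mz) > 0)
      if (!all(keep)) {
        it <- as.numeric(tapply(it, cumsum(keep), sum))
        mz <- mz[keep]
      }
    }
    lvl <- hdr$msLevel[i]
    spectra[[i]] <- spectrum(
      ms_level = lvl, rt = hdr$retentionTime[i], mz = mz, intensity = it,
      precursor_mz = if (lvl == 2L) hdr$precursorMZ[i] else NA_real_,
      precursor_charge = if (lvl == 2L) hdr$precursorCharge[i]
                         else NA_integer_,
      scan_id = as.character(hdr$spectrumId[i]))
  }
  pol <- if (mean(hdr$polarity, na.rm = TRUE) < 0.5) "negative" else "positive"
  inst <- tryCatch(mzR::instrumentInfo(fh), error = function(e) NULL)
  ce <- hdr$collisionEnergy[hdr$msLevel == 2L]
  ce <- ce[is.finite(ce)]
  metadata <- list(
    instrument_type =
      if (!is.null(inst) && nzchar(inst$model %||% "")) inst$model
      else "unknown",
    collision_energy =
      if (length(ce)) paste0(format(ce[1], trim = TRUE), " eV") else "unknown")
  ms_run(run_id = tools::file_path_sans_ext(basename(path)),
         polarity = pol, spectra = spectra, source_path = path,
         metadata = metadata)
}

`%||%` <- function(a, b) {
  if (is.null(a) || length(a) == 0L) return(b)
  if (is.atomic(a) && length(a) == 1L && is.na(a)) return(b)
  a
}

#' Write a run to mzML
#'
#' Serialises a [ms_run()] to mzML (used by the synthetic generator and
#' for round-trip tests). Output is deterministic for a fixed run object.
#'
#' @param run A `semiq_run`.
#' @param path Output mzML path.
#' @return `path`, invisibly.
#' @export
write_run <- function(run, path) {
  n <- length(run$spectra)
  pol <- if (run$polarity == "positive") 1L else 0L
  lv <- vapply(run$spectra, `[[`, integer(1), "ms_level")
  rts <- vapply(run$spectra, `[[`, numeric(1), "rt")
  npk <- vapply(run$spectra, function(s) length(s$mz), integer(1))
  tic <- vapply(run$spectra, function(s) sum(s$intensity), numeric(1))
  bpmz <- vapply(run$spectra, function(s)
    if (length(s$mz)) s$mz[which.max(s$intensity)] else 0, numeric(1))
  bpint <- vapply(run$spectra, function(s)
    if (length(s$intensity)) max(s$intensity) else 0, numeric(1))
  lomz <- vapply(run$spectra, function(s)
    if (length(s$mz)) min(s$mz) else 0, numeric(1))
  himz <- vapply(run$spectra, function(s)
    if (length(s$mz)) max(s$mz) else 0, numeric(1))
  pmz <- vapply(run$spectra, `[[`, numeric(1), "precursor_mz")
  pch <- vapply(run$spectra, `[[`, integer(1), "precursor_charge")
  ce <- suppressWarnings(
    as.numeric(gsub("[^0-9.]", "", run$metadata$collision_energy %||% "")))
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n), msLevel = lv,
    polarity = pol, peaksCount = npk, totIonCurrent = tic,
    retentionTime = rts, basePeakMZ = bpmz, basePeakIntensity = bpint,
    collisionEnergy = ifelse(lv == 2L, ce %||% NA_real_, NA_real_),
    ionisationEnergy = 0, lowMZ = lomz, highMZ = himz,
    precursorScanNum = NA_integer_, precursorMZ = pmz, precursorCharge = pch,
    precursorIntensity = NA_real_, mergedScan = NA_integer_,
    mergedResultScanNum = NA_integer_, mergedResultStartScanNum = NA_integer_,
    mergedResultEndScanNum = NA_integer_, injectionTime = 0,
    filterString = NA_character_,
    spectrumId = paste0("scan=", seq_len(n)), centroided = TRUE,
    ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = pmz,
    isolationWindowLowerOffset = ifelse(lv == 2L, 0.5, NA_real_),
    isolationWindowUpperOffset = ifelse(lv == 2L, 0.5, NA_real_),
    scanWindowLowerLimit = lomz, scanWindowUpperLimit = himz,
    stringsAsFactors = FALSE)
  pk <- lapply(run$spectra, function(s) cbind(mz = s$mz,
                                             intensity = s$intensity))
  mzR::writeMSData(pk, file = path, header = hdr, outformat = "mzml")
  invisible(path)
}

#' Read a compound library from CSV
#'
#' The CSV must have a header with columns `name`, `mz`, `rt` and may have
#' `adduct` and `group`. The retention-time unit of the file is declared
#' by `rt_unit`; minutes are converted so that all internal retention
#' times are seconds.
#'
#' @param path CSV path.
#' @param kind `"analyte"` or `"internal_standard"`.
#' @param rt_unit `"seconds"` (default) or `"minutes"`.
#' @param library_id Library identifier (default: file name).
#' @return A `semiq_library`.
#' @export
read_compound_library <- function(path, kind = c("analyte",
                                                 "internal_standard"),
                                  rt_unit = c("seconds", "minutes"),
                                  library_id = NULL) {
  kind <- match.arg(kind)
  rt_unit <- match.arg(rt_unit)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("name", "mz", "rt") %in% names(df)))
    stop("compound library CSV must have columns name, mz, rt")
  mz <- suppressWarnings(as.numeric(df$mz))
  rt <- suppressWarnings(as.numeric(df$rt))
  bad <- which(!is.finite(mz) | !is.finite(rt))
  if (length(bad))
    stop("non-numeric mz/rt in compound library at line(s) ",
         paste(bad + 1L, collapse = ", "))  # +1 for the header line
  df$mz <- mz
  df$rt <- if (rt_unit == "minutes") rt * 60 else rt
  compound_library(
    library_id = library_id %||% tools::file_path_sans_ext(basename(path)),
    kind = kind, targets = df)
}

#' Read a spectral library from MSP
#'
#' Parses NIST-style MSP records (`Name:`, `PrecursorMZ:`, `Num Peaks:`
#' and fragment lines). Acquisition metadata is carried in a `Comment:`
#' line as semicolon-separated `key=value` pairs; unknown keys are
#' preserved verbatim on round-trip.
#'
#' @param path MSP path.
#' @return A list of [spectral_entry()] objects.
#' @export
read_msp <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  entries <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    if (!grepl("^Name:", lines[i])) { i <- i + 1L; next }
    fields <- list(); comment <- ""
    while (i <= n && nzchar(trimws(lines[i])) &&
           !grepl("^Num Peaks:", lines[i])) {
      kv <- regmatches(lines[i], regexec("^([^:]+):\\s*(.*)$", lines[i]))[[1]]
      if (length(kv) == 3L) {
        if (kv[2] == "Comment") comment <- kv[3] else fields[[kv[2]]] <- kv[3]
      }
      i <- i + 1L
    }
    if (i > n || !grepl("^Num Peaks:", lines[i]))
      stop("MSP record '", fields$Name, "': missing Num Peaks")
    npk <- as.integer(sub("^Num Peaks:\\s*", "", lines[i]))
    i <- i + 1L
    frag <- matrix(NA_real_, nrow = 0, ncol = 2)
    while (i <= n && nzchar(trimws(lines[i]))) {
      parts <- strsplit(trimws(lines[i]), "[\t ]+")[[1]]
      frag <- rbind(frag, as.numeric(parts[1:2]))
      i <- i + 1L
    }
    if (nrow(frag) != npk)
      stop("MSP record '", fields$Name, "': Num Peaks is ", npk,
           " but ", nrow(frag), " fragment lines found")
    meta <- parse_msp_comment(comment)
    entries[[length(entries) + 1L]] <- spectral_entry(
      compound_name = fields$Name,
      precursor_mz = as.numeric(fields$PrecursorMZ),
      fragments = data.frame(mz = frag[, 1], intensity = frag[, 2]),
      instrument_type = meta$instrument_type %||% "unknown",
      collision_energy = meta$collision_energy %||% "unknown",
      ionization_mode = meta$ionization_mode %||% "positive",
      file_source = meta$file_source %||% "unknown",
      rt = as.numeric(meta$rt %||% 0),
      approved = identical(meta$approved, "true"))
    attr(entries[[length(entries)]], "extra_comment_keys") <-
      meta[setdiff(names(meta),
                   c("instrument_type", "collision_energy",
                     "ionization_mode", "file_source", "rt", "approved"))]
  }
  entries
}

parse_msp_comment <- function(comment) {
  if (!nzchar(comment)) return(list())
  parts <- strsplit(comment, ";")[[1]]
  out <- list()
  for (p in parts) {
    kv <- regmatches(p, regexec("^\\s*([^=]+)=(.*)$", p))[[1]]
    if (length(kv) == 3L) out[[trimws(kv[2])]] <- trimws(kv[3])
  }
  out
}

#' Write a spectral library to MSP
#'
#' Entries are written sorted by compound name then precursor m/z so the
#' output is byte-stable for a fixed entry set. Fragment m/z values are
#' written with six decimals.
#'
#' @param entries List of [spectral_entry()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_msp <- function(entries, path) {
  entries <- sort_entries(entries)
  con <- file(path, open = "wt")
  on.exit(close(con), add = TRUE)
  for (e in entries) {
    extra <- attr(e, "extra_comment_keys")
    comment <- paste0(
      "instrument_type=", e$instrument_type,
      "; collision_energy=", e$collision_energy,
      "; ionization_mode=", e$ionization_mode,
      "; file_source=", e$file_source,
      "; rt=", formatC(e$rt, format = "f", digits = 3),
      "; approved=", if (e$approved) "true" else "false")
    if (length(extra))
      comment <- paste0(comment, "; ",
                        paste(names(extra), unlist(extra), sep = "=",
                              collapse = "; "))
    writeLines(c(
      paste0("Name: ", e$compound_name),
      paste0("PrecursorMZ: ", formatC(e$precursor_mz, format = "f",
                                      digits = 6)),
      paste0("Comment: ", comment),
      paste0("Num Peaks: ", nrow(e$fragments)),
      paste(formatC(e$fragments$mz, format = "f", digits = 6),
            formatC(e$fragments$intensity, format = "f", digits = 4)),
      ""), con)
  }
  invisible(path)
}

sort_entries <- function(entries) {
  if (length(entries) <= 1L) return(entries)
  nm <- vapply(entries, `[[`, character(1), "compound_name")
  pm <- vapply(entries, `[[`, numeric(1), "precursor_mz")
  entries[order(nm, pm)]
}

#' Export spectral entries to MGF
#'
#' Writes one `BEGIN IONS`/`END IONS` block per entry with `PEPMASS` and
#' `RTINSECONDS` headers, sorted by compound name then precursor m/z.
#'
#' @param entries List of [spectral_entry()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_mgf <- function(entries, path) {
  if (length(entries) == 0L) {
    warning("no spectral entries to export; writing empty MGF")
    file.create(path)
    return(invisible(path))
  }
  entries <- sort_entries(entries)
  con <- file(path, open = "wt")
  on.exit(close(con), add = TRUE)
  for (e in entries) {
    writeLines(c(
      "BEGIN IONS",
      paste0("TITLE=", e$compound_name, " [", e$file_source, "]"),
      paste0("PEPMASS=", formatC(e$precursor_mz, format = "f", digits = 6)),
      paste0("RTINSECONDS=", formatC(e$rt, format = "f", digits = 3)),
      paste(formatC(e$fragments$mz, format = "f", digits = 6),
            formatC(e$fragments$intensity, format = "f", digits = 4)),
      "END IONS", ""), con)
  }
  invisible(path)
}
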