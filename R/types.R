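#' Construct a mass spectrum
#'
#' Lightweight container for one centroided spectrum (MS1 or MS2).
#'
#' @param ms_level Integer, 1 or 2.
#' @param rt Retention time in seconds (>= 0).
#' @param mz Numeric vector of centroid m/z values, strictly ascending.
#' @param intensity Numeric vector of nonnegative intensities, same length
#'   as `mz`.
#' @param precursor_mz Precursor m/z (required for MS2, `NA` for MS1).
#' @param precursor_charge Precursor charge, `NA` when unknown.
#' @param scan_id Opaque scan identifier string.
#'
#' @return A `semiq_spectrum` object (a list).
#' @export
spectrum <- function(ms_level, rt, mz, intensity,
                     precursor_mz = NA_real_, precursor_charge = NA_integer_,
                     scan_id = "") {
  ms_level <- as.integer(ms_level)
  stopifnot(ms_level %in% c(1L, 2L))
  if (length(mz) != length(intensity))
    stop("mz and intensity arrays must have equal length")
  if (length(mz) > 1L && any(diff(mz) <= 0))
    stop("mz array must be strictly ascending")
  if (any(intensity < 0)) stop("intensities must be nonnegative")
  if (rt < 0) stop("rt must be >= 0")
  if (ms_level == 2L && is.na(precursor_mz))
    stop("MS2 spectrum requires precursor_mz")
  structure(
    list(ms_level = ms_level, rt = as.numeric(rt),
         mz = as.numeric(mz), intensity = as.numeric(intensity),
         precursor_mz = as.numeric(precursor_mz),
         precursor_charge = as.integer(precursor_charge),
         scan_id = as.character(scan_id)),
    class = "semiq_spectrum")
}

#' Construct an MS run
#'
#' An ordered collection of centroided spectra (MS1 + DDA MS2) with
#' retention times in seconds and optional acquisition metadata.
#'
#' @param run_id Run identifier (typically the file name without extension).
#' @param polarity `"positive"` or `"negative"`.
#' @param spectra List of [spectrum()] objects ordered by retention time.
#' @param source_path Path of the file the run was read from ("" if none).
#' @param metadata Named list of acquisition metadata; recognised keys are
#'   `instrument_type` and `collision_energy` (used during spectral
#'   curation; missing values are recorded as `"unknown"`).
#'
#' @return A `semiq_run` object.
#' @export
ms_run <- function(run_id, polarity = c("positive", "negative"), spectra,
                   source_path = "", metadata = list()) {
  polarity <- match.arg(polarity)
  if (length(spectra) == 0L) stop("run contains no spectra")
  rts <- vapply(spectra, `[[`, numeric(1), "rt")
  if (any(diff(rts) < 0)) stop("spectra must be nondecreasing in rt")
  levels <- vapply(spectra, `[[`, integer(1), "ms_level")
  if (!any(levels == 1L)) stop("run contains no MS1 spectra")
  structure(
    list(run_id = as.character(run_id), polarity = polarity,
         spectra = spectra, source_path = as.character(source_path),
         metadata = metadata),
    class = "semiq_run")
}

#' @export
print.semiq_run <- function(x, ...) {
  lv <- vapply(x$spectra, `[[`, integer(1), "ms_level")
  rts <- vapply(x$spectra, `[[`, numeric(1), "rt")
  cat(sprintf("<semiq_run> %s (%s mode)\n", x$run_id, x$polarity))
  cat(sprintf("  %d spectra (%d MS1, %d MS2), rt %.1f-%.1f s\n",
              length(lv), sum(lv == 1L), sum(lv == 2L),
              min(rts), max(rts)))
  invisible(x)
}

#' Construct a compound library
#'
#' A set of quantification targets (analytes or internal standards), each
#' with an accurate m/z and an expected retention time.
#'
#' @param library_id Library identifier.
#' @param kind `"analyte"` or `"internal_standard"`.
#' @param targets A data.frame with columns `name`, `mz` (Th), `rt`
#'   (seconds) and optionally `adduct` and `group`.
#'
#' @return A `semiq_library` object.
#' @export
compound_library <- function(library_id,
                             kind = c("analyte", "internal_standard"),
                             targets) {
  kind <- match.arg(kind)
  targets <- as.data.frame(targets, stringsAsFactors = FALSE)
  req <- c("name", "mz", "rt")
  if (!all(req %in% names(targets)))
    stop("targets must have columns name, mz, rt")
  if (nrow(targets) == 0L) stop("compound library is empty")
  if (!"adduct" %in% names(targets)) targets$adduct <- NA_character_
  if (!"group" %in% names(targets)) targets$group <- NA_character_
  dup <- unique(targets$name[duplicated(targets$name)])
  if (length(dup))
    stop("duplicate compound names in library: ", paste(dup, collapse = ", "))
  if (any(!is.finite(targets$mz)) || any(targets$mz <= 0))
    stop("all target m/z must be finite and > 0")
  if (any(!is.finite(targets$rt)) || any(targets$rt < 0))
    stop("all target rt must be finite and >= 0")
  structure(
    list(library_id = as.character(library_id), kind = kind,
         targets = targets[, c("name", "mz", "rt", "adduct", "group")]),
    class = "semiq_library")
}

#' @export
print.semiq_library <- function(x, ...) {
  cat(sprintf("<semiq_library> %s (%s), %d targets\n",
              x$library_id, x$kind, nrow(x$targets)))
  invisible(x)
}

#' Construct a reference spectral entry
#'
#' One curated MS2 spectrum together with the acquisition metadata that
#' makes it reusable across projects: instrument type, collision energy,
#' ionization mode and the file it came from.
#'
#' @param compound_name Compound the spectrum belongs to.
#' @param precursor_mz Precursor m/z (Th).
#' @param fragments data.frame with columns `mz` (ascending) and
#'   `intensity` (> 0, relative units).
#' @param instrument_type,collision_energy Free-text metadata; `"unknown"`
#'   when not recorded.
#' @param ionization_mode `"positive"` or `"negative"`.
#' @param file_source Identifier of the run the spectrum came from.
#' @param rt Retention time of the source scan, seconds.
#' @param approved Whether the entry has been approved by inspection.
#'
#' @return A `semiq_spectral_entry` object.
#' @export
spectral_entry <- function(compound_name, precursor_mz, fragments,
                           instrument_type = "unknown",
                           collision_energy = "unknown",
                           ionization_mode = c("positive", "negative"),
                           file_source = "unknown", rt = 0,
                           approved = FALSE) {
  ionization_mode <- match.arg(ionization_mode)
  fragments <- as.data.frame(fragments, stringsAsFactors = FALSE)
  stopifnot(all(c("mz", "intensity") %in% names(fragments)))
  if (nrow(fragments) == 0L) stop("spectral entry has no fragments")
  fragments <- fragments[order(fragments$mz), c("mz", "intensity")]
  if (any(fragments$intensity <= 0)) stop("fragment intensities must be > 0")
  meta_or_unknown <- function(x)
    if (is.null(x) || is.na(x) || !nzchar(as.character(x))) "unknown"
    else as.character(x)
  structure(
    list(compound_name = as.character(compound_name),
         precursor_mz = as.numeric(precursor_mz),
         fragments = fragments,
         instrument_type = meta_or_unknown(instrument_type),
         collision_energy = meta_or_unknown(collision_energy),
         ionization_mode = ionization_mode,
         file_source = meta_or_unknown(file_source),
         rt = as.numeric(rt), approved = isTRUE(approved)),
    class = "semiq_spectral_entry")
}

#' Identifier of a spectral entry
#'
#' Entries are addressed by the triple (compound, file source, rt), which
#' is also the de-duplication key for library merges.
#'
#' @param entry A [spectral_entry()].
#' @return A character id.
#' @export
entry_id <- function(entry) {
  sprintf("%s|%s|%.3f", entry$compound_name, entry$file_source, entry$rt)
}

# internal constructor for a detected chromatographic peak; integration,
# screening and identification fill the remaining fields in later steps
new_chrom_peak <- function(compound_name, file_id,
                           rt_start, rt_apex, rt_end,
                           apex_intensity, n_points) {
  structure(
    list(compound_name = as.character(compound_name),
         file_id = as.character(file_id),
         rt_start = rt_start, rt_apex = rt_apex, rt_end = rt_end,
         apex_intensity = apex_intensity,
         area = NA_real_, snr = NA_real_,
         width = rt_end - rt_start,
         asymmetry = (rt_apex - rt_start) / max(rt_end - rt_apex, 1e-12),
         n_points = as.integer(n_points),
         screen_flags = character(0),
         status = "unknown",
         identification = NULL),
    class = "semiq_peak")
}

#' Convert a list of peaks to a data.frame
#'
#' @param peaks A list of chromatographic peak objects.
#' @return A data.frame with one row per peak (identification and flags
#'   collapsed to strings).
#' @export
peaks_to_df <- function(peaks) {
  if (length(peaks) == 0L)
    return(data.frame(compound_name = character(0), file_id = character(0),
                      rt_start = numeric(0), rt_apex = numeric(0),
                      rt_end = numeric(0), apex_intensity = numeric(0),
                      area = numeric(0), snr = numeric(0),
                      width = numeric(0), asymmetry = numeric(0),
                      n_points = integer(0), screen_flags = character(0),
                      status = character(0), identified = logical(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, lapply(peaks, function(p) {
    data.frame(compound_name = p$compound_name, file_id = p$file_id,
               rt_start = p$rt_start, rt_apex = p$rt_apex,
               rt_end = p$rt_end, apex_intensity = p$apex_intensity,
               area = p$area, snr = p$snr, width = p$width,
               asymmetry = p$asymmetry, n_points = p$n_points,
               screen_flags = paste(p$screen_flags, collapse = ";"),
               status = p$status,
               identified = if (is.null(p$identification)) NA
                            else isTRUE(p$identification$identified),
               stringsAsFactors = FALSE)
  }))
}
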