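#' Read a manual-annotation file
#'
#' Annotations are the scriptable replacement for interactive batch
#' inspection: a CSV with columns `compound`, `file`, `status` and
#' optionally `rt_start`, `rt_end`. A row overrides the auto-assigned
#' status of that (compound, file) cell; when bounds are given, the peak
#' is re-integrated over them with the configured integrator.
#'
#' @param path CSV path.
#' @return A data.frame of annotations.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("compound", "file", "status") %in% names(df)))
    stop("annotations CSV must have columns compound, file, status")
  if (!all(df$status %in% c("pass", "unknown", "fail")))
    stop("annotation status must be one of pass, unknown, fail")
  if (!"rt_start" %in% names(df)) df$rt_start <- NA_real_
  if (!"rt_end" %in% names(df)) df$rt_end <- NA_real_
  df
}

#' Apply manual annotations to an Overview
#'
#' Overrides auto-assigned statuses and, where an annotation supplies
#' peak bounds, re-integrates the peak over those bounds using exactly
#' the integrator the automatic pass used (re-extracting the EIC from
#' the run, so `runs` is required in that case).
#'
#' @param overview A `semiq_overview`.
#' @param annotations Data.frame from [read_annotations()] (or built in
#'   code).
#' @param runs The runs of the overview (needed only when bounds are
#'   edited).
#' @param library The analyte [compound_library()] (needed only when
#'   bounds are edited).
#' @return The updated overview.
#' @export
apply_annotations <- function(overview, annotations, runs = NULL,
                              library = NULL) {
  if (is.character(runs)) runs <- lapply(runs, read_run)
  if (!is.null(runs)) {
    if (inherits(runs, "semiq_run")) runs <- list(runs)
    names(runs) <- vapply(runs, `[[`, character(1), "run_id")
  }
  if (!"rt_start" %in% names(annotations)) annotations$rt_start <- NA_real_
  if (!"rt_end" %in% names(annotations)) annotations$rt_end <- NA_real_
  offenders <- character(0)
  for (i in seq_len(nrow(annotations))) {
    cn <- annotations$compound[i]; f <- annotations$file[i]
    if (is.null(overview$peak_table[[cn]]) ||
        !f %in% names(overview$peak_table[[cn]])) {
      offenders <- c(offenders, paste0("(", cn, ", ", f, ")"))
      next
    }
  }
  if (length(offenders))
    stop("annotations reference unknown (compound, file): ",
         paste(offenders, collapse = ", "))
  for (i in seq_len(nrow(annotations))) {
    cn <- annotations$compound[i]; f <- annotations$file[i]
    cell <- overview$peak_table[[cn]][[f]]
    if (is.finite(annotations$rt_start[i]) &&
        is.finite(annotations$rt_end[i])) {
      if (is.null(runs) || is.null(library))
        stop("bound edits require runs and library for re-integration")
      pk <- selected_peak(cell)
      if (is.null(pk)) stop("cannot edit bounds of (", cn, ", ", f,
                            "): no selected peak")
      tg <- library$targets[library$targets$name == cn, ]
      e <- overview$params$eic
      eic <- extract_eic(runs[[f]], tg, ppm_tol = e$ppm_tol)
      eic <- estimate_noise(eic, method = e$noise_method)
      pk$rt_start <- annotations$rt_start[i]
      pk$rt_end <- annotations$rt_end[i]
      idx <- which(eic$rt >= pk$rt_start & eic$rt <= pk$rt_end)
      apex_i <- idx[which.max(eic$intensity[idx])]
      pk$rt_apex <- eic$rt[apex_i]
      pk$apex_intensity <- eic$intensity[apex_i]
      pk$width <- pk$rt_end - pk$rt_start
      pk$asymmetry <- (pk$rt_apex - pk$rt_start) /
        max(pk$rt_end - pk$rt_apex, 1e-12)
      pk$n_points <- length(idx)
      pk <- integrate_peak(eic, pk,
                           method = overview$params$peak$integrator)
      cell$candidates[[cell$selected_idx]] <- pk
      cell$manually_integrated <- TRUE
    }
    cell$status <- annotations$status[i]
    cell$manual_status <- TRUE
    overview$peak_table[[cn]][[f]] <- cell
  }
  overview
}

#' Export quantification tables
#'
#' Writes the final report of a batch analysis:
#' \itemize{
#'   \item a wide CSV of compounds (rows) by files (columns) holding
#'     peak areas, with empty cells for every peak whose status is not
#'     `pass` (non-pass peaks never appear in the final report);
#'   \item optionally a companion long CSV with one row per
#'     (compound, file) cell regardless of status, carrying status,
#'     apex retention time, bounds, area, S/N, screen flags and
#'     identification outcome.
#' }
#'
#' @param overview A `semiq_overview`, optionally after
#'   [apply_annotations()].
#' @param path Output path of the wide CSV.
#' @param long_path Optional output path of the long CSV.
#' @return The wide table, invisibly.
#' @export
export_quant_table <- function(overview, path, long_path = NULL) {
  long <- overview_status_table(overview)
  comps <- names(overview$peak_table)
  wide <- data.frame(compound = comps, stringsAsFactors = FALSE)
  for (f in overview$files) {
    v <- rep(NA_real_, length(comps))
    for (i in seq_along(comps)) {
      row <- long[long$compound == comps[i] & long$file == f, ]
      if (nrow(row) == 1L && row$status == "pass") v[i] <- row$area
    }
    wide[[f]] <- v
  }
  utils::write.csv(wide, path, row.names = FALSE, na = "")
  if (!is.null(long_path))
    utils::write.csv(long, long_path, row.names = FALSE, na = "")
  invisible(wide)
}
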