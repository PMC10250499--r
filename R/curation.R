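#' Harvest approved MS2 spectra from an analysed batch
#'
#' For each approved (compound, file) pair with status `pass`, the best
#' in-peak MS2 scan — the DDA scan whose precursor lies within the
#' precursor tolerance of the target m/z, inside the peak bounds, and
#' nearest the peak apex — becomes a [spectral_entry()] carrying the
#' acquisition metadata of its run (instrument type, collision energy,
#' ionization mode; `"unknown"` where the run does not record it) and
#' the run id as file source. Only inspected, passing peaks can be
#' curated: approving a non-pass peak is an error.
#'
#' @param overview A `semiq_overview` from [run_semi_targeted()].
#' @param runs The runs the overview was computed from (list of
#'   [ms_run()], named by run id, or mzML paths).
#' @param approvals `"all_pass"` to approve every pass-status peak, or a
#'   data.frame with columns `compound`, `file`.
#' @param library The analyte [compound_library()] (provides the target
#'   m/z for precursor matching).
#' @param precursor_tol Precursor matching tolerance in Da.
#' @param min_fragments,min_total_intensity Structural quality filters
#'   applied to the harvested scans.
#' @return A list of [spectral_entry()] objects grouped (ordered) by
#'   compound name.
#' @export
curate_spectra <- function(overview, runs, approvals = "all_pass",
                           library, precursor_tol = 0.5,
                           min_fragments = 1L, min_total_intensity = 0) {
  if (is.character(runs)) runs <- lapply(runs, read_run)
  if (inherits(runs, "semiq_run")) runs <- list(runs)
  names(runs) <- vapply(runs, `[[`, character(1), "run_id")
  if (identical(approvals, "all_pass")) {
    rows <- list()
    for (cn in names(overview$peak_table))
      for (f in overview$files)
        if (identical(overview$peak_table[[cn]][[f]]$status, "pass"))
          rows[[length(rows) + 1L]] <- data.frame(compound = cn, file = f)
    approvals <- if (length(rows)) do.call(rbind, rows)
                 else data.frame(compound = character(0),
                                 file = character(0))
  }
  entries <- list()
  for (i in seq_len(nrow(approvals))) {
    cn <- approvals$compound[i]; f <- approvals$file[i]
    cell <- overview$peak_table[[cn]][[f]]
    if (is.null(cell))
      stop("approval references unknown (compound, file): ", cn, ", ", f)
    if (!identical(cell$status, "pass"))
      stop("cannot curate '", cn, "' in '", f, "': status is '",
           cell$status, "' (library curation requires an inspected, ",
           "pass-status result)")
    pk <- selected_peak(cell)
    run <- runs[[f]]
    tg <- library$targets[library$targets$name == cn, ]
    scans <- Filter(function(s)
      s$ms_level == 2L && is.finite(s$precursor_mz) &&
        abs(s$precursor_mz - tg$mz) <= precursor_tol &&
        s$rt >= pk$rt_start && s$rt <= pk$rt_end,
      run$spectra)
    if (length(scans) == 0L) next
    drt <- vapply(scans, function(s) abs(s$rt - pk$rt_apex), numeric(1))
    sc <- scans[[which.min(drt)]]
    if (length(sc$mz) < min_fragments ||
        sum(sc$intensity) < min_total_intensity) next
    entries[[length(entries) + 1L]] <- spectral_entry(
      compound_name = cn, precursor_mz = tg$mz,
      fragments = data.frame(mz = sc$mz, intensity = sc$intensity),
      instrument_type = run$metadata$instrument_type %||% "unknown",
      collision_energy = run$metadata$collision_energy %||% "unknown",
      ionization_mode = run$polarity,
      file_source = run$run_id, rt = sc$rt, approved = TRUE)
  }
  sort_entries(entries)
}

#' Build a consensus spectrum from replicate entries
#'
#' Fragments from all entries are clustered by single linkage in m/z
#' (clusters break where the gap between adjacent sorted fragments
#' exceeds `frag_tol`). Clusters observed in at least `min_frac` of the
#' entries are kept; the consensus m/z is the intensity-weighted mean,
#' the consensus intensity the median of the per-entry intensities
#' (entries contributing several fragments to one cluster are summed
#' first), renormalised to a maximum of 100. Metadata fields are decided
#' by majority vote.
#'
#' @param entries List of at least two [spectral_entry()] objects of the
#'   same compound.
#' @param frag_tol Single-linkage gap tolerance, Da.
#' @param min_frac Minimum fraction of entries a cluster must appear in.
#' @return A consensus [spectral_entry()] (file source
#'   `"consensus"`).
#' @export
consensus_spectrum <- function(entries, frag_tol = 0.02, min_frac = 0.5) {
  if (length(entries) < 2L)
    stop("consensus requires >= 2 entries; use the single entry directly")
  cn <- unique(vapply(entries, `[[`, character(1), "compound_name"))
  if (length(cn) != 1L)
    stop("all entries must belong to the same compound")
  k <- length(entries)
  frag <- do.call(rbind, lapply(seq_len(k), function(i)
    cbind(entry = i, mz = entries[[i]]$fragments$mz,
          intensity = entries[[i]]$fragments$intensity)))
  frag <- frag[order(frag[, "mz"]), , drop = FALSE]
  cluster <- cumsum(c(1, diff(frag[, "mz"]) > frag_tol))
  out_mz <- numeric(0); out_int <- numeric(0)
  for (cl in unique(cluster)) {
    rows <- frag[cluster == cl, , drop = FALSE]
    n_entries <- length(unique(rows[, "entry"]))
    if (n_entries / k < min_frac) next
    wmz <- sum(rows[, "mz"] * rows[, "intensity"]) / sum(rows[, "intensity"])
    per_entry <- tapply(rows[, "intensity"], rows[, "entry"], sum)
    out_mz <- c(out_mz, wmz)
    out_int <- c(out_int, stats::median(per_entry))
  }
  if (length(out_mz) == 0L)
    stop("no fragment cluster reached min_frac = ", min_frac)
  out_int <- out_int / max(out_int) * 100
  majority <- function(field) {
    v <- vapply(entries, `[[`, character(1), field)
    names(sort(table(v), decreasing = TRUE))[1]
  }
  spectral_entry(
    compound_name = cn,
    precursor_mz = stats::median(vapply(entries, `[[`, numeric(1),
                                        "precursor_mz")),
    fragments = data.frame(mz = out_mz, intensity = out_int),
    instrument_type = majority("instrument_type"),
    collision_energy = majority("collision_energy"),
    ionization_mode = majority("ionization_mode"),
    file_source = "consensus",
    rt = stats::median(vapply(entries, `[[`, numeric(1), "rt")),
    approved = all(vapply(entries, `[[`, logical(1), "approved")))
}

#' Manage a spectral library
#'
#' `op = "list"` returns the entry ids; `op = "delete"` removes exactly
#' the named entries (error if any id is unknown); `op = "merge"` unions
#' the library with another, de-duplicating exact (compound, file
#' source, rt) triples.
#'
#' @param library List of [spectral_entry()] objects.
#' @param op `"list"`, `"delete"` or `"merge"`.
#' @param entry_ids Character ids (see [entry_id()]) for `delete`.
#' @param other Second library for `merge`.
#' @return For `list`, a character vector of ids; otherwise the updated
#'   library (sorted by compound then precursor m/z).
#' @export
library_ops <- function(library, op = c("list", "delete", "merge"),
                        entry_ids = character(0), other = list()) {
  op <- match.arg(op)
  ids <- vapply(library, entry_id, character(1))
  if (op == "list") return(ids)
  if (op == "delete") {
    unknown <- setdiff(entry_ids, ids)
    if (length(unknown))
      stop("unknown entry id(s): ", paste(unknown, collapse = ", "))
    return(sort_entries(library[!ids %in% entry_ids]))
  }
  merged <- c(library, other)
  mids <- vapply(merged, entry_id, character(1))
  sort_entries(merged[!duplicated(mids)])
}
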