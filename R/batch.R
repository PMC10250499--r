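#' Build a retention-time calibration from anchor pairs
#'
#' Anchors are (expected, observed) retention-time pairs, typically from
#' internal-standard peaks. Observed times are first made monotone in
#' expected time by pool-adjacent-violators ([stats::isoreg()]); the
#' mapping is then piecewise-linear interpolation through the monotone
#' anchors, extrapolated with slope 1 beyond the anchor range. With
#' fewer than two anchors the mapping is the identity (with a warning
#' when exactly one anchor is supplied).
#'
#' @param expected,observed Numeric vectors of equal length (seconds).
#' @return A `semiq_rt_calibration`; use [predict()] to map expected to
#'   observed retention times.
#' @export
rt_calibration <- function(expected = numeric(0), observed = numeric(0)) {
  stopifnot(length(expected) == length(observed))
  if (length(expected) >= 1L) {
    o <- order(expected)
    expected <- expected[o]; observed <- observed[o]
    # collapse duplicate expected times
    if (anyDuplicated(expected)) {
      observed <- as.numeric(tapply(observed, match(expected,
                                                    unique(expected)), mean))
      expected <- unique(expected)
    }
  }
  if (length(expected) < 2L) {
    if (length(expected) == 1L)
      warning("fewer than 2 anchors; using identity RT mapping")
    return(structure(list(anchors = data.frame(expected = numeric(0),
                                               observed = numeric(0)),
                          identity = TRUE),
                     class = "semiq_rt_calibration"))
  }
  if (any(diff(observed) < 0))
    message("non-monotone RT anchors pooled by isotonic regression")
  fit <- stats::isoreg(expected, observed)
  structure(list(anchors = data.frame(expected = expected,
                                      observed = fit$yf),
                 identity = FALSE),
            class = "semiq_rt_calibration")
}

#' @param object A `semiq_rt_calibration`.
#' @param newdata Numeric vector of expected retention times (seconds).
#' @param ... Unused.
#' @rdname rt_calibration
#' @export
predict.semiq_rt_calibration <- function(object, newdata, ...) {
  x <- as.numeric(newdata)
  if (object$identity || nrow(object$anchors) < 2L) return(x)
  a <- object$anchors
  y <- stats::approx(a$expected, a$observed, xout = x, rule = 1,
                     ties = "ordered")$y
  lo <- x < a$expected[1]
  hi <- x > a$expected[nrow(a)]
  y[lo] <- a$observed[1] - (a$expected[1] - x[lo])
  y[hi] <- a$observed[nrow(a)] + (x[hi] - a$expected[nrow(a)])
  y
}

#' @export
print.semiq_rt_calibration <- function(x, ...) {
  if (x$identity) cat("<semiq_rt_calibration> identity\n")
  else cat(sprintf("<semiq_rt_calibration> %d anchors, rt %.1f-%.1f s\n",
                   nrow(x$anchors), x$anchors$expected[1],
                   x$anchors$expected[nrow(x$anchors)]))
  invisible(x)
}

# best candidate: fewest screen flags, then highest snr, then earliest rt
best_candidate_idx <- function(cands) {
  if (length(cands) == 0L) return(NA_integer_)
  nf <- vapply(cands, function(p) length(p$screen_flags), integer(1))
  sn <- vapply(cands, function(p) ifelse(is.finite(p$snr), p$snr, 0),
               numeric(1))
  rt <- vapply(cands, `[[`, numeric(1), "rt_apex")
  order(nf, -sn, rt)[1]
}

#' Calibrate retention times per file from internal-standard peaks
#'
#' For each file, pairs every internal-standard target that produced an
#' acceptable peak (no `snr` or `intensity` flag; the best candidate by
#' fewest flags then highest S/N) with its library retention time and
#' builds an [rt_calibration()].
#'
#' @param is_library The internal-standard [compound_library()].
#' @param is_peaks_per_file Named list: file id -> list of screened,
#'   integrated candidate peaks for the IS targets of that file.
#' @return Named list of `semiq_rt_calibration`, one per file.
#' @export
calibrate_rt <- function(is_library, is_peaks_per_file) {
  lapply(is_peaks_per_file, function(cands) {
    exp_rt <- numeric(0); obs_rt <- numeric(0)
    for (i in seq_len(nrow(is_library$targets))) {
      tg <- is_library$targets[i, ]
      mine <- Filter(function(p)
        p$compound_name == tg$name &&
          !any(c("snr", "intensity") %in% p$screen_flags), cands)
      if (length(mine) == 0L) next
      best <- mine[[best_candidate_idx(mine)]]
      exp_rt <- c(exp_rt, tg$rt)
      obs_rt <- c(obs_rt, best$rt_apex)
    }
    suppressWarnings(rt_calibration(exp_rt, obs_rt))
  })
}

#' Align one compound's candidate peaks across files
#'
#' Computes a consensus retention time as the median apex of each file's
#' best candidate (fewest screen flags, then highest S/N), then makes
#' every file re-select the candidate nearest the consensus, overriding
#' its local best. Files whose nearest candidate lies farther than
#' `rt_tol` from the consensus keep that candidate but are marked
#' inconsistent (they end up with status `unknown`). When per-file
#' retention-time calibrations exist, their shifts are passed as
#' `offsets` and subtracted from the apex times first, so the consensus
#' is formed in a drift-corrected common frame rather than in absolute
#' time.
#'
#' @param candidates_per_file Named list: file id -> list of screened,
#'   integrated candidate peaks (possibly empty).
#' @param rt_tol Maximum apex distance from the consensus, seconds.
#' @param offsets Optional named numeric of per-file retention-time
#'   shifts (observed minus expected, as given by the file's
#'   calibration); defaults to 0 for every file.
#' @return List with `consensus_rt` (in the drift-corrected frame) and
#'   `selection`, a named list per file of `list(idx, consistent)`
#'   (`idx` `NA` when the file has no candidates).
#' @export
align_eics <- function(candidates_per_file, rt_tol = 30, offsets = NULL) {
  files <- names(candidates_per_file)
  if (is.null(offsets))
    offsets <- stats::setNames(rep(0, length(candidates_per_file)), files)
  best_rts <- numeric(0)
  for (f in seq_along(candidates_per_file)) {
    cands <- candidates_per_file[[f]]
    bi <- best_candidate_idx(cands)
    if (!is.na(bi))
      best_rts <- c(best_rts, cands[[bi]]$rt_apex - offsets[[f]])
  }
  if (length(best_rts) == 0L)
    return(list(consensus_rt = NA_real_,
                selection = lapply(candidates_per_file, function(x)
                  list(idx = NA_integer_, consistent = FALSE))))
  consensus <- stats::median(best_rts)
  selection <- lapply(seq_along(candidates_per_file), function(f) {
    cands <- candidates_per_file[[f]]
    if (length(cands) == 0L)
      return(list(idx = NA_integer_, consistent = FALSE))
    d <- abs(vapply(cands, `[[`, numeric(1), "rt_apex") - offsets[[f]] -
               consensus)
    i <- which.min(d)
    list(idx = i, consistent = d[i] <= rt_tol)
  })
  names(selection) <- files
  list(consensus_rt = consensus, selection = selection)
}

#' Refine peak selection from the retention-time pattern of neighbours
#'
#' Compounds eluting close together share retention-time drift. For each
#' file the per-compound shift `delta = rt_apex - calibrated expected rt`
#' is computed over clean peaks (empty screen flags); each compound's
#' expected local shift is the median over neighbours whose library
#' retention time lies within `neighbor_window` (default 120 s, the
#' compound itself excluded, at least 3 neighbours required, otherwise
#' the file's global median shift). A compound deviating from its local
#' shift by more than `dev_max` (default 20 s) is re-selected to the
#' candidate nearest `expected + local_shift`; if no candidate lands
#' within `dev_max` of that position, the cell is demoted to status
#' `unknown`. The procedure runs once and is idempotent.
#'
#' @param library The analyte [compound_library()].
#' @param peak_table Nested named list `[[compound]][[file]]` of cells as
#'   built by [run_semi_targeted()] (fields `candidates`, `selected_idx`,
#'   `consistent`, `expected_rt_cal`, `demoted`).
#' @param neighbor_window Library-rt window defining neighbours, seconds.
#' @param dev_max Maximum tolerated deviation from the local shift,
#'   seconds.
#' @return The corrected peak table.
#' @export
refine_by_rt_pattern <- function(library, peak_table,
                                 neighbor_window = 120, dev_max = 20) {
  comps <- names(peak_table)
  files <- unique(unlist(lapply(peak_table, names)))
  lib_rt <- stats::setNames(library$targets$rt, library$targets$name)
  for (f in files) {
    delta <- rep(NA_real_, length(comps))
    names(delta) <- comps
    for (cn in comps) {
      cell <- peak_table[[cn]][[f]]
      if (is.null(cell) || is.na(cell$selected_idx)) next
      pk <- cell$candidates[[cell$selected_idx]]
      if (length(pk$screen_flags) == 0L)
        delta[cn] <- pk$rt_apex - cell$expected_rt_cal
    }
    clean <- names(delta)[!is.na(delta)]
    if (length(clean) == 0L) next
    global_shift <- stats::median(delta[clean])
    for (cn in comps) {
      cell <- peak_table[[cn]][[f]]
      if (is.null(cell) || is.na(cell$selected_idx)) next
      nb <- setdiff(clean, cn)
      nb <- nb[abs(lib_rt[nb] - lib_rt[cn]) <= neighbor_window]
      local_shift <- if (length(nb) >= 3L) stats::median(delta[nb])
                     else global_shift
      pk <- cell$candidates[[cell$selected_idx]]
      dev <- (pk$rt_apex - cell$expected_rt_cal) - local_shift
      if (abs(dev) <= dev_max) next
      target_rt <- cell$expected_rt_cal + local_shift
      d <- abs(vapply(cell$candidates, `[[`, numeric(1), "rt_apex") -
                 target_rt)
      i <- which.min(d)
      if (d[i] <= dev_max) {
        cell$selected_idx <- i
        cell$rt_refined <- TRUE
      } else {
        cell$demoted <- TRUE
      }
      peak_table[[cn]][[f]] <- cell
    }
  }
  peak_table
}

# run the per-EIC part of the chain for one target on one run
detect_for_target <- function(run, target, expected_rt_cal, config,
                              rt_tol = NULL) {
  e <- config$eic
  window <- NULL
  if (is.finite(e$rt_window))
    window <- c(expected_rt_cal - e$rt_window, expected_rt_cal + e$rt_window)
  eic <- tryCatch(
    extract_eic(run, target, ppm_tol = e$ppm_tol, rt_window = window),
    error = function(err) NULL)
  if (is.null(eic) || length(eic$intensity) < 5L)
    return(list(eic = NULL, candidates = list()))
  eic <- smooth_eic(eic, method = e$smoother, params = e$smoother_params)
  eic <- estimate_noise(eic, method = e$noise_method)
  pparams <- config$peak
  if (!is.null(rt_tol)) pparams$rt_tol <- rt_tol
  cands <- select_peaks(eic, method = pparams$method, params = pparams,
                        file_id = run$run_id)
  cands <- lapply(cands, function(p) {
    p <- integrate_peak(eic, p, method = pparams$integrator)
    screen_peak(p, expected_rt = expected_rt_cal, params = pparams)
  })
  list(eic = eic, candidates = cands)
}

#' Run the semi-targeted quantification chain over a batch of files
#'
#' Executes the eight steps in order on every (compound, file) pair:
#' EIC extraction, smoothing, noise estimation, peak selection,
#' integration, screening, identification, and batch optimization
#' (internal-standard retention-time calibration, cross-file alignment,
#' retention-time pattern refinement). Statuses are auto-assigned:
#' `pass` when a clean, consistent, identified peak was selected,
#' `unknown` when candidates exist but the best one is flagged,
#' inconsistent or unidentified, `fail` when the compound produced no
#' candidate in that file. Errors for single compounds or files are
#' isolated and never abort the batch.
#'
#' @param runs List of [ms_run()] objects or mzML file paths.
#' @param analyte_library The analyte [compound_library()].
#' @param is_library Optional internal-standard [compound_library()] for
#'   retention-time calibration (`NULL` to skip; the mapping is then the
#'   identity).
#' @param config Configuration list (see [default_config()]).
#' @param spectral_library List of [spectral_entry()] reference spectra
#'   (used when `config$id$strategy == "mz_rt_ms2"`).
#' @param seed Integer seed recorded in the Overview (the chain itself is
#'   deterministic).
#' @param overview_id Identifier of the resulting Overview.
#' @param created_at Timestamp string recorded in the Overview; defaults
#'   to the current time. Pass a fixed value to make repeated runs on
#'   identical inputs byte-identical.
#' @return A `semiq_overview`: list with `overview_id`, `created_at`,
#'   `params`, `files`, `library_id`, `seed` and `peak_table`
#'   (`[[compound]][[file]]` cells carrying candidates, the selected
#'   peak, status and identification evidence).
#' @export
run_semi_targeted <- function(runs, analyte_library, is_library = NULL,
                              config = default_config(),
                              spectral_library = list(), seed = NULL,
                              overview_id = "overview",
                              created_at = NULL) {
  config <- merge_config(default_config(), config)
  if (!is.null(seed)) set.seed(seed)
  if (is.character(runs)) runs <- lapply(runs, read_run)
  if (inherits(runs, "semiq_run")) runs <- list(runs)
  names(runs) <- vapply(runs, `[[`, character(1), "run_id")
  files <- names(runs)

  # step 8a: internal-standard RT calibration (relaxed rt tolerance)
  calibs <- stats::setNames(
    replicate(length(files), rt_calibration(), simplify = FALSE), files)
  if (!is.null(is_library)) {
    is_peaks <- lapply(runs, function(run) {
      out <- list()
      for (i in seq_len(nrow(is_library$targets))) {
        tg <- is_library$targets[i, ]
        det <- tryCatch(
          detect_for_target(run, tg, tg$rt, config,
                            rt_tol = config$peak$rt_tol *
                              config$batch$is_rt_tol_factor),
          error = function(e) list(candidates = list()))
        out <- c(out, det$candidates)
      }
      out
    })
    calibs <- calibrate_rt(is_library, is_peaks)
  }

  # steps 1-6 per compound per file
  targets <- analyte_library$targets
  peak_table <- list()
  for (ci in seq_len(nrow(targets))) {
    tg <- targets[ci, ]
    row <- list()
    for (f in files) {
      expected_cal <- predict(calibs[[f]], tg$rt)
      det <- tryCatch(detect_for_target(runs[[f]], tg, expected_cal, config),
                      error = function(e) list(candidates = list()))
      row[[f]] <- list(candidates = det$candidates,
                       selected_idx = NA_integer_, consistent = FALSE,
                       expected_rt_cal = expected_cal,
                       demoted = FALSE, rt_refined = FALSE,
                       identification = NULL, status = "fail")
    }
    # step 8b: cross-file alignment in the calibration-corrected frame
    offs <- vapply(row, function(cell) cell$expected_rt_cal - tg$rt,
                   numeric(1))
    al <- align_eics(lapply(row, `[[`, "candidates"),
                     rt_tol = config$batch$align_rt_tol, offsets = offs)
    for (f in files) {
      row[[f]]$selected_idx <- al$selection[[f]]$idx
      row[[f]]$consistent <- al$selection[[f]]$consistent
      row[[f]]$consensus_rt <- al$consensus_rt
    }
    peak_table[[tg$name]] <- row
  }

  # step 8c: RT-pattern refinement
  peak_table <- refine_by_rt_pattern(analyte_library, peak_table,
                                     neighbor_window =
                                       config$batch$neighbor_window,
                                     dev_max = config$batch$dev_max)

  # step 7: identification + status assignment
  for (cn in names(peak_table)) {
    tg <- targets[targets$name == cn, ]
    for (f in names(peak_table[[cn]])) {
      cell <- peak_table[[cn]][[f]]
      if (length(cell$candidates) == 0L) {
        cell$status <- "fail"
        peak_table[[cn]][[f]] <- cell
        next
      }
      if (is.na(cell$selected_idx)) {
        cell$status <- "unknown"
        peak_table[[cn]][[f]] <- cell
        next
      }
      pk <- cell$candidates[[cell$selected_idx]]
      idp <- config$id
      idp$ppm_tol <- config$eic$ppm_tol
      ident <- tryCatch(
        identify_peak(pk, tg, runs[[f]], spectral_library,
                      strategy = config$id$strategy, params = idp),
        error = function(e) list(identified = FALSE,
                                 reason = conditionMessage(e)))
      cell$identification <- ident
      ok <- length(pk$screen_flags) == 0L && cell$consistent &&
        isTRUE(ident$identified) && !isTRUE(cell$demoted)
      cell$status <- if (ok) "pass" else "unknown"
      pk$status <- cell$status
      pk$identification <- ident
      cell$candidates[[cell$selected_idx]] <- pk
      peak_table[[cn]][[f]] <- cell
    }
  }

  structure(
    list(overview_id = overview_id,
         created_at = created_at %||% format(Sys.time(),
                                             "%Y-%m-%dT%H:%M:%S%z"),
         params = config, files = files,
         library_id = analyte_library$library_id,
         seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
         peak_table = peak_table),
    class = "semiq_overview")
}

#' @export
print.semiq_overview <- function(x, ...) {
  st <- overview_status_table(x)
  cat(sprintf("<semiq_overview> %s: %d compounds x %d files\n",
              x$overview_id, length(x$peak_table), length(x$files)))
  print(table(st$status))
  invisible(x)
}

# long-format status summary used by print and the report writer
overview_status_table <- function(overview) {
  rows <- list()
  for (cn in names(overview$peak_table)) {
    for (f in overview$files) {
      cell <- overview$peak_table[[cn]][[f]]
      pk <- selected_peak(cell)
      rows[[length(rows) + 1L]] <- data.frame(
        compound = cn, file = f,
        status = if (is.null(cell)) "fail" else cell$status,
        rt_apex = if (is.null(pk)) NA_real_ else pk$rt_apex,
        rt_start = if (is.null(pk)) NA_real_ else pk$rt_start,
        rt_end = if (is.null(pk)) NA_real_ else pk$rt_end,
        area = if (is.null(pk)) NA_real_ else pk$area,
        snr = if (is.null(pk)) NA_real_ else pk$snr,
        screen_flags = if (is.null(pk)) ""
                       else paste(pk$screen_flags, collapse = ";"),
        identified = if (is.null(cell) || is.null(cell$identification)) NA
                     else isTRUE(cell$identification$identified),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

selected_peak <- function(cell) {
  if (is.null(cell) || is.na(cell$selected_idx) ||
      length(cell$candidates) == 0L) return(NULL)
  cell$candidates[[cell$selected_idx]]
}

#' Write an Overview to JSON
#'
#' Serialises an Overview (peak table, statuses, identification evidence
#' and the full parameter snapshot) to a JSON file. Output is
#' byte-stable for a fixed Overview object.
#'
#' @param overview A `semiq_overview`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_overview <- function(overview, path) {
  ser_cell <- function(cell) {
    if (is.null(cell)) return(NULL)
    pk <- selected_peak(cell)
    list(
      status = cell$status,
      consistent = cell$consistent,
      demoted = isTRUE(cell$demoted),
      rt_refined = isTRUE(cell$rt_refined),
      expected_rt_cal = round(cell$expected_rt_cal, 6),
      consensus_rt = round(cell$consensus_rt %||% NA_real_, 6),
      n_candidates = length(cell$candidates),
      peak = if (is.null(pk)) NULL else list(
        rt_start = round(pk$rt_start, 6), rt_apex = round(pk$rt_apex, 6),
        rt_end = round(pk$rt_end, 6),
        apex_intensity = round(pk$apex_intensity, 6),
        area = round(pk$area, 6), snr = round(pk$snr, 6),
        width = round(pk$width, 6), asymmetry = round(pk$asymmetry, 6),
        n_points = pk$n_points,
        screen_flags = as.list(pk$screen_flags)),
      identification = if (is.null(cell$identification)) NULL else {
        id <- cell$identification
        list(strategy = id$strategy,
             identified = isTRUE(id$identified),
             matched_properties = as.list(id$matched_properties),
             isotope_score = id$isotope_score,
             combined_ms2_score =
               if (is.null(id$spectral_match)) NULL
               else round(id$spectral_match$combined, 6),
             best_reference = id$best_reference,
             reason = id$reason)
      })
  }
  obj <- list(
    overview_id = overview$overview_id,
    created_at = overview$created_at,
    library_id = overview$library_id,
    files = as.list(overview$files),
    seed = overview$seed,
    params = overview$params,
    peak_table = lapply(overview$peak_table, function(row)
      lapply(row, ser_cell)))
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                           null = "null", na = "null", pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}
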