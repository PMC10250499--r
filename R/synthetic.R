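#' Define a synthetic DDA run
#'
#' A design bundles the compound set and the acquisition parameters that
#' a [simulate_run()] emulates: Gaussian chromatographic elution, a
#' crude one-parameter isotope envelope (M+1 at the carbon-count ratio
#' used by [score_isotope_pattern()]), additive baseline plus Gaussian
#' intensity noise clipped at zero, per-centroid mass jitter, and top-N
#' DDA MS2 triggering with a 20 s dynamic exclusion.
#'
#' @param compounds data.frame with columns `name`, `mz` (Th), `rt_true`
#'   (s), `peak_sigma` (s), `abundance` (apex intensity units) and
#'   optionally `group`, `ratio`.
#' @param fragments Named list (by compound name) of data.frames with
#'   `mz`, `rel_intensity` — the MS2 fragment templates. Compounds
#'   without a template trigger no informative MS2.
#' @param run_length Gradient length, seconds.
#' @param ms1_interval MS1 scan interval, seconds.
#' @param dda_top_n MS2 scans triggered per MS1 survey (0 = MS1 only).
#' @param dda_min_intensity Minimum precursor intensity to trigger MS2.
#' @param noise_sigma Standard deviation of the additive intensity
#'   noise.
#' @param baseline Constant intensity baseline on every ion channel.
#' @param rt_drift Global retention-time shift of this run, seconds.
#' @param ppm_error_sigma Per-centroid mass jitter, ppm.
#' @param polarity Ionization mode of the simulated run.
#' @param collision_energy Collision energy recorded in the run
#'   metadata.
#' @param seed Mandatory integer seed.
#' @return A `semiq_design` list.
#' @export
synthetic_design <- function(compounds, fragments = list(),
                             run_length = 600, ms1_interval = 1,
                             dda_top_n = 3, dda_min_intensity = 1000,
                             noise_sigma = 50, baseline = 100,
                             rt_drift = 0, ppm_error_sigma = 2,
                             polarity = "positive",
                             collision_energy = "35 eV",
                             seed) {
  if (missing(seed) || !is.finite(seed)) stop("a seed is mandatory")
  compounds <- as.data.frame(compounds, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "mz", "rt_true", "peak_sigma", "abundance") %in%
                  names(compounds)))
  if (any(compounds$mz <= 0) || any(compounds$peak_sigma <= 0) ||
      any(compounds$abundance <= 0) || run_length <= 0 ||
      ms1_interval <= 0 || dda_top_n < 0 || noise_sigma < 0 ||
      baseline < 0 || ppm_error_sigma < 0)
    stop("invalid design parameters")
  structure(
    list(compounds = compounds, fragments = fragments,
         run_length = run_length, ms1_interval = ms1_interval,
         dda_top_n = as.integer(dda_top_n),
         dda_min_intensity = dda_min_intensity,
         noise_sigma = noise_sigma, baseline = baseline,
         rt_drift = rt_drift, ppm_error_sigma = ppm_error_sigma,
         polarity = polarity, collision_energy = collision_energy,
         seed = as.integer(seed)),
    class = "semiq_design")
}

ISOTOPE_SPACING <- 1.00336
CARBON_FRACTION <- 0.0455
C13_ABUNDANCE <- 0.0108
DDA_EXCLUSION_S <- 20

#' Simulate a DDA run from a design
#'
#' Generates the run scan by scan. Each MS1 survey carries, per
#' compound, a monoisotopic centroid at `mz * (1 + eps)` with
#' `eps ~ N(0, ppm_error_sigma)` and intensity
#' `abundance * exp(-(t - rt_true - rt_drift)^2 / (2 sigma^2))` plus
#' baseline and Gaussian noise (clipped at 0), and an M+1 centroid at
#' the carbon-model isotope ratio. After each survey up to `dda_top_n`
#' MS2 scans are triggered on the most intense eligible precursors
#' (above `dda_min_intensity`, not triggered within the last 20 s); MS2
#' spectra are the compound's fragment template scaled to the precursor
#' signal, with noise. Output is byte-identical across repeated calls
#' with the same design.
#'
#' @param design A [synthetic_design()].
#' @param path Optional mzML output path (the ground truth is then also
#'   written next to it as `<path>.truth.csv`).
#' @return List with `run` (a [ms_run()]), `truth` (data.frame with
#'   `name`, `mz`, `rt_true` — drift included —, `peak_sigma`,
#'   `abundance`, `true_area = abundance * sigma * sqrt(2*pi)` and any
#'   `group`/`ratio` columns), and `path` (`NULL` when not written).
#' @export
simulate_run <- function(design, path = NULL) {
  stopifnot(inherits(design, "semiq_design"))
  set.seed(design$seed)
  cp <- design$compounds
  n <- nrow(cp)
  rt0 <- cp$rt_true + design$rt_drift
  iso_ratio <- cp$mz * CARBON_FRACTION * C13_ABUNDANCE
  scan_times <- seq(0, design$run_length, by = design$ms1_interval)
  spectra <- vector("list", 0)
  last_trigger <- rep(-Inf, n)
  scan_no <- 0L
  for (t in scan_times) {
    sig <- cp$abundance * exp(-(t - rt0)^2 / (2 * cp$peak_sigma^2))
    mono_int <- pmax(sig + design$baseline +
                       stats::rnorm(n, 0, design$noise_sigma), 0)
    iso_int <- pmax(sig * iso_ratio + design$baseline +
                      stats::rnorm(n, 0, design$noise_sigma), 0)
    mono_mz <- cp$mz *
      (1 + stats::rnorm(n, 0, design$ppm_error_sigma) * 1e-6)
    iso_mz <- (cp$mz + ISOTOPE_SPACING) *
      (1 + stats::rnorm(n, 0, design$ppm_error_sigma) * 1e-6)
    mz <- c(mono_mz, iso_mz)
    it <- c(mono_int, iso_int)
    keep <- it > 0
    mz <- mz[keep]; it <- it[keep]
    o <- order(mz)
    mz <- mz[o]; it <- it[o]
    dup <- c(FALSE, diff(mz) <= 0)
    if (any(dup)) { mz <- mz[!dup]; it <- it[!dup] }
    scan_no <- scan_no + 1L
    spectra[[length(spectra) + 1L]] <- spectrum(
      ms_level = 1L, rt = t, mz = mz, intensity = it,
      scan_id = paste0("scan=", scan_no))
    # DDA cycle: top-N most intense eligible precursors
    if (design$dda_top_n > 0L) {
      eligible <- which(mono_int >= design$dda_min_intensity &
                          (t - last_trigger) >= DDA_EXCLUSION_S)
      eligible <- eligible[order(-mono_int[eligible])]
      picks <- utils::head(eligible, design$dda_top_n)
      for (j in seq_along(picks)) {
        ci <- picks[j]
        last_trigger[ci] <- t
        tmpl <- design$fragments[[cp$name[ci]]]
        if (is.null(tmpl)) next
        fmz <- tmpl$mz *
          (1 + stats::rnorm(nrow(tmpl), 0, design$ppm_error_sigma) * 1e-6)
        fint <- pmax(tmpl$rel_intensity / 100 * sig[ci] * 0.3 +
                       stats::rnorm(nrow(tmpl), 0,
                                    design$noise_sigma / 2), 0)
        keepf <- fint > 0
        if (!any(keepf)) next
        fmz <- fmz[keepf]; fint <- fint[keepf]
        of <- order(fmz); fmz <- fmz[of]; fint <- fint[of]
        dupf <- c(FALSE, diff(fmz) <= 0)
        if (any(dupf)) { fmz <- fmz[!dupf]; fint <- fint[!dupf] }
        scan_no <- scan_no + 1L
        spectra[[length(spectra) + 1L]] <- spectrum(
          ms_level = 2L,
          rt = t + j * design$ms1_interval / (design$dda_top_n + 1),
          mz = fmz, intensity = fint,
          precursor_mz = mono_mz[ci], precursor_charge = 1L,
          scan_id = paste0("scan=", scan_no))
      }
    }
  }
  run_id <- if (is.null(path)) sprintf("sim_seed%d", design$seed)
            else tools::file_path_sans_ext(basename(path))
  run <- ms_run(run_id = run_id, polarity = design$polarity,
                spectra = spectra,
                source_path = if (is.null(path)) "" else path,
                metadata = list(instrument_type = "synthetic",
                                collision_energy =
                                  design$collision_energy))
  truth <- data.frame(name = cp$name, mz = cp$mz, rt_true = rt0,
                      peak_sigma = cp$peak_sigma,
                      abundance = cp$abundance,
                      true_area = cp$abundance * cp$peak_sigma *
                        sqrt(2 * pi),
                      stringsAsFactors = FALSE)
  if (!is.null(cp$group)) truth$group <- cp$group
  if (!is.null(cp$ratio)) truth$ratio <- cp$ratio
  if (!is.null(path)) {
    write_run(run, path)
    utils::write.csv(truth, paste0(path, ".truth.csv"), row.names = FALSE)
  }
  list(run = run, truth = truth, path = path)
}

#' Default concentration ratios of the two-mixture benchmark
#'
#' Seven compound groups; `Gm` is equimolar in both mixtures and the six
#' `Gd*` groups are mixed at SB:SA ratios 1/16, 1/4, 1/2, 2, 4 and 16.
#'
#' @return Named numeric vector of SB:SA ratios.
#' @export
benchmark_ratios <- function() {
  c(Gd1 = 1 / 16, Gd2 = 1 / 4, Gd3 = 1 / 2, Gm = 1,
    Gd4 = 2, Gd5 = 4, Gd6 = 16)
}

#' Simulate the SA/SB two-mixture benchmark pair
#'
#' Draws `n_per_group` compounds per group (well separated in m/z so ion
#' channels never overlap within the extraction tolerance), assigns each
#' group its SB:SA concentration ratio, and simulates two runs that are
#' identical in design except for the group-wise abundance scaling, a
#' small retention-time drift on SB, and fresh noise.
#'
#' @param n_per_group Compounds per group (>= 1).
#' @param base_design Optional named list overriding acquisition
#'   parameters of [synthetic_design()] (e.g. `run_length`,
#'   `noise_sigma`, `rt_drift_sb`).
#' @param ratios Named SB:SA ratios per group; defaults to
#'   [benchmark_ratios()].
#' @param seed Integer seed driving compound generation and both runs.
#' @param dir Optional directory; when given, `SA.mzML`, `SB.mzML` and
#'   `truth.csv` are written there.
#' @return List with `sa`, `sb` (each a [simulate_run()] result) and
#'   `truth` (per-compound design table with `group` and `ratio`).
#' @export
simulate_benchmark_pair <- function(n_per_group = 20, base_design = list(),
                                    ratios = benchmark_ratios(), seed = 1,
                                    dir = NULL) {
  if (n_per_group < 1) stop("n_per_group must be >= 1")
  set.seed(seed)
  groups <- names(ratios)
  n <- n_per_group * length(groups)
  bd <- merge_config(
    list(run_length = 600, ms1_interval = 1, dda_top_n = 3,
         dda_min_intensity = 1000, noise_sigma = 50, baseline = 100,
         ppm_error_sigma = 2, rt_drift_sb = 5,
         abundance_range = c(8e4, 6e5), sigma_range = c(3, 6),
         n_fragments = c(4L, 8L)),
    base_design)
  # well-separated m/z grid: 2 Th spacing keeps every monoisotopic and
  # M+1 channel > 0.8 Th away from any foreign channel
  slots <- seq(100, 898, by = 2)
  mz <- sort(sample(slots, n)) + stats::runif(n, -0.1, 0.1)
  rt <- stats::runif(n, 60, bd$run_length - 60)
  sg <- stats::runif(n, bd$sigma_range[1], bd$sigma_range[2])
  ab <- exp(stats::runif(n, log(bd$abundance_range[1]),
                         log(bd$abundance_range[2])))
  group <- rep(groups, each = n_per_group)
  name <- sprintf("%s_%02d", group, rep(seq_len(n_per_group),
                                        times = length(groups)))
  compounds_sa <- data.frame(name = name, mz = mz, rt_true = rt,
                             peak_sigma = sg, abundance = ab,
                             group = group,
                             ratio = unname(ratios[group]),
                             stringsAsFactors = FALSE)
  fragments <- stats::setNames(lapply(seq_len(n), function(i) {
    k <- sample(seq(bd$n_fragments[1], bd$n_fragments[2]), 1)
    fmz <- sort(stats::runif(k, 50, max(mz[i] - 20, 60)))
    data.frame(mz = fmz, rel_intensity = stats::runif(k, 5, 100))
  }), name)
  compounds_sb <- compounds_sa
  compounds_sb$abundance <- compounds_sa$abundance * compounds_sa$ratio
  mk <- function(cpds, drift, run_seed)
    synthetic_design(compounds = cpds, fragments = fragments,
                     run_length = bd$run_length,
                     ms1_interval = bd$ms1_interval,
                     dda_top_n = bd$dda_top_n,
                     dda_min_intensity = bd$dda_min_intensity,
                     noise_sigma = bd$noise_sigma, baseline = bd$baseline,
                     rt_drift = drift,
                     ppm_error_sigma = bd$ppm_error_sigma,
                     seed = run_seed)
  seed_sa <- (seed * 2L) %% .Machine$integer.max
  seed_sb <- (seed * 2L + 1L) %% .Machine$integer.max
  des_sa <- mk(compounds_sa, 0, seed_sa)
  des_sb <- mk(compounds_sb, bd$rt_drift_sb, seed_sb)
  path_sa <- if (is.null(dir)) NULL else file.path(dir, "SA.mzML")
  path_sb <- if (is.null(dir)) NULL else file.path(dir, "SB.mzML")
  sa <- simulate_run(des_sa, path_sa)
  sb <- simulate_run(des_sb, path_sb)
  sa$run$run_id <- "SA"
  sb$run$run_id <- "SB"
  truth <- compounds_sa
  truth$abundance_sb <- compounds_sb$abundance
  truth$true_area_sa <- truth$abundance * truth$peak_sigma * sqrt(2 * pi)
  truth$true_area_sb <- truth$abundance_sb * truth$peak_sigma * sqrt(2 * pi)
  if (!is.null(dir))
    utils::write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
  list(sa = sa, sb = sb, truth = truth)
}

#' Recover SB:SA fold changes from a benchmark analysis
#'
#' Convenience summary used in validation: runs the full semi-targeted
#' chain on both benchmark runs and returns per-compound quantified
#' area ratios with group labels, for compounds that reached status
#' `pass` in both mixtures.
#'
#' @param bench Result of [simulate_benchmark_pair()].
#' @param config Analysis configuration (see [default_config()]).
#' @return List with `per_compound` (data.frame `name`, `group`,
#'   `ratio`, `recovered`) and `per_group` (data.frame `group`,
#'   `generating_ratio`, `median_recovered`, `n`).
#' @export
recover_benchmark_ratios <- function(bench, config = default_config()) {
  lib <- compound_library(
    "benchmark", "analyte",
    data.frame(name = bench$truth$name, mz = bench$truth$mz,
               rt = bench$truth$rt_true, group = bench$truth$group))
  ov <- run_semi_targeted(list(bench$sa$run, bench$sb$run), lib,
                          config = config, created_at = "benchmark")
  long <- overview_status_table(ov)
  per <- NULL
  for (i in seq_len(nrow(bench$truth))) {
    nm <- bench$truth$name[i]
    a <- long[long$compound == nm & long$file == "SA", ]
    b <- long[long$compound == nm & long$file == "SB", ]
    if (nrow(a) == 1L && nrow(b) == 1L &&
        a$status == "pass" && b$status == "pass" && a$area > 0)
      per <- rbind(per, data.frame(
        name = nm, group = bench$truth$group[i],
        ratio = bench$truth$ratio[i],
        recovered = b$area / a$area, stringsAsFactors = FALSE))
  }
  groups <- unique(bench$truth$group)
  per_group <- do.call(rbind, lapply(groups, function(g) {
    sub <- per[per$group == g, ]
    data.frame(group = g,
               generating_ratio = unique(bench$truth$ratio[
                 bench$truth$group == g]),
               median_recovered = if (nrow(sub)) stats::median(sub$recovered)
                                  else NA_real_,
               n = nrow(sub), stringsAsFactors = FALSE)
  }))
  list(per_compound = per, per_group = per_group, overview = ov)
}
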