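#' Default analysis configuration
#'
#' Returns the full, nested default configuration for the quantification
#' chain. Every analysis records the configuration it used in its
#' Overview, so results are reproducible from the Overview alone.
#'
#' Keys (defaults in parentheses):
#' \describe{
#'   \item{eic}{`ppm_tol` (20 ppm), `rt_window` (`NA` = whole run),
#'     `rt_unit` of library CSV files ("seconds"),
#'     `smoother` ("savitzky_golay"), `smoother_params`
#'     (`window` 7, `order` 2, `sigma` 2, `span` 0.15),
#'     `noise_method` ("mad").}
#'   \item{peak}{`method` ("local_max"), `integrator`
#'     ("baseline_trapezoid"), `snr_min` (3), `int_min` (1000),
#'     `rt_tol` (30 s), `width_min` (2 s), `width_max` (90 s),
#'     `asym_max` (5), `local_max_k` (2), `boundary_frac` (0.05),
#'     `deriv_eps` (0.01), `cwt_scales` (2:16).}
#'   \item{id}{`strategy` ("mz_rt"), `frag_tol` (0.02 Da),
#'     `precursor_tol` (0.5 Da), `iso_min` (0.5), `ms2_min` (0.7),
#'     `weights` (all seven equal to 1).}
#'   \item{batch}{`align_rt_tol` (30 s), `neighbor_window` (120 s),
#'     `dev_max` (20 s), `is_rt_tol_factor` (2).}
#'   \item{curation}{`frag_tol` (0.02 Da), `min_frac` (0.5),
#'     `min_fragments` (1), `min_total_intensity` (0).}
#' }
#'
#' @return A nested named list.
#' @export
default_config <- function() {
  list(
    eic = list(
      ppm_tol = 20,
      rt_window = NA_real_,
      rt_unit = "seconds",
      smoother = "savitzky_golay",
      smoother_params = list(window = 7L, order = 2L, sigma = 2, span = 0.15),
      noise_method = "mad"
    ),
    peak = list(
      method = "local_max",
      integrator = "baseline_trapezoid",
      snr_min = 3,
      int_min = 1000,
      rt_tol = 30,
      width_min = 2,
      width_max = 90,
      asym_max = 5,
      local_max_k = 2L,
      boundary_frac = 0.05,
      deriv_eps = 0.01,
      cwt_scales = 2:16
    ),
    id = list(
      strategy = "mz_rt",
      frag_tol = 0.02,
      precursor_tol = 0.5,
      iso_min = 0.5,
      ms2_min = 0.7,
      weights = list(cosine = 1, weighted_cosine = 1, entropy_similarity = 1,
                     matched_frac_query = 1, matched_frac_reference = 1,
                     matched_intensity_frac = 1, mz_accuracy = 1)
    ),
    batch = list(
      align_rt_tol = 30,
      neighbor_window = 120,
      dev_max = 20,
      is_rt_tol_factor = 2
    ),
    curation = list(
      frag_tol = 0.02,
      min_frac = 0.5,
      min_fragments = 1L,
      min_total_intensity = 0
    )
  )
}

#' Load a configuration file
#'
#' Reads a YAML configuration file and merges it (recursively) over the
#' defaults, so a config file only needs to state what it changes.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @return The merged configuration list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  merge_config(cfg, user)
}

# recursive right-biased merge of nested named lists
merge_config <- function(base, override) {
  if (!is.list(override)) return(override)
  for (k in names(override)) {
    base[[k]] <- if (is.list(base[[k]]) && is.list(override[[k]]))
      merge_config(base[[k]], override[[k]]) else override[[k]]
  }
  base
}
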