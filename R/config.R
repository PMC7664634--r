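#' Run configuration for the block-learning pipeline
#'
#' Collects every tunable knob with its default. The config round-trips
#' losslessly through YAML ([write_config()] / [read_config()]) and is
#' embedded in each fit's provenance, so any run can be reproduced exactly.
#'
#' @param alpha significance level of the G^2 independence tests (default
#'   0.05).
#' @param max_cond maximum conditioning-set size in MMPC (default 3).
#' @param pc_cap forward-phase PC size cap (default 10).
#' @param orientation_cap maximum number of inter-block edges to enumerate
#'   (default 16, i.e. 65,536 candidates).
#' @param dp_cap maximum block size for the exact DP (default 25).
#' @param forced_mandatory if `TRUE` (default) an oriented inter-block edge
#'   makes its parent a mandatory parent of the child; if `FALSE` it is only
#'   a candidate.
#' @param mkm_init medoid initialization, `"random"` or `"mi_weighted"`.
#' @param mkm_max_iter MKM sweep cap (default 100).
#' @param seed master seed; fans out to MKM initialization (sampling uses its
#'   own seed at data generation time).
#' @return an object of class `blmkm_config`.
#' @export
blmkm_config <- function(alpha = 0.05, max_cond = 3L, pc_cap = 10L,
                         orientation_cap = 16L, dp_cap = 25L,
                         forced_mandatory = TRUE,
                         mkm_init = "random", mkm_max_iter = 100L, seed = 1L) {
  cfg <- structure(
    list(alpha = alpha, max_cond = as.integer(max_cond),
         pc_cap = as.integer(pc_cap),
         orientation_cap = as.integer(orientation_cap),
         dp_cap = as.integer(dp_cap),
         forced_mandatory = isTRUE(forced_mandatory),
         mkm_init = mkm_init, mkm_max_iter = as.integer(mkm_max_iter),
         seed = as.integer(seed), log_base = "natural"),
    class = "blmkm_config"
  )
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  if (cfg$alpha <= 0 || cfg$alpha >= 1) stop("alpha must be in (0, 1)")
  for (f in c("max_cond", "pc_cap", "orientation_cap", "dp_cap", "mkm_max_iter")) {
    if (cfg[[f]] < 1L) stop(f, " must be positive")
  }
  if (!cfg$mkm_init %in% c("random", "mi_weighted")) {
    stop("mkm_init must be 'random' or 'mi_weighted'")
  }
  invisible(cfg)
}

#' @rdname blmkm_config
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname blmkm_config
#' @param config a `blmkm_config` (for [write_config()]).
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$log_base <- NULL
  do.call(blmkm_config, raw)
}
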