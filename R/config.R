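#' Default run configuration
#'
#' Returns the full set of tunable parameters used across the pipeline, with
#' defaults matching the published GPCR:G protein protocol: geometric contact
#' cutoffs, the 20% persistence threshold, 50 hill-climbing restarts, BDeu
#' equivalent sample size 1, the 10 A neighboring/allosteric split, 1000
#' perturbation and resampling trials at a 0.99 empirical confidence level,
#' and the top-quartile (0.25) cooperativity selection.
#'
#' @param ... named overrides of individual defaults. Unknown names are an
#'   error, so typos in config files fail loudly.
#' @return A named list of class `contactbn_config`.
#' @examples
#' cfg <- contactbn_config(persistence_threshold = 0.5)
#' cfg$salt_bridge_dist
#' @export
contactbn_config <- function(...) {
  cfg <- list(
    # contact geometry (distances in Angstrom, angles in degrees)
    salt_bridge_dist      = 4.0,
    hbond_dist            = 3.5,
    hbond_angle           = 70,
    vdw_tolerance         = 0.5,   # added to r_i + r_j (set vdw_gap_mode for literal gap rule)
    vdw_gap_mode          = FALSE, # TRUE: contact if d - (r_i + r_j) < vdw_gap
    vdw_gap               = 2.0,
    pi_stack_dist         = 7.0,
    pi_stack_angle        = 30,
    cation_pi_dist        = 6.0,
    cation_pi_angle       = 60,
    # fingerprint filtering
    persistence_threshold = 0.20,
    # structure learning
    restarts              = 50,
    ess                   = 1.0,
    max_parents           = 5L,
    # allostery classification
    allosteric_cutoff     = 10.0,
    edge_distance_mode    = "min", # min | mean | centroid over cross residue pairs
    # robustness
    n_perturbations       = 1000L,
    n_resamples           = 1000L,
    move_budget           = 2L,
    ci_level              = 0.99,
    # cooperativity
    quartile_fraction     = 0.25,
    # joint distributions
    jsd_pseudocount       = 0.5,
    state_cap             = 2^20,
    seed                  = 1L
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad) || is.null(names(dots)) || any(names(dots) == "")) {
      stop("unknown config option(s): ", paste(bad, collapse = ", "))
    }
    cfg[names(dots)] <- dots
  }
  validate_config(cfg)
  class(cfg) <- "contactbn_config"
  cfg
}

validate_config <- function(cfg) {
  dist_fields <- c("salt_bridge_dist", "hbond_dist", "pi_stack_dist",
                   "cation_pi_dist", "allosteric_cutoff", "vdw_gap")
  for (f in dist_fields) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0) stop("config ", f, " must be > 0")
  }
  if (cfg$persistence_threshold < 0 || cfg$persistence_threshold > 1) {
    stop("persistence_threshold must lie in [0, 1]")
  }
  if (cfg$ci_level <= 0 || cfg$ci_level >= 1) stop("ci_level must lie in (0, 1)")
  if (cfg$quartile_fraction <= 0 || cfg$quartile_fraction > 1) {
    stop("quartile_fraction must lie in (0, 1]")
  }
  if (cfg$ess <= 0) stop("ess must be positive")
  invisible(cfg)
}

#' Read a run configuration from a YAML file
#'
#' Keys in the file override the defaults of [contactbn_config()].
#'
#' @param path path to a YAML file of option: value pairs.
#' @return A `contactbn_config` list.
#' @export
read_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required to read config files")
  }
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  do.call(contactbn_config, vals)
}
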