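#' Default run configuration
#'
#' All tunable constants of the pipeline in one nested list. The defaults
#' reproduce the method's stated constants: 5 A contact/summation/member
#' cutoffs, 10 A geometry sphere and patch-merge radius, contact-filter
#' threshold -0.1, confidence bins of width 0.1 with 0.5/0.1 seed/member
#' cuts, the 30% residue rule, 76 hidden nodes, learning rate 0.01,
#' momentum 0.1, 20 bags, 1.5x bag negatives, 2x ANN/SVM negatives, 1000
#' iterations with validation every 10.
#'
#' @return A named list of class `glyco_config`.
#' @export
default_config <- function() {
  structure(list(
    contact_cutoff = 5,
    sasa_probe = 1.4,
    sasa_points = 1920L,
    geometry_radius = 10,
    min_contact_atoms = 25L,
    filter_threshold = -0.1,
    template_spacing = 1,
    template_sigma = 1,
    grid_spacing = 1,
    sum_radius = 5,
    agg_radius = 5,
    label_cutoff = 5,
    residue_fraction = 0.3,
    seed_confidence = 0.5,
    member_confidence = 0.1,
    member_radius = 5,
    merge_radius = 10,
    training = list(
      hidden_nodes = 76L,
      learning_rate = 0.01,
      momentum = 0.1,
      max_iterations = 1000L,
      validation_every = 10L,
      mae_tol = 1e-4,
      neg_pos_ratio = 2,
      bag_neg_ratio = 1.5,
      bags = 20L,
      min_positives = 3L,
      svm_cost_grid = 2^seq(-5, 15, by = 2),
      svm_gamma_grid = 2^seq(-15, 3, by = 2)
    )
  ), class = "glyco_config")
}

#' Hash of a configuration
#'
#' Stable digest of the configuration list; model bundles embed it and
#' refuse to predict when the feature configuration differs.
#'
#' @param config A `glyco_config`.
#' @return Character hash.
#' @export
config_hash <- function(config) {
  digest::digest(unclass(config), algo = "sha1")
}

#' Read / write a configuration as YAML
#'
#' @param path File path.
#' @param config A `glyco_config` (for writing).
#' @return The configuration (reading) or `path` invisibly (writing).
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- unclass(default_config())
  base_tr <- base$training
  if (!is.null(cfg$training)) base_tr[names(cfg$training)] <- cfg$training
  cfg$training <- NULL
  base[names(cfg)] <- cfg
  base$training <- base_tr
  structure(base, class = "glyco_config")
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
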