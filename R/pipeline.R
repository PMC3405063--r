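# End-to-end orchestration: corpus featurization with leave-query-out,
# per-atom-type training, confidence calibration, and whole-structure
# prediction.

#' Featurize a corpus of complexes with leave-query-out density maps
#'
#' Computes SASA and binding labels for every structure, extracts the
#' corpus-wide interacting-pair database, and featurizes each structure
#' against templates built with that structure's own pairs excluded
#' (leave-query-out, the blind-test surrogate). Scaling bounds are the
#' per-protein max/min medians over `bounds_ids` (default: all proteins).
#'
#' @param corpus List of `glyco_structure`s (or [generate_toy_complex()]
#'   outputs, whose `$structure` is taken).
#' @param config A `glyco_config`.
#' @param bounds_ids Protein ids used to derive the scaling bounds.
#' @param filter A `glyco_filter`.
#' @return A list (`glyco_corpus_features`): `features` (one tibble, all
#'   proteins, with `protein` and `label` columns), `bounds`, `pairs`,
#'   `structures` (named list), `config_hash`.
#' @export
featurize_corpus <- function(corpus, config = default_config(),
                             bounds_ids = NULL,
                             filter = default_contact_filter(config$filter_threshold)) {
  corpus <- purrr::map(corpus, function(x) {
    if (inherits(x, "glyco_structure")) x else x$structure
  })
  corpus <- purrr::map(corpus, function(s) {
    if (all(is.na(s$atoms$sasa))) {
      compute_sasa_apo(s, config$sasa_probe, config$sasa_points)
    } else s
  })
  names(corpus) <- purrr::map_chr(corpus, "id")
  pairs <- extract_pairs(corpus, filter = filter,
                         cutoff = config$contact_cutoff)
  raw <- purrr::map(corpus, function(s) {
    tpl <- build_templates(pairs, spacing = config$template_spacing,
                           sigma = config$template_sigma,
                           exclude_sources = s$id)
    pdm <- project_pdm(s, tpl, spacing = config$grid_spacing,
                       mask_radius = config$contact_cutoff)
    ft <- featurize(s, pdm, bounds = NULL,
                    sum_radius = config$sum_radius,
                    agg_radius = config$agg_radius)
    lab <- label_atoms(s, cutoff = config$label_cutoff)
    ft$label <- lab$label[match(ft$atom_idx, lab$atom_idx)]
    ft$protein <- s$id
    ft
  })
  if (is.null(bounds_ids)) bounds_ids <- names(corpus)
  A_list <- purrr::map(raw[bounds_ids], function(ft) {
    as.matrix(ft[, .A_cols()])
  })
  bounds <- scaling_bounds(A_list)
  feats <- purrr::map(raw, function(ft) {
    sc <- scale_attribute(as.matrix(ft[, .A_cols()]), bounds$m_min,
                          bounds$m_max)
    colnames(sc) <- .a_cols()
    dplyr::bind_cols(ft, tibble::as_tibble(sc))
  })
  structure(list(features = dplyr::bind_rows(feats), bounds = bounds,
                 pairs = pairs, structures = corpus,
                 config_hash = config_hash(config)),
            class = "glyco_corpus_features")
}

#' Train the per-atom-type site predictor on a featurized corpus
#'
#' Splits proteins into training, validation and test roles, trains one
#' classifier per protein atom type present with enough positives in the
#' training proteins (all positives plus ratio-sampled negatives), selects
#' each model's decision threshold and builds its confidence lookup table
#' on the validation proteins.
#'
#' @param cf A `glyco_corpus_features` from [featurize_corpus()].
#' @param algorithm `"ann"`, `"svm"` or `"ann_bagging"`.
#' @param roles Named character vector mapping protein id ->
#'   `"train"` / `"validation"` / `"test"`.
#' @param config A `glyco_config` (hash must match the features).
#' @param seed Integer RNG seed.
#' @return A `glyco_predictor` bundle: per-type models, thresholds,
#'   confidence tables, bounds, the pair database and the config hash.
#' @export
train_site_predictor <- function(cf, algorithm = c("ann", "svm", "ann_bagging"),
                                 roles, config = default_config(), seed = 1L) {
  algorithm <- match.arg(algorithm)
  if (!identical(cf$config_hash, config_hash(config))) {
    rlang::abort("feature table was built with a different configuration")
  }
  ft <- cf$features
  ft$role <- unname(roles[ft$protein])
  tr <- config$training
  train_ft <- ft[ft$role == "train", ]
  val_ft <- ft[ft$role == "validation", ]
  types <- sort(unique(train_ft$type_id))
  models <- list(); thresholds <- list(); conf_tables <- list()
  for (t in types) {
    sub <- train_ft[train_ft$type_id == t, ]
    vsub <- val_ft[val_ft$type_id == t, ]
    if (sum(sub$label) < tr$min_positives || all(sub$label) ||
        !nrow(vsub)) next
    x <- as.matrix(sub[, .a_cols()])
    xv <- as.matrix(vsub[, .a_cols()])
    key <- as.character(t)
    if (algorithm == "ann_bagging") {
      models[[key]] <- train_bagged(x, sub$label, xv, vsub$label,
                                    config = config, seed = seed + t)
    } else {
      idx <- subsample_training_set(sub$label, ratio = tr$neg_pos_ratio,
                                    seed = seed + t)
      models[[key]] <- train_model(x[idx, , drop = FALSE], sub$label[idx],
                                   algorithm = algorithm, config = config,
                                   seed = seed + t)
    }
    pv <- predict(models[[key]], xv)
    thresholds[[key]] <- select_threshold(pv, vsub$label, quiet = TRUE)
    conf_tables[[key]] <- build_confidence_table(pv, vsub$label)
  }
  structure(list(algorithm = algorithm, models = models,
                 thresholds = thresholds, conf_tables = conf_tables,
                 bounds = cf$bounds, pairs = cf$pairs, roles = roles,
                 config = config, config_hash = cf$config_hash,
                 seed = seed),
            class = "glyco_predictor")
}

#' @export
print.glyco_predictor <- function(x, ...) {
  cat(sprintf("<glyco_predictor> %s: %d atom-type models\n", x$algorithm,
              length(x$models)))
  invisible(x)
}

#' Per-atom activities and confidences from a feature table
#'
#' Applies the per-type models of a trained bundle to an already
#' featurized atom table. Atoms whose type has no model receive activity
#' and confidence 0.
#'
#' @param bundle A `glyco_predictor`.
#' @param features A `glyco_features` tibble with scaled columns.
#' @return The feature identifier columns plus `activity`, `confidence`
#'   and `predicted` (activity >= the type threshold).
#' @export
predict_atoms <- function(bundle, features) {
  out <- features[, c("atom_idx", "serial", "chain", "resi", "icode",
                      "resn", "atom", "type_id", "x", "y", "z",
                      intersect("protein", names(features)))]
  out$activity <- 0; out$confidence <- 0; out$predicted <- FALSE
  for (key in names(bundle$models)) {
    t <- as.integer(key)
    rows <- which(features$type_id == t)
    if (!length(rows)) next
    act <- predict(bundle$models[[key]],
                   as.matrix(features[rows, .a_cols()]))
    out$activity[rows] <- act
    out$confidence[rows] <- to_confidence(act, bundle$conf_tables[[key]])
    out$predicted[rows] <- act >= bundle$thresholds[[key]]
  }
  out
}

#' Predict carbohydrate-binding sites on a structure
#'
#' The full prediction path for one query: SASA, leave-query-out density
#' templates from the bundle's pair database, PDM projection, attribute
#' encoding with the bundle's scaling bounds, per-atom-type classifier
#' activities, confidence conversion, patch clustering and residue-level
#' prediction.
#'
#' @param structure A `glyco_structure` (SASA computed if missing).
#' @param bundle A trained `glyco_predictor`.
#' @param config A `glyco_config`; must hash-match the bundle.
#' @return A list (`glyco_prediction`): `atoms` (per-surface-atom tibble
#'   with activity/confidence), `patches` (a `glyco_patches` tibble) and
#'   `residues` (predicted residue keys).
#' @export
predict_binding_sites <- function(structure, bundle,
                                  config = bundle$config) {
  if (!identical(bundle$config_hash, config_hash(config))) {
    rlang::abort("bundle was trained under a different configuration")
  }
  if (all(is.na(structure$atoms$sasa))) {
    structure <- compute_sasa_apo(structure, config$sasa_probe,
                                  config$sasa_points)
  }
  tpl <- build_templates(bundle$pairs, spacing = config$template_spacing,
                         sigma = config$template_sigma,
                         exclude_sources = structure$id)
  pdm <- project_pdm(structure, tpl, spacing = config$grid_spacing,
                     mask_radius = config$contact_cutoff)
  ft <- featurize(structure, pdm, bounds = bundle$bounds,
                  sum_radius = config$sum_radius,
                  agg_radius = config$agg_radius)
  atoms <- predict_atoms(bundle, ft)
  res <- .patches_and_residues(atoms, structure, config)
  structure(list(atoms = atoms, patches = res$patches,
                 residues = res$residues, id = structure$id),
            class = "glyco_prediction")
}

.patches_and_residues <- function(atoms, structure, config) {
  co <- cbind(atoms$x, atoms$y, atoms$z)
  patches <- cluster_patches(co, atoms$confidence,
                             seed_threshold = config$seed_confidence,
                             member_threshold = config$member_confidence,
                             member_radius = config$member_radius,
                             merge_radius = config$merge_radius)
  members <- unique(unlist(patches$members))
  residues <- residues_from_patch(atoms$atom_idx[members], structure,
                                  min_fraction = config$residue_fraction)
  list(patches = patches, residues = residues)
}

#' Residue-level evaluation of a trained predictor on held-out proteins
#'
#' For each protein in the requested role, converts per-atom confidences
#' into patches and residue predictions (reusing the corpus feature
#' table), compares them with the ground-truth binding residues, and
#' pools the confusion counts.
#'
#' @param bundle A `glyco_predictor`.
#' @param cf The `glyco_corpus_features` used in training.
#' @param role Which proteins to evaluate (default `"test"`).
#' @param config A `glyco_config`.
#' @return A list: `per_protein` tibble (id + six scores + counts),
#'   `pooled` one-row benchmark tibble, `atoms` (per-atom predictions).
#' @export
evaluate_site_predictor <- function(bundle, cf, role = "test",
                                    config = bundle$config) {
  ids <- names(bundle$roles)[bundle$roles == role]
  atoms_all <- list(); rows <- list()
  for (id in ids) {
    st <- cf$structures[[id]]
    ft <- cf$features[cf$features$protein == id, ]
    atoms <- predict_atoms(bundle, ft)
    pr <- .patches_and_residues(atoms, st, config)
    actual <- actual_binding_residues(st, cutoff = config$label_cutoff,
                                      min_fraction = config$residue_fraction,
                                      probe_radius = config$sasa_probe,
                                      n_points = config$sasa_points)
    universe <- surface_residues(st, apo = TRUE,
                                 probe_radius = config$sasa_probe,
                                 n_points = config$sasa_points)
    cc <- confusion(intersect(pr$residues, universe),
                    intersect(actual, universe), universe)
    rows[[id]] <- dplyr::bind_cols(tibble::tibble(id = id), cc)
    atoms_all[[id]] <- atoms
  }
  per_protein <- benchmark_scores(dplyr::bind_rows(rows))
  pooled <- benchmark_scores(tibble::tibble(
    tp = sum(per_protein$tp), tn = sum(per_protein$tn),
    fp = sum(per_protein$fp), fn = sum(per_protein$fn)))
  list(per_protein = per_protein, pooled = pooled,
       atoms = dplyr::bind_rows(atoms_all))
}

#' Standard train/validation/test role assignment
#'
#' @param ids Protein ids.
#' @param n_val,n_test Validation and test set sizes (defaults 5 and 5).
#' @param seed Integer seed for the shuffle.
#' @return Named character vector id -> role.
#' @export
assign_roles <- function(ids, n_val = 5L, n_test = 5L, seed = 1L) {
  set.seed(seed)
  ids <- sample(unique(ids))
  roles <- rep("train", length(ids))
  roles[seq_len(n_test)] <- "test"
  roles[n_test + seq_len(n_val)] <- "validation"
  stats::setNames(roles, ids)
}

#' 10-fold cross-validation of the site predictor
#'
#' Rotates [crossval_folds()] role assignments, trains one bundle per
#' fold on that fold's 80% training proteins, and pools the test-fold
#' predictions so every protein is predicted exactly once.
#'
#' @param cf A `glyco_corpus_features`.
#' @param algorithm Passed to [train_site_predictor()].
#' @param config A `glyco_config`.
#' @param k Number of folds (default 10).
#' @param seed Integer seed.
#' @return A list: `folds` assignment tibble, `bundles` (per fold),
#'   `pooled` residue-level benchmark, `per_protein` scores.
#' @export
crossval_site_predictor <- function(cf, algorithm = "ann",
                                    config = default_config(), k = 10L,
                                    seed = 1L) {
  ids <- unique(cf$features$protein)
  folds <- crossval_folds(ids, k = k, seed = seed)
  bundles <- list(); per_protein <- list()
  for (f in seq_len(k)) {
    fr <- fold_roles(folds, f)
    roles <- stats::setNames(fr$role, fr$id)
    bundle <- train_site_predictor(cf, algorithm = algorithm, roles = roles,
                                   config = config, seed = seed + f)
    ev <- evaluate_site_predictor(bundle, cf, role = "test", config = config)
    bundles[[f]] <- bundle
    per_protein[[f]] <- dplyr::mutate(ev$per_protein, fold = f)
  }
  per_protein <- dplyr::bind_rows(per_protein)
  pooled <- benchmark_scores(tibble::tibble(
    tp = sum(per_protein$tp), tn = sum(per_protein$tn),
    fp = sum(per_protein$fp), fn = sum(per_protein$fn)))
  list(folds = folds, bundles = bundles, pooled = pooled,
       per_protein = per_protein)
}
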