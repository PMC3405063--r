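#' Subsample a training set with a negative:positive ratio
#'
#' Keeps every positive case and `round(ratio * n_pos)` negatives sampled
#' without replacement (all negatives when fewer exist). Reproducible for
#' a fixed seed.
#'
#' @param labels Logical vector (TRUE = positive).
#' @param ratio Negatives per positive (default 2).
#' @param seed Integer RNG seed.
#' @return Sorted integer indices of the selected cases.
#' @export
subsample_training_set <- function(labels, ratio = 2, seed = 1L) {
  pos <- which(labels)
  neg <- which(!labels)
  if (!length(pos)) rlang::abort("no positive cases to train on")
  n_neg <- min(length(neg), round(ratio * length(pos)))
  set.seed(seed)
  sort(c(pos, sample(neg, n_neg)))
}

#' MCC-optimal decision threshold from validation outputs
#'
#' Scans the midpoints of consecutive sorted unique outputs and returns
#' the threshold maximising the MCC of the rule `output >= threshold`;
#' ties break toward the lowest threshold.
#'
#' @param outputs Numeric classifier outputs in `[0, 1]`.
#' @param labels Logical labels.
#' @param quiet Suppress the single-class warning.
#' @return Threshold in `[0, 1]`.
#' @export
select_threshold <- function(outputs, labels, quiet = FALSE) {
  if (length(unique(labels)) < 2) {
    if (!quiet) rlang::warn("validation set has one class; threshold 0.5")
    return(0.5)
  }
  sc <- .mcc_scan(outputs, labels)
  sc$threshold[which.max(sc$mcc)]  # first (lowest) maximiser wins ties
}

#' Train one per-atom-type classifier
#'
#' Fits a single model mapping the 37 scaled attributes to a binding
#' probability in `[0, 1]`. `"ann"` is a 37-`hidden`-1 feed-forward
#' network trained by plain back-propagation (fixed learning rate and
#' momentum, mean-absolute-error convergence stop); `"svm"` is a radial
#' kernel support vector machine whose cost/gamma are grid-searched by
#' training MCC and whose outputs are class probabilities.
#'
#' @param x Numeric matrix of attributes (rows = cases).
#' @param y Logical labels (both classes required).
#' @param algorithm `"ann"` or `"svm"`.
#' @param config Training configuration, see [default_config()].
#' @param seed Integer RNG seed.
#' @return A `glyco_model` with a `predict()` method returning values in
#'   `[0, 1]`.
#' @export
train_model <- function(x, y, algorithm = c("ann", "svm"),
                        config = default_config(), seed = 1L) {
  algorithm <- match.arg(algorithm)
  if (length(unique(y)) < 2) rlang::abort("training data has a single class")
  tr <- config$training
  fit <- if (algorithm == "ann") {
    .train_backprop(x, as.numeric(y), hidden = tr$hidden_nodes,
                    lr = tr$learning_rate, momentum = tr$momentum,
                    max_iter = tr$max_iterations, tol = tr$mae_tol,
                    seed = seed)
  } else {
    .train_svm_grid(x, y, cost_grid = tr$svm_cost_grid,
                    gamma_grid = tr$svm_gamma_grid, seed = seed)
  }
  structure(list(algorithm = algorithm, fit = fit), class = "glyco_model")
}

.train_svm_grid <- function(x, y, cost_grid, gamma_grid, seed = 1L) {
  yf <- factor(ifelse(y, "pos", "neg"), levels = c("neg", "pos"))
  best <- c(NA, NA); best_mcc <- -Inf
  for (cost in cost_grid) {
    for (gamma in gamma_grid) {
      set.seed(seed)
      m <- e1071::svm(x, yf, kernel = "radial", cost = cost, gamma = gamma)
      pred <- stats::predict(m, x) == "pos"
      mcc <- .mcc_at(as.numeric(pred), y, 0.5)
      if (mcc > best_mcc) { best_mcc <- mcc; best <- c(cost, gamma) }
    }
  }
  set.seed(seed)
  e1071::svm(x, yf, kernel = "radial", cost = best[1], gamma = best[2],
             probability = TRUE)
}

.svm_prob <- function(m, x) {
  pr <- attr(stats::predict(m, x, probability = TRUE), "probabilities")
  as.vector(pr[, "pos"])
}

#' @export
predict.glyco_model <- function(object, newdata, ...) {
  if (object$algorithm == "ann") {
    .nn_forward(object$fit, newdata)
  } else {
    .svm_prob(object$fit, newdata)
  }
}

#' Train a bagged ensemble of resilient-propagation networks
#'
#' Trains `bags` networks, each on a bootstrap-style bag holding every
#' positive case plus `bag_neg_ratio` times as many randomly sampled
#' negatives. Each network trains for up to `max_iterations` Rprop
#' iterations; every `validation_every` iterations the validation MCC is
#' measured and the iteration with the best MCC supplies the weights.
#' The ensemble prediction is the unweighted mean of the bag outputs.
#'
#' @param x,y Training attributes and logical labels.
#' @param xval,yval Validation attributes and labels (iteration choice).
#' @param config Training configuration, see [default_config()].
#' @param seed Integer RNG seed; bag b uses `seed + b`.
#' @return A `glyco_bagged` model with a `predict()` method.
#' @export
train_bagged <- function(x, y, xval, yval, config = default_config(),
                         seed = 1L) {
  if (length(unique(y)) < 2) rlang::abort("training data has a single class")
  tr <- config$training
  pos <- which(y); neg <- which(!y)
  fits <- purrr::map(seq_len(tr$bags), function(b) {
    set.seed(seed + b)
    n_neg <- min(length(neg), round(tr$bag_neg_ratio * length(pos)))
    bag <- c(pos, sample(neg, n_neg))
    net <- .train_rprop(x[bag, , drop = FALSE], as.numeric(y[bag]),
                        xval, as.numeric(yval), hidden = tr$hidden_nodes,
                        max_iter = tr$max_iterations,
                        validate_every = tr$validation_every, seed = seed + b)
    list(net = net, bag = bag)
  })
  structure(list(algorithm = "ann_bagging",
                 nets = purrr::map(fits, "net"),
                 bags = purrr::map(fits, "bag")),
            class = c("glyco_bagged", "glyco_model"))
}

#' @export
predict.glyco_bagged <- function(object, newdata, ...) {
  outs <- vapply(object$nets, function(net) .nn_forward(net, newdata),
                 numeric(nrow(newdata)))
  rowMeans(matrix(outs, nrow = nrow(newdata)))
}

#' Assign proteins to 10-fold cross-validation splits
#'
#' Partitions proteins (never atoms, so no structural neighbours leak
#' between folds) into k groups; in fold f the f-th group is the test set,
#' the next group the validation set, and the remaining 80% the training
#' set.
#'
#' @param ids Character vector of protein ids.
#' @param k Number of folds (default 10).
#' @param seed Integer RNG seed for the shuffle.
#' @return A tibble with columns `id`, `group`, and list-columns are not
#'   used; combine with [fold_roles()] for per-fold role assignment.
#' @export
crossval_folds <- function(ids, k = 10L, seed = 1L) {
  ids <- unique(ids)
  if (length(ids) < k) {
    rlang::abort(sprintf("need at least %d proteins for %d-fold CV", k, k))
  }
  set.seed(seed)
  shuffled <- sample(ids)
  tibble::tibble(id = shuffled,
                 group = rep(seq_len(k), length.out = length(ids)))
}

#' Role of each protein in one cross-validation fold
#'
#' @param folds Output of [crossval_folds()].
#' @param fold Fold number (1..k).
#' @return The folds tibble with a `role` column:
#'   `"test"`, `"validation"` or `"train"`.
#' @export
fold_roles <- function(folds, fold) {
  k <- max(folds$group)
  val <- fold %% k + 1
  dplyr::mutate(folds, role = dplyr::case_when(
    .data$group == fold ~ "test",
    .data$group == val ~ "validation",
    TRUE ~ "train"))
}
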