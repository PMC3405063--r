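#' Aggregate per-atom PDM sums over surface neighbours
#'
#' The neighbour-aggregation step of the attribute encoding: for each
#' surface atom i, `A[i, j]` is the distance-weighted sum of the raw PDM
#' sums `S[k, j]` over all surface atoms k within `radius` of i (the atom
#' itself included at distance zero).
#'
#' @param S n x m matrix of per-atom sums (rows follow `coords`).
#' @param coords n x 3 matrix of the same atoms' coordinates.
#' @param radius Aggregation radius in Angstrom (default 5).
#' @param weight_fn Distance weight, default `function(d) 1 / (1 + d)`.
#' @return n x m matrix `A`.
#' @export
aggregate_neighbors <- function(S, coords, radius = 5, weight_fn = NULL) {
  if (is.null(weight_fn)) weight_fn <- function(d) 1 / (1 + d)
  d <- as.matrix(stats::dist(coords))
  W <- weight_fn(d)
  W[d > radius] <- 0
  diag(W) <- weight_fn(0)
  unname(W %*% S)
}

#' Median-based scaling bounds over a training corpus
#'
#' For each attribute j, collects every protein's maximum and minimum
#' `A[i, j]` and takes the median of each collection; these medians bound
#' the linear rescaling of the attributes to `[0, 1]`.
#'
#' @param A_list List of per-protein A matrices (n_i x m, same m).
#' @return A tibble (`glyco_bounds`) with columns `attribute`, `m_min`,
#'   `m_max`.
#' @export
scaling_bounds <- function(A_list) {
  stopifnot(length(A_list) >= 1)
  maxima <- vapply(A_list, function(A) apply(A, 2, max), numeric(ncol(A_list[[1]])))
  minima <- vapply(A_list, function(A) apply(A, 2, min), numeric(ncol(A_list[[1]])))
  maxima <- matrix(maxima, ncol = length(A_list))
  minima <- matrix(minima, ncol = length(A_list))
  out <- tibble::tibble(
    attribute = seq_len(nrow(maxima)),
    m_min = apply(minima, 1, stats::median),
    m_max = apply(maxima, 1, stats::median))
  # attributes with no spread anywhere (e.g. an interacting type absent
  # from the corpus) degenerate to a 0/1 step at the bound
  out$degenerate <- out$m_min >= out$m_max
  class(out) <- c("glyco_bounds", class(out))
  out
}

#' Scale an attribute to [0, 1]
#'
#' Clamp-and-interpolate scaling: values above `m_max` map to 1, values
#' below `m_min` map to 0, and values in between map linearly.
#'
#' @param A Numeric vector (or matrix) of raw attribute values.
#' @param m_min,m_max Scaling bounds (scalars, or vectors matching the
#'   columns of `A`).
#' @return Scaled values in `[0, 1]`, same shape as `A`.
#' @export
scale_attribute <- function(A, m_min, m_max) {
  if (any(m_min > m_max)) rlang::abort("m_min must not exceed m_max")
  denom <- m_max - m_min
  if (is.matrix(A)) {
    out <- sweep(sweep(A, 2, m_min, "-"), 2, denom, "/")
    for (j in which(denom == 0)) {
      out[, j] <- as.numeric(A[, j] > m_max[j])  # degenerate: 0/1 step
    }
  } else if (all(denom == 0)) {
    out <- as.numeric(A > m_max)
  } else {
    out <- (A - m_min) / denom
  }
  pmin(pmax(out, 0), 1)
}

#' Compute the 37 attributes for every surface atom of one structure
#'
#' Composes the full attribute encoding: raw PDM channel sums `S[i, j]`
#' (j = 1..36) around each surface atom, neighbour aggregation into
#' `A[i, j]`, the raw local-geometry term as attribute 37, and the
#' median-bound rescaling of all 37 attributes to `[0, 1]`. When `bounds`
#' is `NULL` the raw table is returned unscaled (used while deriving
#' corpus bounds).
#'
#' @param structure A `glyco_structure` with SASA computed.
#' @param pdm The structure's `glyco_pdm` (built with leave-query-out
#'   templates).
#' @param bounds A `glyco_bounds` table (37 rows) or `NULL`.
#' @param sum_radius,agg_radius Radii of the two summation steps (A).
#' @param sum_weight,agg_weight Optional weight functions.
#' @return A tibble (`glyco_features`) with one row per surface atom:
#'   identifier columns (`atom_idx`, `serial`, `chain`, `resi`, `icode`,
#'   `resn`, `atom`, `type_id`), raw columns `A1..A37`, and -- when bounds
#'   are given -- scaled columns `a1..a37` in `[0, 1]`.
#' @export
featurize <- function(structure, pdm, bounds = NULL,
                      sum_radius = 5, agg_radius = 5,
                      sum_weight = NULL, agg_weight = NULL) {
  surf <- surface_atoms(structure)
  a <- structure$atoms
  co <- structure_coords(structure, surf)
  S <- pdm_sums(pdm, co, radius = sum_radius, weight_fn = sum_weight)
  A <- aggregate_neighbors(S, co, radius = agg_radius, weight_fn = agg_weight)
  g37 <- geometry_attribute_raw(structure, idx = surf)
  A_full <- cbind(A, g37)
  colnames(A_full) <- paste0("A", 1:37)
  out <- tibble::tibble(
    atom_idx = surf,
    serial = a$serial[surf], chain = a$chain[surf], resi = a$resi[surf],
    icode = a$icode[surf], resn = a$resn[surf], atom = a$atom[surf],
    type_id = a$type_id[surf],
    x = a$x[surf], y = a$y[surf], z = a$z[surf])
  out <- dplyr::bind_cols(out, tibble::as_tibble(A_full))
  if (!is.null(bounds)) {
    stopifnot(nrow(bounds) == 37)
    sc <- scale_attribute(A_full, bounds$m_min, bounds$m_max)
    colnames(sc) <- paste0("a", 1:37)
    out <- dplyr::bind_cols(out, tibble::as_tibble(sc))
  }
  class(out) <- c("glyco_features", class(out))
  out
}

# Column helpers
.a_cols <- function() paste0("a", 1:37)
.A_cols <- function() paste0("A", 1:37)

feature_matrix <- function(features, scaled = TRUE) {
  cols <- if (scaled) .a_cols() else .A_cols()
  as.matrix(features[, cols])
}
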