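#' Cluster high-confidence surface atoms into binding patches
#'
#' Atoms with confidence above `seed_threshold` act as cluster seeds; each
#' seed collects surface atoms within `member_radius` whose confidence
#' exceeds `member_threshold`. Seed groups whose members are mutually
#' within `merge_radius` are merged into one patch; merging is applied
#' transitively (any two seeds within the merge radius share a patch), and
#' merged patches union their member sets.
#'
#' @param coords n x 3 matrix of surface-atom coordinates.
#' @param confidences Numeric confidence levels, one per row of `coords`.
#' @param seed_threshold Seed confidence cut (default 0.5, strict).
#' @param member_threshold Member confidence cut (default 0.1, strict).
#' @param member_radius Seed-to-member inclusion radius (default 5 A).
#' @param merge_radius Seed-to-seed merge radius (default 10 A).
#' @return A tibble (`glyco_patches`) with one row per patch: `patch`,
#'   list-columns `seeds` and `members` (row indices into `coords`), and
#'   centroid coordinates `cx`, `cy`, `cz`. Zero rows when no seed exists.
#' @export
cluster_patches <- function(coords, confidences, seed_threshold = 0.5,
                            member_threshold = 0.1, member_radius = 5,
                            merge_radius = 10) {
  stopifnot(nrow(coords) == length(confidences))
  seeds <- which(confidences > seed_threshold)
  empty <- tibble::tibble(patch = integer(0), seeds = list(),
                          members = list(), cx = numeric(0),
                          cy = numeric(0), cz = numeric(0))
  class(empty) <- c("glyco_patches", class(empty))
  if (!length(seeds)) return(empty)
  eligible <- which(confidences > member_threshold)
  # transitive merge: connected components of the merge-radius seed graph
  comp <- .distance_components(coords[seeds, , drop = FALSE], merge_radius)
  rows <- purrr::imap(split(seeds, comp), function(sd, key) {
    mem <- unique(unlist(lapply(sd, function(s) {
      d2 <- (coords[eligible, 1] - coords[s, 1])^2 +
        (coords[eligible, 2] - coords[s, 2])^2 +
        (coords[eligible, 3] - coords[s, 3])^2
      eligible[d2 <= member_radius^2]
    })))
    mem <- sort(union(mem, sd))
    ctr <- colMeans(coords[mem, , drop = FALSE])
    tibble::tibble(seeds = list(sort(sd)), members = list(mem),
                   cx = ctr[1], cy = ctr[2], cz = ctr[3])
  })
  out <- dplyr::bind_rows(rows)
  out <- dplyr::bind_cols(tibble::tibble(patch = seq_len(nrow(out))), out)
  class(out) <- c("glyco_patches", class(out))
  out
}

# Union-find over points with an edge when distance <= radius.
.distance_components <- function(co, radius) {
  n <- nrow(co)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1) {
    d <- as.matrix(stats::dist(co))
    for (i in seq_len(n - 1)) {
      for (j in seq((i + 1), n)) {
        if (d[i, j] <= radius) {
          a <- find(i); b <- find(j)
          if (a != b) parent[a] <- b
        }
      }
    }
  }
  vapply(seq_len(n), find, integer(1))
}

#' Convert an atom patch to predicted binding residues
#'
#' A residue is predicted to bind when strictly more than `min_fraction`
#' of its surface atoms (SASA > 0) belong to the atom patch.
#'
#' @param member_idx Atom indices (into the structure) of the patch.
#' @param structure A `glyco_structure` with SASA computed.
#' @param min_fraction Surface-atom fraction cut (default 0.3, strict).
#' @return Character vector of residue keys (`chain resi icode resn`).
#' @export
residues_from_patch <- function(member_idx, structure, min_fraction = 0.3) {
  a <- structure$atoms
  surf <- surface_atoms(structure)
  key <- paste(a$chain, a$resi, a$icode, a$resn)
  n_surf <- table(key[surf])
  in_patch <- intersect(member_idx, surf)
  if (!length(in_patch)) return(character(0))
  n_in <- table(key[in_patch])
  frac <- as.numeric(n_in) / as.numeric(n_surf[names(n_in)])
  sort(names(n_in)[frac > min_fraction])
}

#' Actual carbohydrate-binding residues of a complex
#'
#' Ground truth under the same residue rule as the predictions: a residue
#' binds when more than `min_fraction` of its surface atoms -- SASA
#' computed on the protein with the ligand removed -- lie within `cutoff`
#' of any carbohydrate ligand atom.
#'
#' @param structure A `glyco_structure` holding the complex.
#' @param cutoff Contact distance (default 5 A).
#' @param min_fraction Surface-atom fraction cut (default 0.3, strict).
#' @param probe_radius,n_points Passed to [compute_sasa()] for the apo
#'   surface.
#' @return Character vector of residue keys (`chain resi icode resn`).
#' @export
actual_binding_residues <- function(structure, cutoff = 5,
                                    min_fraction = 0.3, probe_radius = 1.4,
                                    n_points = 1920L) {
  lig <- which(structure$atoms$is_carb)
  if (!length(lig)) return(character(0))
  co_l <- structure_coords(structure, lig)
  apo <- compute_sasa(strip_ligands(structure), probe_radius = probe_radius,
                      n_points = n_points)
  surf <- surface_atoms(apo)
  if (!length(surf)) return(character(0))
  dmin <- .min_dist_to_set(structure_coords(apo, surf), co_l)
  contact_idx <- surf[dmin <= cutoff]
  a <- apo$atoms
  key <- paste(a$chain, a$resi, a$icode, a$resn)
  n_surf <- table(key[surf])
  if (!length(contact_idx)) return(character(0))
  n_in <- table(key[contact_idx])
  frac <- as.numeric(n_in) / as.numeric(n_surf[names(n_in)])
  sort(names(n_in)[frac > min_fraction])
}

#' Residue keys with at least one surface atom
#'
#' The residue-level evaluation universe of a structure (apo surface by
#' default, matching [actual_binding_residues()]).
#'
#' @param structure A `glyco_structure`.
#' @param apo Strip ligands and recompute SASA first (default TRUE).
#' @param probe_radius,n_points Passed to [compute_sasa()].
#' @return Character vector of residue keys.
#' @export
surface_residues <- function(structure, apo = TRUE, probe_radius = 1.4,
                             n_points = 1920L) {
  s <- if (apo) {
    compute_sasa(strip_ligands(structure), probe_radius = probe_radius,
                 n_points = n_points)
  } else structure
  a <- s$atoms
  surf <- surface_atoms(s)
  sort(unique(paste(a$chain, a$resi, a$icode, a$resn)[surf]))
}
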