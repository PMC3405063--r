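# Deterministic quasi-uniform points on the unit sphere (golden-spiral).
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# Antipodally symmetrised point set used for SASA: pairing each direction
# with its mirror halves the directional bias, keeping per-atom SASA
# rotation-invariant to < 1% at the default density.
.sasa_points <- function(n) {
  half <- .sphere_points(max(1L, n %/% 2L))
  rbind(half, -half)
}

#' Per-atom solvent accessible surface area (Shrake-Rupley)
#'
#' Sphere-sampling SASA with the package's type radii: each atom's
#' solvent-accessible sphere (vdW radius + probe) is sampled with a fixed
#' deterministic point set; points falling inside any neighbouring atom's
#' accessible sphere are buried. All atoms in the structure occlude,
#' including ligands and water, so computing the apo surface requires
#' [strip_ligands()] first.
#'
#' @param structure A `glyco_structure`.
#' @param probe_radius Solvent probe radius in Angstrom (default 1.4).
#' @param n_points Sample points per atom (default 1920, antipodally
#'   paired).
#' @return The structure with the `sasa` column of the atom table filled
#'   (square Angstrom).
#' @export
compute_sasa <- function(structure, probe_radius = 1.4, n_points = 1920L) {
  a <- structure$atoms
  n <- nrow(a)
  if (!n) rlang::abort("structure has no atoms")
  co <- structure_coords(structure)
  rad <- a$vdw + probe_radius
  pts <- .sasa_points(n_points)
  n_points <- nrow(pts)
  d <- as.matrix(stats::dist(co))
  sasa <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(d[i, ] < rad[i] + rad & seq_len(n) != i)
    if (!length(nb)) {
      sasa[i] <- 4 * pi * rad[i]^2
      next
    }
    p <- pts * rad[i]
    p <- sweep(p, 2, co[i, ], "+")
    # point buried if within any neighbour's accessible sphere
    buried <- rep(FALSE, n_points)
    for (j in nb) {
      if (all(buried)) break
      dj <- (p[, 1] - co[j, 1])^2 + (p[, 2] - co[j, 2])^2 +
        (p[, 3] - co[j, 3])^2
      buried <- buried | dj < rad[j]^2
    }
    sasa[i] <- 4 * pi * rad[i]^2 * sum(!buried) / n_points
  }
  structure$atoms$sasa <- sasa
  structure
}

#' Apo-surface SASA: ligand-independent solvent accessibility
#'
#' Computes per-atom SASA on the protein alone (ligands, water and
#' aglycone stripped) and writes the values back onto the full structure;
#' non-protein atoms get SASA 0. This is the surface definition used for
#' featurization and labelling: the binding-site atoms must count as
#' surface even when a co-crystallised ligand occludes them, exactly as
#' when predicting an unbound structure.
#'
#' @inheritParams compute_sasa
#' @return The structure with the `sasa` column filled.
#' @export
compute_sasa_apo <- function(structure, probe_radius = 1.4,
                             n_points = 1920L) {
  apo <- compute_sasa(strip_ligands(structure), probe_radius = probe_radius,
                      n_points = n_points)
  idx <- match(apo$atoms$serial, structure$atoms$serial)
  structure$atoms$sasa <- 0
  structure$atoms$sasa[idx] <- apo$atoms$sasa
  structure
}

# Integer-offset voxel ball of radius r (spacing 1 A): K x 3 matrix.
.ball_offsets <- function(r) {
  s <- seq(-floor(r), floor(r))
  g <- as.matrix(expand.grid(x = s, y = s, z = s))
  g[rowSums(g^2) <= r^2, , drop = FALSE]
}

#' Local-geometry attribute: unoccupied-volume fraction
#'
#' For each requested atom, the fraction of a 10-A sphere centred on the
#' atom that is not occupied by the van der Waals volume of the protein.
#' Concave pockets score low, convex or flat surface patches score high.
#' Occupancy is evaluated on a fixed 1-A voxel grid so the value is
#' deterministic.
#'
#' @param structure A `glyco_structure`.
#' @param idx Atom indices to evaluate (default: all protein surface atoms).
#' @param radius Sphere radius in Angstrom (default 10).
#' @param spacing Occupancy voxel size in Angstrom (default 0.5).
#' @return Numeric vector in `[0, 1]`, one value per index.
#' @export
geometry_attribute_raw <- function(structure, idx = NULL, radius = 10,
                                   spacing = 0.5) {
  a <- structure$atoms
  if (is.null(idx)) idx <- surface_atoms(structure)
  prot <- which(a$is_protein)
  co <- structure_coords(structure, prot)
  vdw <- a$vdw[prot]

  # occupancy on a fixed voxel grid covering the protein plus the reach
  lo <- floor((apply(co, 2, min) - max(vdw) - spacing) / spacing) * spacing
  hi <- ceiling((apply(co, 2, max) + max(vdw) + spacing) / spacing) * spacing
  dim3 <- as.integer(round((hi - lo) / spacing)) + 1L
  occ <- array(FALSE, dim3)
  for (k in seq_along(prot)) {
    ctr_vox <- (co[k, ] - lo) / spacing       # 0-based continuous
    ctr <- round(ctr_vox) + 1
    vox <- sweep(.ball_offsets(vdw[k] / spacing + 0.87), 2, ctr, "+")
    d2 <- (vox[, 1] - 1 - ctr_vox[1])^2 + (vox[, 2] - 1 - ctr_vox[2])^2 +
      (vox[, 3] - 1 - ctr_vox[3])^2
    vox <- vox[d2 * spacing^2 <= vdw[k]^2, , drop = FALSE]
    keep <- vox[, 1] >= 1 & vox[, 1] <= dim3[1] &
      vox[, 2] >= 1 & vox[, 2] <= dim3[2] &
      vox[, 3] >= 1 & vox[, 3] <= dim3[3]
    vox <- vox[keep, , drop = FALSE]
    if (nrow(vox)) occ[vox] <- TRUE
  }

  ball <- .ball_offsets(radius / spacing)
  n_ball <- nrow(ball)
  out <- numeric(length(idx))
  for (q in seq_along(idx)) {
    ctr <- round((c(a$x[idx[q]], a$y[idx[q]], a$z[idx[q]]) - lo) / spacing) + 1
    vox <- sweep(ball, 2, ctr, "+")
    keep <- vox[, 1] >= 1 & vox[, 1] <= dim3[1] &
      vox[, 2] >= 1 & vox[, 2] <= dim3[2] &
      vox[, 3] >= 1 & vox[, 3] <= dim3[3]
    n_occ <- if (any(keep)) sum(occ[vox[keep, , drop = FALSE]]) else 0L
    out[q] <- 1 - n_occ / n_ball
  }
  out
}
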