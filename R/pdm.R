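#' Project density templates onto a query protein surface
#'
#' Produces the query's 36-channel probability density map (PDM): for each
#' protein surface atom, the density templates of its atom type are placed
#' rigidly into world space through the atom's local frame and accumulated
#' onto a common cubic grid (trilinear splatting), one channel per
#' interacting atom type. Channels are only defined inside the surface
#' shell mask (within `mask_radius` of some surface atom); values outside
#' are zero. Self-information is removed upstream by building the
#' templates with `exclude_sources = query id` (see [build_templates()]).
#'
#' @param query A `glyco_structure` with SASA computed.
#' @param templates A `glyco_templates` set.
#' @param spacing Global grid spacing in Angstrom; must equal the template
#'   spacing (default 1).
#' @param mask_radius Surface-shell radius in Angstrom (default 5).
#' @return A `glyco_pdm`: list with `g` (4-D array, x/y/z/channel),
#'   `origin`, `spacing`, `dim`, `mask` (3-D logical array).
#' @export
project_pdm <- function(query, templates, spacing = 1, mask_radius = 5) {
  if (abs(templates$spacing - spacing) > 1e-9) {
    rlang::abort("template spacing does not match requested grid spacing")
  }
  a <- query$atoms
  surf <- surface_atoms(query)
  co_surf <- structure_coords(query, surf)
  half <- max(abs(.template_axis(templates$spacing)))
  margin <- half * sqrt(3) + spacing
  lo <- floor((apply(co_surf, 2, min) - margin) / spacing) * spacing
  hi <- ceiling((apply(co_surf, 2, max) + margin) / spacing) * spacing
  dim3 <- as.integer(round((hi - lo) / spacing)) + 1L
  g <- array(0, c(dim3, 36L))
  nxyz <- prod(dim3)

  ax <- .template_axis(templates$spacing)
  vox <- as.matrix(expand.grid(x = ax, y = ax, z = ax))

  # per-center-type template stacks, built once
  stacks <- list()
  for (ct in unique(a$type_id[surf])) {
    keys <- paste0(ct, "_", 1:36)
    have <- keys %in% names(templates$templates)
    if (!any(have)) next
    ch <- which(have)
    V <- vapply(keys[ch],
                function(k) as.vector(templates$templates[[k]]$grid),
                numeric(nrow(vox)))
    V <- matrix(V, nrow = nrow(vox))
    nz <- which(rowSums(V) > 0)
    if (!length(nz)) next
    stacks[[as.character(ct)]] <-
      list(ch = ch, nz = nz,
           Vnz = V[nz, , drop = FALSE] * templates$spacing^3 / spacing^3)
  }

  for (i in surf) {
    stk <- stacks[[as.character(a$type_id[i])]]
    if (is.null(stk)) next
    ch <- stk$ch; nz <- stk$nz
    fr <- local_frame(query, i)
    world <- vox[nz, , drop = FALSE] %*% t(fr)
    world <- sweep(world, 2, c(a$x[i], a$y[i], a$z[i]), "+")
    t3 <- sweep(world, 2, lo, "-") / spacing  # 0-based continuous index
    i0 <- floor(t3)
    f <- t3 - i0
    Vnz <- stk$Vnz
    nzr <- nrow(Vnz)
    lin8 <- integer(0); w8 <- numeric(0); row8 <- integer(0)
    for (corner in 0:7) {
      cx <- corner %% 2; cy <- (corner %/% 2) %% 2; cz <- corner %/% 4
      ix <- i0[, 1] + cx; iy <- i0[, 2] + cy; iz <- i0[, 3] + cz
      w <- (if (cx == 1) f[, 1] else 1 - f[, 1]) *
        (if (cy == 1) f[, 2] else 1 - f[, 2]) *
        (if (cz == 1) f[, 3] else 1 - f[, 3])
      ok <- ix >= 0 & ix < dim3[1] & iy >= 0 & iy < dim3[2] &
        iz >= 0 & iz < dim3[3] & w > 0
      if (!any(ok)) next
      lin8 <- c(lin8, 1L + ix[ok] + iy[ok] * dim3[1] +
                  iz[ok] * dim3[1] * dim3[2])
      w8 <- c(w8, w[ok])
      row8 <- c(row8, which(ok))
    }
    if (!length(lin8)) next
    add <- rowsum(Vnz[row8, , drop = FALSE] * w8, lin8)
    tgt <- as.integer(rownames(add))
    for (c2 in seq_along(ch)) {
      off <- (ch[c2] - 1L) * nxyz
      g[tgt + off] <- g[tgt + off] + add[, c2]
    }
  }

  mask <- .shell_mask(dim3, lo, spacing, co_surf, mask_radius)
  g <- g * as.vector(mask)  # channels defined only inside the shell
  structure(list(g = g, origin = lo, spacing = spacing, dim = dim3,
                 mask = mask),
            class = "glyco_pdm")
}

.shell_mask <- function(dim3, lo, spacing, coords, radius) {
  mask <- array(FALSE, dim3)
  off <- .ball_offsets(radius / spacing + 1)
  for (k in seq_len(nrow(coords))) {
    ctr_cont <- (coords[k, ] - lo) / spacing  # 0-based
    ctr <- round(ctr_cont)
    vox <- sweep(off, 2, ctr, "+")
    d2 <- (vox[, 1] - ctr_cont[1])^2 + (vox[, 2] - ctr_cont[2])^2 +
      (vox[, 3] - ctr_cont[3])^2
    vox <- vox[d2 * spacing^2 <= radius^2, , drop = FALSE]
    ok <- vox[, 1] >= 0 & vox[, 1] < dim3[1] & vox[, 2] >= 0 &
      vox[, 2] < dim3[2] & vox[, 3] >= 0 & vox[, 3] < dim3[3]
    vox <- vox[ok, , drop = FALSE] + 1L
    if (nrow(vox)) mask[vox] <- TRUE
  }
  mask
}

#' Total PDM grid mass
#' @param pdm A `glyco_pdm`.
#' @return Sum over all channels of value x voxel volume.
#' @export
pdm_mass <- function(pdm) sum(pdm$g) * pdm$spacing^3

#' PDM sum of one channel around one point
#'
#' The distance-weighted sum of PDM channel values over the grid points
#' within `radius` of `point` (the S term of the attribute encoding).
#'
#' @param pdm A `glyco_pdm`.
#' @param point Numeric length-3 world coordinate.
#' @param channel Interacting atom type 1--36.
#' @param radius Summation radius, Angstrom (default 5).
#' @param weight_fn Distance weight, default `function(r) 1 - r / radius`.
#' @return Numeric scalar.
#' @export
pdm_sum <- function(pdm, point, channel, radius = 5, weight_fn = NULL) {
  S <- pdm_sums(pdm, matrix(point, nrow = 1), radius = radius,
                weight_fn = weight_fn)
  S[1, channel]
}

#' PDM sums for many points, all 36 channels
#'
#' @param pdm A `glyco_pdm`.
#' @param coords n x 3 matrix of world coordinates.
#' @inheritParams pdm_sum
#' @return n x 36 numeric matrix of channel sums.
#' @export
pdm_sums <- function(pdm, coords, radius = 5, weight_fn = NULL) {
  if (is.null(weight_fn)) weight_fn <- function(r) 1 - r / radius
  dim3 <- pdm$dim
  nxyz <- prod(dim3)
  gm <- matrix(pdm$g, nrow = nxyz, ncol = 36)
  off <- .ball_offsets(radius / pdm$spacing + 1)
  out <- matrix(0, nrow(coords), 36)
  for (q in seq_len(nrow(coords))) {
    ctr_cont <- (coords[q, ] - pdm$origin) / pdm$spacing
    ctr <- round(ctr_cont)
    vox <- sweep(off, 2, ctr, "+")
    r <- sqrt((vox[, 1] - ctr_cont[1])^2 + (vox[, 2] - ctr_cont[2])^2 +
                (vox[, 3] - ctr_cont[3])^2) * pdm$spacing
    keep <- r <= radius & vox[, 1] >= 0 & vox[, 1] < dim3[1] &
      vox[, 2] >= 0 & vox[, 2] < dim3[2] & vox[, 3] >= 0 & vox[, 3] < dim3[3]
    if (!any(keep)) next
    vox <- vox[keep, , drop = FALSE]
    lin <- 1L + vox[, 1] + vox[, 2] * dim3[1] + vox[, 3] * dim3[1] * dim3[2]
    out[q, ] <- as.vector(weight_fn(r[keep]) %*% gm[lin, , drop = FALSE])
  }
  out
}

#' Write one PDM channel as an OpenDX-style text volume
#'
#' @param pdm A `glyco_pdm`.
#' @param channel Channel 1--36.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_pdm_dx <- function(pdm, channel, path) {
  d <- pdm$dim
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %g %g %g", pdm$origin[1], pdm$origin[2], pdm$origin[3]),
    sprintf("delta %g 0 0", pdm$spacing),
    sprintf("delta 0 %g 0", pdm$spacing),
    sprintf("delta 0 0 %g", pdm$spacing),
    sprintf("object 2 class gridconnections counts %d %d %d", d[1], d[2], d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            prod(d))), con)
  vals <- as.vector(aperm(array(pdm$g[, , , channel], d), c(3, 2, 1)))
  writeLines(paste(formatC(vals, format = "g"), collapse = " "), con)
  writeLines("attribute \"dep\" string \"positions\"", con)
  invisible(path)
}
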