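#' Default contact-type filter
#'
#' A 36 x 36 admissibility score matrix over atom-type pairs with a
#' threshold: a pair is admitted to the interacting-atom database when its
#' score is strictly below the threshold (default -0.1). The default
#' matrix encodes the chemical principle that aliphatic/apolar carbons do
#' not interact with polar oxygen, nitrogen or water: those pairs score 0
#' (rejected); every other combination -- carbon with carbon, polar with
#' polar, polar with aromatic, sulfur with anything -- scores -1
#' (admitted). The matrix and threshold are plain data and can be replaced
#' wholesale for a different parameterisation.
#'
#' @param threshold Admission threshold (default -0.1).
#' @return An object of class `glyco_filter` with elements `matrix`
#'   (36 x 36, symmetric) and `threshold`.
#' @export
default_contact_filter <- function(threshold = -0.1) {
  # aliphatic carbons (sp3, incl. sugar ring/side carbons); aromatic
  # carbons and sulfur remain admissible with polar partners
  apolar_c <- c(6, 7, 8, 13, 14, 34, 35)
  polar_on <- c(1, 4, 10, 11, 12, 15, 16, 17, 26, 29, 31, 32, 33, 36)
  m <- matrix(-1, 36, 36)
  m[apolar_c, polar_on] <- 0
  m[polar_on, apolar_c] <- 0
  codes <- atom_type_table()$code
  dimnames(m) <- list(codes, codes)
  structure(list(matrix = m, threshold = threshold), class = "glyco_filter")
}

#' Does an atom-type pair pass the contact filter?
#' @param filter A `glyco_filter`.
#' @param center_type,partner_type Integer type ids.
#' @return Logical vector.
#' @export
filter_admits <- function(filter, center_type, partner_type) {
  filter$matrix[cbind(center_type, partner_type)] < filter$threshold
}

#' Local orthonormal frame of an atom
#'
#' Builds a right-handed orthonormal frame from an atom and its covalent
#' environment: the first axis points to the first bonded neighbour; the
#' third axis is the normal of the plane spanned with a second reference
#' atom (another bonded neighbour, or a neighbour of the first neighbour
#' when the atom is terminal). The frame is equivariant under rigid motion
#' of the structure. When no non-collinear reference exists a fixed
#' fallback axis is used (deterministic, but then only
#' rotation-equivariant up to the fallback).
#'
#' @param structure A `glyco_structure`.
#' @param i Atom index.
#' @return 3 x 3 matrix with the frame axes as columns (determinant +1).
#' @export
local_frame <- function(structure, i) {
  co <- structure_coords(structure)
  nb <- .bonded_neighbours(structure$bonds, i)
  if (!length(nb)) {
    # bond-orphaned atom (e.g. a slightly stretched terminal bond):
    # fall back to the nearest atom within covalent-plus-slack range
    d2 <- (co[, 1] - co[i, 1])^2 + (co[, 2] - co[i, 2])^2 +
      (co[, 3] - co[i, 3])^2
    d2[i] <- Inf
    if (min(d2) > 2.5^2) {
      rlang::abort(sprintf("atom %d has no covalent neighbour", i))
    }
    nb <- which.min(d2)
  }
  nb <- sort(nb)
  e1 <- co[nb[1], ] - co[i, ]
  e1 <- e1 / sqrt(sum(e1^2))
  ref <- NULL
  cands <- c(setdiff(nb, nb[1]), sort(setdiff(.bonded_neighbours(structure$bonds, nb[1]), i)))
  for (c2 in cands) {
    v <- co[c2, ] - co[i, ]
    cr <- .cross3(e1, v)
    if (sqrt(sum(cr^2)) > 1e-6 * sqrt(sum(v^2))) { ref <- cr; break }
  }
  if (is.null(ref)) {
    # no usable covalent reference: try the nearest other atom (keeps the
    # frame equivariant), then a fixed axis as the last resort
    d2 <- (co[, 1] - co[i, 1])^2 + (co[, 2] - co[i, 2])^2 +
      (co[, 3] - co[i, 3])^2
    d2[c(i, nb)] <- Inf
    for (c2 in order(d2)[1:min(3, length(d2))]) {
      if (!is.finite(d2[c2]) || d2[c2] > 36) break
      v <- co[c2, ] - co[i, ]
      cr <- .cross3(e1, v)
      if (sqrt(sum(cr^2)) > 1e-6 * sqrt(sum(v^2))) { ref <- cr; break }
    }
  }
  if (is.null(ref)) {
    ax <- diag(3)[, which.min(abs(e1)), drop = TRUE]
    ref <- .cross3(e1, ax)
  }
  e3 <- ref / sqrt(sum(ref^2))
  e2 <- .cross3(e3, e1)
  cbind(e1, e2, e3, deparse.level = 0)
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

.bonded_neighbours <- function(bonds, i) {
  c(bonds[bonds[, 1] == i, 2], bonds[bonds[, 2] == i, 1])
}

# 1-2 and 1-3 covalent exclusion sets per atom, as a list of index vectors.
.covalent_12_13 <- function(bonds, n) {
  adj <- vector("list", n)
  if (nrow(bonds)) {
    for (k in seq_len(nrow(bonds))) {
      i <- bonds[k, 1]; j <- bonds[k, 2]
      adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
    }
  }
  lapply(seq_len(n), function(i) {
    one <- adj[[i]]
    two <- unique(unlist(adj[one], use.names = FALSE))
    setdiff(unique(c(one, two)), i)
  })
}

#' Extract non-covalent interacting atom pairs from a corpus
#'
#' For every protein surface atom (the "center") in every structure, every
#' typed partner atom within `cutoff` whose type pair passes the contact
#' filter yields one pair, recorded as the partner displacement expressed
#' in the center atom's local frame. Partners in the same residue, or
#' covalently bonded to the center within two bonds (1-2/1-3), are
#' excluded as covalent rather than interacting neighbours.
#'
#' @param corpus A list of `glyco_structure`s with SASA computed.
#' @param filter A `glyco_filter` (default [default_contact_filter()]).
#' @param cutoff Contact cutoff in Angstrom (default 5).
#' @return A tibble (`glyco_pairs`) with columns `center_type`,
#'   `partner_type`, `dx`, `dy`, `dz` (local-frame Angstrom) and `source`
#'   (structure id).
#' @export
extract_pairs <- function(corpus, filter = default_contact_filter(),
                          cutoff = 5) {
  if (inherits(corpus, "glyco_structure")) corpus <- list(corpus)
  out <- purrr::map(corpus, function(s) {
    a <- s$atoms
    n <- nrow(a)
    surf <- surface_atoms(s)
    partners_all <- which(!is.na(a$type_id) & !a$is_aglycone)
    if (!length(surf) || !length(partners_all)) return(NULL)
    excl <- .covalent_12_13(s$bonds, n)
    co <- structure_coords(s)
    reskey <- paste(a$chain, a$resi, a$icode)
    rows <- vector("list", length(surf))
    for (q in seq_along(surf)) {
      i <- surf[q]
      d2 <- (co[partners_all, 1] - co[i, 1])^2 +
        (co[partners_all, 2] - co[i, 2])^2 +
        (co[partners_all, 3] - co[i, 3])^2
      cand <- partners_all[d2 <= cutoff^2]
      cand <- cand[cand != i &
                     reskey[cand] != reskey[i] &
                     !(cand %in% excl[[i]])]
      if (!length(cand)) next
      ok <- filter_admits(filter, a$type_id[i], a$type_id[cand])
      cand <- cand[ok]
      if (!length(cand)) next
      fr <- local_frame(s, i)
      disp <- sweep(co[cand, , drop = FALSE], 2, co[i, ], "-") %*% fr
      rows[[q]] <- tibble::tibble(
        center_type = a$type_id[i],
        partner_type = a$type_id[cand],
        dx = disp[, 1], dy = disp[, 2], dz = disp[, 3],
        source = s$id)
    }
    dplyr::bind_rows(rows)
  })
  res <- dplyr::bind_rows(out)
  if (!nrow(res)) {
    res <- tibble::tibble(center_type = integer(0), partner_type = integer(0),
                          dx = numeric(0), dy = numeric(0), dz = numeric(0),
                          source = character(0))
  }
  class(res) <- c("glyco_pairs", class(res))
  res
}

# --- density templates ------------------------------------------------------

.template_axis <- function(spacing = 1, half = 5) {
  seq(-half, half, by = spacing)
}

# separable 1-D Gaussian kernel, truncated at 4 sigma, renormalised
.gauss_kernel <- function(sigma, spacing) {
  if (sigma <= 0) return(1)
  m <- max(1L, ceiling(4 * sigma / spacing))
  k <- exp(-(seq(-m, m) * spacing)^2 / (2 * sigma^2))
  k / sum(k)
}

.smooth3d <- function(arr, kernel) {
  if (length(kernel) == 1) return(arr)
  d <- dim(arr)
  m <- (length(kernel) - 1L) / 2L
  conv1 <- function(v) {
    out <- numeric(length(v))
    for (t in seq_along(kernel)) {
      s <- t - m - 1L
      src <- seq_along(v) - s
      ok <- src >= 1 & src <= length(v)
      out[ok] <- out[ok] + kernel[t] * v[src[ok]]
    }
    out
  }
  for (pass in 1:3) {
    arr <- apply(arr, c(2, 3), conv1)  # convolve along dim 1
    arr <- aperm(arr, c(2, 3, 1))      # rotate axes; identity after 3 passes
  }
  arr
}

#' Build one local-frame density template
#'
#' Histograms the local-frame displacements of the pairs of a single
#' (center type, partner type) combination on a cubic grid over
#' `[-5, 5]^3`, Gaussian-smooths it, and divides by the pair count so that
#' templates from different sample sizes are comparable. The recorded
#' `total_mass` equals `sum(grid) * spacing^3`.
#'
#' @param pairs A `glyco_pairs` tibble (already restricted to one type
#'   combination; extra columns are ignored).
#' @param spacing Grid spacing in Angstrom (default 1).
#' @param sigma Gaussian smoothing width in Angstrom (default 1).
#' @return A `glyco_template`: list with `grid` (3-D array), `axis`,
#'   `spacing`, `n_pairs`, `total_mass`, `empty`.
#' @export
build_density_template <- function(pairs, spacing = 1, sigma = 1) {
  ax <- .template_axis(spacing)
  nd <- length(ax)
  grid <- array(0, c(nd, nd, nd))
  n <- nrow(pairs)
  if (n > 0) {
    ix <- findInterval(pairs$dx, ax - spacing / 2, all.inside = TRUE)
    iy <- findInterval(pairs$dy, ax - spacing / 2, all.inside = TRUE)
    iz <- findInterval(pairs$dz, ax - spacing / 2, all.inside = TRUE)
    idx <- (iz - 1L) * nd * nd + (iy - 1L) * nd + ix
    counts <- tabulate(idx, nbins = nd^3)
    grid <- array(counts, c(nd, nd, nd))
    grid <- .smooth3d(grid, .gauss_kernel(sigma, spacing)) / n
  }
  structure(list(grid = grid, axis = ax, spacing = spacing,
                 n_pairs = n, total_mass = sum(grid) * spacing^3,
                 empty = n == 0),
            class = "glyco_template")
}

#' Build the full template set from a pair database
#'
#' One [build_density_template()] per (center type, partner type)
#' combination present in the pair table, optionally excluding pairs from
#' the listed source structures (leave-query-out).
#'
#' @param pairs A `glyco_pairs` tibble.
#' @param spacing,sigma Passed to [build_density_template()].
#' @param exclude_sources Character vector of source ids to drop.
#' @return A `glyco_templates` object: named list of templates keyed
#'   `"<center>_<partner>"` plus `spacing` and `sigma` attributes.
#' @export
build_templates <- function(pairs, spacing = 1, sigma = 1,
                            exclude_sources = NULL) {
  if (!is.null(exclude_sources)) {
    pairs <- pairs[!(pairs$source %in% exclude_sources), ]
  }
  keys <- paste(pairs$center_type, pairs$partner_type, sep = "_")
  groups <- split(seq_len(nrow(pairs)), keys)
  tpl <- purrr::map(groups, function(ii) {
    build_density_template(pairs[ii, ], spacing = spacing, sigma = sigma)
  })
  structure(list(templates = tpl, spacing = spacing, sigma = sigma),
            class = "glyco_templates")
}

#' @export
print.glyco_templates <- function(x, ...) {
  cat(sprintf("<glyco_templates> %d (center, partner) combinations, spacing %g A, sigma %g A\n",
              length(x$templates), x$spacing, x$sigma))
  invisible(x)
}
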