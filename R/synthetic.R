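# Deterministic generators for toy protein-carbohydrate complexes and
# pair-database fixtures. The pseudo-proteins reuse real residue and atom
# names so the chemical atom typing applies unchanged; geometry aims for
# sane interatomic distances and ring topology, not chemical realism.

# --- residue templates ------------------------------------------------------
# Local coordinates: CA at the origin, side chain budding along +x, all
# bond lengths within covalent-inference range.

.res_templates <- local({
  bb <- rbind(N = c(0, 1.37, 0.50), CA = c(0, 0, 0),
              C = c(0, -0.70, -1.34), O = c(0, -1.93, -1.41))
  w <- c(0.867, 0, 0.499)   # side-chain continuation direction
  p <- c(-0.499, 0, 0.867)  # in-plane perpendicular
  CB <- c(1.53, 0, 0)
  hex_from_edge <- function(v_from, v_to, centre_hint) {
    # four new vertices completing a hexagon on edge v_from -> v_to,
    # fused away from centre_hint
    mid <- (v_from + v_to) / 2
    e <- sqrt(sum((v_to - v_from)^2))
    h <- mid - centre_hint; h <- h / sqrt(sum(h^2))
    M <- mid + e * cos(pi / 6) * h
    b1 <- (v_from - M) / sqrt(sum((v_from - M)^2))
    nrm <- c(b1[2] * h[3] - b1[3] * h[2], b1[3] * h[1] - b1[1] * h[3],
             b1[1] * h[2] - b1[2] * h[1])
    b2 <- nrm / sqrt(sum(nrm^2))
    proj <- function(v) { d <- v - M; c(sum(d * b1), sum(d * b2)) }
    a0 <- 0
    q1 <- proj(v_to); a1 <- atan2(q1[2], q1[1])
    sweep <- a1 - sign(a1) * 2 * pi  # the long way round
    R <- sqrt(sum((v_from - M)^2))
    t(vapply(1:4, function(m) {
      th <- a0 + m * sweep / 5
      M + R * (cos(th) * b1 + sin(th) * b2)
    }, numeric(3)))
  }
  ring6 <- function(base, w, p, edge = 1.39) {
    M <- base + edge * w
    t(vapply(0:5, function(k) {
      th <- k * pi / 3
      M + edge * (cos(th) * (-w) + sin(th) * p)
    }, numeric(3)))  # rows: base, +60, +120, 180, 240, 300
  }
  CG_ar <- CB + 1.53 * c(0.66, 0, 0.75)
  tyr_ring <- ring6(CG_ar, w, p)
  trp_R5 <- 1.24
  trp_M5 <- CG_ar + trp_R5 * w
  trp_pent <- t(vapply(0:4, function(k) {
    th <- k * 2 * pi / 5
    trp_M5 + trp_R5 * (cos(th) * (-w) + sin(th) * p)
  }, numeric(3)))  # CG, CD1, NE1, CE2, CD2
  trp_hex <- hex_from_edge(trp_pent[5, ], trp_pent[4, ], trp_M5)
  list(
    GLY = bb,
    ALA = rbind(bb, CB = CB),
    VAL = rbind(bb, CB = CB, CG1 = CB + c(0.88, 1.25, 0),
                CG2 = CB + c(0.88, -1.25, 0)),
    LEU = rbind(bb, CB = CB, CG = CB + c(0.88, 0, 1.25),
                CD1 = CB + c(0.88, 0, 1.25) + c(0.88, 1.25, 0),
                CD2 = CB + c(0.88, 0, 1.25) + c(0.88, -1.25, 0)),
    SER = rbind(bb, CB = CB, OG = CB + c(0.80, 0, 1.17)),
    ASN = rbind(bb, CB = CB, CG = CB + c(1.01, 0, 1.15),
                OD1 = CB + c(1.01, 0, 1.15) + c(1.10, 0.55, 0),
                ND2 = CB + c(1.01, 0, 1.15) + c(0.60, -1.19, 0)),
    LYS = rbind(bb, CB = CB, CG = CB + c(0.88, 0, 1.25),
                CD = CB + c(1.76, 0, 0), CE = CB + c(2.64, 0, 1.25),
                NZ = CB + c(3.48, 0, 0.06)),
    TYR = rbind(bb, CB = CB, CG = tyr_ring[1, ], CD1 = tyr_ring[2, ],
                CE1 = tyr_ring[3, ], CZ = tyr_ring[4, ],
                CE2 = tyr_ring[5, ], CD2 = tyr_ring[6, ],
                OH = tyr_ring[4, ] + 1.37 * w),
    TRP = rbind(bb, CB = CB, CG = trp_pent[1, ], CD1 = trp_pent[2, ],
                NE1 = trp_pent[3, ], CE2 = trp_pent[4, ],
                CD2 = trp_pent[5, ], CE3 = trp_hex[1, ],
                CZ3 = trp_hex[2, ], CH2 = trp_hex[3, ],
                CZ2 = trp_hex[4, ])
  )
})

.lining_classes <- list(
  aromatic = c("TRP", "TYR"),
  donor = c("ASN", "SER", "LYS"),
  aliphatic = c("VAL", "ALA", "LEU")
)

.background_mix <- c(ALA = 0.18, VAL = 0.14, GLY = 0.14, SER = 0.14,
                     ASN = 0.12, TYR = 0.10, TRP = 0.10, LYS = 0.08)

# Rotation taking +x to direction `d`, with roll angle about d.
.orient <- function(d, roll = 0) {
  d <- d / sqrt(sum(d^2))
  up <- if (abs(d[3]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
  e2 <- .cross3(up, d); e2 <- e2 / sqrt(sum(e2^2))
  e3 <- .cross3(d, e2)
  R <- cbind(d, e2, e3)
  cr <- cos(roll); sr <- sin(roll)
  R %*% rbind(c(1, 0, 0), c(0, cr, -sr), c(0, sr, cr))
}

.fibonacci_sphere <- function(n) .sphere_points(n)

#' Specification of a synthetic binding-pocket complex
#'
#' @param depth Pocket depth class: `"deep"`, `"shallow"` or `"flat"`.
#' @param lining Named fractions (`aromatic`, `donor`, `aliphatic`) of the
#'   pocket-lining residue composition; must sum to 1.
#' @param ring_size Sugar ring size, 5 or 6.
#' @param aglycone Attach a non-sugar acetyl fragment to the ligand?
#' @param noise Coordinate noise s.d. in Angstrom (default 0.15).
#' @param seed Integer seed fixing all randomness.
#' @return A `pocket_spec` list.
#' @export
pocket_spec <- function(depth = c("deep", "shallow", "flat"),
                        lining = c(aromatic = 0.5, donor = 0.35,
                                   aliphatic = 0.15),
                        ring_size = 6L, aglycone = FALSE, noise = 0.15,
                        seed = 1L) {
  depth <- match.arg(depth)
  if (!ring_size %in% c(5L, 6L)) {
    rlang::abort(sprintf("infeasible sugar ring size %d", ring_size))
  }
  if (abs(sum(lining) - 1) > 1e-6) rlang::abort("lining fractions must sum to 1")
  structure(list(depth = depth, lining = lining, ring_size = ring_size,
                 aglycone = aglycone, noise = noise, seed = as.integer(seed)),
            class = "pocket_spec")
}

#' Generate a toy protein-carbohydrate complex
#'
#' Builds a 100--500-atom pseudo-protein (two concentric residue shells
#' plus a small core) with a geometric pocket along +z lined according to
#' the spec's composition, places a ring sugar ligand (5 C + 1 O for a
#' pyranose, hydroxyl oxygens on the ring carbons, optional N-acetyl arm
#' and acetyl aglycone) at a depth set by the pocket class, and perturbs
#' all coordinates with seeded Gaussian noise. Output is both a parsed
#' `glyco_structure` and equivalent PDB-format text; the ground-truth
#' contact set is every protein atom within 5 A of a sugar atom.
#'
#' @param spec A [pocket_spec()].
#' @return A list with `structure` (`glyco_structure`), `pdb` (character
#'   lines), `truth_serials` (ground-truth contact atom serials) and
#'   `spec`.
#' @export
generate_toy_complex <- function(spec) {
  stopifnot(inherits(spec, "pocket_spec"))
  set.seed(spec$seed)
  depth <- spec$depth

  # solid body: three concentric anchor shells; the pocket is carved as a
  # cylindrical cavity along +z, the ligand sits inside it
  z_lig <- switch(depth, deep = 7.0, shallow = 10.5, flat = 13.8)
  lig_ctr <- c(0, 0, z_lig)
  anchors <- rbind(.fibonacci_sphere(40) * 11,
                   .fibonacci_sphere(14) * 7,
                   .fibonacci_sphere(4) * 3.5,
                   c(0, 0, 0))
  shell <- c(rep("outer", 40), rep("mid", 14), rep("core", 5))
  axis_dist <- sqrt(anchors[, 1]^2 + anchors[, 2]^2)
  carved <- switch(depth,
    deep = axis_dist < 4.6 & anchors[, 3] > 2.5,
    shallow = axis_dist < 4.6 & anchors[, 3] > 7,
    flat = rep(FALSE, nrow(anchors)))
  anchors <- anchors[!carved, , drop = FALSE]
  shell <- shell[!carved]
  d_lig <- sqrt(rowSums(sweep(anchors, 2, lig_ctr, "-")^2))
  lining_sel <- d_lig >= 4.0 & d_lig <= 8.5

  draw_lining <- function(n) {
    cls <- sample(names(spec$lining), n, replace = TRUE, prob = spec$lining)
    vapply(cls, function(cl) sample(.lining_classes[[cl]], 1), character(1))
  }
  draw_background <- function(n) {
    sample(names(.background_mix), n, replace = TRUE, prob = .background_mix)
  }

  res_rows <- list(); resi <- 0L
  place_residue <- function(resn, anchor, dir) {
    resi <<- resi + 1L
    tmpl <- .res_templates[[resn]]
    R <- .orient(dir, roll = stats::runif(1, 0, 2 * pi))
    co <- tmpl %*% t(R)
    co <- sweep(co, 2, anchor, "+")
    tibble::tibble(resn = unname(resn), resi = resi,
                   atom = rownames(tmpl),
                   x = unname(co[, 1]), y = unname(co[, 2]),
                   z = unname(co[, 3]))
  }

  for (k in seq_len(nrow(anchors))) {
    anchor <- anchors[k, ]
    if (lining_sel[k]) {
      res_rows[[length(res_rows) + 1L]] <-
        place_residue(draw_lining(1), anchor, lig_ctr - anchor)
    } else if (shell[k] == "outer") {
      res_rows[[length(res_rows) + 1L]] <-
        place_residue(draw_background(1), anchor, anchor)
    } else {
      dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
      res_rows[[length(res_rows) + 1L]] <-
        place_residue(draw_background(1), anchor, dir)
    }
  }
  prot <- dplyr::bind_rows(res_rows)
  prot$chain <- "A"; prot$het <- FALSE
  prot$elem <- substr(prot$atom, 1, 1)

  lig <- .ligand_atoms(spec, lig_ctr)
  # per-atom noise on the protein; the sugar is jittered as a rigid body
  # so its ring topology survives bond inference
  prot$x <- prot$x + stats::rnorm(nrow(prot), 0, spec$noise)
  prot$y <- prot$y + stats::rnorm(nrow(prot), 0, spec$noise)
  prot$z <- prot$z + stats::rnorm(nrow(prot), 0, spec$noise)
  R <- .orient(stats::rnorm(3), roll = stats::runif(1, 0, 2 * pi))
  lco <- sweep(cbind(lig$x, lig$y, lig$z), 2, lig_ctr, "-") %*% t(R)
  lco <- sweep(lco, 2, lig_ctr + stats::rnorm(3, 0, spec$noise), "+")
  lig$x <- lco[, 1]; lig$y <- lco[, 2]; lig$z <- lco[, 3]
  all <- dplyr::bind_rows(prot, lig)
  all$serial <- seq_len(nrow(all))
  all$icode <- ""

  id <- sprintf("toy_%s_%d", depth, spec$seed)
  st <- .finish_structure(
    all[, c("serial", "chain", "resn", "resi", "icode", "atom", "elem",
            "x", "y", "z", "het")],
    id, carw = default_carb_residues())

  a <- st$atoms
  sug <- which(a$is_carb)
  pr <- which(a$is_protein)
  truth <- if (length(sug)) {
    pr[.min_dist_to_set(structure_coords(st, pr),
                        structure_coords(st, sug)) <= 5]
  } else integer(0)
  list(structure = st, pdb = .format_pdb(st$atoms),
       truth_serials = a$serial[truth], spec = spec)
}

.ligand_atoms <- function(spec, ctr) {
  nring <- spec$ring_size
  edge <- 1.45
  Rr <- edge / (2 * sin(pi / nring))
  th <- (seq_len(nring) - 1) * 2 * pi / nring + pi / 2
  ring <- cbind(Rr * cos(th), Rr * sin(th), 0)
  nC <- nring - 1L
  nm <- c("O5", paste0("C", seq_len(nC)))
  rows <- tibble::tibble(atom = nm, x = ring[, 1], y = ring[, 2], z = ring[, 3])
  acet <- spec$aglycone || FALSE
  use_nag <- spec$ring_size == 6L && stats::runif(1) < 0.35
  # hydroxyl substituents on the ring carbons, alternating above/below;
  # the carbon next to the ring oxygen carries the exocyclic C6-O6 arm
  for (k in seq_len(nC)) {
    cpos <- ring[k + 1, ]
    if (use_nag && k == 2) next
    out <- cpos / sqrt(sum(cpos^2))
    if (k == nC && nring == 6L) {
      c6 <- cpos + 1.53 * (out * 0.55 + c(0, 0, 0.835))
      o6 <- c6 + 1.43 * (out * 0.835 + c(0, 0, 0.55))
      rows <- dplyr::bind_rows(rows, tibble::tibble(
        atom = c("C6", "O6"), x = c(c6[1], o6[1]),
        y = c(c6[2], o6[2]), z = c(c6[3], o6[3])))
      next
    }
    zt <- if (k %% 2 == 0) 0.45 else -0.45
    d <- out + c(0, 0, zt); d <- d / sqrt(sum(d^2))
    rows <- dplyr::bind_rows(rows, tibble::tibble(
      atom = paste0("O", k), x = cpos[1] + 1.43 * d[1],
      y = cpos[2] + 1.43 * d[2], z = cpos[3] + 1.43 * d[3]))
  }
  if (use_nag) {  # N-acetyl arm on C2
    cpos <- ring[3, ]
    out <- cpos / sqrt(sum(cpos^2))
    n2 <- cpos + 1.45 * out
    c7 <- n2 + 1.33 * (out + c(0, 0, 0.4)) / sqrt(sum((out + c(0, 0, 0.4))^2))
    o7 <- c7 + 1.23 * c(0, 0, 1)
    c8 <- c7 + 1.50 * out
    rows <- dplyr::bind_rows(rows, tibble::tibble(
      atom = c("N2", "C7", "O7", "C8"),
      x = c(n2[1], c7[1], o7[1], c8[1]),
      y = c(n2[2], c7[2], o7[2], c8[2]),
      z = c(n2[3], c7[3], o7[3], c8[3])))
  }
  rows$x <- rows$x + ctr[1]; rows$y <- rows$y + ctr[2]
  rows$z <- rows$z + ctr[3]
  rows$resn <- if (use_nag) "NAG" else "GLC"
  rows$resi <- 1L; rows$chain <- "X"; rows$het <- TRUE
  rows$elem <- substr(rows$atom, 1, 1)
  if (acet) {  # aglycone: acetyl fragment hanging off the ligand, +z side
    base <- c(ctr[1], ctr[2] + Rr + 1.43, ctr[3] + 0.3)
    frag <- tibble::tibble(
      atom = c("C1A", "O1A", "C2A"),
      x = base[1] + c(0, 0.6, 0.75),
      y = base[2] + c(1.40, 2.20, 1.90),
      z = base[3] + c(0.4, -0.3, 1.55),
      resn = "ACE", resi = 2L, chain = "X", het = TRUE)
    frag$elem <- substr(frag$atom, 1, 1)
    rows <- dplyr::bind_rows(rows, frag)
  }
  rows
}

.format_pdb <- function(atoms) {
  vapply(seq_len(nrow(atoms)), function(i) {
    a <- atoms[i, ]
    rec <- if (a$het) "HETATM" else "ATOM  "
    name <- if (nchar(a$atom) < 4) sprintf(" %-3s", a$atom) else a$atom
    sprintf("%s%5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            rec, a$serial, name, a$resn, a$chain, a$resi,
            a$x, a$y, a$z, 1.00, 0.00, a$elem)
  }, character(1))
}

#' Write a toy complex to a PDB file (with ground-truth sidecar)
#'
#' @param complex Output of [generate_toy_complex()].
#' @param path PDB output path; the ground truth is written next to it as
#'   `<path>.truth.tsv`.
#' @return `path`, invisibly.
#' @export
write_toy_complex <- function(complex, path) {
  writeLines(c(complex$pdb, "END"), path)
  utils::write.table(
    data.frame(serial = complex$truth_serials),
    paste0(path, ".truth.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Generate a synthetic study corpus
#'
#' A list of toy complexes with varied pocket depth, lining composition,
#' sugar ring and aglycone flags, each deterministically seeded from the
#' master seed.
#'
#' @param n Number of complexes (default 30).
#' @param seed Master integer seed.
#' @param depths Depth classes to cycle over (default all-deep, the
#'   easy-geometry regime).
#' @return List of [generate_toy_complex()] results.
#' @export
generate_corpus <- function(n = 30L, seed = 1L, depths = "deep") {
  set.seed(seed)
  purrr::map(seq_len(n), function(i) {
    arom <- stats::runif(1, 0.4, 0.6)
    lin <- c(aromatic = arom, donor = (1 - arom) * 0.7,
             aliphatic = (1 - arom) * 0.3)
    sp <- pocket_spec(
      depth = depths[(i - 1L) %% length(depths) + 1L],
      lining = lin,
      ring_size = if (i %% 5 == 0) 5L else 6L,
      aglycone = i %% 4 == 0,
      noise = 0.15,
      seed = (seed * 7919L + i * 104729L) %% 2147483647L)
    generate_toy_complex(sp)
  })
}

#' Generate a pair-database fixture with planted modes
#'
#' Draws local-frame displacement pairs around planted offsets, used to
#' verify template modes and PDM projection.
#'
#' @param n_pairs Pairs to draw per planted offset row.
#' @param offsets Tibble with columns `center_type`, `partner_type`,
#'   `dx`, `dy`, `dz` and optionally `sd` (spread, default 0.3 A).
#' @param seed Integer seed.
#' @param source Source id recorded on the pairs.
#' @return A `glyco_pairs` tibble.
#' @export
generate_pair_fixture <- function(n_pairs, offsets, seed = 1L,
                                  source = "fixture") {
  set.seed(seed)
  if (n_pairs == 0 || !nrow(offsets)) {
    out <- tibble::tibble(center_type = integer(0), partner_type = integer(0),
                          dx = numeric(0), dy = numeric(0), dz = numeric(0),
                          source = character(0))
    class(out) <- c("glyco_pairs", class(out))
    return(out)
  }
  if (is.null(offsets$sd)) offsets$sd <- 0.3
  rows <- purrr::pmap(offsets, function(center_type, partner_type, dx, dy,
                                        dz, sd) {
    d <- cbind(stats::rnorm(n_pairs, dx, sd), stats::rnorm(n_pairs, dy, sd),
               stats::rnorm(n_pairs, dz, sd))
    r <- sqrt(rowSums(d^2))
    over <- r > 5
    d[over, ] <- d[over, ] * (4.999 / r[over])  # keep inside the cutoff
    tibble::tibble(center_type = center_type, partner_type = partner_type,
                   dx = d[, 1], dy = d[, 2], dz = d[, 3], source = source)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("glyco_pairs", class(out))
  out
}
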