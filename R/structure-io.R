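#' @keywords internal
.element_radius <- function(elem) {
  r <- c(C = 1.87, N = 1.65, O = 1.40, S = 1.85)[elem]
  ifelse(is.na(r), 1.70, r)
}

.covalent_radius <- function(elem) {
  r <- c(C = 0.77, N = 0.75, O = 0.73, S = 1.02)[elem]
  ifelse(is.na(r), 0.80, r)
}

.standard_aa <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                  "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                  "THR", "TRP", "TYR", "VAL")

#' Default carbohydrate residue-name whitelist
#'
#' Residue names recognised as sugar monomers when detecting carbohydrate
#' ligands in HETATM records. Recognition additionally requires a
#' detectable sugar ring, so the list errs on the inclusive side.
#'
#' @return Character vector of residue names.
#' @export
default_carb_residues <- function() {
  c("GLC", "BGC", "GAL", "GLA", "MAN", "BMA", "NAG", "NDG", "A2G", "NGA",
    "FUC", "FUL", "XYL", "XYS", "LXC", "SIA", "SLB", "RIB", "ARA", "FRU",
    "GCU", "BDP", "IDU", "MAL", "LAT", "CEL", "TRE", "SUC", "GCS", "RAM")
}

new_structure <- function(atoms, bonds, id = "structure") {
  stopifnot(is.data.frame(atoms))
  bonds <- .normalise_bonds(bonds)
  structure(list(atoms = tibble::as_tibble(atoms), bonds = bonds, id = id),
            class = "glyco_structure")
}

.normalise_bonds <- function(bonds) {
  if (is.null(bonds) || !length(bonds)) {
    return(matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("i", "j"))))
  }
  bonds <- matrix(as.integer(bonds), ncol = 2)
  swap <- bonds[, 1] > bonds[, 2]
  bonds[swap, ] <- bonds[swap, 2:1]
  bonds <- unique(bonds)
  colnames(bonds) <- c("i", "j")
  bonds
}

#' @export
print.glyco_structure <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("<glyco_structure> %s: %d atoms (%d protein, %d carbohydrate, %d water), %d bonds\n",
              x$id, nrow(a), sum(a$is_protein), sum(a$is_carb),
              sum(a$is_water), nrow(x$bonds)))
  invisible(x)
}

#' @export
as_tibble.glyco_structure <- function(x, ...) x$atoms

structure_coords <- function(structure, idx = NULL) {
  a <- structure$atoms
  m <- cbind(a$x, a$y, a$z)
  if (!is.null(idx)) m <- m[idx, , drop = FALSE]
  m
}

#' Indices of protein surface atoms
#'
#' Surface atoms are protein atoms with solvent-accessible surface area
#' strictly greater than zero; [compute_sasa()] must have been run.
#'
#' @param structure A `glyco_structure`.
#' @return Integer atom indices.
#' @export
surface_atoms <- function(structure) {
  a <- structure$atoms
  if (all(is.na(a$sasa))) {
    rlang::abort("SASA not computed; call compute_sasa() first")
  }
  which(a$is_protein & !is.na(a$sasa) & a$sasa > 0)
}

#' Remove ligand, water and aglycone atoms from a structure
#'
#' Returns the protein-only structure, used e.g. to compute the
#' apo-surface SASA that defines actual binding residues.
#'
#' @param structure A `glyco_structure`.
#' @return A `glyco_structure` containing only protein atoms.
#' @export
strip_ligands <- function(structure) {
  keep <- which(structure$atoms$is_protein)
  .subset_structure(structure, keep)
}

.subset_structure <- function(structure, keep) {
  remap <- match(seq_len(nrow(structure$atoms)), keep)
  b <- structure$bonds
  if (nrow(b)) {
    b <- cbind(remap[b[, 1]], remap[b[, 2]])
    b <- b[stats::complete.cases(b), , drop = FALSE]
  }
  new_structure(structure$atoms[keep, ], b, structure$id)
}

#' Parse a PDB file into a typed structure
#'
#' Reads ATOM/HETATM records (via bio3d), drops hydrogens, alternate
#' locations other than the first, and zero-occupancy atoms, then assigns
#' the 36 atom types and van der Waals radii. Covalent bonds are taken
#' from CONECT records where present and inferred by interatomic distance
#' (sum of covalent radii + 0.45 A) otherwise. HETATM residues on the
#' carbohydrate whitelist that carry a detectable sugar ring become
#' carbohydrate ligand atoms grouped into connected ligand components;
#' non-sugar HETATM components and non-sugar residues attached to a sugar
#' (aglycone) are retained but flagged and never count as carbohydrate.
#' Sugars covalently LINKed to a protein atom (glycosylation) are excluded
#' from the ligand set.
#'
#' @param path Path to a PDB file.
#' @param id Structure identifier; defaults to the file name.
#' @param carb_residues Residue-name whitelist, see [default_carb_residues()].
#' @return A `glyco_structure`: a list with an `atoms` tibble (coordinates,
#'   `type_id`, `vdw`, classification flags, `ligand_group`, `sasa`),
#'   a two-column `bonds` matrix and the `id`.
#' @export
read_structure <- function(path, id = NULL,
                           carb_residues = default_carb_residues()) {
  if (is.null(id)) id <- sub("\\.(pdb|ent)$", "", basename(path))
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  raw <- readLines(path, warn = FALSE)
  at <- tibble::as_tibble(pdb$atom)

  elem <- toupper(trimws(at$elesy))
  miss <- is.na(elem) | elem == ""
  elem[miss] <- substr(gsub("[0-9']", "", trimws(at$elety[miss])), 1, 1)

  keep <- elem != "H" & elem != "D" &
    (is.na(at$alt) | at$alt %in% c("", "A")) &
    (is.na(at$o) | at$o > 0)
  at <- at[keep, ]; elem <- elem[keep]
  if (!nrow(at)) rlang::abort("no heavy atoms in PDB file")

  atoms <- tibble::tibble(
    serial = as.integer(at$eleno),
    chain = ifelse(is.na(at$chain), "", at$chain),
    resn = toupper(at$resid),
    resi = as.integer(at$resno),
    icode = ifelse(is.na(at$insert), "", at$insert),
    atom = toupper(trimws(at$elety)),
    elem = elem,
    x = at$x, y = at$y, z = at$z,
    het = at$type == "HETATM"
  )
  .finish_structure(atoms, id, carw = carb_residues, raw_lines = raw)
}

# Shared finishing step: typing, bonds, ligand groups, flags.
.finish_structure <- function(atoms, id, carw, raw_lines = character(0)) {
  n <- nrow(atoms)
  atoms$type_id <- NA_integer_
  atoms$is_protein <- !atoms$het & atoms$resn %in% .standard_aa
  atoms$is_water <- atoms$resn %in% c("HOH", "WAT", "DOD")
  atoms$is_carb <- FALSE
  atoms$is_aglycone <- FALSE
  atoms$ligand_group <- NA_integer_

  # protein typing; unknown residue/atom names are skipped with a warning
  pidx <- which(atoms$is_protein)
  if (length(pidx)) {
    key <- paste(atoms$resn[pidx], atoms$atom[pidx])
    tid <- unname(.protein_type_map[key])
    if (anyNA(tid)) {
      bad <- pidx[is.na(tid)]
      rlang::warn(sprintf("skipping %d unrecognised protein atom(s), e.g. %s %s",
                          length(bad), atoms$resn[bad[1]], atoms$atom[bad[1]]))
      keep <- setdiff(seq_len(n), bad)
      return(.finish_structure(atoms[keep, ], id, carw, raw_lines))
    }
    atoms$type_id[pidx] <- tid
  }
  atoms$type_id[atoms$is_water] <- 31L

  bonds <- .structure_bonds(atoms, raw_lines)

  # ligand groups: connected components over non-protein, non-water atoms
  het <- which(!atoms$is_protein & !atoms$is_water)
  if (length(het)) {
    comp <- .connected_components(het, bonds)
    linked <- .protein_linked_residues(atoms, raw_lines)
    g <- 0L
    for (members in comp) {
      sugar <- members[atoms$resn[members] %in% carw]
      is_linked <- length(sugar) && any(
        paste(atoms$chain[sugar], atoms$resi[sugar], atoms$resn[sugar]) %in% linked)
      typed <- FALSE
      if (length(sugar) && !is_linked) {
        sub_b <- bonds[bonds[, 1] %in% sugar & bonds[, 2] %in% sugar, ,
                       drop = FALSE]
        local <- cbind(match(sub_b[, 1], sugar), match(sub_b[, 2], sugar))
        tid <- tryCatch(
          assign_carbohydrate_atom_types(atoms$elem[sugar], local),
          glycosurf_non_sugar = function(e) NULL)
        if (!is.null(tid)) {
          g <- g + 1L
          atoms$type_id[sugar] <- tid
          atoms$is_carb[sugar] <- TRUE
          atoms$ligand_group[members] <- g
          atoms$is_aglycone[setdiff(members, sugar)] <- TRUE
          typed <- TRUE
        }
      }
      if (!typed) atoms$is_aglycone[members] <- TRUE
    }
  }

  atoms$vdw <- ifelse(is.na(atoms$type_id),
                      .element_radius(atoms$elem),
                      .type_radii()[atoms$type_id])
  atoms$sasa <- NA_real_
  new_structure(atoms, bonds, id)
}

# Bonds from CONECT records plus distance inference (non-water atoms).
.structure_bonds <- function(atoms, raw_lines) {
  n <- nrow(atoms)
  bonds <- matrix(integer(0), ncol = 2)
  con <- grep("^CONECT", raw_lines, value = TRUE)
  if (length(con)) {
    for (ln in con) {
      f <- suppressWarnings(as.integer(strsplit(trimws(substr(ln, 7, 80)),
                                                "\\s+")[[1]]))
      f <- f[!is.na(f)]
      if (length(f) >= 2) {
        i <- match(f[1], atoms$serial)
        js <- match(f[-1], atoms$serial)
        js <- js[!is.na(js)]
        if (!is.na(i) && length(js)) bonds <- rbind(bonds, cbind(i, js))
      }
    }
  }
  idx <- which(!atoms$is_water)
  if (length(idx) > 1) {
    co <- cbind(atoms$x[idx], atoms$y[idx], atoms$z[idx])
    rad <- .covalent_radius(atoms$elem[idx])
    nb <- .neighbour_pairs(co, max(rad) * 2 + 0.45)
    if (nrow(nb)) {
      lim <- rad[nb[, 1]] + rad[nb[, 2]] + 0.45
      ok <- nb[, 3] <= lim & nb[, 3] > 0.4
      bonds <- rbind(bonds, cbind(idx[nb[ok, 1]], idx[nb[ok, 2]]))
    }
  }
  .normalise_bonds(bonds)
}

# All unordered pairs with distance <= cutoff; returns cbind(i, j, d).
.neighbour_pairs <- function(co, cutoff) {
  n <- nrow(co)
  if (n < 2) return(matrix(numeric(0), ncol = 3))
  d <- as.matrix(stats::dist(co))
  hit <- which(upper.tri(d) & d <= cutoff, arr.ind = TRUE)
  cbind(hit[, 1], hit[, 2], d[hit])
}

.connected_components <- function(nodes, bonds) {
  parent <- stats::setNames(nodes, nodes)
  find <- function(x) {
    while (parent[[as.character(x)]] != x) {
      parent[[as.character(x)]] <<- parent[[as.character(parent[[as.character(x)]])]]
      x <- parent[[as.character(x)]]
    }
    x
  }
  inset <- bonds[, 1] %in% nodes & bonds[, 2] %in% nodes
  for (k in which(inset)) {
    a <- find(bonds[k, 1]); b <- find(bonds[k, 2])
    if (a != b) parent[[as.character(a)]] <- b
  }
  roots <- vapply(nodes, find, numeric(1))
  split(nodes, roots)
}

# Residues named in LINK records on the protein side of a covalent link.
.protein_linked_residues <- function(atoms, raw_lines) {
  out <- character(0)
  for (ln in grep("^LINK", raw_lines, value = TRUE)) {
    r1 <- toupper(trimws(substr(ln, 18, 20)))
    c1 <- trimws(substr(ln, 22, 22))
    i1 <- suppressWarnings(as.integer(trimws(substr(ln, 23, 26))))
    r2 <- toupper(trimws(substr(ln, 48, 50)))
    c2 <- trimws(substr(ln, 52, 52))
    i2 <- suppressWarnings(as.integer(trimws(substr(ln, 53, 56))))
    if (r1 %in% .standard_aa && !(r2 %in% .standard_aa)) {
      out <- c(out, paste(c2, i2, r2))
    } else if (r2 %in% .standard_aa && !(r1 %in% .standard_aa)) {
      out <- c(out, paste(c1, i1, r1))
    }
  }
  out
}

#' Build a typed structure from a raw atom table
#'
#' Programmatic equivalent of [read_structure()]: takes a plain atom
#' tibble (columns `serial`, `chain`, `resn`, `resi`, `icode`, `atom`,
#' `elem`, `x`, `y`, `z`, `het`) and runs the same typing, bond inference
#' and ligand-group detection as the PDB reader. Useful for building
#' fixtures and synthetic structures in code.
#'
#' @param atoms Atom tibble as described above (`icode` may be omitted).
#' @param id Structure identifier.
#' @param carb_residues Sugar residue-name whitelist.
#' @return A `glyco_structure`.
#' @export
typed_structure <- function(atoms, id = "structure",
                            carb_residues = default_carb_residues()) {
  atoms <- tibble::as_tibble(atoms)
  if (!"icode" %in% names(atoms)) atoms$icode <- ""
  if (!"het" %in% names(atoms)) atoms$het <- FALSE
  cols <- c("serial", "chain", "resn", "resi", "icode", "atom", "elem",
            "x", "y", "z", "het")
  stopifnot(all(cols %in% names(atoms)))
  .finish_structure(atoms[, cols], id, carw = carb_residues)
}

#' Does a complex pass the dataset inclusion criterion?
#'
#' A protein-carbohydrate complex enters the corpus when at least
#' `min_contacts` protein atoms lie within `cutoff` of any carbohydrate
#' ligand atom.
#'
#' @param structure A `glyco_structure` with at least one sugar ligand.
#' @param min_contacts Minimum protein contact-atom count (default 25).
#' @param cutoff Contact distance in Angstrom (default 5).
#' @return Logical scalar.
#' @export
complex_passes_criterion <- function(structure, min_contacts = 25L,
                                     cutoff = 5) {
  a <- structure$atoms
  lig <- which(a$is_carb)
  if (!length(lig)) {
    rlang::warn("structure has no carbohydrate ligand group")
    return(FALSE)
  }
  prot <- which(a$is_protein)
  if (!length(prot)) return(FALSE)
  n_contact <- sum(.min_dist_to_set(structure_coords(structure, prot),
                                    structure_coords(structure, lig)) <= cutoff)
  n_contact >= min_contacts
}

# For each row of `from`, the minimum distance to any row of `to`.
.min_dist_to_set <- function(from, to) {
  cross <- outer(rowSums(from^2), rowSums(to^2), "+") -
    2 * from %*% t(to)
  sqrt(pmax(apply(cross, 1, min), 0))
}

#' Export the typed-atom table as TSV
#'
#' @param structure A `glyco_structure`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_structure_tsv <- function(structure, path) {
  a <- structure$atoms[, c("serial", "chain", "resi", "resn", "atom",
                           "type_id", "sasa")]
  utils::write.table(a, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
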