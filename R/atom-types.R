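#' Atom type definitions
#'
#' The 36 interacting-atom types used throughout the package: 30 protein
#' heavy-atom classes (derived from the Laskowski-style chemical typing of
#' the 20 natural amino acids), water, and 5 carbohydrate classes. Each
#' type carries the van der Waals radius used for solvent-accessibility
#' and occupancy calculations.
#'
#' @return A tibble with columns `type_id`, `code`, `radius`, `description`.
#' @export
#' @examples
#' atom_type_table()
atom_type_table <- function() {
  tibble::tribble(
    ~type_id, ~code, ~radius, ~description,
    1L,  "NH1",  1.65, "Backbone NH",
    2L,  "C",    1.76, "Backbone C",
    3L,  "CH1E", 1.87, "Backbone CA (exc. Gly)",
    4L,  "O",    1.40, "Backbone O",
    5L,  "CH0",  1.76, "Arg CZ, Asn CG, Asp CG, Gln CD, Glu CD",
    6L,  "CH1S", 1.87, "Sidechain CH1: Ile CB, Leu CG, Thr CB, Val CB",
    7L,  "CH2E", 1.87, "Tetrahedral CH2 (except CH2P, CH2G)",
    8L,  "CH3E", 1.87, "Tetrahedral CH3",
    9L,  "CR1E", 1.76, "Aromatic CH (except CR1W, CRHH, CR1H)",
    10L, "OH1",  1.40, "Alcohol OH (Ser OG, Thr OG1, Tyr OH)",
    11L, "OC",   1.40, "Carboxyl O (Asp OD1, OD2, Glu OE1, OE2)",
    12L, "OS",   1.40, "Sidechain O: Asn OD1, Gln OE1",
    13L, "CH2G", 1.87, "Gly CA",
    14L, "CH2P", 1.87, "Pro CB, CG, CD",
    15L, "NH1S", 1.65, "Sidechain NH: Arg NE, His ND1/NE2, Trp NE1",
    16L, "NC2",  1.65, "Arg NH1, NH2",
    17L, "NH2",  1.65, "Asn ND2, Gln NE2",
    18L, "CR1W", 1.76, "Trp CZ2, CH2",
    19L, "CY2",  1.76, "Tyr CZ",
    20L, "SC",   1.85, "Cys S",
    21L, "CF",   1.76, "Phe CG",
    22L, "SM",   1.85, "Met S",
    23L, "CY",   1.76, "Tyr CG",
    24L, "CW",   1.76, "Trp CD2, CE2",
    25L, "CRHH", 1.76, "His CE1",
    26L, "NH3",  1.50, "Lys NZ",
    27L, "CR1H", 1.76, "His CD2",
    28L, "C5",   1.76, "His CG",
    29L, "N",    1.65, "Pro N",
    30L, "C5W",  1.76, "Trp CG",
    31L, "HOH",  1.40, "Water",
    32L, "O.RX", 1.40, "Ring oxygen",
    33L, "O.LX", 1.40, "Oxygen of hydroxyl group",
    34L, "C.RX", 1.87, "Ring carbon",
    35L, "C.LX", 1.87, "Non-sugar carbon",
    36L, "N.LX", 1.65, "Nitrogen of N-acetyl group"
  )
}

# vdW radius lookup vector, index = type_id
.type_radii <- function() {
  c(1.65, 1.76, 1.87, 1.40, 1.76, 1.87, 1.87, 1.87, 1.76, 1.40,
    1.40, 1.40, 1.87, 1.87, 1.65, 1.65, 1.65, 1.76, 1.76, 1.85,
    1.76, 1.85, 1.76, 1.76, 1.76, 1.50, 1.76, 1.76, 1.65, 1.76,
    1.40, 1.40, 1.40, 1.87, 1.87, 1.65)
}

# Full residue/atom -> type_id map over the 20 standard amino acids.
# Backbone: N -> 1 (Pro N -> 29), CA -> 3 (Gly CA -> 13), C -> 2, O -> 4.
# OXT is typed like backbone O.
.protein_type_map <- local({
  aa <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL")
  m <- list()
  for (r in aa) {
    m[[paste(r, "N")]]  <- if (r == "PRO") 29L else 1L
    m[[paste(r, "CA")]] <- if (r == "GLY") 13L else 3L
    m[[paste(r, "C")]]  <- 2L
    m[[paste(r, "O")]]  <- 4L
    m[[paste(r, "OXT")]] <- 4L
  }
  side <- list(
    ALA = c(CB = 8L),
    ARG = c(CB = 7L, CG = 7L, CD = 7L, NE = 15L, CZ = 5L, NH1 = 16L, NH2 = 16L),
    ASN = c(CB = 7L, CG = 5L, OD1 = 12L, ND2 = 17L),
    ASP = c(CB = 7L, CG = 5L, OD1 = 11L, OD2 = 11L),
    CYS = c(CB = 7L, SG = 20L),
    GLN = c(CB = 7L, CG = 7L, CD = 5L, OE1 = 12L, NE2 = 17L),
    GLU = c(CB = 7L, CG = 7L, CD = 5L, OE1 = 11L, OE2 = 11L),
    GLY = c(),
    HIS = c(CB = 7L, CG = 28L, ND1 = 15L, CD2 = 27L, CE1 = 25L, NE2 = 15L),
    ILE = c(CB = 6L, CG1 = 7L, CG2 = 8L, CD1 = 8L),
    LEU = c(CB = 7L, CG = 6L, CD1 = 8L, CD2 = 8L),
    LYS = c(CB = 7L, CG = 7L, CD = 7L, CE = 7L, NZ = 26L),
    MET = c(CB = 7L, CG = 7L, SD = 22L, CE = 8L),
    PHE = c(CB = 7L, CG = 21L, CD1 = 9L, CD2 = 9L, CE1 = 9L, CE2 = 9L, CZ = 9L),
    PRO = c(CB = 14L, CG = 14L, CD = 14L),
    SER = c(CB = 7L, OG = 10L),
    THR = c(CB = 6L, OG1 = 10L, CG2 = 8L),
    TRP = c(CB = 7L, CG = 30L, CD1 = 9L, CD2 = 24L, NE1 = 15L, CE2 = 24L,
            CE3 = 9L, CZ2 = 18L, CZ3 = 9L, CH2 = 18L),
    TYR = c(CB = 7L, CG = 23L, CD1 = 9L, CD2 = 9L, CE1 = 9L, CE2 = 9L,
            CZ = 19L, OH = 10L),
    VAL = c(CB = 6L, CG1 = 8L, CG2 = 8L)
  )
  for (r in names(side)) {
    s <- side[[r]]
    for (a in names(s)) m[[paste(r, a)]] <- s[[a]]
  }
  unlist(m)
})

#' Assign the protein atom type of a heavy atom
#'
#' Deterministic chemical typing of protein heavy atoms into the 30
#' protein atom classes. Backbone atoms map to types 1--4 (Pro N to 29,
#' Gly CA to 13); side-chain atoms map by residue/atom name. The terminal
#' OXT is typed like the backbone O. Ala CB is typed as tetrahedral CH3
#' (the specific CH1/CH3 listings take precedence over the generic
#' tetrahedral-CH2 class).
#'
#' @param residue_name Three-letter upper-case residue name (e.g. `"TRP"`).
#' @param atom_name PDB atom name (e.g. `"CG"`), hydrogens excluded.
#' @return Integer type id in 1--30.
#' @export
#' @examples
#' assign_protein_atom_type("TRP", "CG")  # 30, Trp C5W
#' assign_protein_atom_type("GLY", "CA")  # 13, CH2G
assign_protein_atom_type <- function(residue_name, atom_name) {
  key <- paste(toupper(residue_name), toupper(atom_name))
  out <- unname(.protein_type_map[key])
  bad <- is.na(out)
  if (any(bad)) {
    rlang::abort(
      sprintf("no protein atom type for residue '%s', atom '%s'",
              residue_name[bad][1], atom_name[bad][1]),
      class = "glycosurf_untyped_atom")
  }
  out
}

#' Assign carbohydrate atom types to a sugar ligand
#'
#' Types the atoms of one connected sugar ligand into the 5 carbohydrate
#' classes by ring detection on the covalent bond graph: a 5- or 6-membered
#' ring containing exactly one oxygen marks the sugar ring. Ring O is the
#' ring-oxygen class (32), ring C the ring-carbon class (34), exocyclic
#' oxygens are hydroxyl oxygens (33), remaining carbons are non-sugar
#' carbons (35), and nitrogens (N-acetyl) are type 36.
#'
#' @param elements Character vector of element symbols for the ligand atoms
#'   (`"C"`, `"O"`, `"N"`, ...).
#' @param bonds Two-column integer matrix of covalent bonds, indices into
#'   `elements`.
#' @return Integer vector of type ids (32--36), or an error of class
#'   `glycosurf_non_sugar` if no sugar ring is found.
#' @export
assign_carbohydrate_atom_types <- function(elements, bonds) {
  n <- length(elements)
  adj <- .adjacency_list(bonds, n)
  ring <- .find_sugar_ring(elements, adj)
  if (is.null(ring)) {
    rlang::abort("ligand has no detectable sugar ring (5/6-ring with one O)",
                 class = "glycosurf_non_sugar")
  }
  type <- integer(n)
  in_ring <- seq_len(n) %in% ring
  for (i in seq_len(n)) {
    e <- elements[i]
    type[i] <-
      if (e == "O") { if (in_ring[i]) 32L else 33L } else
      if (e == "C") { if (in_ring[i]) 34L else 35L } else
      if (e == "N") 36L else
      35L  # rare hetero atoms grouped with non-sugar carbon
  }
  type
}

.adjacency_list <- function(bonds, n) {
  adj <- vector("list", n)
  if (length(bonds)) {
    for (k in seq_len(nrow(bonds))) {
      i <- bonds[k, 1]; j <- bonds[k, 2]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }
  adj
}

# Find a 5- or 6-membered cycle containing exactly one oxygen. Small
# ligands only; DFS from each oxygen.
.find_sugar_ring <- function(elements, adj) {
  ox <- which(elements == "O")
  for (o in ox) {
    ring <- .ring_search(o, adj, elements, max_len = 6L)
    if (!is.null(ring)) return(ring)
  }
  NULL
}

.ring_search <- function(start, adj, elements, max_len) {
  # DFS for a simple cycle through `start` of length 5 or 6 with one O
  path <- integer(0)
  found <- NULL
  visit <- function(v, parent) {
    if (!is.null(found)) return()
    path <<- c(path, v)
    if (length(path) <= max_len) {
      for (w in adj[[v]]) {
        if (!is.null(found)) break
        if (w == parent) next
        if (w == start && length(path) >= 5L) {
          if (sum(elements[path] == "O") == 1L) found <<- path
        } else if (!(w %in% path) && length(path) < max_len) {
          visit(w, v)
        }
      }
    }
    path <<- path[-length(path)]
  }
  visit(start, -1L)
  found
}
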