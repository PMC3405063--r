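# Shared fixtures, memoised so expensive objects are built once per run.
.fx <- new.env(parent = emptyenv())

fx_memo <- function(name, build) {
  if (is.null(.fx[[name]])) .fx[[name]] <- build()
  .fx[[name]]
}

# One deep-pocket toy complex with SASA computed.
fx_complex <- function() {
  fx_memo("complex", function() {
    cx <- generate_toy_complex(pocket_spec(seed = 42L))
    cx$structure <- compute_sasa(cx$structure)
    cx
  })
}

# A 4-complex corpus (structures with SASA) and its pair database.
fx_corpus4 <- function() {
  fx_memo("corpus4", function() {
    corpus <- generate_corpus(n = 4, seed = 7)
    structures <- lapply(corpus, function(cx) compute_sasa(cx$structure))
    pairs <- extract_pairs(structures)
    list(complexes = corpus, structures = structures, pairs = pairs)
  })
}

# A small hand-made structure: a SER-GLY dipeptide-like pair of residues
# far apart, for analytic SASA and frame tests.
fx_two_residues <- function() {
  fx_memo("two_residues", function() {
    atoms <- tibble::tibble(
      serial = 1:10,
      chain = "A",
      resn = c(rep("SER", 6), rep("GLY", 4)),
      resi = c(rep(1L, 6), rep(2L, 4)),
      atom = c("N", "CA", "C", "O", "CB", "OG", "N", "CA", "C", "O"),
      elem = c("N", "C", "C", "O", "C", "O", "N", "C", "C", "O"),
      x = c(0, 1.46, 2.0, 1.6, 1.9, 3.0, 20, 21.46, 22.0, 21.6),
      y = c(0, 0, 1.3, 2.4, -1.3, -1.6, 0, 0, 1.3, 2.4),
      z = 0,
      het = FALSE)
    typed_structure(atoms, id = "dipep")
  })
}

# Single isolated atom structure (ALA CB-like carbon), for analytic SASA.
fx_lone_atom <- function(type_resn = "ALA", type_atom = "CB") {
  atoms <- tibble::tibble(
    serial = 1L, chain = "A", resn = type_resn, resi = 1L,
    atom = type_atom, elem = substr(type_atom, 1, 1),
    x = 0, y = 0, z = 0, het = FALSE)
  typed_structure(atoms, id = "lone")
}

# A pyranose-like ring fixture: elements + bonds for carbohydrate typing.
fx_sugar_graph <- function(acetyl = FALSE) {
  # atoms: O5 C1 C2 C3 C4 C5 O3 C6 [N2 C7 O7]
  elements <- c("O", "C", "C", "C", "C", "C", "O", "C")
  bonds <- rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(5, 6), c(6, 1),
                 c(4, 7),  # O3 on ring carbon C3
                 c(6, 8))  # exocyclic C6
  if (acetyl) {
    elements <- c(elements, "N", "C", "O")
    bonds <- rbind(bonds, c(3, 9), c(9, 10), c(10, 11))
  }
  list(elements = elements, bonds = bonds)
}

# Random rigid motion, seeded.
fx_rigid_motion <- function(seed) {
  set.seed(seed)
  ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
  th <- stats::runif(1, 0, 2 * pi)
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  list(R = R, t = stats::rnorm(3, sd = 5))
}

apply_motion <- function(structure, motion) {
  co <- cbind(structure$atoms$x, structure$atoms$y, structure$atoms$z)
  co <- co %*% t(motion$R)
  co <- sweep(co, 2, motion$t, "+")
  structure$atoms$x <- co[, 1]
  structure$atoms$y <- co[, 2]
  structure$atoms$z <- co[, 3]
  structure
}

# The printed benchmark regression table (per-case rows and pooled rows).
fx_benchmark_table <- function() {
  tibble::tribble(
    ~id, ~acc, ~pre, ~sen, ~spe, ~mcc, ~fsc, ~tp, ~tn, ~fp, ~fn,
    "2UVE", 0.94, 0.34, 0.93, 0.94, 0.55, 0.50, 14, 452, 27, 1,
    "2WSU", 0.94, 0.33, 0.78, 0.95, 0.49, 0.47, 7, 261, 14, 2,
    "2XHH", 0.94, 0.50, 0.29, 0.98, 0.35, 0.36, 2, 100, 2, 5,
    "1NOF", 0.97, 0.63, 0.71, 0.98, 0.65, 0.68, 10, 317, 6, 4,
    "3ACF", 0.94, 0.40, 0.44, 0.96, 0.39, 0.42, 4, 161, 6, 5,
    "3M9W", 0.94, 0.33, 0.88, 0.94, 0.52, 0.48, 7, 231, 14, 1,
    "2X2S", 0.93, 0.40, 0.86, 0.93, 0.56, 0.55, 6, 122, 9, 1,
    "1R13", 0.96, 0.63, 0.71, 0.98, 0.65, 0.68, 5, 126, 3, 2,
    "3NSM", 0.97, 0.29, 0.50, 0.98, 0.37, 0.37, 5, 491, 12, 5,
    "1M71", 0.95, 0.00, 0.00, 0.99, -0.02, 0.00, 0, 196, 2, 8,
    "2XHN", 0.96, 0.83, 0.38, 1.00, 0.54, 0.51, 9, 439, 2, 15,
    "3K01", 0.96, 0.93, 0.50, 1.00, 0.67, 0.65, 13, 327, 1, 13,
    "1MSB", 0.95, 1.00, 0.38, 1.00, 0.60, 0.55, 3, 98, 0, 5,
    "low-id-overall", 0.95, 0.46, 0.56, 0.97, 0.49, 0.51, 85, 3321, 98, 67,
    "1CLY", 0.98, 1.00, 0.33, 1.00, 0.57, 0.50, 5, 386, 0, 10,
    "1M7D", 0.96, 0.83, 0.25, 1.00, 0.44, 0.39, 5, 384, 1, 15,
    "1MFA", 0.97, 0.61, 1.00, 0.97, 0.77, 0.76, 11, 191, 7, 0,
    "1OP3", 0.96, 0.33, 0.15, 0.99, 0.21, 0.21, 2, 392, 4, 11,
    "1Q9Q", 0.98, 0.64, 0.69, 0.99, 0.66, 0.67, 9, 383, 5, 4,
    "1S3K", 0.98, 0.78, 0.47, 1.00, 0.59, 0.58, 7, 376, 2, 8,
    "1UZ8", 0.97, 0.73, 0.50, 0.99, 0.59, 0.59, 8, 379, 3, 8,
    "3BZ4", 0.95, 0.43, 0.18, 0.99, 0.26, 0.25, 3, 370, 4, 14,
    "3DUR", 0.93, 0.43, 0.23, 0.98, 0.28, 0.30, 3, 193, 4, 10,
    "3EYV", 0.97, 0.78, 0.44, 1.00, 0.57, 0.56, 7, 389, 2, 9,
    "3HNS", 0.97, 0.67, 0.59, 0.99, 0.61, 0.63, 10, 382, 5, 7,
    "3I02", 0.97, 0.63, 0.36, 0.99, 0.46, 0.46, 5, 384, 3, 9,
    "3IF1", 0.99, 1.00, 0.58, 1.00, 0.76, 0.74, 7, 383, 0, 5,
    "3IJH", 0.97, 0.50, 0.43, 0.98, 0.45, 0.46, 6, 381, 6, 8,
    "3OAU", 0.96, 0.22, 0.15, 0.98, 0.16, 0.18, 2, 379, 7, 11,
    "antibody-overall", 0.97, 0.63, 0.41, 0.99, 0.49, 0.50, 90, 5352, 53, 129)
}
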