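# Confidence calibration, patch clustering, residue conversion.

test_that("confidence bins hold the validation TP fraction", {
  out <- c(rep(0.05, 10), rep(0.95, 10))
  lab <- c(rep(c(TRUE, FALSE), c(3, 7)), rep(TRUE, 10))
  tab <- build_confidence_table(out, lab, shrink = 0)
  expect_equal(tab$confidence[1], 0.3)    # 3 TP of 10 in the first bin
  expect_equal(tab$confidence[10], 1.0)   # all-positive top bin
  expect_true(all(tab$n[2:9] == 0))
  # positive and negative confidences are complementary by construction
  expect_equal(tab$confidence + (1 - tab$confidence), rep(1, 10))
  # interpolation bridges the empty middle monotonically
  expect_true(all(diff(tab$confidence) >= 0))
})

test_that("activity-to-confidence lookup handles edges and clamps", {
  out <- seq(0.05, 0.95, by = 0.1)
  lab <- seq_along(out) > 5
  tab <- build_confidence_table(out, lab, shrink = 0)
  expect_equal(to_confidence(0.05, tab), tab$confidence[1])
  expect_equal(to_confidence(1.0, tab), tab$confidence[10])  # top bin closed
  expect_warning(cc <- to_confidence(1.2, tab), "clamping")
  expect_equal(cc, tab$confidence[10])
  # a monotone table yields a monotone conversion
  expect_true(all(diff(to_confidence(seq(0, 1, 0.01), tab)) >= 0))
})

test_that("single seeds form singleton patches and near seeds merge", {
  co <- rbind(c(0, 0, 0), c(8, 0, 0), c(30, 0, 0), c(2, 0, 0))
  conf <- c(0.9, 0.8, 0.7, 0.05)
  p <- cluster_patches(co, conf)
  # seeds 1 and 2 are 8 A apart -> merged; seed 3 is remote -> own patch;
  # atom 4 is low-confidence -> not a member anywhere
  expect_identical(nrow(p), 2L)
  sizes <- sort(vapply(p$seeds, length, integer(1)))
  expect_identical(sizes, c(1L, 2L))
  expect_false(any(4L %in% unlist(p$members)))
  # no seeds -> no patches
  expect_identical(nrow(cluster_patches(co, rep(0, 4))), 0L)
})

test_that("members lie within 5 A of a seed and above the member threshold", {
  set.seed(41)
  co <- matrix(runif(90, 0, 25), 30, 3)
  conf <- runif(30)
  p <- cluster_patches(co, conf)
  for (r in seq_len(nrow(p))) {
    sd_ <- p$seeds[[r]]; mem <- p$members[[r]]
    expect_true(all(conf[sd_] > 0.5))
    expect_true(all(conf[mem] > 0.1))
    d <- as.matrix(stats::dist(co))
    expect_true(all(vapply(mem, function(m) min(d[m, sd_]) <= 5 + 1e-9,
                           logical(1))))
    expect_true(all(sd_ %in% mem))
  }
})

test_that("patch clustering equals the exhaustive subset-merge oracle", {
  # oracle: enumerate every seed subset, keep those with all pairwise
  # distances <= 10, merge overlapping subsets transitively
  subset_oracle <- function(co, seeds) {
    n <- length(seeds)
    d <- as.matrix(stats::dist(co))[seeds, seeds, drop = FALSE]
    groups <- list()
    for (mask in seq_len(2^n - 1)) {
      ii <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
      if (all(d[ii, ii] <= 10)) groups[[length(groups) + 1]] <- ii
    }
    # transitive merge of overlapping admissible subsets
    changed <- TRUE
    while (changed) {
      changed <- FALSE
      for (a in seq_along(groups)) {
        for (b in seq_along(groups)) {
          if (a < b && length(intersect(groups[[a]], groups[[b]]))) {
            groups[[a]] <- sort(union(groups[[a]], groups[[b]]))
            groups[[b]] <- NULL
            changed <- TRUE
            break
          }
        }
        if (changed) break
      }
    }
    lapply(groups, function(ii) sort(seeds[ii]))
  }
  set.seed(7)
  for (trial in 1:25) {
    n <- sample(2:8, 1)
    co <- matrix(runif(3 * n, 0, 22), n, 3)
    conf <- rep(0.9, n)  # everyone is a seed
    p <- cluster_patches(co, conf)
    got <- lapply(p$seeds, sort)
    want <- subset_oracle(co, seq_len(n))
    key <- function(l) sort(vapply(l, paste, character(1), collapse = ","))
    expect_identical(key(got), key(want))
  }
})

test_that("raising the seed threshold never grows the member set", {
  set.seed(13)
  co <- matrix(runif(120, 0, 20), 40, 3)
  conf <- runif(40)
  sizes <- vapply(c(0.3, 0.5, 0.7, 0.9), function(th) {
    p <- cluster_patches(co, conf, seed_threshold = th)
    length(unique(unlist(p$members)))
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("residue conversion applies the strict 30% surface-atom rule", {
  # one residue with 5 surface atoms; vary how many fall in the patch
  atoms <- tibble::tibble(
    serial = 1:7,
    chain = "A",
    resn = c(rep("LYS", 6), "GLY"),
    resi = c(rep(1L, 6), 2L),
    atom = c("CA", "CB", "CG", "CD", "CE", "NZ", "CA"),
    elem = "C",
    x = c(0, 1.53, 2.4, 3.2, 4.1, 4.9, 20), y = 0, z = 0, het = FALSE)
  st <- typed_structure(atoms)
  st$atoms$sasa <- c(1, 1, 1, 1, 1, 0, 1)   # 5 surface atoms in LYS 1
  key <- "A 1  LYS"
  expect_identical(residues_from_patch(c(1, 2), st), key)        # 40% in
  expect_identical(residues_from_patch(c(1), st), character(0))  # 20% in
  # exactly 30% is excluded (strict inequality): 3 of 10 surface atoms
  st10 <- st
  st10$atoms <- dplyr::bind_rows(st$atoms, dplyr::mutate(
    st$atoms[1:5, ], serial = .data$serial + 100L, atom = paste0("X", 1:5)))
  st10$atoms$sasa <- c(1, 1, 1, 1, 1, 0, 1, 1, 1, 1, 1, 1)
  expect_identical(residues_from_patch(c(1, 2, 3), st10), character(0))
  expect_identical(residues_from_patch(c(1, 2, 3, 4), st10), key)
})

test_that("actual binding residues recover the planted pocket contacts", {
  cx <- fx_complex()
  st <- cx$structure
  actual <- actual_binding_residues(st)
  expect_gt(length(actual), 3)
  # oracle from the generator's ground truth: same 30%/5-A rule applied
  # to the truth atom list on the apo surface
  apo <- compute_sasa(strip_ligands(st))
  surf <- surface_atoms(apo)
  a <- apo$atoms
  key <- paste(a$chain, a$resi, a$icode, a$resn)
  truth_idx <- which(a$serial %in% cx$truth_serials)
  n_surf <- table(key[surf])
  n_in <- table(key[intersect(truth_idx, surf)])
  frac <- as.numeric(n_in) / as.numeric(n_surf[names(n_in)])
  want <- sort(names(n_in)[frac > 0.3])
  expect_identical(actual, want)
  # a structure with no ligand has no binding residues
  expect_identical(actual_binding_residues(strip_ligands(st)), character(0))
})

test_that("residue conversion is invariant to atom order", {
  st <- fx_complex()$structure
  members <- surface_atoms(st)[1:40]
  r1 <- residues_from_patch(members, st)
  r2 <- residues_from_patch(rev(members), st)
  expect_identical(r1, r2)
})
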