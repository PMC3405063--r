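# Local frames, interacting-pair extraction, contact filter, templates.

test_that("local frames are right-handed orthonormal bases", {
  st <- fx_two_residues()
  for (i in c(1, 2, 5, 6)) {
    fr <- local_frame(st, i)
    expect_equal(t(fr) %*% fr, diag(3), tolerance = 1e-10)
    expect_equal(det(fr), 1, tolerance = 1e-10)
  }
})

test_that("local frames are equivariant under random rigid rotations", {
  st <- fx_two_residues()
  base <- local_frame(st, 2)
  for (s in 4:6) {
    m <- fx_rigid_motion(s)
    fr <- local_frame(apply_motion(st, m), 2)
    expect_equal(fr, m$R %*% base, tolerance = 1e-8)
  }
})

test_that("a collinear covalent environment falls back to a deterministic frame", {
  # three collinear carbons: centre atom's neighbours give no plane
  atoms <- tibble::tibble(
    serial = 1:3, chain = "A", resn = "ALA", resi = c(1L, 1L, 2L),
    atom = "CB", elem = "C", x = c(0, 1.5, 3.0), y = 0, z = 0, het = FALSE)
  st <- typed_structure(atoms)
  fr <- local_frame(st, 2)
  expect_equal(t(fr) %*% fr, diag(3), tolerance = 1e-10)
  expect_equal(det(fr), 1, tolerance = 1e-10)
  expect_equal(fr, local_frame(st, 2))  # deterministic
})

test_that("the default contact filter rejects apolar-carbon / polar pairs", {
  f <- default_contact_filter()
  expect_false(filter_admits(f, 8L, 11L))   # CH3E vs carboxyl O
  expect_false(filter_admits(f, 34L, 26L))  # ring C vs Lys NH3
  expect_true(filter_admits(f, 8L, 8L))     # C with C
  expect_true(filter_admits(f, 11L, 26L))   # polar with polar
  expect_true(filter_admits(f, 9L, 32L))    # aromatic C with ring O
  expect_true(all(f$matrix == t(f$matrix)))
})

test_that("pair extraction respects the 5-A cutoff strictly", {
  # a lone SER residue plus one water partner at a controlled distance
  mk <- function(d) {
    atoms <- tibble::tibble(
      serial = 1:4, chain = c("A", "A", "A", "W"),
      resn = c("SER", "SER", "SER", "HOH"), resi = c(1L, 1L, 1L, 2L),
      atom = c("CA", "CB", "OG", "O"), elem = c("C", "C", "O", "O"),
      x = c(0, 1.53, 2.33, d), y = c(0, 0, 1.17, 0), z = 0,
      het = c(FALSE, FALSE, FALSE, TRUE))
    compute_sasa(typed_structure(atoms))
  }
  near <- extract_pairs(list(mk(4.9)))
  far <- extract_pairs(list(mk(5.1)))
  expect_true(any(near$partner_type == 31 & near$center_type == 3))
  expect_false(any(far$partner_type == 31 & far$center_type == 3 &
                     abs(far$dx) > 5 - 1e-9))
  # distance of every recorded displacement within the cutoff
  expect_true(all(sqrt(near$dx^2 + near$dy^2 + near$dz^2) <= 5 + 1e-9))
  expect_true(all(sqrt(far$dx^2 + far$dy^2 + far$dz^2) <= 5 + 1e-9))
})

test_that("pair extraction excludes same-residue and 1-2/1-3 covalent partners", {
  st <- fx_two_residues()
  st <- compute_sasa(st)
  pairs <- extract_pairs(list(st))
  # the two residues are 20 A apart: no cross-residue partner in range,
  # and same-residue partners are banned, so no pairs at all
  expect_identical(nrow(pairs), 0L)
})

test_that("with an all-pass filter, extraction equals a brute-force double loop", {
  st <- compute_sasa(fx_complex()$structure)
  open_filter <- default_contact_filter(threshold = Inf)
  pairs <- extract_pairs(list(st), filter = open_filter)
  # brute force on a subset of surface atoms
  a <- st$atoms
  surf <- surface_atoms(st)[1:25]
  co <- cbind(a$x, a$y, a$z)
  excl <- glycosurf:::.covalent_12_13(st$bonds, nrow(a))
  reskey <- paste(a$chain, a$resi, a$icode)
  for (i in surf) {
    expected <- 0L
    for (j in which(!is.na(a$type_id) & !a$is_aglycone)) {
      if (j == i || reskey[j] == reskey[i] || j %in% excl[[i]]) next
      if (sqrt(sum((co[j, ] - co[i, ])^2)) <= 5) expected <- expected + 1L
    }
    # per-centre count: rerun extraction with only this atom on the surface
    st_i <- st
    st_i$atoms$sasa <- ifelse(seq_len(nrow(a)) == i, 1, 0)
    got <- nrow(extract_pairs(list(st_i), filter = open_filter))
    expect_identical(got, expected)
  }
})

test_that("pair extraction is invariant under corpus order", {
  fx <- fx_corpus4()
  p12 <- extract_pairs(fx$structures[c(1, 2)])
  p21 <- extract_pairs(fx$structures[c(2, 1)])
  key <- function(p) sort(paste(p$source, p$center_type, p$partner_type,
                                round(p$dx, 6), round(p$dy, 6),
                                round(p$dz, 6)))
  expect_identical(key(p12), key(p21))
})

test_that("templates are bit-identical under rigid motion of the source", {
  # keep the SASA column fixed: rigid motion does not change the true
  # surface, and the invariant concerns template building
  st <- compute_sasa(fx_complex()$structure)
  moved <- apply_motion(st, fx_rigid_motion(11))
  t1 <- build_templates(extract_pairs(list(st)))
  t2 <- build_templates(extract_pairs(list(moved)))
  expect_identical(names(t1$templates), names(t2$templates))
  for (k in names(t1$templates)) {
    expect_equal(t1$templates[[k]]$grid, t2$templates[[k]]$grid,
                 tolerance = 1e-9)
  }
})

test_that("density templates conserve mass and locate planted modes", {
  # uniform pairs in the shell: mass conservation is exact
  set.seed(5)
  n <- 2000
  d <- matrix(runif(3 * n, -5, 5), ncol = 3)
  d <- d[rowSums(d^2) <= 25, ]
  pairs <- tibble::tibble(center_type = 9L, partner_type = 33L,
                          dx = d[, 1], dy = d[, 2], dz = d[, 3],
                          source = "u")
  tpl <- build_density_template(pairs)
  expect_equal(sum(tpl$grid) * tpl$spacing^3, tpl$total_mass)
  expect_true(all(tpl$grid >= 0))

  # 1000 pairs planted at one offset: mode at that voxel
  planted <- generate_pair_fixture(
    1000, tibble::tibble(center_type = 9L, partner_type = 33L,
                         dx = 2, dy = -1, dz = 3, sd = 0.05), seed = 2)
  tp <- build_density_template(planted, sigma = 0.5)
  m <- which(tp$grid == max(tp$grid), arr.ind = TRUE)
  ax <- tp$axis
  expect_equal(c(ax[m[1, 1]], ax[m[1, 2]], ax[m[1, 3]]), c(2, -1, 3))

  # empty input: all-zero grid flagged empty
  te <- build_density_template(pairs[0, ])
  expect_true(te$empty)
  expect_equal(te$total_mass, 0)
  expect_true(all(te$grid == 0))
})
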