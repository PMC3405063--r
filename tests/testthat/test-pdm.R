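# PDM projection: placement, exclusion, conservation, equivariance.

# A minimal query with a single surface atom of known type and frame.
.pdm_query <- function() {
  atoms <- tibble::tibble(
    serial = 1:3, chain = "A", resn = "SER", resi = 1L,
    atom = c("CA", "CB", "OG"), elem = c("C", "C", "O"),
    x = c(0, 1.53, 2.33), y = c(0, 0, 1.17), z = 0, het = FALSE)
  compute_sasa(typed_structure(atoms, id = "query"))
}

# A near-delta template set: one (center, partner) pair planted at `off`.
.delta_templates <- function(center, partner, off, sigma = 0) {
  pairs <- tibble::tibble(center_type = center, partner_type = partner,
                          dx = off[1], dy = off[2], dz = off[3],
                          source = "db")
  pairs <- pairs[rep(1, 50), ]
  build_templates(pairs, sigma = sigma)
}

test_that("a delta-like template lands at frame * offset + atom position", {
  st <- .pdm_query()
  ct <- st$atoms$type_id[2]  # CB
  off <- c(2, 1, -1)
  tpl <- .delta_templates(ct, 33L, off)
  # silence the other surface atoms so only CB projects
  st$atoms$sasa <- c(0, 1, 0)
  pdm <- project_pdm(st, tpl)
  w <- which(pdm$g == max(pdm$g), arr.ind = TRUE)
  expect_identical(unname(w[1, 4]), 33L)
  peak <- pdm$origin + (w[1, 1:3] - 1) * pdm$spacing
  fr <- local_frame(st, 2)
  target <- c(st$atoms$x[2], st$atoms$y[2], st$atoms$z[2]) +
    as.vector(fr %*% off)
  expect_lt(sqrt(sum((peak - target)^2)), sqrt(3) / 2 + 1e-9)
  # total mass equals the template mass (one contributing atom)
  expect_equal(pdm_mass(pdm), tpl$templates[[paste0(ct, "_33")]]$total_mass,
               tolerance = 1e-6)
})

test_that("leave-query-out on a database built from the query alone gives a zero PDM", {
  st <- compute_sasa(fx_complex()$structure)
  pairs <- extract_pairs(list(st))
  tpl <- build_templates(pairs, exclude_sources = st$id)
  expect_identical(length(tpl$templates), 0L)
  pdm <- project_pdm(st, tpl)
  expect_true(all(pdm$g == 0))
})

test_that("projected grid mass is conserved within discretisation tolerance", {
  # low-smoothing templates with interior offsets keep mass inside the mask
  st <- compute_sasa(fx_complex()$structure)
  surf <- surface_atoms(st)
  types <- unique(st$atoms$type_id[surf])
  offsets <- tibble::tibble(
    center_type = rep(types[1:3], each = 2),
    partner_type = rep(c(33L, 34L), 3),
    dx = c(1, -2, 2, 0, -1, 1), dy = c(2, 1, 0, 2, -2, 0),
    dz = c(-1, 1, 1, -2, 0, 2), sd = 0.2)
  pairs <- generate_pair_fixture(300, offsets, seed = 9)
  tpl <- build_templates(pairs, sigma = 0.3)
  pdm <- project_pdm(st, tpl)
  n_by_type <- table(factor(st$atoms$type_id[surf], levels = 1:36))
  expected <- sum(vapply(names(tpl$templates), function(k) {
    ct <- as.integer(strsplit(k, "_")[[1]][1])
    tpl$templates[[k]]$total_mass * n_by_type[[as.character(ct)]]
  }, numeric(1)))
  expect_equal(pdm_mass(pdm), expected, tolerance = 0.02)
})

test_that("PDM sums are equivariant under rigid motion of the query", {
  fx <- fx_corpus4()
  st <- fx$structures[[1]]
  tpl <- build_templates(fx$pairs, exclude_sources = st$id)
  pdm <- project_pdm(st, tpl)
  surf <- surface_atoms(st)
  S0 <- pdm_sums(pdm, cbind(st$atoms$x, st$atoms$y, st$atoms$z)[surf, ])
  m <- fx_rigid_motion(3)
  stm <- apply_motion(st, m)
  pdm_m <- project_pdm(stm, tpl)
  S1 <- pdm_sums(pdm_m, cbind(stm$atoms$x, stm$atoms$y, stm$atoms$z)[surf, ])
  scale <- max(S0)
  expect_gt(scale, 0)
  expect_lt(max(abs(S1 - S0)) / scale, 0.05)
})

test_that("adding a structure to the database never decreases channel values", {
  fx <- fx_corpus4()
  st <- fx$structures[[1]]
  p_small <- fx$pairs[fx$pairs$source == fx$structures[[2]]$id, ]
  p_big <- fx$pairs[fx$pairs$source %in% c(fx$structures[[2]]$id,
                                           fx$structures[[3]]$id), ]
  # monotonicity holds at the raw-count scale: undo the per-pair
  # normalisation by multiplying each template grid by its pair count
  raw <- function(p) {
    tp <- build_templates(p)
    for (k in names(tp$templates)) {
      tp$templates[[k]]$grid <- tp$templates[[k]]$grid *
        tp$templates[[k]]$n_pairs
    }
    project_pdm(st, tp)$g
  }
  expect_true(all(raw(p_big) - raw(p_small) >= -1e-9))
})

test_that("pdm_sum matches a brute-force voxel loop", {
  fx <- fx_corpus4()
  st <- fx$structures[[1]]
  tpl <- build_templates(fx$pairs, exclude_sources = st$id)
  pdm <- project_pdm(st, tpl)
  surf <- surface_atoms(st)
  pt <- c(st$atoms$x[surf[5]], st$atoms$y[surf[5]], st$atoms$z[surf[5]])
  got <- pdm_sum(pdm, pt, channel = 33L)
  # brute force over every voxel of the grid
  d3 <- pdm$dim
  acc <- 0
  for (ix in seq_len(d3[1])) for (iy in seq_len(d3[2])) {
    zvals <- pdm$g[ix, iy, , 33L]
    nzz <- which(zvals != 0)
    for (iz in nzz) {
      p <- pdm$origin + (c(ix, iy, iz) - 1) * pdm$spacing
      r <- sqrt(sum((p - pt)^2))
      if (r <= 5) acc <- acc + (1 - r / 5) * zvals[iz]
    }
  }
  expect_equal(got, acc, tolerance = 1e-9)
  # an all-zero channel sums to zero
  empty_ch <- which(vapply(1:36, function(j) all(pdm$g[, , , j] == 0),
                           logical(1)))[1]
  expect_identical(pdm_sum(pdm, pt, channel = empty_ch), 0)
})

test_that("OpenDX channel export round-trips the voxel count", {
  fx <- fx_corpus4()
  st <- fx$structures[[1]]
  tpl <- build_templates(fx$pairs, exclude_sources = st$id)
  pdm <- project_pdm(st, tpl)
  tf <- withr::local_tempfile(fileext = ".dx")
  write_pdm_dx(pdm, 33L, tf)
  lines <- readLines(tf)
  expect_match(lines[1], sprintf("counts %d %d %d", pdm$dim[1], pdm$dim[2],
                                 pdm$dim[3]))
  vals <- as.numeric(strsplit(lines[8], " ")[[1]])
  expect_identical(length(vals), as.integer(prod(pdm$dim)))
  expect_equal(sum(vals), sum(pdm$g[, , , 33L]), tolerance = 1e-4)
})
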