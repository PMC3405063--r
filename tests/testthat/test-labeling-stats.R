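# Binding labels, rank-sum screening, correlation profiles.

test_that("atoms are labelled by sugar proximity with aglycone exclusion", {
  # protein atoms at controlled distances from a sugar atom and an
  # aglycone atom
  cx <- generate_toy_complex(pocket_spec(aglycone = TRUE, seed = 77))
  st <- compute_sasa(cx$structure)
  lab <- label_atoms(st)
  a <- st$atoms
  surf <- surface_atoms(st)
  expect_identical(lab$atom_idx, surf)
  co <- cbind(a$x, a$y, a$z)
  sug <- which(a$is_carb)
  agl <- which(a$is_aglycone)
  expect_gt(length(agl), 0)
  dmin_sugar <- apply(co[surf, , drop = FALSE], 1, function(p) {
    min(sqrt(colSums((t(co[sug, , drop = FALSE]) - p)^2)))
  })
  expect_identical(lab$label, dmin_sugar <= 5 + 1e-9)
  # an atom near only the aglycone must be negative
  near_agl_only <- which(!lab$label &
    apply(co[surf, , drop = FALSE], 1, function(p) {
      min(sqrt(colSums((t(co[agl, , drop = FALSE]) - p)^2)))
    }) <= 5)
  expect_true(all(!lab$label[near_agl_only]))
  # buried atoms carry no label row at all
  buried <- which(a$is_protein & a$sasa == 0)
  expect_identical(length(intersect(lab$atom_idx, buried)), 0L)
})

test_that("labelling a ligand-free structure warns and returns all negatives", {
  st <- compute_sasa(strip_ligands(fx_complex()$structure))
  expect_warning(lab <- label_atoms(st), "no carbohydrate")
  expect_true(all(!lab$label))
})

test_that("the rank-sum test reproduces exact enumeration on small samples", {
  # enumeration oracle: all C(6,3) = 20 assignments of ranks
  ranksum_exact <- function(x, y) {
    pooled <- c(x, y)
    r <- rank(pooled)
    w_obs <- sum(r[seq_along(x)])
    combos <- utils::combn(length(pooled), length(x))
    ws <- apply(combos, 2, function(ii) sum(r[ii]))
    mu <- length(x) * (length(pooled) + 1) / 2
    mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9)
  }
  x <- c(1, 2, 3); y <- c(4, 5, 6)
  expect_equal(ranksum_exact(x, y), 0.1)
  u <- mann_whitney_u(x, y)
  expect_equal(u$p_value, 0.1)
  expect_identical(u$sign, "-")
  u_rev <- mann_whitney_u(y, x)
  expect_equal(u_rev$p_value, 0.1)
  expect_identical(u_rev$sign, "+")
  # random small samples against the oracle
  set.seed(3)
  for (trial in 1:20) {
    x <- round(runif(sample(3:6, 1), 0, 100), 3)
    y <- round(runif(sample(3:6, 1), 0, 100), 3)
    expect_equal(mann_whitney_u(x, y)$p_value, ranksum_exact(x, y),
                 tolerance = 1e-9)
  }
})

test_that("identical samples are statistically indistinguishable (p = 1)", {
  u <- mann_whitney_u(c(2, 2, 2), c(2, 2, 2))
  expect_equal(u$p_value, 1)
})

test_that("exact and normal-approximation branches agree within 0.02 at n = 7-8", {
  set.seed(11)
  for (trial in 1:20) {
    x <- rnorm(sample(7:8, 1))
    y <- rnorm(sample(7:8, 1), mean = runif(1, 0, 1.5))
    p_exact <- mann_whitney_u(x, y, exact_max = 8L)$p_value
    p_approx <- mann_whitney_u(x, y, exact_max = 0L)$p_value
    expect_lt(abs(p_exact - p_approx), 0.02)
  }
})

test_that("the significance screen spans 30 x 37 and flags planted shifts", {
  # synthetic feature table: one atom type with a 3-sigma shifted attribute
  set.seed(21)
  n_pos <- 50; n_neg <- 500
  ft <- tibble::tibble(type_id = rep(9L, n_pos + n_neg),
                       label = rep(c(TRUE, FALSE), c(n_pos, n_neg)))
  for (j in 1:37) {
    base <- rnorm(n_pos + n_neg)
    ft[[paste0("A", j)]] <- base
    ft[[paste0("a", j)]] <- base
  }
  ft$A5 <- ft$A5 + 3 * ft$label  # attribute 5 shifted by 3 sigma
  sig <- significance_screen(ft, value = "A")
  expect_identical(nrow(sig), 30L * 37L)
  row5 <- sig[sig$type_id == 9 & sig$attribute == 5, ]
  expect_lt(row5$p_value, 0.025)
  expect_identical(row5$sign, "+")
  # absent atom types are marked missing
  expect_true(all(is.na(sig$p_value[sig$type_id != 9])))
  # an identical-across-classes attribute is near p = 1 territory
  expect_gt(sig$p_value[sig$type_id == 9 & sig$attribute == 6], 0.025)
})

test_that("correlation profiles match the covariance formula and handle constants", {
  set.seed(2)
  n <- 80
  ft <- tibble::tibble(type_id = rep(9L, n))
  for (j in 1:37) ft[[paste0("a", j)]] <- rnorm(n)
  ft$a3 <- seq_len(n) / n
  resp <- ft$a3                       # r = 1 against itself
  prof <- correlation_profile(ft, resp)
  expect_equal(prof$r[prof$attribute == 3], 1)
  prof_neg <- correlation_profile(ft, -resp)
  expect_equal(prof_neg$r[prof_neg$attribute == 3], -1)
  # covariance-formula oracle for a random attribute
  v <- ft$a7
  oracle <- sum((v - mean(v)) * (resp - mean(resp))) /
    sqrt(sum((v - mean(v))^2) * sum((resp - mean(resp))^2))
  expect_equal(prof$r[prof$attribute == 7], oracle, tolerance = 1e-12)
  # zero-variance attribute flagged and reported as 0
  ft$a9 <- 1
  prof0 <- correlation_profile(ft, resp)
  expect_equal(prof0$r[prof0$attribute == 9], 0)
  expect_true(prof0$constant[prof0$attribute == 9])
})

test_that("significance export writes signed log10 p-values", {
  ft <- tibble::tibble(type_id = rep(3L, 40),
                       label = rep(c(TRUE, FALSE), 20))
  for (j in 1:37) {
    v <- rnorm(40)
    ft[[paste0("A", j)]] <- v
    ft[[paste0("a", j)]] <- v
  }
  sig <- significance_screen(ft, value = "A")
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_significance_tsv(sig, tf)
  tab <- utils::read.delim(tf)
  expect_identical(nrow(tab), 30L)
  expect_identical(ncol(tab), 38L)
})
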