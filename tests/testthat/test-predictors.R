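# Classifier training: subsampling, thresholds, the three model families,
# cross-validation splits.

# Two-class Gaussian blobs in the 37-dimensional attribute space;
# .blobs is well separated, .blobs2 exposes the noise scale.
.blobs2 <- function(n_pos, n_neg, delta = 6, seed = 1, sd = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_pos * 37, mean = delta / 2, sd = sd), n_pos),
             matrix(rnorm(n_neg * 37, mean = -delta / 2, sd = sd), n_neg))
  x <- (x - min(x)) / (max(x) - min(x))  # into [0, 1] like scaled attributes
  list(x = x, y = rep(c(TRUE, FALSE), c(n_pos, n_neg)))
}
.blobs <- function(n_pos, n_neg, delta = 6, seed = 1) {
  .blobs2(n_pos, n_neg, delta = delta, seed = seed, sd = 0.5)
}

test_that("negative subsampling keeps all positives at the stated ratio", {
  labels <- rep(c(TRUE, FALSE), c(10, 100))
  idx <- subsample_training_set(labels, ratio = 2, seed = 4)
  expect_identical(length(idx), 30L)                 # 10 pos + 20 neg
  expect_true(all(which(labels) %in% idx))
  # negative exhaustion caps the sample
  labels2 <- rep(c(TRUE, FALSE), c(10, 5))
  idx2 <- subsample_training_set(labels2, ratio = 2, seed = 4)
  expect_identical(length(idx2), 15L)
  # determinism by seed
  expect_identical(idx, subsample_training_set(labels, ratio = 2, seed = 4))
  expect_error(subsample_training_set(rep(FALSE, 5), 2, 1), "positive")
})

test_that("both single-model families separate clean blobs perfectly", {
  b <- .blobs(40, 80)
  for (alg in c("ann", "svm")) {
    m <- train_model(b$x, b$y, algorithm = alg, seed = 5)
    p <- predict(m, b$x)
    expect_true(all(p >= 0 & p <= 1))
    expect_equal(glycosurf:::.mcc_at(p, b$y, 0.5), 1)
  }
  expect_error(train_model(b$x, rep(TRUE, nrow(b$x)), "ann"), "single class")
})

test_that("model training is reproducible for a fixed seed", {
  b <- .blobs(20, 40)
  m1 <- train_model(b$x, b$y, "ann", seed = 9)
  m2 <- train_model(b$x, b$y, "ann", seed = 9)
  expect_identical(predict(m1, b$x), predict(m2, b$x))
})

test_that("threshold selection maximises MCC and breaks ties downward", {
  expect_equal(select_threshold(c(0.9, 0.1), c(TRUE, FALSE)), 0.5)
  # degenerate: all outputs equal
  expect_equal(select_threshold(rep(0.4, 6), rep(c(TRUE, FALSE), 3)), 0.4)
  # one-class validation set falls back to 0.5 with a warning
  expect_warning(t1 <- select_threshold(runif(5), rep(TRUE, 5)), "one class")
  expect_equal(t1, 0.5)
  # exhaustive-scan oracle on random 50-case sets
  set.seed(17)
  for (trial in 1:10) {
    o <- round(runif(50), 2)
    l <- runif(50) < 0.4
    if (length(unique(l)) < 2) next
    got <- select_threshold(o, l)
    u <- sort(unique(o))
    cand <- if (length(u) == 1) u else (u[-1] + u[-length(u)]) / 2
    mccs <- vapply(cand, function(t) glycosurf:::.mcc_at(o, l, t), numeric(1))
    expect_equal(got, cand[which.max(mccs)])
    expect_equal(glycosurf:::.mcc_at(o, l, got), max(mccs))
  }
})

test_that("bagged training uses all positives plus 1.5x negatives per bag", {
  b <- .blobs(30, 120, seed = 3)
  bv <- .blobs(15, 60, seed = 4)
  cfg <- default_config()
  cfg$training$bags <- 5L  # smaller ensemble for speed; ratio unchanged
  m <- train_bagged(b$x, b$y, bv$x, bv$y, config = cfg, seed = 2)
  expect_identical(length(m$nets), 5L)
  pos <- which(b$y)
  for (bag in m$bags) {
    expect_true(all(pos %in% bag))
    expect_identical(length(bag),
                     length(pos) + as.integer(round(1.5 * length(pos))))
  }
  p <- predict(m, bv$x)
  expect_true(all(p >= 0 & p <= 1))
  expect_equal(glycosurf:::.mcc_at(p, bv$y, 0.5), 1)
  # bagged MCC is within 0.1 of the best single bag on a separable fixture
  best_single <- max(vapply(m$nets, function(nt) {
    glycosurf:::.mcc_at(glycosurf:::.nn_forward(nt, bv$x), bv$y, 0.5)
  }, numeric(1)))
  bag_mcc <- glycosurf:::.mcc_at(p, bv$y, 0.5)
  expect_gte(bag_mcc, best_single - 0.1)
})

test_that("averaging identical bag members equals the single-member output", {
  b <- .blobs(10, 20)
  m <- train_model(b$x, b$y, "ann", seed = 1)
  fake <- structure(list(algorithm = "ann_bagging",
                         nets = rep(list(m$fit), 20),
                         bags = rep(list(seq_len(nrow(b$x))), 20)),
                    class = c("glyco_bagged", "glyco_model"))
  expect_equal(predict(fake, b$x), predict(m, b$x), tolerance = 1e-12)
})

test_that("bag-output spread shrinks as bag training sets grow", {
  # overlapping classes so individual bags genuinely disagree
  mk <- function(n_pos, seed) .blobs2(n_pos, 4 * n_pos, delta = 1, seed = seed)
  spread <- function(n_pos) {
    b <- mk(n_pos, 6)
    bv <- .blobs2(30, 60, delta = 1, seed = 999)
    cfg <- default_config()
    cfg$training$bags <- 15L
    m <- train_bagged(b$x, b$y, bv$x, bv$y, config = cfg, seed = 5)
    outs <- vapply(m$nets, function(nt) glycosurf:::.nn_forward(nt, bv$x),
                   numeric(nrow(bv$x)))
    mean(apply(outs, 1, stats::sd))
  }
  expect_lt(spread(150), spread(5))
})

test_that("10-fold splits partition proteins 8/1/1 with zero leakage", {
  ids <- sprintf("prot%02d", 1:10)
  folds <- crossval_folds(ids, k = 10, seed = 3)
  expect_setequal(folds$id, ids)
  test_sets <- list()
  for (f in 1:10) {
    fr <- fold_roles(folds, f)
    expect_identical(sum(fr$role == "train"), 8L)
    expect_identical(sum(fr$role == "validation"), 1L)
    expect_identical(sum(fr$role == "test"), 1L)
    expect_identical(length(intersect(fr$id[fr$role == "train"],
                                      fr$id[fr$role == "test"])), 0L)
    test_sets[[f]] <- fr$id[fr$role == "test"]
  }
  # union of test folds covers the corpus exactly once
  expect_setequal(unlist(test_sets), ids)
  expect_identical(anyDuplicated(unlist(test_sets)), 0L)
  expect_error(crossval_folds(ids[1:9], k = 10), "at least 10")
})
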