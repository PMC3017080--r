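test_that("discretize maps tails, middles, missings and constants", {
  # two distinct values pass through as categories: the outlier alone
  # occupies the top state
  d <- discretize(c(0, 0, 0, 10))
  expect_equal(d[1:3], rep(d[1], 3))
  expect_true(d[4] > d[1])
  # mean-sigma binning on a genuinely continuous vector:
  # mean 21.2, sd ~44.1, so only the outlier exceeds mean + sd
  expect_equal(discretize(c(0, 1, 2, 3, 100)), c(2L, 2L, 2L, 2L, 3L))
  expect_warning(d <- discretize(c(5, 5, 5)), "constant")
  expect_equal(d, c(2L, 2L, 2L))
  # missing values get their own category, never a numeric bin
  d <- discretize(c(1, NA, 2, 100, -100, 3, 4))
  expect_equal(d[2], 0L)
  expect_true(all(d[-2] > 0L))
  expect_error(discretize(c(NA, NA, 1)), "non-missing")
})

test_that("mutual information matches hand values and is symmetric", {
  expect_equal(mutual_information(c(0, 0, 1, 1), c(0, 0, 1, 1)), 1)
  expect_equal(mutual_information(c(0, 1, 0, 1), c(0, 0, 1, 1)), 0)
  set.seed(4)
  for (rep in 1:20) {
    x <- sample(1:3, 15, TRUE)
    y <- sample(1:4, 15, TRUE)
    expect_equal(mutual_information(x, y), mutual_information(y, x),
                 tolerance = 1e-12)
    expect_equal(mutual_information(x, y), mi_oracle(x, y), tolerance = 1e-12)
    # MI is invariant to monotone relabeling of the bins
    expect_equal(mutual_information(4 - x, y), mutual_information(x, y),
                 tolerance = 1e-12)
  }
})

test_that("relevance and redundancy reduce to MI means", {
  y <- c(0, 0, 1, 1, 1, 0)
  f <- c(1, 1, 0, 0, 0, 1)
  expect_equal(relevance(f, y), mutual_information(f, y))
  expect_equal(redundancy(f, list(f)), mi_oracle(f, f), tolerance = 1e-12)
  expect_equal(redundancy(f, list()), 0)
  a <- c(0, 1, 0, 1, 0, 1); b <- c(1, 1, 0, 0, 1, 1)
  expect_equal(redundancy(f, list(a, b)),
               (mutual_information(f, a) + mutual_information(f, b)) / 2,
               tolerance = 1e-12)
})

test_that("the worked 6x4 fixture is ranked exactly as the greedy oracle", {
  wet <- worked_example_tables()
  rk <- mrmr_rank(wet$mrmr$x, wet$mrmr$labels)
  # frozen oracle-verified order: f1 by relevance; the perfectly redundant
  # f2 still precedes f3/f4 because all round-2 difference scores are 0 and
  # ties break by higher relevance
  expect_identical(rk$order, c("f1", "f2", "f3", "f4"))
  cols <- lapply(seq_len(4), function(j) wet$mrmr$x[, j])
  names(cols) <- colnames(wet$mrmr$x)
  expect_identical(rk$order, mrmr_oracle(cols, as.integer(wet$mrmr$labels)))
  # round-1 reduction: first selected feature maximizes relevance
  rels <- vapply(cols, function(f)
    relevance(f, as.integer(wet$mrmr$labels)), numeric(1))
  expect_equal(rk$relevance[[1]], max(rels))
})

test_that("a duplicate with strictly lower criterion never precedes an informative feature", {
  # frozen fixture: fb duplicates fa (selected first); its round-2 score is
  # strictly below fc's and fd's, so the oracle order ends with fb
  y <- c(0, 0, 0, 0, 1, 1, 1, 1)
  x <- feature_matrix(cbind(
    fa = c(1, 1, 0, 1, 0, 1, 0, 0),
    fb = c(1, 1, 0, 1, 0, 1, 0, 0),
    fc = c(1, 1, 0, 0, 0, 0, 0, 1),
    fd = c(0, 0, 1, 0, 0, 0, 0, 1)), sample_ids = paste0("s", 1:8))
  rk <- mrmr_rank(x, factor(y, labels = c("low", "high")))
  expect_identical(rk$order, c("fa", "fc", "fd", "fb"))
})

test_that("mrmr_rank equals the exhaustive re-derivation oracle on random pools", {
  set.seed(77)
  for (rep in 1:50) {
    n <- sample(6:12, 1)
    p <- sample(3:8, 1)
    repeat {
      y <- sample(c("low", "high"), n, TRUE)
      if (length(unique(y)) == 2) break
    }
    vals <- matrix(sample(0:2, n * p, TRUE), n, p)
    x <- feature_matrix(vals, sample_ids = paste0("s", 1:n),
                        feature_names = paste0("f", 1:p))
    rk <- suppressWarnings(mrmr_rank(x, factor(y, levels = c("low", "high"))))
    cols <- lapply(seq_len(p), function(j) {
      suppressWarnings(discretize(x[, j]))
    })
    names(cols) <- colnames(x)
    yl <- as.integer(factor(y, levels = c("low", "high")))
    expect_identical(rk$order, mrmr_oracle(cols, yl))
  }
})

test_that("the ranking is invariant to feature column order", {
  set.seed(15)
  n <- 12; p <- 6
  x <- feature_matrix(matrix(rnorm(n * p), n, p),
                      sample_ids = paste0("s", 1:n),
                      feature_names = paste0("f", 1:p))
  y <- factor(rep(c("low", "high"), each = 6), levels = c("low", "high"))
  rk1 <- mrmr_rank(x, y)
  perm <- sample(p)
  rk2 <- mrmr_rank(x[, perm], y)
  expect_identical(rk1$order, rk2$order)
  expect_equal(rk1$relevance, rk2$relevance)
})

test_that("mrmr_rank validates its inputs", {
  wet <- worked_example_tables()
  expect_error(mrmr_rank(wet$mrmr$x, wet$mrmr$labels, top_k = 0), "top_k")
  expect_error(mrmr_rank(wet$mrmr$x, wet$mrmr$labels, top_k = 5), "top_k")
  expect_error(mrmr_rank(wet$mrmr$x, factor(rep("low", 6),
                                            levels = c("low", "high"))),
               "both classes")
})
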