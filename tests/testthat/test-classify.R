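test_that("cosine distance matches hand values and handles zero vectors", {
  expect_equal(cosine_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(cosine_distance(c(1, 0), c(0, 1)), 1)
  expect_equal(cosine_distance(c(1, 0), c(1, 1)), 1 - 1 / sqrt(2),
               tolerance = 1e-12)
  expect_equal(cosine_distance(c(1, 0), c(-1, 0)), 2)
  expect_warning(d <- cosine_distance(c(0, 0), c(1, 1)), "zero")
  expect_equal(d, 2)
  expect_error(cosine_distance(1:2, 1:3), "length")
})

test_that("nna_predict picks the nearest row with earliest-index ties", {
  train <- rbind(c(1, 0), c(0, 1))
  expect_equal(nna_predict(train, c("low", "high"), c(1, 0.1)), "low")
  expect_equal(nna_predict(train, c("low", "high"), c(0.1, 1)), "high")
  # exact tie: rows 1 and 2 equidistant -> earliest training row
  expect_equal(nna_predict(rbind(c(1, 0), c(0, 1)), c("a", "b"), c(1, 1)), "a")
  # query equal to a training row returns that row's label
  expect_equal(nna_predict(train, c("low", "high"), c(0, 1)), "high")
  expect_error(nna_predict(train[0, , drop = FALSE], character(0), c(1, 2)),
               "empty")
})

test_that("nna_predict equals an exhaustive-scan oracle on random instances", {
  set.seed(31)
  for (rep in 1:100) {
    n <- sample(2:50, 1)
    d <- sample(2:20, 1)
    train <- matrix(rnorm(n * d), n, d)
    labels <- sample(c("low", "high"), n, TRUE)
    query <- rnorm(d)
    expect_identical(nna_predict(train, labels, query),
                     nna_oracle(train, labels, query))
  }
})

test_that("jackknife accuracy reproduces the hand-checked layouts", {
  wet <- worked_example_tables()
  # each point's nearest neighbor is its class partner
  r <- jackknife_accuracy(wet$nna$x, wet$nna$labels, scale = "none")
  expect_equal(r$accuracy, 1)
  expect_equal(r$correct_high, 2L)
  expect_equal(r$correct_low, 2L)
  expect_equal(r$accuracy,
               (r$correct_high + r$correct_low) / (r$n_high + r$n_low))

  # two identical points with opposite labels predict each other's label
  x <- feature_matrix(rbind(c(1, 1), c(1, 1)), paste0("s", 1:2), c("a", "b"))
  labs <- factor(c("low", "high"), levels = c("low", "high"))
  expect_equal(jackknife_accuracy(x, labs, scale = "none")$accuracy, 0)

  # determinism
  r2 <- jackknife_accuracy(wet$nna$x, wet$nna$labels, scale = "none")
  expect_identical(r$predictions, r2$predictions)
})

test_that("jackknife matches a naive leave-one-out reimplementation", {
  set.seed(55)
  n <- 25; p <- 6
  x <- feature_matrix(matrix(rnorm(n * p), n, p), paste0("s", 1:n),
                      paste0("f", 1:p))
  x[sample(length(x), 15)] <- NA
  labs <- factor(sample(c("low", "high"), n, TRUE, prob = c(0.5, 0.5)),
                 levels = c("low", "high"))
  while (nlevels(droplevels(labs)) < 2) {
    labs <- factor(sample(c("low", "high"), n, TRUE), levels = c("low", "high"))
  }
  for (sc in c("minmax", "none")) {
    got <- jackknife_accuracy(x, labs, scale = sc)
    naive <- vapply(seq_len(n), function(i) {
      tr <- x[-i, , drop = FALSE]; q <- x[i, ]
      mu <- colMeans(tr, na.rm = TRUE); mu[is.nan(mu)] <- 0
      for (j in seq_len(p)) tr[is.na(tr[, j]), j] <- mu[j]
      q[is.na(q)] <- mu[is.na(q)]
      if (sc == "minmax") {
        mn <- apply(tr, 2, min); mx <- apply(tr, 2, max)
        rng <- mx - mn; rng[rng <= 0] <- 1
        tr <- sweep(sweep(tr, 2, mn), 2, rng, "/")
        q <- (q - mn) / rng
      }
      as.character(nna_oracle(tr, as.character(labs[-i]), q))
    }, character(1))
    expect_identical(as.character(got$predictions), naive)
  }
})

test_that("the IFS curve evaluates exactly one nested model per size", {
  wet <- worked_example_tables()
  rk <- mrmr_rank(wet$mrmr$x, wet$mrmr$labels)
  curve <- ifs(wet$mrmr$x, wet$mrmr$labels, rk, k_max = 4)
  expect_s3_class(curve, "ifs_curve")
  expect_equal(curve$k, 1:4)
  expect_true(all(curve$accuracy >= 0 & curve$accuracy <= 1))
  # k_max = 1 uses only the top feature
  c1 <- ifs(wet$mrmr$x, wet$mrmr$labels, rk, k_max = 1)
  expect_equal(nrow(c1), 1L)
  expect_equal(c1$accuracy,
               jackknife_accuracy(wet$mrmr$x, wet$mrmr$labels,
                                  rk$order[1])$accuracy)
  expect_error(ifs(wet$mrmr$x, wet$mrmr$labels, rk, k_max = 0), "k_max")
  expect_error(ifs(wet$mrmr$x, wet$mrmr$labels, rk, k_max = 9), "k_max")
})

test_that("optimal_feature_set takes the accuracy peak, ties to smaller k", {
  rk <- structure(list(order = c("a", "b", "c"),
                       relevance = c(a = 1, b = 0.5, c = 0.1),
                       score = c(a = 1, b = 0.2, c = 0)),
                  class = "ranked_features")
  curve <- structure(
    data.frame(k = 1:3, accuracy = c(0.6, 0.7, 0.7),
               correct_high = 0L, correct_low = 0L),
    ranking = rk, class = c("ifs_curve", "data.frame"))
  opt <- optimal_feature_set(curve)
  expect_equal(opt$k, 2)
  expect_equal(opt$accuracy, 0.7)
  expect_identical(opt$features, c("a", "b"))

  mono <- curve; mono$accuracy <- c(0.5, 0.6, 0.9)
  expect_equal(optimal_feature_set(mono)$k, 3)
  single <- curve[1, ]
  attr(single, "ranking") <- rk
  class(single) <- c("ifs_curve", "data.frame")
  expect_equal(optimal_feature_set(single)$k, 1)
})

test_that("jackknife rejects invalid subsets and degenerate inputs", {
  wet <- worked_example_tables()
  expect_error(jackknife_accuracy(wet$nna$x, wet$nna$labels, "nope"),
               "absent")
  expect_error(
    jackknife_accuracy(wet$nna$x,
                       factor(rep("low", 4), levels = c("low", "high"))),
    "both classes")
})
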