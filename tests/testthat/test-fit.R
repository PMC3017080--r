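test_that("featurize_orfs concatenates families in the documented order", {
  ds <- small_planted()
  expect_message(
    x <- featurize_orfs(ds$records, ds$network, ds$annotations),
    "codon=64.*protein=132.*start=24.*other=10"
  )
  n_terms <- length(ds$annotations$term_to_genes)
  expect_equal(ncol(x), 64 + n_terms + 132 + 24 + 10)
  expect_equal(nrow(x), length(ds$records))
  # family order: codon block first, auxiliary block last
  expect_identical(colnames(x)[1:64], codon_table())
  expect_identical(colnames(x)[(ncol(x) - 9):ncol(x)],
                   c("cds_length", "utr5_length", "utr3_length", "tf_count",
                     "rbp_count", "protein_abundance", "mrna_half_life",
                     "protein_half_life", "utr5_free_energy",
                     "tss_window_free_energy"))

  # disabling a family removes exactly its columns
  xc <- suppressMessages(featurize_orfs(ds$records, families = "codon"))
  expect_equal(ncol(xc), 64L)
  xng <- suppressMessages(
    featurize_orfs(ds$records, families = c("codon", "protein", "start",
                                            "other")))
  expect_equal(ncol(xng), 64 + 132 + 24 + 10)
  expect_identical(x[, colnames(xng)], xng)

  expect_error(suppressMessages(featurize_orfs(ds$records, families = "go")),
               "network")
})

test_that("te_fit returns a complete model object with working methods", {
  ds <- small_planted()
  x <- suppressMessages(
    featurize_orfs(ds$records, ds$network, ds$annotations))
  fit <- te_fit(x, rates = ds$rates, top_k = 15, k_max = 10)

  expect_s3_class(fit, "te_fit")
  expect_length(fit$ranking$order, 15L)
  expect_equal(nrow(fit$curve), 10L)
  expect_equal(fit$optimal$k, fit$curve$k[which.max(fit$curve$accuracy)])
  expect_identical(fit$optimal$features,
                   fit$ranking$order[seq_len(fit$optimal$k)])
  expect_equal(nrow(fit$correlations), fit$optimal$k)

  expect_output(print(fit), "optimal subset")
  s <- summary(fit)
  expect_s3_class(s, "summary.te_fit")
  expect_output(print(s), "IFS peak")
  co <- coef(fit)
  expect_named(co, fit$correlations$feature)

  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("predict.te_fit classifies training rows consistently", {
  ds <- small_planted()
  x <- suppressMessages(
    featurize_orfs(ds$records, ds$network, ds$annotations))
  fit <- te_fit(x, rates = ds$rates, top_k = 15, k_max = 10)
  pred <- predict(fit, x)
  expect_s3_class(pred, "factor")
  expect_identical(levels(pred), c("low", "high"))
  # resubstitution: each row is its own nearest neighbor
  expect_identical(as.character(pred), as.character(fit$labels))
  expect_error(predict(fit, x[, 1:3]), "lacks")
})

test_that("run_pipeline writes every artifact plus a reproducible manifest", {
  ds <- small_planted()
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  fit <- suppressMessages(
    run_pipeline(ds, out1, top_k = 12, k_max = 8, seed = 1L))
  suppressMessages(run_pipeline(ds, out2, top_k = 12, k_max = 8, seed = 1L))

  files <- c("features.tsv", "ranking.tsv", "ifs_curve.tsv", "ifs_curve.pdf",
             "optimal_features.tsv", "point_biserial.tsv", "manifest.json")
  expect_true(all(file.exists(file.path(out1, files))))

  # identical report across two runs on the same dataset
  for (f in setdiff(files, c("ifs_curve.pdf", "manifest.json"))) {
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)))
  }
  man <- jsonlite::read_json(file.path(out1, "manifest.json"))
  expect_equal(man$optimal_k, fit$optimal$k)
  expect_equal(man$n_features, ncol(fit$x))
  expect_equal(man$seed, 1L)

  # artifacts are consistent with the returned fit
  rk <- utils::read.delim(file.path(out1, "ranking.tsv"))
  expect_identical(rk$feature, fit$ranking$order)
  curve <- utils::read.delim(file.path(out1, "ifs_curve.tsv"))
  expect_equal(curve$accuracy, fit$curve$accuracy)
})
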