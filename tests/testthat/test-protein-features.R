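test_that("amino-acid composition sums to one", {
  v <- aa_composition("AAAA")
  expect_length(v, 20L)
  expect_equal(unname(v["A"]), 1)
  expect_equal(sum(v), 1)

  v <- aa_composition("ACDE")
  expect_equal(unname(v[c("A", "C", "D", "E")]), rep(0.25, 4))
  expect_error(aa_composition("ACDX"), "position 4")
})

test_that("group assignment follows the published residue groupings", {
  # hydrophobicity: C hydrophobic (group 1), A neutral (group 2)
  expect_equal(to_group_sequence("AAACCC", "hydrophobicity"),
               c(2, 2, 2, 1, 1, 1))
  # polarity: K in the polar group (group 1)
  expect_equal(to_group_sequence("KKK", "polarity"), c(1, 1, 1))
  # every scheme partitions all 20 residues
  all20 <- "ACDEFGHIKLMNPQRSTVWY"
  for (p in c("hydrophobicity", "polarizability", "vdw_volume", "polarity")) {
    g <- to_group_sequence(all20, p)
    expect_false(anyNA(g))
    expect_true(all(g %in% 1:3))
  }
})

test_that("annotations drive the structure/accessibility grouping", {
  g <- to_group_sequence("AAA", "secondary_structure", annotation = "HEC")
  expect_equal(g, c(1, 2, 3))
  g <- to_group_sequence("AAA", "solvent_accessibility", annotation = "EBE")
  expect_equal(g, c(1, 2, 1))
  expect_error(
    to_group_sequence("AAA", "secondary_structure", annotation = "HE"),
    "length"
  )
  expect_error(
    to_group_sequence("AAA", "secondary_structure", fallback = FALSE),
    "annotation"
  )
  # fallback is deterministic and total
  g1 <- to_group_sequence("ACDEFGHIKLMNPQRSTVWY", "secondary_structure")
  expect_false(anyNA(g1))
  expect_identical(g1, to_group_sequence("ACDEFGHIKLMNPQRSTVWY",
                                         "secondary_structure"))
})

test_that("ctd_block reproduces the hand-enumerated examples", {
  b <- ctd_block(c(2, 2, 2, 1, 1, 1), 3L)
  expect_length(b, 21L)
  expect_equal(unname(b[c("comp_g1", "comp_g2", "comp_g3")]), c(0.5, 0.5, 0))
  expect_equal(unname(b["trans_g1g2"]), 0.2)
  expect_equal(unname(b[c("trans_g1g3", "trans_g2g3")]), c(0, 0))
  expect_equal(unname(b[paste0("dist_g1_", c("first", "q25", "q50", "q75", "last"))]),
               c(4, 4, 5, 6, 6) / 6)

  b <- ctd_block(c(1, 1, 1, 1), 3L)
  expect_equal(unname(b[c("comp_g1", "comp_g2", "comp_g3")]), c(1, 0, 0))
  expect_true(all(b[grep("trans", names(b))] == 0))
  expect_equal(unname(b[paste0("dist_g1_", c("first", "q25", "q50", "q75", "last"))]),
               c(0.25, 0.25, 0.5, 0.75, 1))
  expect_true(all(b[grep("dist_g[23]", names(b))] == 0))

  # constant sequence: no transitions
  expect_true(all(ctd_block(rep(2L, 9), 3L)[4:6] == 0))
  # block sizes
  expect_length(ctd_block(c(1, 2, 1), 2L), 7L)
})

test_that("ctd_block agrees with brute-force enumeration on random sequences", {
  set.seed(42)
  for (rep in 1:200) {
    ng <- sample(2:3, 1)
    L <- sample(2:30, 1)
    gs <- sample(seq_len(ng), L, replace = TRUE)
    expect_equal(unname(ctd_block(gs, ng)), ctd_oracle(gs, ng),
                 tolerance = 1e-12)
  }
})

test_that("ctd values obey their range and monotonicity invariants", {
  set.seed(9)
  for (rep in 1:50) {
    ng <- sample(2:3, 1)
    gs <- sample(seq_len(ng), sample(2:40, 1), replace = TRUE)
    b <- ctd_block(gs, ng)
    comp <- b[grep("^comp", names(b))]
    expect_equal(sum(comp), 1)
    expect_true(all(b >= 0 & b <= 1))
    for (g in if (ng == 3) 1:3 else 1) {
      d <- b[paste0("dist_g", g, "_", c("first", "q25", "q50", "q75", "last"))]
      d <- d[!is.na(d)]
      expect_true(all(diff(d) >= -1e-12))
    }
  }
})

test_that("the protein feature vector has 132 deterministic named values", {
  set.seed(13)
  prot <- paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 60,
                       replace = TRUE), collapse = "")
  v <- protein_feature_vector(prot)
  expect_length(v, 132L)
  expect_false(anyNA(v))
  expect_equal(anyDuplicated(names(v)), 0L)
  expect_identical(v, protein_feature_vector(prot))

  expect_error(protein_feature_vector(prot, fallback = FALSE), "annotation")

  # real annotations override the fallback
  ss <- paste(sample(c("H", "E", "C"), nchar(prot), TRUE), collapse = "")
  acc <- paste(sample(c("E", "B"), nchar(prot), TRUE), collapse = "")
  v2 <- protein_feature_vector(prot, ss_annotation = ss, acc_annotation = acc)
  expect_length(v2, 132L)
  expect_false(identical(v, v2))
  # amino-acid composition part is annotation-independent
  expect_identical(v[1:20], v2[1:20])
})
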