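# Independent oracles used to cross-check the implementation. Each oracle
# takes a deliberately different computational route from the package code.

# Mutual information via the entropy identity H(X) + H(Y) - H(X,Y), in bits.
mi_oracle <- function(a, b) {
  H <- function(v) {
    p <- table(v) / length(v)
    -sum(p * log2(p))
  }
  H(a) + H(b) - H(paste(a, b))
}

# Greedy mRMR re-derived from scratch each round (difference criterion,
# ties: higher relevance then lexicographic name).
mrmr_oracle <- function(cols, y, top_k = length(cols)) {
  rel <- vapply(cols, mi_oracle, numeric(1), b = y)
  sel <- character(0)
  for (r in seq_len(top_k)) {
    cand <- setdiff(names(cols), sel)
    sc <- vapply(cand, function(f) {
      red <- if (!length(sel)) 0 else
        mean(vapply(sel, function(s) mi_oracle(cols[[f]], cols[[s]]),
                    numeric(1)))
      rel[[f]] - red
    }, numeric(1))
    o <- order(-round(sc, 10), -round(rel[cand], 10), cand)
    sel <- c(sel, cand[o[1]])
  }
  sel
}

# Upper-tail hypergeometric probability by exhaustive summation of
# binomial-coefficient terms.
hyper_upper_oracle <- function(N, K, m, k) {
  js <- k:min(K, m)
  sum(choose(K, js) * choose(N - K, m - js)) / choose(N, m)
}

# Nearest neighbor by explicit scan with a from-scratch cosine distance.
nna_oracle <- function(train, labels, query) {
  best_d <- Inf
  best_i <- NA_integer_
  for (i in seq_len(nrow(train))) {
    v <- train[i, ]
    nv <- sqrt(sum(v * v)); nq <- sqrt(sum(query * query))
    d <- if (nv == 0 || nq == 0) 2 else 1 - sum(v * query) / (nv * nq)
    if (d < best_d) {
      best_d <- d
      best_i <- i
    }
  }
  labels[best_i]
}

# CTD block by explicit enumeration loops (same landmark convention,
# re-derived independently).
ctd_oracle <- function(gs, ng) {
  L <- length(gs)
  comp <- vapply(seq_len(ng), function(g) sum(gs == g) / L, numeric(1))
  prs <- utils::combn(seq_len(ng), 2)
  trans <- apply(prs, 2, function(p) {
    cnt <- 0
    if (L >= 2) {
      for (i in seq_len(L - 1)) {
        if (all(sort(c(gs[i], gs[i + 1])) == p)) cnt <- cnt + 1
      }
    }
    cnt / (L - 1)
  })
  dist <- c()
  gset <- if (ng == 3) seq_len(ng) else 1L
  for (g in gset) {
    pos <- which(gs == g)
    n <- length(pos)
    if (n == 0) {
      dist <- c(dist, rep(0, 5))
    } else {
      landmarks <- c(pos[1],
                     pos[max(1, ceiling(0.25 * n))],
                     pos[max(1, ceiling(0.50 * n))],
                     pos[max(1, ceiling(0.75 * n))],
                     pos[n])
      dist <- c(dist, landmarks / L)
    }
  }
  if (ng == 2) dist <- dist[1:4]
  unname(c(comp, trans, dist))
}

# Shared small planted dataset, generated once per test run.
.fixture_env <- new.env(parent = emptyenv())

small_planted <- function() {
  if (is.null(.fixture_env$small)) {
    cfg <- simulation_config(n_orfs = 40L, seed = 1L, go_module_size = 12L,
                             n_go_terms = 10L, n_module_terms = 3L)
    .fixture_env$small <- generate_dataset(cfg)
  }
  .fixture_env$small
}
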