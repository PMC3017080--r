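# Maximum-relevance minimum-redundancy feature ranking.
# Relevance of a feature is its mutual information (MI, in bits) with the
# class; redundancy is its mean MI with the already-selected features; the
# greedy criterion each round is relevance - redundancy (the difference form,
# MID), with a quotient form available. MI is a plug-in estimate on
# discretized features.

#' Discretization rule for the mutual-information estimator
#'
#' @param scheme `"three_state_mean_sigma"` (default): values below
#'   `mean - alpha * sd` map to state 1, above `mean + alpha * sd` to state
#'   3, the rest to state 2 (sample sd). `"equal_frequency_k"`: k
#'   equal-frequency bins by quantile.
#' @param alpha Sigma multiplier for the three-state scheme (default 1).
#' @param k Bin count for the equal-frequency scheme (default 3).
#' @return A list of class `"discretization_rule"`.
#' @export
discretization_rule <- function(scheme = c("three_state_mean_sigma",
                                           "equal_frequency_k"),
                                alpha = 1, k = 3L) {
  scheme <- match.arg(scheme)
  stopifnot(alpha > 0, k >= 2L)
  structure(list(scheme = scheme, alpha = alpha, k = as.integer(k)),
            class = "discretization_rule")
}

#' Discretize a numeric feature
#'
#' Missing values get their own dedicated category (they are never silently
#' pooled with a numeric bin). A constant vector maps entirely to the middle
#' state, with a warning. A vector with at most three distinct non-missing
#' values (e.g. a binary indicator) is treated as already discrete and passes
#' through with its values as categories; mean-sigma binning would otherwise
#' collapse such features into the middle state.
#'
#' @param values Numeric vector, possibly with `NA`s; at least 2 non-missing
#'   values required.
#' @param rule A [discretization_rule()].
#' @return Integer vector of states; `NA` inputs become state 0 (the missing
#'   category).
#' @export
discretize <- function(values, rule = discretization_rule()) {
  stopifnot(inherits(rule, "discretization_rule"))
  ok <- !is.na(values)
  if (sum(ok) < 2L) stop("need at least 2 non-missing values", call. = FALSE)
  v <- values[ok]
  out <- integer(length(values))  # 0 = missing category
  u <- sort(unique(v))
  if (rule$scheme == "three_state_mean_sigma") {
    m <- mean(v); s <- stats::sd(v)
    if (s == 0) {
      warning("constant feature: all values assigned the middle state")
      states <- rep(2L, length(v))
    } else if (length(u) <= 3L) {
      # already (near-)discrete: use the values themselves as categories
      states <- match(v, u)
    } else {
      states <- ifelse(v < m - rule$alpha * s, 1L,
                       ifelse(v > m + rule$alpha * s, 3L, 2L))
    }
  } else {
    qs <- unique(stats::quantile(v, probs = seq(0, 1, length.out = rule$k + 1),
                                 names = FALSE, type = 7))
    if (length(qs) < 2L) {
      warning("constant feature: all values assigned the middle state")
      states <- rep(2L, length(v))
    } else {
      states <- as.integer(cut(v, breaks = qs, include.lowest = TRUE))
    }
  }
  out[ok] <- states
  out
}

.as_codes <- function(x) {
  if (is.factor(x)) return(as.integer(x))
  match(x, unique(x))
}

#' Mutual information between two categorical vectors, in bits
#'
#' Plug-in estimate over the observed joint cell counts,
#' `sum p(x, y) * log2(p(x, y) / (p(x) p(y)))`, with empty cells contributing
#' zero.
#'
#' @param x,y Categorical vectors (factor, integer or character) of equal
#'   length.
#' @return Non-negative value in bits.
#' @export
mutual_information <- function(x, y) {
  if (length(x) != length(y))
    stop("x and y must have equal length", call. = FALSE)
  if (length(x) == 0L) stop("empty input", call. = FALSE)
  xi <- .as_codes(x); yi <- .as_codes(y)
  nx <- max(xi); ny <- max(yi)
  joint <- tabulate(xi + nx * (yi - 1L), nbins = nx * ny)
  n <- length(xi)
  pj <- joint / n
  px <- tabulate(xi, nbins = nx) / n
  py <- tabulate(yi, nbins = ny) / n
  pe <- as.vector(outer(px, py))
  nz <- pj > 0
  sum(pj[nz] * log2(pj[nz] / pe[nz]))
}

#' Relevance of a feature: MI with the class labels
#'
#' @param feature Categorical vector.
#' @param labels Class labels (any categorical vector).
#' @return MI in bits.
#' @export
relevance <- function(feature, labels) mutual_information(feature, labels)

#' Redundancy of a feature with a selected set
#'
#' Mean MI between the feature and each member of `selected`; an empty set
#' has redundancy 0 (the first-round convention).
#'
#' @param feature Categorical vector.
#' @param selected List of categorical vectors.
#' @return Mean MI in bits.
#' @export
redundancy <- function(feature, selected) {
  if (length(selected) == 0L) return(0)
  mean(vapply(selected, function(s) mutual_information(feature, s), numeric(1)))
}

#' Greedy mRMR feature ranking
#'
#' Features are discretized, then selected greedily: each round picks the
#' candidate maximizing `relevance - redundancy` (difference form; a quotient
#' form `relevance / (redundancy + eps)` is available). The first selected
#' feature is the relevance maximizer. Criterion scores agreeing to 10
#' decimals count as tied (guarding exact ties against floating-point
#' summation noise); ties are broken by higher relevance, then lexicographic
#' feature name, so the ranking is deterministic and invariant to column
#' order.
#'
#' The ranking is computed once on the full labeled dataset (ranking precedes
#' the jackknife); see the methods vignette for the information-leakage
#' caveat and `refit` in [ifs()] docs for discussion.
#'
#' @param x Feature matrix (see [feature_matrix()]).
#' @param labels Class labels, one per row of `x`; both classes must be
#'   present.
#' @param top_k Number of features to rank (default all).
#' @param rule A [discretization_rule()].
#' @param criterion `"difference"` (default) or `"quotient"`.
#' @return An object of class `"ranked_features"`: list with `order`
#'   (feature names in selection order), `relevance` (MI with the class, in
#'   selection order) and `score` (criterion value at the round of
#'   selection).
#' @export
mrmr_rank <- function(x, labels, top_k = ncol(x),
                      rule = discretization_rule(),
                      criterion = c("difference", "quotient")) {
  criterion <- match.arg(criterion)
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) < 2L)
    stop("both classes must be present", call. = FALSE)
  if (length(labels) != nrow(x))
    stop("labels length must match row count", call. = FALSE)
  if (top_k <= 0L) stop("top_k must be positive", call. = FALSE)
  if (top_k > ncol(x)) stop("top_k exceeds feature count", call. = FALSE)

  feats <- colnames(x)
  disc <- suppressWarnings(
    lapply(seq_len(ncol(x)), function(j) discretize(x[, j], rule))
  )
  names(disc) <- feats
  y <- as.integer(labels)
  rel <- vapply(disc, function(f) mutual_information(f, y), numeric(1))

  remaining <- feats
  red_sum <- stats::setNames(numeric(length(feats)), feats)
  sel <- character(top_k)
  sel_rel <- sel_score <- numeric(top_k)
  for (round in seq_len(top_k)) {
    n_sel <- round - 1L
    score <- if (n_sel == 0L) {
      rel[remaining]
    } else if (criterion == "difference") {
      rel[remaining] - red_sum[remaining] / n_sel
    } else {
      rel[remaining] / (red_sum[remaining] / n_sel + 1e-12)
    }
    # scores equal to 10 decimals are ties: exact ties computed along
    # different floating-point summation routes must break identically
    ord <- order(-round(score, 10), -round(rel[remaining], 10), remaining)
    pick <- remaining[ord[1L]]
    sel[round] <- pick
    sel_rel[round] <- rel[[pick]]
    sel_score[round] <- score[[ord[1L]]]
    remaining <- setdiff(remaining, pick)
    if (length(remaining)) {
      mi_new <- vapply(remaining,
                       function(f) mutual_information(disc[[f]], disc[[pick]]),
                       numeric(1))
      red_sum[remaining] <- red_sum[remaining] + mi_new
    }
  }
  structure(list(order = sel,
                 relevance = stats::setNames(sel_rel, sel),
                 score = stats::setNames(sel_score, sel)),
            class = "ranked_features")
}

#' @export
print.ranked_features <- function(x, n = 10L, ...) {
  cat("mRMR ranking of", length(x$order), "features\n")
  k <- min(n, length(x$order))
  print(data.frame(rank = seq_len(k), feature = x$order[seq_len(k)],
                   relevance = unname(x$relevance[seq_len(k)]),
                   criterion_score = unname(x$score[seq_len(k)])),
        row.names = FALSE)
  if (length(x$order) > k) cat("... and", length(x$order) - k, "more\n")
  invisible(x)
}

#' Write a ranked feature list to TSV
#'
#' Columns: rank, feature, relevance, criterion_score.
#'
#' @param ranking A `"ranked_features"` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ranking <- function(ranking, path) {
  stopifnot(inherits(ranking, "ranked_features"))
  df <- data.frame(rank = seq_along(ranking$order), feature = ranking$order,
                   relevance = unname(ranking$relevance),
                   criterion_score = unname(ranking$score))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
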