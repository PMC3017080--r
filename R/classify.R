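# Nearest-neighbor classification under the cosine distance, jackknife
# (leave-one-out) evaluation, incremental feature selection, and optimal-set
# extraction.

#' Cosine distance between two vectors
#'
#' `1 - (x . y) / (|x| |y|)`, in `[0, 2]`; smaller means more similar. A
#' zero vector has no direction, so its distance to anything is defined as
#' the maximum 2 (logged via a warning).
#'
#' @param x,y Numeric vectors of equal length.
#' @return Distance in `[0, 2]`.
#' @export
cosine_distance <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) {
    warning("zero vector in cosine distance; returning the maximum 2")
    return(2)
  }
  1 - sum(x * y) / (nx * ny)
}

# Cosine distances from one query to every row of a matrix; zero rows or a
# zero query get distance 2 silently (the caller logs if needed).
.cosine_dist_rows <- function(m, q) {
  qn <- sqrt(sum(q^2))
  rn <- sqrt(rowSums(m^2))
  if (qn == 0) return(rep(2, nrow(m)))
  d <- 1 - as.vector(m %*% q) / (rn * qn)
  d[rn == 0] <- 2
  d
}

#' Nearest-neighbor prediction
#'
#' Predicts the class of `query` as the label of the training row with the
#' smallest cosine distance. Exact distance ties resolve to the earliest
#' training row (deterministic).
#'
#' @param train Numeric training matrix (rows = samples). No missing values;
#'   impute before calling (see [jackknife_accuracy()] for the standard
#'   pipeline treatment).
#' @param train_labels Labels, one per training row.
#' @param query Numeric vector, same dimension as `train` columns.
#' @return The predicted label (same type as `train_labels` elements).
#' @export
nna_predict <- function(train, train_labels, query) {
  train <- as.matrix(train)
  if (nrow(train) == 0L) stop("empty training set", call. = FALSE)
  if (length(train_labels) != nrow(train))
    stop("one label per training row required", call. = FALSE)
  if (length(query) != ncol(train))
    stop("query dimension mismatch", call. = FALSE)
  d <- .cosine_dist_rows(train, as.numeric(query))
  train_labels[which.min(d)]
}

# Per-column first/second smallest and largest values with the row attaining
# the extreme, ignoring NAs. Used to get leave-one-out ranges in O(k).
.col_extremes <- function(xs) {
  k <- ncol(xs); n <- nrow(xs)
  min1 <- min2 <- max1 <- max2 <- rep(NA_real_, k)
  imin <- imax <- integer(k)
  for (j in seq_len(k)) {
    v <- xs[, j]
    o <- order(v, na.last = NA)
    if (length(o) == 0L) next
    min1[j] <- v[o[1L]]; imin[j] <- o[1L]
    min2[j] <- if (length(o) >= 2L) v[o[2L]] else v[o[1L]]
    max1[j] <- v[o[length(o)]]; imax[j] <- o[length(o)]
    max2[j] <- if (length(o) >= 2L) v[o[length(o) - 1L]] else v[o[length(o)]]
  }
  list(min1 = min1, min2 = min2, imin = imin,
       max1 = max1, max2 = max2, imax = imax)
}

#' Jackknife (leave-one-out) accuracy of the nearest-neighbor rule
#'
#' Each sample in turn is held out and predicted from all the others,
#' restricted to `feature_subset`. Within each fold, missing values are
#' imputed with the training-fold feature mean, and (by default) every
#' feature is min-max scaled to `[0, 1]` using the training-fold range, so
#' that raw feature scales (e.g. CDS length vs. frequencies) do not dominate
#' the cosine inner product. `scale = "none"` gives the literal unscaled
#' distance.
#'
#' @param x Feature matrix (see [feature_matrix()]), `NA` = missing.
#' @param labels Factor with levels `low`/`high` (or coercible), one per row.
#' @param feature_subset Character vector of column names to use (default
#'   all).
#' @param scale `"minmax"` (default) or `"none"`.
#' @return An object of class `"eval_result"`: list with `accuracy`,
#'   `correct_high`, `correct_low`, `n_high`, `n_low` and the per-sample
#'   `predictions`.
#' @export
jackknife_accuracy <- function(x, labels, feature_subset = colnames(x),
                               scale = c("minmax", "none")) {
  scale <- match.arg(scale)
  labels <- .as_class_labels(labels)
  n <- nrow(x)
  if (n < 2L) stop("need at least 2 samples", call. = FALSE)
  if (length(labels) != n) stop("one label per row required", call. = FALSE)
  if (nlevels(droplevels(labels)) < 2L)
    stop("both classes must be present", call. = FALSE)
  absent <- setdiff(feature_subset, colnames(x))
  if (length(absent))
    stop("feature(s) absent from matrix: ",
         paste(utils::head(absent, 5L), collapse = ", "), call. = FALSE)
  xs <- x[, feature_subset, drop = FALSE]
  k <- ncol(xs)

  isna <- is.na(xs)
  col_sum <- colSums(xs, na.rm = TRUE)
  col_cnt <- colSums(!isna)
  ext <- .col_extremes(xs)

  pred <- labels[rep(1L, n)]  # placeholder factor of right levels
  for (i in seq_len(n)) {
    xi <- xs[i, ]
    na_i <- isna[i, ]
    cnt <- col_cnt - as.integer(!na_i)
    s <- col_sum - ifelse(na_i, 0, xi)
    mu <- ifelse(cnt > 0L, s / pmax(cnt, 1L), 0)

    tr <- xs[-i, , drop = FALSE]
    na_tr <- which(isna[-i, , drop = FALSE], arr.ind = TRUE)
    if (nrow(na_tr)) tr[na_tr] <- mu[na_tr[, 2L]]
    q <- ifelse(na_i, mu, xi)

    if (scale == "minmax") {
      mn <- ifelse(ext$imin == i, ext$min2, ext$min1)
      mx <- ifelse(ext$imax == i, ext$max2, ext$max1)
      mn[is.na(mn)] <- 0; mx[is.na(mx)] <- 0
      rng <- mx - mn
      rng[rng <= 0] <- 1  # constant feature: maps to 0, carries no signal
      tr <- (tr - rep(mn, each = n - 1L)) / rep(rng, each = n - 1L)
      q <- (q - mn) / rng
    }
    d <- .cosine_dist_rows(tr, q)
    pred[i] <- labels[-i][which.min(d)]
  }

  correct <- pred == labels
  res <- list(
    accuracy = mean(correct),
    correct_high = sum(correct & labels == "high"),
    correct_low = sum(correct & labels == "low"),
    n_high = sum(labels == "high"),
    n_low = sum(labels == "low"),
    predictions = pred
  )
  class(res) <- "eval_result"
  res
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("jackknife accuracy: %.4f (%d/%d high, %d/%d low)\n",
              x$accuracy, x$correct_high, x$n_high, x$correct_low, x$n_low))
  invisible(x)
}

.as_class_labels <- function(labels) {
  if (is.factor(labels)) {
    if (!all(levels(labels) %in% c("low", "high")))
      labels <- factor(as.character(labels), levels = c("low", "high"))
    return(labels)
  }
  factor(as.character(labels), levels = c("low", "high"))
}

#' Incremental feature selection (IFS) curve
#'
#' For k = 1..`k_max`, evaluates the jackknife accuracy of the
#' nearest-neighbor rule on the first k features of an mRMR ranking; the
#' accuracies against k form the IFS curve from which the optimal feature
#' subset is read off.
#'
#' @param x Feature matrix.
#' @param labels Class labels (`low`/`high`).
#' @param ranking A `"ranked_features"` object (see [mrmr_rank()]).
#' @param k_max Largest subset size; must not exceed the ranking length.
#' @param scale Passed to [jackknife_accuracy()].
#' @return An object of class `"ifs_curve"`: a data frame with columns `k`,
#'   `accuracy`, `correct_high`, `correct_low`, with the ranking kept in
#'   `attr(, "ranking")`.
#' @export
ifs <- function(x, labels, ranking, k_max = length(ranking$order),
                scale = c("minmax", "none")) {
  scale <- match.arg(scale)
  stopifnot(inherits(ranking, "ranked_features"))
  if (k_max <= 0L) stop("k_max must be positive", call. = FALSE)
  if (k_max > length(ranking$order))
    stop("k_max exceeds the ranking length", call. = FALSE)
  rows <- lapply(seq_len(k_max), function(k) {
    r <- jackknife_accuracy(x, labels, ranking$order[seq_len(k)], scale = scale)
    data.frame(k = k, accuracy = r$accuracy,
               correct_high = r$correct_high, correct_low = r$correct_low)
  })
  curve <- do.call(rbind, rows)
  attr(curve, "ranking") <- ranking
  class(curve) <- c("ifs_curve", "data.frame")
  curve
}

#' Optimal feature subset from an IFS curve
#'
#' The subset size maximizing jackknife accuracy; exact ties go to the
#' smallest k (the more parsimonious model).
#'
#' @param curve An `"ifs_curve"` from [ifs()].
#' @return List with `k` (optimal size), `accuracy`, and `features` (the
#'   first k ranked names).
#' @export
optimal_feature_set <- function(curve) {
  stopifnot(inherits(curve, "ifs_curve"), nrow(curve) > 0L)
  i <- which.max(curve$accuracy)
  ranking <- attr(curve, "ranking")
  list(k = curve$k[i], accuracy = curve$accuracy[i],
       features = ranking$order[seq_len(curve$k[i])])
}

#' Write an IFS curve to TSV
#'
#' Columns: k, accuracy, correct_high, correct_low.
#'
#' @param curve An `"ifs_curve"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ifs_curve <- function(curve, path) {
  stopifnot(inherits(curve, "ifs_curve"))
  utils::write.table(as.data.frame(curve), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
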