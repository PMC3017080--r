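# Median-split class labeling and point-biserial feature-class correlation.

#' Median split of continuous translation rates into low/high classes
#'
#' Samples with rate less than or equal to the median are labeled `low`, the
#' rest `high`. The median is the standard middle order statistic (the mean
#' of the two central values for even n), so with an odd number of distinct
#' rates the low class is larger by one.
#'
#' @param rates Numeric vector, length >= 2, no missing values.
#' @return Factor with levels `low`/`high`, with the applied rule recorded in
#'   `attr(, "rule")` (the median value and the inclusive-low convention).
#' @export
#' @examples
#' median_split(c(1, 2, 3))   # low low high
median_split <- function(rates) {
  if (length(rates) < 2L) stop("need at least 2 rates", call. = FALSE)
  if (anyNA(rates)) stop("rates must not contain missing values", call. = FALSE)
  med <- stats::median(rates)
  if (all(rates == rates[1L]))
    warning("all rates identical: degenerate split, every sample labeled low")
  labels <- factor(ifelse(rates > med, "high", "low"), levels = c("low", "high"))
  attr(labels, "rule") <- list(statistic = "median", value = med,
                               convention = "<= median is low")
  labels
}

#' Point-biserial correlation between a feature and the class
#'
#' `r_pb = (M1 - M0) / s * sqrt(p * (1 - p))` where `M1`/`M0` are the
#' feature means over the high/low class, `p` the proportion of high-class
#' samples, and `s` the standard deviation of the feature over all samples.
#' Positive values mean large feature values associate with high translation
#' rate. With the population (divide-by-n) sd, the default, `r_pb` is exactly
#' the Pearson correlation between the feature and a 0/1 class indicator.
#'
#' @param feature Numeric vector; pairs with missing feature values are
#'   dropped.
#' @param labels Factor with levels `low`/`high` (or coercible); both classes
#'   must be present among the non-missing pairs.
#' @param sd_type `"population"` (default; Pearson-identity convention) or
#'   `"sample"`.
#' @return Correlation in `[-1, 1]`.
#' @export
point_biserial <- function(feature, labels,
                           sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  labels <- .as_class_labels(labels)
  if (length(feature) != length(labels))
    stop("feature and labels must have equal length", call. = FALSE)
  ok <- !is.na(feature) & !is.na(labels)
  f <- feature[ok]; l <- labels[ok]
  n <- length(f)
  n1 <- sum(l == "high"); n0 <- sum(l == "low")
  if (n1 == 0L || n0 == 0L)
    stop("both classes must be present", call. = FALSE)
  s <- if (sd_type == "population") {
    sqrt(sum((f - mean(f))^2) / n)
  } else {
    stats::sd(f)
  }
  if (s == 0) stop("zero feature standard deviation: r_pb undefined",
                   call. = FALSE)
  p <- n1 / n
  (mean(f[l == "high"]) - mean(f[l == "low"])) / s * sqrt(p * (1 - p))
}

#' Point-biserial correlation report for a feature set
#'
#' @param x Feature matrix.
#' @param labels Class labels.
#' @param features Column names to report (default all).
#' @param sd_type Passed to [point_biserial()].
#' @return Data frame with columns `feature`, `r_pb`, `n_high`, `n_low`
#'   (non-missing counts per feature). Features with zero variance get
#'   `NA` for `r_pb`.
#' @export
point_biserial_table <- function(x, labels, features = colnames(x),
                                 sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  labels <- .as_class_labels(labels)
  rows <- lapply(features, function(f) {
    v <- x[, f]
    ok <- !is.na(v)
    r <- tryCatch(point_biserial(v, labels, sd_type = sd_type),
                  error = function(e) NA_real_)
    data.frame(feature = f, r_pb = r,
               n_high = sum(ok & labels == "high"),
               n_low = sum(ok & labels == "low"))
  })
  do.call(rbind, rows)
}
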