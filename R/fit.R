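# Featurization of ORF records and the central model-fitting interface.

#' Build the full ORF feature matrix
#'
#' Concatenates the enabled feature families in a fixed, documented column
#' order: codon usage (64), GO enrichment scores (one per term),
#' biochemical/physicochemical protein features (132), start-codon context
#' (24), and the auxiliary block (CDS length computed from the sequence plus
#' the 9 auxiliary-table columns, 10 in all). Per-family column counts are
#' reported via `message()`.
#'
#' @param records List of ORF records; each element needs `orf_id` and `cds`,
#'   plus `upstream_utr` for the start-codon family, `protein` (and optional
#'   `ss_annotation`/`acc_annotation`) for the protein family, and an
#'   `auxiliary` named numeric vector for the auxiliary family.
#' @param network,annotations Network and [go_annotation_set()] for the GO
#'   family.
#' @param terms GO term set to score (default: all annotated terms). The
#'   term set is an explicit input; the number of GO columns equals
#'   `length(terms)`.
#' @param families Character subset of
#'   `c("codon", "go", "protein", "start", "other")`.
#' @param fallback Passed to [protein_feature_vector()].
#' @return A [feature_matrix()] with one row per record.
#' @export
featurize_orfs <- function(records, network = NULL, annotations = NULL,
                           terms = NULL,
                           families = c("codon", "go", "protein", "start",
                                        "other"),
                           fallback = TRUE) {
  families <- match.arg(families, several.ok = TRUE)
  ids <- vapply(records, `[[`, character(1), "orf_id")
  if (anyDuplicated(ids))
    stop("duplicate orf_id in records", call. = FALSE)
  blocks <- list()

  if ("codon" %in% families) {
    blocks$codon <- t(vapply(records, function(r) codon_usage(r$cds),
                             numeric(64L)))
  }
  if ("go" %in% families) {
    if (is.null(network) || is.null(annotations))
      stop("GO family enabled but network/annotations missing", call. = FALSE)
    blocks$go <- enrichment_matrix(ids, terms, network, annotations)
  }
  if ("protein" %in% families) {
    blocks$protein <- t(vapply(records, function(r) {
      if (is.null(r$protein))
        stop("protein family enabled but record '", r$orf_id,
             "' has no protein sequence", call. = FALSE)
      protein_feature_vector(r$protein, r$ss_annotation, r$acc_annotation,
                             fallback = fallback)
    }, numeric(132L)))
  }
  if ("start" %in% families) {
    blocks$start <- t(vapply(records, function(r) {
      if (is.null(r$upstream_utr) || nchar(r$upstream_utr) < 3L)
        stop("start family enabled but record '", r$orf_id,
             "' lacks >= 3 nt of upstream UTR", call. = FALSE)
      u <- r$upstream_utr
      start_codon_context(substring(u, nchar(u) - 2L, nchar(u)),
                          substring(r$cds, 4L, 6L))
    }, numeric(24L)))
  }
  if ("other" %in% families) {
    aux_names <- setdiff(.AUX_NAMES, "cds_length")
    blocks$other <- t(vapply(records, function(r) {
      v <- stats::setNames(rep(NA_real_, length(.AUX_NAMES)), .AUX_NAMES)
      v["cds_length"] <- cds_length(r$cds)
      if (!is.null(r$auxiliary)) {
        have <- intersect(names(r$auxiliary), aux_names)
        v[have] <- as.numeric(r$auxiliary[have])
      }
      v
    }, numeric(length(.AUX_NAMES))))
  }

  for (fam in names(blocks)) rownames(blocks[[fam]]) <- ids
  counts <- vapply(blocks, ncol, integer(1))
  message("featurize_orfs: ",
          paste(names(counts), counts, sep = "=", collapse = ", "),
          " (total ", sum(counts), ")")
  feature_matrix(do.call(cbind, blocks), sample_ids = ids)
}

#' Fit a translation-rate classification model
#'
#' The package's central fitting routine, reproducing the full analysis
#' workflow: continuous rates are median-split into low/high classes, all
#' features are ranked once by greedy mRMR on the labeled data, an
#' incremental-feature-selection (IFS) curve of jackknife nearest-neighbor
#' accuracies is computed along the ranking, the peak of the curve gives the
#' optimal feature subset, and point-biserial correlations are reported for
#' the optimal features.
#'
#' @param x Feature matrix (see [feature_matrix()] / [featurize_orfs()]).
#' @param rates Continuous translation rates, one per row of `x`; ignored if
#'   `labels` is given.
#' @param labels Optional precomputed `low`/`high` labels.
#' @param top_k Number of features to rank by mRMR (default
#'   `min(500, ncol(x))`, the conventional depth of the ranked list).
#' @param k_max Largest IFS subset size (default `top_k`).
#' @param rule [discretization_rule()] for the MI estimator.
#' @param scale Feature scaling inside the jackknife, `"minmax"` (default)
#'   or `"none"`.
#' @param criterion mRMR criterion form, `"difference"` or `"quotient"`.
#' @return An object of class `"te_fit"` with components `labels`,
#'   `ranking`, `curve`, `optimal` (list: `k`, `accuracy`, `features`),
#'   `correlations` (point-biserial table of the optimal features), and the
#'   training data needed by [predict.te_fit()].
#' @seealso [predict.te_fit()], [plot.te_fit()], [summary.te_fit()]
#' @export
te_fit <- function(x, rates = NULL, labels = NULL,
                   top_k = min(500L, ncol(x)), k_max = top_k,
                   rule = discretization_rule(),
                   scale = c("minmax", "none"),
                   criterion = c("difference", "quotient")) {
  scale <- match.arg(scale)
  criterion <- match.arg(criterion)
  if (is.null(labels)) {
    if (is.null(rates)) stop("supply rates or labels", call. = FALSE)
    if (length(rates) != nrow(x))
      stop("one rate per sample required", call. = FALSE)
    labels <- median_split(rates)
  } else {
    labels <- .as_class_labels(labels)
  }
  if (k_max > top_k) stop("k_max cannot exceed top_k", call. = FALSE)

  ranking <- mrmr_rank(x, labels, top_k = top_k, rule = rule,
                       criterion = criterion)
  curve <- ifs(x, labels, ranking, k_max = k_max, scale = scale)
  optimal <- optimal_feature_set(curve)
  correlations <- point_biserial_table(x, labels, optimal$features)

  structure(list(x = x, labels = labels, rates = rates, ranking = ranking,
                 curve = curve, optimal = optimal,
                 correlations = correlations, scale = scale,
                 call = match.call()),
            class = "te_fit")
}

#' @export
print.te_fit <- function(x, ...) {
  cat("Translation-rate classification model (mRMR + IFS + 1-NN)\n")
  cat(sprintf("  samples: %d (%d low, %d high), features: %d, ranked: %d\n",
              nrow(x$x), sum(x$labels == "low"), sum(x$labels == "high"),
              ncol(x$x), length(x$ranking$order)))
  cat(sprintf("  optimal subset: %d features, jackknife accuracy %.3f\n",
              x$optimal$k, x$optimal$accuracy))
  invisible(x)
}

#' Summarize a fitted translation-rate model
#'
#' @param object A `"te_fit"`.
#' @param ... Unused.
#' @return A list of class `"summary.te_fit"` with the IFS peak, class
#'   counts, and the point-biserial table of the optimal features sorted by
#'   absolute correlation.
#' @export
summary.te_fit <- function(object, ...) {
  tab <- object$correlations
  tab <- tab[order(-abs(tab$r_pb)), ]
  structure(list(n = nrow(object$x), n_low = sum(object$labels == "low"),
                 n_high = sum(object$labels == "high"),
                 n_features = ncol(object$x),
                 k_opt = object$optimal$k,
                 accuracy = object$optimal$accuracy,
                 correlations = tab),
            class = "summary.te_fit")
}

#' @export
print.summary.te_fit <- function(x, ...) {
  cat(sprintf("n = %d (%d low / %d high), %d features\n",
              x$n, x$n_low, x$n_high, x$n_features))
  cat(sprintf("IFS peak: accuracy %.3f with %d features\n", x$accuracy, x$k_opt))
  cat("optimal features by |point-biserial correlation|:\n")
  print(utils::head(x$correlations, 15L), row.names = FALSE)
  if (nrow(x$correlations) > 15L)
    cat("... and", nrow(x$correlations) - 15L, "more\n")
  invisible(x)
}

#' Point-biserial coefficients of the optimal feature set
#'
#' @param object A `"te_fit"`.
#' @param ... Unused.
#' @return Named numeric vector of point-biserial correlations, in mRMR rank
#'   order.
#' @export
coef.te_fit <- function(object, ...) {
  stats::setNames(object$correlations$r_pb, object$correlations$feature)
}

#' Plot the IFS curve of a fitted model
#'
#' Jackknife accuracy against feature-subset size, with the optimal subset
#' marked.
#'
#' @param x A `"te_fit"`.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.te_fit <- function(x, ...) {
  plot_ifs_curve(x$curve, ...)
  invisible(x)
}

#' @rdname plot.te_fit
#' @param curve An `"ifs_curve"`.
#' @export
plot_ifs_curve <- function(curve, ...) {
  graphics::plot(curve$k, curve$accuracy, type = "l",
                 xlab = "number of features", ylab = "jackknife accuracy", ...)
  i <- which.max(curve$accuracy)
  graphics::points(curve$k[i], curve$accuracy[i], pch = 19, col = "red")
  graphics::abline(h = 0.5, lty = 3)
  invisible(curve)
}

#' Predict translation-rate class for new ORFs
#'
#' Nearest-neighbor prediction against the full training data using the
#' optimal feature subset. Missing values in `newdata` are imputed with
#' training feature means and (if the model was fitted with min-max scaling)
#' both sides are scaled with the training ranges.
#'
#' @param object A `"te_fit"`.
#' @param newdata Feature matrix containing at least the optimal features.
#' @param ... Unused.
#' @return Factor of predicted `low`/`high` labels, one per row of
#'   `newdata`.
#' @export
predict.te_fit <- function(object, newdata, ...) {
  feats <- object$optimal$features
  absent <- setdiff(feats, colnames(newdata))
  if (length(absent))
    stop("newdata lacks feature(s): ",
         paste(utils::head(absent, 5L), collapse = ", "), call. = FALSE)
  tr <- object$x[, feats, drop = FALSE]
  nd <- as.matrix(newdata[, feats, drop = FALSE])
  mu <- colMeans(tr, na.rm = TRUE)
  mu[is.nan(mu)] <- 0
  fill <- function(m) {
    idx <- which(is.na(m), arr.ind = TRUE)
    if (nrow(idx)) m[idx] <- mu[idx[, 2L]]
    m
  }
  tr <- fill(tr); nd <- fill(nd)
  if (object$scale == "minmax") {
    mn <- apply(tr, 2L, min); mx <- apply(tr, 2L, max)
    rng <- mx - mn
    rng[rng <= 0] <- 1
    tr <- (tr - rep(mn, each = nrow(tr))) / rep(rng, each = nrow(tr))
    nd <- (nd - rep(mn, each = nrow(nd))) / rep(rng, each = nrow(nd))
  }
  preds <- vapply(seq_len(nrow(nd)), function(i) {
    as.character(nna_predict(tr, object$labels, nd[i, ]))
  }, character(1))
  factor(preds, levels = c("low", "high"))
}
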