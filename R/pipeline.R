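# File-level pipeline orchestration: load a dataset directory, run the full
# workflow, and write every report artifact with a run manifest.

#' Load an ORF dataset from a directory
#'
#' Reads the file layout written by [write_dataset()]: `cds.fasta`,
#' `protein.fasta`, `orfs.tsv` (orf, upstream_utr), `aux.tsv`, `rates.tsv`,
#' `network.tsv`, `annotations.tsv`. Missing optional files simply leave the
#' corresponding record fields unset.
#'
#' @param dir Dataset directory.
#' @return List with `records`, `network`, `annotations`, `rates`, matching
#'   the in-memory layout of [generate_dataset()].
#' @export
load_dataset <- function(dir) {
  p <- function(f) file.path(dir, f)
  cds <- read_fasta(p("cds.fasta"), "dna")
  ids <- names(cds)
  prot <- if (file.exists(p("protein.fasta")))
    read_fasta(p("protein.fasta"), "protein") else NULL
  utr <- if (file.exists(p("orfs.tsv"))) {
    df <- read_table(p("orfs.tsv"), c("orf", "upstream_utr"))
    stats::setNames(as.character(df$upstream_utr), trimws(df$orf))
  } else NULL
  aux <- if (file.exists(p("aux.tsv"))) read_feature_matrix(p("aux.tsv")) else NULL
  ann_df <- if (file.exists(p("annotations.tsv")))
    read_table(p("annotations.tsv"), c("gene", "term")) else NULL
  records <- lapply(ids, function(id) {
    list(orf_id = id, cds = cds[[id]],
         upstream_utr = if (!is.null(utr)) utr[[id]] else NULL,
         protein = if (!is.null(prot) && id %in% names(prot)) prot[[id]] else NULL,
         ss_annotation = NULL, acc_annotation = NULL,
         auxiliary = if (!is.null(aux) && id %in% rownames(aux)) aux[id, ] else NULL)
  })
  rates <- if (file.exists(p("rates.tsv"))) {
    df <- read_table(p("rates.tsv"), c("orf", "rate"))
    stats::setNames(as.numeric(df$rate), trimws(df$orf))[ids]
  } else NULL
  list(
    records = records,
    network = if (file.exists(p("network.tsv"))) read_network(p("network.tsv")) else NULL,
    annotations = if (!is.null(ann_df)) go_annotation_set(ann_df, universe = ids) else NULL,
    rates = rates
  )
}

#' Run the full analysis workflow and write all report artifacts
#'
#' Featurizes the dataset, fits the model with [te_fit()]
#' (median split, mRMR ranking, IFS with jackknife 1-NN, optimal subset,
#' point-biserial correlations) and writes: `ranking.tsv`, `ifs_curve.tsv`,
#' `ifs_curve.pdf`, `optimal_features.tsv`, `point_biserial.tsv`,
#' `features.tsv` and a JSON run `manifest.json` (configuration, seed,
#' package version, per-stage timings and collected warnings) sufficient to
#' reproduce every output.
#'
#' @param dataset In-memory dataset (from [generate_dataset()] or
#'   [load_dataset()]).
#' @param outdir Output directory.
#' @param families Feature families to include (see [featurize_orfs()]).
#' @param top_k,k_max,scale,criterion Passed to [te_fit()].
#' @param seed Seed recorded in the manifest (the workflow itself is
#'   deterministic given the feature matrix).
#' @return The fitted `"te_fit"` object, invisibly.
#' @export
run_pipeline <- function(dataset, outdir,
                         families = c("codon", "go", "protein", "start",
                                      "other"),
                         top_k = NULL, k_max = NULL,
                         scale = "minmax", criterion = "difference",
                         seed = NA_integer_) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  warnings_log <- character(0)
  timings <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- withCallingHandlers(
      tryCatch(expr, error = function(e) {
        stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
      }),
      warning = function(w) {
        warnings_log <<- c(warnings_log, paste0(name, ": ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }

  x <- stage("featurize", featurize_orfs(
    dataset$records, network = dataset$network,
    annotations = dataset$annotations, families = families))
  if (is.null(top_k)) top_k <- min(500L, ncol(x))
  if (is.null(k_max)) k_max <- top_k
  fit <- stage("fit", te_fit(x, rates = dataset$rates, top_k = top_k,
                             k_max = k_max, scale = scale,
                             criterion = criterion))

  stage("report", {
    write_feature_matrix(x, file.path(outdir, "features.tsv"))
    write_ranking(fit$ranking, file.path(outdir, "ranking.tsv"))
    write_ifs_curve(fit$curve, file.path(outdir, "ifs_curve.tsv"))
    grDevices::pdf(file.path(outdir, "ifs_curve.pdf"), width = 6, height = 4)
    plot(fit)
    grDevices::dev.off()
    utils::write.table(
      data.frame(rank = seq_along(fit$optimal$features),
                 feature = fit$optimal$features),
      file.path(outdir, "optimal_features.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    utils::write.table(fit$correlations,
                       file.path(outdir, "point_biserial.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  })

  manifest <- list(
    package = "teclass",
    version = as.character(utils::packageVersion("teclass")),
    seed = seed,
    families = families,
    top_k = top_k, k_max = k_max, scale = scale, criterion = criterion,
    n_samples = nrow(x), n_features = ncol(x),
    optimal_k = fit$optimal$k, optimal_accuracy = fit$optimal$accuracy,
    timings = timings,
    warnings = warnings_log
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(fit)
}
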