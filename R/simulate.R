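# Deterministic generator of ORF datasets with planted, tunable signal.
# The generator emulates the statistical structure of the real study inputs:
# class-dependent codon usage bias in the coding sequences, a
# class-correlated gene module preferentially annotated to designated GO
# terms on a random interaction network, and noisy auxiliary features with a
# class mean shift and missing cells. It does not simulate ribosome-profiling
# read counts; only the feature-label relationship is targeted.

#' Simulation configuration
#'
#' Defaults define the package's reference study conditions: 300 ORFs with
#' yeast-like coding-sequence lengths (log-normal around 900 nt), a codon
#' log-weight split of 0.3 on 8 informative sense codons (calibrated a
#' priori to give a point-biserial correlation of about 0.3 between an
#' informative codon's frequency and the class at the typical CDS length),
#' a 40-gene module drawn preferentially from the high class on an
#' Erdos-Renyi background network, 5 module GO terms among 30, an
#' auxiliary-feature class shift of 0.5 sd, and 10% missing auxiliary cells.
#'
#' @param n_orfs Number of ORFs.
#' @param seed Mandatory RNG seed; the whole dataset is a deterministic
#'   function of the configuration.
#' @param codon_effect Log-weight split between classes for informative
#'   codons (>= 0; 0 means no codon signal).
#' @param n_informative_codons Number of designated informative sense codons.
#' @param go_module_size Genes in the planted network/GO module.
#' @param go_effect Increase in module-term annotation probability for module
#'   genes over the 0.05 background (0 means no GO signal).
#' @param n_go_terms Total number of simulated GO terms.
#' @param n_module_terms Designated class-correlated terms among them.
#' @param network_p Erdos-Renyi background edge probability.
#' @param module_p Extra within-module edge probability.
#' @param aux_effect Class mean shift, in units of `aux_noise_sd`, on the
#'   designated auxiliary features (0 means no auxiliary signal).
#' @param aux_noise_sd Noise sd of the auxiliary features.
#' @param missing_rate Fraction of auxiliary table cells masked as missing.
#' @param mean_cds_codons Median CDS length in codons (log-normal location).
#' @return A validated list of class `"simulation_config"`.
#' @export
simulation_config <- function(n_orfs = 300L, seed, codon_effect = 0.3,
                              n_informative_codons = 8L,
                              go_module_size = 40L, go_effect = 0.75,
                              n_go_terms = 30L, n_module_terms = 5L,
                              network_p = 0.02, module_p = 0.3,
                              aux_effect = 0.5, aux_noise_sd = 1,
                              missing_rate = 0.1, mean_cds_codons = 300L) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  cfg <- list(n_orfs = as.integer(n_orfs), seed = as.integer(seed),
              codon_effect = codon_effect,
              n_informative_codons = as.integer(n_informative_codons),
              go_module_size = as.integer(go_module_size),
              go_effect = go_effect, n_go_terms = as.integer(n_go_terms),
              n_module_terms = as.integer(n_module_terms),
              network_p = network_p, module_p = module_p,
              aux_effect = aux_effect, aux_noise_sd = aux_noise_sd,
              missing_rate = missing_rate,
              mean_cds_codons = as.integer(mean_cds_codons))
  stopifnot(cfg$n_orfs >= 4L, cfg$codon_effect >= 0,
            cfg$n_informative_codons >= 0L, cfg$go_effect >= 0,
            cfg$go_effect + 0.05 <= 1, cfg$network_p >= 0, cfg$network_p <= 1,
            cfg$module_p >= 0, cfg$module_p <= 1,
            cfg$missing_rate >= 0, cfg$missing_rate < 1,
            cfg$aux_noise_sd > 0, cfg$n_module_terms <= cfg$n_go_terms)
  if (cfg$go_module_size > cfg$n_orfs)
    stop("module larger than gene count", call. = FALSE)
  class(cfg) <- "simulation_config"
  cfg
}

.AUX_NAMES <- c("cds_length", "utr5_length", "utr3_length", "tf_count",
                "rbp_count", "protein_abundance", "mrna_half_life",
                "protein_half_life", "utr5_free_energy",
                "tss_window_free_energy")

# Auxiliary features that carry the planted class shift, with the sign of
# the association (positive = larger in the high class).
.AUX_SHIFTED <- c(protein_abundance = 1, rbp_count = 1,
                  mrna_half_life = 1, utr5_free_energy = -1)

#' Generate a synthetic ORF dataset with planted signal
#'
#' Latent continuous translation rates are drawn first and the true labels
#' are their median split (so the ground-truth invariant
#' `median_split(latent_rates) == true_labels` holds by construction).
#' Coding sequences start with ATG, end with a random stop codon, and draw
#' interior codons from a class-conditional distribution: informative codons
#' are up-weighted by `exp(codon_effect / 2)` in the high class and
#' down-weighted symmetrically in the low class over a uniform background on
#' the 61 sense codons. Proteins are the standard-genetic-code translation
#' of the CDS. The network is Erdos-Renyi with a denser planted module whose
#' members are drawn preferentially (4:1) from the high class; module GO
#' terms annotate module genes with probability `0.05 + go_effect` versus a
#' 0.05 background. Auxiliary features are Gaussian with a class mean shift
#' on the designated columns and `missing_rate` cells masked.
#'
#' @param config A [simulation_config()].
#' @return List with elements `records` (list of per-ORF records: `orf_id`,
#'   `cds`, `upstream_utr`, `protein`, `auxiliary`), `network` (igraph),
#'   `annotations` ([go_annotation_set()]), `rates` (named numeric), and
#'   `truth` (list: `true_labels`, `informative_features`, `latent_rates`,
#'   `module_genes`).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)

  n <- config$n_orfs
  ids <- sprintf("ORF%04d", seq_len(n))
  rates <- stats::setNames(stats::rnorm(n), ids)
  labels <- median_split(rates)

  stops <- c("TAA", "TAG", "TGA")
  sense <- setdiff(codons(), stops)
  informative <- if (config$n_informative_codons > 0L)
    sort(sample(sense, config$n_informative_codons)) else character(0)
  w <- stats::setNames(rep(1, length(sense)), sense)
  w_high <- w; w_low <- w
  w_high[informative] <- exp(config$codon_effect / 2)
  w_low[informative] <- exp(-config$codon_effect / 2)
  w_high <- w_high / sum(w_high); w_low <- w_low / sum(w_low)

  len_codons <- pmax(50L, round(stats::rlnorm(n, log(config$mean_cds_codons), 0.35)))
  gc <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")

  records <- vector("list", n)
  for (i in seq_len(n)) {
    wi <- if (labels[i] == "high") w_high else w_low
    interior <- sample(sense, len_codons[i] - 2L, replace = TRUE, prob = wi)
    cds_codons <- c("ATG", interior, sample(stops, 1L))
    cds <- paste(cds_codons, collapse = "")
    utr <- paste(sample(bases, 30L, replace = TRUE), collapse = "")
    protein <- paste(gc[cds_codons[-length(cds_codons)]], collapse = "")
    records[[i]] <- list(orf_id = ids[i], cds = cds, upstream_utr = utr,
                         protein = protein, ss_annotation = NULL,
                         acc_annotation = NULL)
  }

  # network: ER background + denser planted module, preferentially high-class
  g <- igraph::sample_gnp(n, config$network_p)
  igraph::V(g)$name <- ids
  mod_w <- ifelse(labels == "high", 4, 1)
  module_genes <- sort(sample(ids, config$go_module_size, prob = mod_w))
  if (config$go_module_size >= 2L) {
    pr <- utils::combn(module_genes, 2L)
    keep <- stats::runif(ncol(pr)) < config$module_p
    if (any(keep))
      g <- igraph::add_edges(g, as.vector(pr[, keep, drop = FALSE]))
  }
  g <- igraph::simplify(g)

  # GO annotations
  terms <- sprintf("GO:SIM%04d", seq_len(config$n_go_terms))
  module_terms <- terms[seq_len(config$n_module_terms)]
  is_module <- ids %in% module_genes
  term_to_genes <- lapply(terms, function(tm) {
    p <- if (tm %in% module_terms)
      ifelse(is_module, 0.05 + config$go_effect, 0.05) else rep(0.1, n)
    hit <- ids[stats::runif(n) < p]
    if (length(hit) == 0L) hit <- sample(ids, 1L)
    hit
  })
  names(term_to_genes) <- terms
  annotations <- go_annotation_set(term_to_genes, universe = ids)

  # auxiliary features: class shift on designated columns + noise + masking
  z <- ifelse(labels == "high", 0.5, -0.5)
  base_mean <- c(utr5_length = 90, utr3_length = 120, tf_count = 3,
                 rbp_count = 4, protein_abundance = 8, mrna_half_life = 20,
                 protein_half_life = 40, utr5_free_energy = -25,
                 tss_window_free_energy = -8)
  aux <- matrix(NA_real_, n, length(.AUX_NAMES),
                dimnames = list(ids, .AUX_NAMES))
  aux[, "cds_length"] <- 3 * (len_codons + 2L)
  for (nm in names(base_mean)) {
    shift <- if (nm %in% names(.AUX_SHIFTED))
      .AUX_SHIFTED[[nm]] * config$aux_effect * config$aux_noise_sd * z else 0
    aux[, nm] <- base_mean[[nm]] + shift +
      stats::rnorm(n, 0, config$aux_noise_sd)
  }
  if (config$missing_rate > 0) {
    maskable <- setdiff(.AUX_NAMES, "cds_length")
    mask <- matrix(stats::runif(n * length(maskable)) < config$missing_rate,
                   n, length(maskable))
    aux[, maskable][mask] <- NA_real_
  }
  for (i in seq_len(n)) records[[i]]$auxiliary <- aux[i, ]

  truth <- list(
    true_labels = labels,
    informative_features = c(informative,
                             if (config$go_effect > 0) module_terms,
                             if (config$aux_effect > 0) names(.AUX_SHIFTED)),
    latent_rates = rates,
    module_genes = module_genes
  )
  list(records = records, network = g, annotations = annotations,
       rates = rates, truth = truth, config = config)
}

#' Write a generated dataset to disk in the package's input formats
#'
#' Produces exactly the files the readers consume: `cds.fasta`,
#' `protein.fasta`, `aux.tsv`, `rates.tsv`, `network.tsv` (edge list) and
#' `annotations.tsv` (gene/term pairs), plus `orfs.tsv` listing the ORF ids
#' and upstream UTRs.
#'
#' @param dataset Output of [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- vapply(dataset$records, `[[`, character(1), "orf_id")
  cds <- stats::setNames(vapply(dataset$records, `[[`, character(1), "cds"), ids)
  prot <- stats::setNames(vapply(dataset$records, `[[`, character(1), "protein"), ids)
  utr <- vapply(dataset$records, `[[`, character(1), "upstream_utr")
  write_fasta(cds, file.path(dir, "cds.fasta"))
  write_fasta(prot, file.path(dir, "protein.fasta"))
  utils::write.table(data.frame(orf = ids, upstream_utr = utr),
                     file.path(dir, "orfs.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  aux <- do.call(rbind, lapply(dataset$records, `[[`, "auxiliary"))
  write_feature_matrix(feature_matrix(aux, ids, colnames(aux)),
                       file.path(dir, "aux.tsv"))
  utils::write.table(data.frame(orf = ids,
                                rate = sprintf("%.17g", dataset$rates[ids])),
                     file.path(dir, "rates.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  el <- igraph::as_edgelist(dataset$network)
  utils::write.table(el, file.path(dir, "network.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  ann <- data.frame(
    gene = unlist(dataset$annotations$term_to_genes, use.names = FALSE),
    term = rep(names(dataset$annotations$term_to_genes),
               lengths(dataset$annotations$term_to_genes))
  )
  utils::write.table(ann, file.path(dir, "annotations.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Small fixed worked-example fixtures
#'
#' The hand-checkable fixtures used throughout the documentation and tests:
#' a 6-sample by 4-binary-feature mRMR table with labels, the 4-point 2-D
#' nearest-neighbor layout, and the N = 10 enrichment query whose upper-tail
#' probability is 5/210.
#'
#' @return List with elements `mrmr` (list: `x`, `labels`), `nna` (list:
#'   `x`, `labels`), and `enrichment` (an [enrichment_query()]).
#' @export
worked_example_tables <- function() {
  mrmr_x <- feature_matrix(
    cbind(f1 = c(0, 0, 0, 1, 1, 1),
          f2 = c(1, 1, 1, 0, 0, 0),
          f3 = c(0, 0, 1, 1, 1, 1),
          f4 = c(0, 1, 0, 1, 0, 1)),
    sample_ids = paste0("s", 1:6)
  )
  nna_x <- feature_matrix(
    rbind(c(1, 0), c(0.9, 0.1), c(0, 1), c(0.1, 0.9)),
    sample_ids = paste0("p", 1:4), feature_names = c("x", "y")
  )
  list(
    mrmr = list(x = mrmr_x,
                labels = factor(c("low", "low", "low", "high", "high", "high"),
                                levels = c("low", "high"))),
    nna = list(x = nna_x,
               labels = factor(c("low", "low", "high", "high"),
                               levels = c("low", "high"))),
    enrichment = enrichment_query(universe_size = 10, term_size = 5,
                                  neighborhood_size = 4, overlap = 4)
  )
}
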