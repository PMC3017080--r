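# Network-neighborhood GO enrichment: for each (gene, term) pair, the
# -log10 upper-tail hypergeometric p-value of the term among the gene's
# network neighborhood (the gene plus its direct interactors).

#' Construct a neighborhood enrichment query
#'
#' The four counts of the hypergeometric test: `universe_size` (N, all ORFs),
#' `term_size` (ORFs annotated to the term), `neighborhood_size` (the gene
#' plus its neighbors, counted within the universe) and `overlap`
#' (neighborhood members annotated to the term).
#'
#' @param universe_size,term_size,neighborhood_size,overlap Non-negative
#'   integers satisfying `overlap <= min(term_size, neighborhood_size)` and
#'   `term_size, neighborhood_size <= universe_size`.
#' @return A list of class `"enrichment_query"`.
#' @export
enrichment_query <- function(universe_size, term_size, neighborhood_size,
                             overlap) {
  v <- c(universe_size = universe_size, term_size = term_size,
         neighborhood_size = neighborhood_size, overlap = overlap)
  if (any(v < 0) || any(v != round(v)))
    stop("all query counts must be non-negative integers", call. = FALSE)
  if (term_size > universe_size || neighborhood_size > universe_size)
    stop("term and neighborhood sizes cannot exceed the universe", call. = FALSE)
  if (overlap > min(term_size, neighborhood_size))
    stop("overlap exceeds min(term_size, neighborhood_size)", call. = FALSE)
  structure(as.list(v), class = "enrichment_query")
}

#' Upper-tail hypergeometric probability of an enrichment query
#'
#' P(X >= overlap) for X ~ Hypergeometric(universe_size, term_size,
#' neighborhood_size): the over-representation reading (larger overlap,
#' smaller p). Computed with [stats::phyper()].
#'
#' @param q An [enrichment_query()].
#' @return Probability in (0, 1].
#' @export
hypergeom_upper_p <- function(q) {
  stopifnot(inherits(q, "enrichment_query"))
  stats::phyper(q$overlap - 1, q$term_size,
                q$universe_size - q$term_size,
                q$neighborhood_size, lower.tail = FALSE)
}

#' Network neighborhood of a gene
#'
#' The gene itself plus its direct neighbors. A gene absent from the network
#' has neighborhood `{gene}`.
#'
#' @param gene Gene id.
#' @param network An undirected [igraph::igraph] with named vertices.
#' @return Character vector of gene ids (gene first).
#' @export
gene_neighborhood <- function(gene, network) {
  vn <- igraph::V(network)$name
  if (is.null(vn) || !gene %in% vn) return(gene)
  nb <- names(igraph::neighbors(network, gene))
  unique(c(gene, nb))
}

#' Neighborhood GO enrichment score of one (gene, term) pair
#'
#' `-log10` of the upper-tail hypergeometric p-value of the term among the
#' gene's network neighborhood; larger means more over-represented. The
#' p-value is floored at 1e-300 before the log so scores stay finite.
#' Neighborhood members outside the annotation universe are not counted.
#'
#' @param gene Gene id.
#' @param term Term id; must exist in `annotations`.
#' @param network An undirected [igraph::igraph].
#' @param annotations A [go_annotation_set()].
#' @return Non-negative score.
#' @export
enrichment_score <- function(gene, term, network, annotations) {
  stopifnot(inherits(annotations, "go_annotation_set"))
  if (!term %in% names(annotations$term_to_genes))
    stop("unknown GO term '", term, "'", call. = FALSE)
  nb <- intersect(gene_neighborhood(gene, network), annotations$universe)
  if (!gene %in% annotations$universe) nb <- union(gene, nb)
  tg <- annotations$term_to_genes[[term]]
  q <- enrichment_query(
    universe_size = length(annotations$universe),
    term_size = length(tg),
    neighborhood_size = length(nb),
    overlap = length(intersect(nb, tg))
  )
  -log10(max(hypergeom_upper_p(q), 1e-300))
}

#' Enrichment-score feature matrix
#'
#' One row per gene (input order) and one column per term (sorted term id,
#' so column order is deterministic).
#'
#' @param genes Character vector of gene ids.
#' @param terms Character vector of term ids; default all annotated terms.
#' @param network An undirected [igraph::igraph].
#' @param annotations A [go_annotation_set()].
#' @return A [feature_matrix()] of dimension `length(genes) x length(terms)`.
#' @export
enrichment_matrix <- function(genes, terms = NULL, network, annotations) {
  stopifnot(inherits(annotations, "go_annotation_set"))
  if (is.null(terms)) terms <- names(annotations$term_to_genes)
  if (length(terms) == 0L) stop("no GO terms supplied", call. = FALSE)
  missing <- setdiff(terms, names(annotations$term_to_genes))
  if (length(missing))
    stop("unknown GO term(s): ", paste(utils::head(missing, 5L), collapse = ", "),
         call. = FALSE)
  terms <- sort(terms)
  universe <- annotations$universe
  N <- length(universe)
  term_genes <- annotations$term_to_genes[terms]
  term_size <- lengths(term_genes)
  # invert to gene -> term indices for fast neighborhood overlap counting
  g2t <- split(rep(seq_along(term_genes), term_size),
               unlist(term_genes, use.names = FALSE))
  rows <- lapply(genes, function(g) {
    nb <- intersect(gene_neighborhood(g, network), universe)
    if (!g %in% universe) nb <- union(g, nb)
    m <- length(nb)
    hits <- unlist(g2t[intersect(nb, names(g2t))], use.names = FALSE)
    overlap <- tabulate(if (is.null(hits)) integer(0) else hits,
                        nbins = length(terms))
    p <- stats::phyper(overlap - 1, term_size, N - term_size, m,
                       lower.tail = FALSE)
    -log10(pmax(p, 1e-300))
  })
  feature_matrix(do.call(rbind, rows), sample_ids = genes,
                 feature_names = terms)
}
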