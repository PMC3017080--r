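#' Read a FASTA file
#'
#' Thin validating wrapper around [Biostrings::readBStringSet()]. Sequences
#' are uppercased and checked against the requested alphabet; record order is
#' preserved.
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"dna"` (A/C/G/T only) or `"protein"` (the 20 standard
#'   one-letter residue codes).
#' @return A named character vector: names are record ids (header up to the
#'   first whitespace, trimmed), values the uppercased sequences. An empty
#'   file yields an empty vector.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">orf1", "atggct"), fa)
#' read_fasta(fa, "dna")
read_fasta <- function(path, alphabet = c("dna", "protein")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) {
      stop("malformed FASTA in '", path, "': ", conditionMessage(e),
           call. = FALSE)
    }
  )
  if (length(set) == 0L) return(stats::setNames(character(0), character(0)))
  ids <- trimws(sub("\\s.*$", "", names(set)))
  if (any(!nzchar(ids))) {
    stop("FASTA record ", which(!nzchar(ids))[1L], " in '", path,
         "' has an empty header", call. = FALSE)
  }
  seqs <- toupper(as.character(set))
  pat <- if (alphabet == "dna") "^[ACGT]*$" else "^[ACDEFGHIKLMNPQRSTVWY]*$"
  bad <- !grepl(pat, seqs)
  if (any(bad)) {
    stop("record '", ids[which(bad)[1L]], "' contains characters outside the ",
         alphabet, " alphabet", call. = FALSE)
  }
  stats::setNames(seqs, ids)
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a tab-separated table with required columns
#'
#' Empty cells and literal `NA` are read as missing values (never silently as
#' zero).
#'
#' @param path Path to a TSV file with a header row.
#' @param required_columns Character vector of column names that must be
#'   present.
#' @return A data frame.
#' @export
read_table <- function(path, required_columns = character(0)) {
  if (!file.exists(path)) stop("table not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("", "NA"))
  missing <- setdiff(required_columns, names(df))
  if (length(missing)) {
    stop("table '", path, "' lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df
}

#' Read an undirected gene-gene interaction network
#'
#' Accepts a two-column whitespace- or tab-delimited edge list. Duplicate and
#' reversed edges are collapsed; self-loops are dropped (with a message giving
#' the count). Gene identifiers are matched case-sensitively after whitespace
#' trimming.
#'
#' @param path Path to the edge-list file.
#' @return An undirected, simplified [igraph::igraph] object whose vertex
#'   names are the gene ids appearing in the file.
#' @export
read_network <- function(path) {
  if (!file.exists(path)) stop("network file not found: ", path, call. = FALSE)
  df <- tryCatch(
    utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                      colClasses = "character"),
    error = function(e) {
      stop("cannot parse edge list '", path, "': ", conditionMessage(e),
           call. = FALSE)
    }
  )
  if (nrow(df) == 0L) return(igraph::make_empty_graph(directed = FALSE))
  if (ncol(df) != 2L) {
    stop("edge list '", path, "' must have exactly 2 fields per line, found ",
         ncol(df), call. = FALSE)
  }
  df[] <- lapply(df, trimws)
  n_loops <- sum(df[[1L]] == df[[2L]])
  if (n_loops > 0L) message("read_network: dropped ", n_loops, " self-loop(s)")
  g <- igraph::graph_from_data_frame(df, directed = FALSE)
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Assemble a feature matrix
#'
#' The feature-matrix container used throughout the package is a plain
#' numeric matrix with sample ids as row names and unique feature names as
#' column names; missing values are `NA` and are excluded from every
#' statistic (imputation happens only at classification time).
#'
#' @param values Numeric matrix (samples x features).
#' @param sample_ids Row names; default taken from `values`.
#' @param feature_names Column names; default taken from `values`.
#' @return A validated numeric matrix with dimnames.
#' @export
feature_matrix <- function(values, sample_ids = rownames(values),
                           feature_names = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(sample_ids) || length(sample_ids) != nrow(values))
    stop("sample_ids must name every row", call. = FALSE)
  if (is.null(feature_names) || length(feature_names) != ncol(values))
    stop("feature_names must name every column", call. = FALSE)
  if (anyDuplicated(feature_names))
    stop("duplicate feature names: ",
         paste(unique(feature_names[duplicated(feature_names)]), collapse = ", "),
         call. = FALSE)
  dimnames(values) <- list(as.character(sample_ids), as.character(feature_names))
  values
}

#' Write / read a feature matrix as TSV
#'
#' The first column holds sample ids; empty cells mean missing. Values are
#' serialized at full double precision so that a write/read round trip is
#' bit-exact.
#'
#' @param x Feature matrix (see [feature_matrix()]).
#' @param path Output (or input) path.
#' @return `write_feature_matrix()` returns `path` invisibly;
#'   `read_feature_matrix()` returns the matrix.
#' @export
write_feature_matrix <- function(x, path) {
  fmt <- function(v) ifelse(is.na(v), "", sprintf("%.17g", v))
  lines <- c(
    paste(c("sample", colnames(x)), collapse = "\t"),
    vapply(seq_len(nrow(x)), function(i) {
      paste(c(rownames(x)[i], fmt(x[i, ])), collapse = "\t")
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  df <- read_table(path, required_columns = "sample")
  ids <- as.character(df[["sample"]])
  df[["sample"]] <- NULL
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  feature_matrix(m, sample_ids = ids, feature_names = colnames(df))
}

#' Construct a GO annotation set
#'
#' @param term_to_genes Named list: term id -> character vector of gene ids,
#'   or a two-column data frame with columns `gene` and `term`.
#' @param universe Character vector of all gene/ORF ids (the hypergeometric
#'   population). Every annotated gene must be a member.
#' @return An object of class `"go_annotation_set"` with elements
#'   `term_to_genes` (named list of unique gene sets) and `universe`.
#' @export
go_annotation_set <- function(term_to_genes, universe) {
  universe <- unique(trimws(as.character(universe)))
  if (is.data.frame(term_to_genes)) {
    df <- term_to_genes
    if (!all(c("gene", "term") %in% names(df)))
      stop("annotation data frame needs columns 'gene' and 'term'", call. = FALSE)
    term_to_genes <- split(trimws(as.character(df$gene)),
                           trimws(as.character(df$term)))
  }
  term_to_genes <- lapply(term_to_genes, function(g) unique(trimws(as.character(g))))
  if (any(lengths(term_to_genes) == 0L))
    stop("empty GO terms are not allowed", call. = FALSE)
  stray <- setdiff(unique(unlist(term_to_genes, use.names = FALSE)), universe)
  if (length(stray))
    stop("annotated gene(s) outside the universe: ",
         paste(utils::head(stray, 5L), collapse = ", "), call. = FALSE)
  structure(list(term_to_genes = term_to_genes, universe = universe),
            class = "go_annotation_set")
}

#' Read gene-to-term GO annotations from TSV
#'
#' @param path TSV with columns `gene` and `term`, one pair per line.
#' @param universe Character vector of all ORF ids; the universe is supplied
#'   explicitly (from the ORF list), never inferred from annotation coverage.
#' @return A [go_annotation_set()].
#' @export
read_go_annotations <- function(path, universe) {
  df <- read_table(path, required_columns = c("gene", "term"))
  go_annotation_set(df, universe = universe)
}
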