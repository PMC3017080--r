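# Nucleotide-level encoders: codon usage, start-codon context, CDS length,
# and the 42-nt window across the translation start site.

#' The 64 codons in fixed lexicographic order
#'
#' @return Character vector of the 64 trinucleotides over A/C/G/T, sorted
#'   lexicographically (AAA, AAC, ..., TTT). Stop codons are included: the
#'   codon-usage feature block has exactly 64 entries.
#' @export
codon_table <- function() {
  bases <- c("A", "C", "G", "T")
  eg <- expand.grid(b3 = bases, b2 = bases, b1 = bases,
                    stringsAsFactors = FALSE)
  paste0(eg$b1, eg$b2, eg$b3)
}

.CODONS <- codon_table()

codons <- function() .CODONS

.check_dna <- function(x, what = "sequence") {
  if (!is.character(x) || length(x) != 1L)
    stop(what, " must be a single string", call. = FALSE)
  if (grepl("[^ACGT]", x))
    stop(what, " contains characters outside A/C/G/T", call. = FALSE)
  invisible(x)
}

#' Codon relative frequencies of a coding sequence
#'
#' Counts each of the 64 codons in frame and divides by the total number of
#' codons; the result sums to 1. A trailing partial codon is dropped with a
#' warning (annotation slippage is tolerated rather than fatal).
#'
#' @param cds DNA string (A/C/G/T), length >= 3.
#' @return Named numeric vector of length 64 in [codon_table()] order.
#' @export
#' @examples
#' codon_usage("ATGGCTGCTTAA")[c("ATG", "GCT", "TAA")]
codon_usage <- function(cds) {
  .check_dna(cds, "cds")
  n <- nchar(cds)
  if (n < 3L) stop("cds shorter than one codon", call. = FALSE)
  if (n %% 3L != 0L) {
    warning("cds length ", n, " not divisible by 3; trailing partial codon dropped")
    n <- n - n %% 3L
  }
  cod <- substring(cds, seq(1L, n - 2L, by = 3L), seq(3L, n, by = 3L))
  counts <- tabulate(match(cod, codons()), nbins = 64L)
  stats::setNames(counts / sum(counts), codons())
}

#' One-hot encoding of the start-codon context
#'
#' Encodes the 3 bases immediately upstream of the initial ATG and the 3
#' bases immediately downstream of it (CDS positions +4..+6) as six
#' concatenated one-hot 4-vectors. The base-to-position mapping is the fixed
#' convention A, C, G, T.
#'
#' @param upstream3 DNA string of length 3 (positions -3..-1).
#' @param downstream3 DNA string of length 3 (CDS positions +4..+6, i.e. the
#'   codon after ATG).
#' @return Named binary vector of length 24 with exactly six 1s.
#' @export
start_codon_context <- function(upstream3, downstream3) {
  .check_dna(upstream3, "upstream3")
  .check_dna(downstream3, "downstream3")
  if (nchar(upstream3) != 3L || nchar(downstream3) != 3L)
    stop("both flanks must be exactly 3 nt", call. = FALSE)
  bases <- c("A", "C", "G", "T")
  six <- strsplit(paste0(upstream3, downstream3), "")[[1L]]
  pos_labels <- c("u3", "u2", "u1", "d1", "d2", "d3")
  out <- numeric(24L)
  names(out) <- paste0("sc_", rep(pos_labels, each = 4L), "_", rep(bases, 6L))
  out[(seq_along(six) - 1L) * 4L + match(six, bases)] <- 1
  out
}

#' Coding-sequence length in nucleotides
#'
#' @param cds DNA string.
#' @return Integer nucleotide count.
#' @export
cds_length <- function(cds) {
  .check_dna(cds, "cds")
  if (nchar(cds) == 0L) stop("cds is empty", call. = FALSE)
  nchar(cds)
}

#' Extract the 42-nt window across the translation start site
#'
#' Returns the 4 nt immediately upstream of the A of the start ATG followed
#' by the first 38 nt of the CDS, 42 nt in total. This is the window whose
#' predicted folding energy is used as an auxiliary feature (the energy
#' itself is consumed from the auxiliary table, not computed here).
#'
#' Coordinate convention: "-4 to +37 relative to the start site" with a
#' stated width of 42 nt is arithmetically ambiguous (the inclusive span
#' skipping 0 has 41 nt); this package fixes the window as 4 upstream + 38
#' coding nucleotides so the width is exactly 42.
#'
#' @param upstream_utr DNA string, length >= 4.
#' @param cds DNA string, length >= 38.
#' @param orf_id Optional id used in error messages.
#' @return DNA string of length 42.
#' @export
tss_window <- function(upstream_utr, cds, orf_id = "<unnamed>") {
  .check_dna(upstream_utr, "upstream_utr")
  .check_dna(cds, "cds")
  if (nchar(upstream_utr) < 4L)
    stop("ORF '", orf_id, "': upstream UTR shorter than 4 nt", call. = FALSE)
  if (nchar(cds) < 38L)
    stop("ORF '", orf_id, "': cds shorter than 38 nt", call. = FALSE)
  paste0(substring(upstream_utr, nchar(upstream_utr) - 3L, nchar(upstream_utr)),
         substring(cds, 1L, 38L))
}
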