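# The 132 biochemical/physicochemical protein descriptors:
# 20 amino-acid composition fractions, a 7-value CTD block for the two-group
# solvent-accessibility property, and 21-value CTD blocks for five
# three-group properties (hydrophobicity, polarizability, normalized van der
# Waals volume, polarity, secondary structure).

.AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]

#' Amino-acid grouping schemes for CTD descriptors
#'
#' Returns the partition of the 20 standard residues (or of per-residue
#' annotation symbols) into the pseudo-groups used by the CTD descriptors.
#' The residue group lists for hydrophobicity, polarizability, normalized van
#' der Waals volume and polarity follow the standard published groupings;
#' secondary structure (helix/strand/coil) and solvent accessibility
#' (exposed/buried) are annotation-driven, with a deterministic per-residue
#' propensity fallback (see [to_group_sequence()]).
#'
#' @return Named list; each element has `groups` (named list of symbols) and
#'   `alphabet` (`"residue"` or `"annotation"`).
#' @export
property_schemes <- function() {
  list(
    solvent_accessibility = list(
      alphabet = "annotation",
      groups = list(exposed = "E", buried = "B"),
      fallback = list(
        buried  = c("A", "C", "F", "I", "L", "M", "V", "W"),
        exposed = c("D", "E", "G", "H", "K", "N", "P", "Q", "R", "S", "T", "Y")
      )
    ),
    hydrophobicity = list(
      alphabet = "residue",
      groups = list(
        hydrophobic = c("C", "V", "F", "L", "I", "M", "W"),
        neutral     = c("G", "P", "H", "A", "S", "T", "Y"),
        polar       = c("Q", "E", "R", "K", "D", "N")
      )
    ),
    polarizability = list(
      alphabet = "residue",
      groups = list(
        g1 = c("Y", "M", "K", "R", "H", "F", "W"),
        g2 = c("C", "Q", "I", "P", "N", "V", "E", "L"),
        g3 = c("S", "D", "G", "A", "T")
      )
    ),
    vdw_volume = list(
      alphabet = "residue",
      groups = list(
        g1 = c("K", "F", "M", "H", "R", "Y", "W"),
        g2 = c("E", "Q", "N", "V", "I", "L"),
        g3 = c("S", "C", "G", "A", "T", "P", "D")
      )
    ),
    polarity = list(
      alphabet = "residue",
      groups = list(
        polar       = c("K", "N", "H", "Q", "R", "E", "D"),
        neutral     = c("T", "G", "P", "A", "S"),
        hydrophobic = c("W", "C", "L", "I", "F", "M", "V", "Y")
      )
    ),
    secondary_structure = list(
      alphabet = "annotation",
      groups = list(helix = "H", strand = "E", coil = "C"),
      fallback = list(
        helix  = c("A", "E", "L", "M", "Q", "K", "R", "H"),
        strand = c("V", "I", "Y", "C", "W", "F", "T"),
        coil   = c("G", "N", "P", "S", "D")
      )
    )
  )
}

.check_protein <- function(protein) {
  if (!is.character(protein) || length(protein) != 1L || nchar(protein) == 0L)
    stop("protein must be a nonempty string", call. = FALSE)
  res <- strsplit(protein, "")[[1L]]
  bad <- which(!res %in% .AA)
  if (length(bad))
    stop("illegal residue '", res[bad[1L]], "' at position ", bad[1L],
         call. = FALSE)
  res
}

#' Amino-acid composition
#'
#' @param protein Protein string over the 20-letter alphabet.
#' @return Named numeric vector of 20 fractions summing to 1, in alphabetical
#'   residue order.
#' @export
aa_composition <- function(protein) {
  res <- .check_protein(protein)
  counts <- tabulate(match(res, .AA), nbins = 20L)
  stats::setNames(counts / length(res), .AA)
}

#' Map a protein to its pseudo-group index sequence
#'
#' For residue-based properties the mapping uses the residue identity; for
#' secondary structure and solvent accessibility it uses the per-residue
#' annotation string (symbols H/E/C and E/B respectively). When the
#' annotation is absent and `fallback = TRUE`, a deterministic per-residue
#' propensity table assigns each residue to its most likely group, so the
#' full 132-feature vector is always computable; real annotations override
#' the fallback.
#'
#' @param protein Protein string.
#' @param property Name of a scheme in [property_schemes()].
#' @param annotation Optional per-residue annotation string, same length as
#'   `protein` (required alphabet depends on the property).
#' @param fallback Use the propensity fallback when a required annotation is
#'   missing? Default `TRUE`.
#' @return Integer vector of group indices (1..2 or 1..3), one per residue.
#' @export
to_group_sequence <- function(protein, property, annotation = NULL,
                              fallback = TRUE) {
  schemes <- property_schemes()
  if (!property %in% names(schemes))
    stop("unknown property '", property, "'", call. = FALSE)
  sch <- schemes[[property]]
  res <- .check_protein(protein)
  if (sch$alphabet == "residue") {
    map <- stats::setNames(rep(seq_along(sch$groups), lengths(sch$groups)),
                           unlist(sch$groups, use.names = FALSE))
    return(unname(map[res]))
  }
  # annotation-driven property
  if (!is.null(annotation)) {
    sym <- strsplit(toupper(annotation), "")[[1L]]
    if (length(sym) != length(res))
      stop(property, " annotation length ", length(sym),
           " does not match protein length ", length(res), call. = FALSE)
    map <- stats::setNames(rep(seq_along(sch$groups), lengths(sch$groups)),
                           unlist(sch$groups, use.names = FALSE))
    idx <- map[sym]
    if (anyNA(idx))
      stop("illegal ", property, " annotation symbol '",
           sym[which(is.na(idx))[1L]], "'", call. = FALSE)
    return(unname(idx))
  }
  if (!fallback)
    stop("property '", property, "' requires a per-residue annotation ",
         "(fallback disabled)", call. = FALSE)
  map <- stats::setNames(rep(seq_along(sch$fallback), lengths(sch$fallback)),
                         unlist(sch$fallback, use.names = FALSE))
  unname(map[res])
}

#' Composition-transition-distribution block for a group sequence
#'
#' Composition: the fraction of positions in each group. Transition: for
#' each unordered group pair, the number of adjacent positions whose groups
#' differ as that pair, divided by L-1. Distribution: for each group, the
#' relative sequence position (position / L) of its first occurrence and of
#' occurrence number `ceiling(q * n)` for q = 0.25, 0.5, 0.75, 1 among its n
#' occurrences; absent groups report zeros.
#'
#' Block sizes: three groups give 3 + 3 + 15 = 21 values; two groups give
#' 2 + 1 + 4 = 7 (composition, the single transition pair, and the
#' distribution of the first group only), matching the 132-feature layout.
#'
#' @param group_seq Integer vector of group indices.
#' @param group_count 2 or 3.
#' @return Named numeric vector of length 21 (3 groups) or 7 (2 groups).
#' @export
ctd_block <- function(group_seq, group_count) {
  if (length(group_seq) < 1L) stop("empty group sequence", call. = FALSE)
  if (!group_count %in% c(2L, 3L)) stop("group_count must be 2 or 3", call. = FALSE)
  if (any(!group_seq %in% seq_len(group_count)))
    stop("group indices must lie in 1..", group_count, call. = FALSE)
  L <- length(group_seq)
  gs <- seq_len(group_count)

  comp <- vapply(gs, function(g) mean(group_seq == g), numeric(1))
  names(comp) <- paste0("comp_g", gs)

  pairs <- utils::combn(gs, 2L)
  if (L >= 2L) {
    a <- group_seq[-L]; b <- group_seq[-1L]
    lo <- pmin(a, b); hi <- pmax(a, b)
    trans <- vapply(seq_len(ncol(pairs)), function(j) {
      sum(lo == pairs[1L, j] & hi == pairs[2L, j]) / (L - 1L)
    }, numeric(1))
  } else {
    trans <- numeric(ncol(pairs))
  }
  names(trans) <- paste0("trans_g", pairs[1L, ], "g", pairs[2L, ])

  dist_one <- function(g) {
    pos <- which(group_seq == g)
    n <- length(pos)
    if (n == 0L) return(numeric(5L))
    idx <- c(1L, pmax(1L, ceiling(c(0.25, 0.5, 0.75, 1) * n)))
    pos[idx] / L
  }
  dist_groups <- if (group_count == 3L) gs else 1L
  q_names <- c("first", "q25", "q50", "q75", "last")
  dist <- unlist(lapply(dist_groups, function(g) {
    stats::setNames(dist_one(g), paste0("dist_g", g, "_", q_names))
  }))
  if (group_count == 2L) dist <- dist[1:4]  # first/25/50/75 of group 1 only

  c(comp, trans, dist)
}

#' The 132-value biochemical/physicochemical feature vector of a protein
#'
#' Concatenates the amino-acid composition (20), the solvent-accessibility
#' CTD block (7) and the CTD blocks of the five three-group properties
#' (hydrophobicity, polarizability, normalized van der Waals volume,
#' polarity, secondary structure; 21 each), for 132 named values.
#'
#' @param protein Protein string.
#' @param ss_annotation Optional per-residue secondary-structure string
#'   (H/E/C).
#' @param acc_annotation Optional per-residue solvent-accessibility string
#'   (E/B).
#' @param fallback Use the deterministic propensity fallback for missing
#'   annotations? Default `TRUE`; with `FALSE`, a missing annotation is an
#'   error.
#' @return Named numeric vector of length 132.
#' @export
protein_feature_vector <- function(protein, ss_annotation = NULL,
                                   acc_annotation = NULL, fallback = TRUE) {
  aa <- aa_composition(protein)
  names(aa) <- paste0("aa_", names(aa))
  blocks <- list(
    acc = ctd_block(to_group_sequence(protein, "solvent_accessibility",
                                      acc_annotation, fallback), 2L),
    hyd = ctd_block(to_group_sequence(protein, "hydrophobicity"), 3L),
    plz = ctd_block(to_group_sequence(protein, "polarizability"), 3L),
    vdw = ctd_block(to_group_sequence(protein, "vdw_volume"), 3L),
    pol = ctd_block(to_group_sequence(protein, "polarity"), 3L),
    ss  = ctd_block(to_group_sequence(protein, "secondary_structure",
                                      ss_annotation, fallback), 3L)
  )
  out <- c(aa, unlist(lapply(names(blocks), function(p) {
    stats::setNames(blocks[[p]], paste0(p, "_", names(blocks[[p]])))
  })))
  stopifnot(length(out) == 132L)
  out
}
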