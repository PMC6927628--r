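#' Classify marker bands into monomorphic/polymorphic and diagnostic sets
#'
#' Categories follow the standard dominant-marker definitions: a band is
#' monomorphic when present in all scored specimens and polymorphic when
#' present in at least one but not all. A band is unique to a parental taxon
#' when present in at least one of its specimens and absent from all
#' specimens of the other parental taxon; it is diagnostic
#' (species-specific) when present in every specimen of one parental taxon
#' and absent from every specimen of the other. Query specimens never
#' affect unique/diagnostic calls, so adding putative hybrids cannot change
#' the diagnostic sets. Loci present only in excluded groups (by default the
#' outgroup) are dropped before classification and reported in
#' `excluded_loci`.
#'
#' @param matrix a [marker_matrix()].
#' @param meta a [specimen_meta()] covering all specimens.
#' @param exclude_groups groups removed before scoring (default
#'   `"outgroup"`).
#' @param max_violations diagnostic-strictness tolerance: the maximum number
#'   of specimens per parental group allowed to violate the fixed
#'   present/absent pattern (default 0, strict fixation).
#' @return an object of class `band_classification`: list with `category`
#'   (named factor, monomorphic/polymorphic), logical per-locus flags
#'   `unique_to_A`, `unique_to_B`, `diagnostic_A`, `diagnostic_B`,
#'   `novel_in_query`, plus `counts`, `excluded_loci` and the scored locus
#'   ids.
#' @export
classify_bands <- function(matrix, meta, exclude_groups = "outgroup",
                           max_violations = 0L) {
  stopifnot(inherits(matrix, "marker_matrix"))
  grp <- meta_group(matrix, meta)
  keep <- !(grp %in% exclude_groups)
  v <- matrix$values[keep, , drop = FALSE]
  grp <- grp[keep]
  nA <- sum(grp == "parent_A"); nB <- sum(grp == "parent_B")
  if (nA < 1 || nB < 1)
    stop_hb("need >= 1 specimen in each parental group after exclusions (parent_A: %d, parent_B: %d)",
            nA, nB, class = "classification_error")
  # loci present only in excluded specimens carry no information here
  scored <- colSums(v) > 0 | colSums(matrix$values) == 0
  excluded_loci <- locus_ids(matrix)[!scored]
  v <- v[, scored, drop = FALSE]
  loci <- colnames(v)

  presA <- colSums(v[grp == "parent_A", , drop = FALSE])
  presB <- colSums(v[grp == "parent_B", , drop = FALSE])
  tot <- colSums(v)

  category <- factor(ifelse(tot == nrow(v), "monomorphic", "polymorphic"),
                     levels = c("monomorphic", "polymorphic"))
  names(category) <- loci
  unique_to_A <- presA >= 1 & presB == 0
  unique_to_B <- presB >= 1 & presA == 0
  diagnostic_A <- (presA >= nA - max_violations) & (presB <= max_violations)
  diagnostic_B <- (presB >= nB - max_violations) & (presA <= max_violations)
  # diagnostic implies unique under strict fixation; keep the implication
  # under a nonzero tolerance too
  diagnostic_A <- diagnostic_A & unique_to_A
  diagnostic_B <- diagnostic_B & unique_to_B
  has_query <- any(grp == "query")
  presQ <- if (has_query) colSums(v[grp == "query", , drop = FALSE]) else
    rep(0L, length(loci))
  novel_in_query <- presQ >= 1 & presA == 0 & presB == 0

  counts <- c(scored = length(loci),
              monomorphic = sum(category == "monomorphic"),
              polymorphic = sum(category == "polymorphic"),
              unique_to_A = sum(unique_to_A), unique_to_B = sum(unique_to_B),
              diagnostic_A = sum(diagnostic_A), diagnostic_B = sum(diagnostic_B),
              novel_in_query = sum(novel_in_query),
              excluded = length(excluded_loci))
  structure(list(locus_ids = loci, category = category,
                 unique_to_A = setNames(unique_to_A, loci),
                 unique_to_B = setNames(unique_to_B, loci),
                 diagnostic_A = setNames(diagnostic_A, loci),
                 diagnostic_B = setNames(diagnostic_B, loci),
                 novel_in_query = setNames(novel_in_query, loci),
                 counts = counts, excluded_loci = excluded_loci),
            class = "band_classification")
}

#' @export
print.band_classification <- function(x, ...) {
  cat("band_classification\n")
  print(x$counts)
  invisible(x)
}

#' Loci carried only by query specimens (hybrid-novel bands)
#'
#' Bands present in at least one query specimen and absent from every
#' parental specimen; such non-parental bands are occasionally generated in
#' hybrids (e.g. by recombination or heteroduplex formation) and are useful
#' hybrid fingerprints.
#'
#' @param matrix a [marker_matrix()].
#' @param meta a [specimen_meta()].
#' @return character vector of locus ids (empty, with a warning, when there
#'   are no query specimens).
#' @export
novel_bands <- function(matrix, meta) {
  grp <- meta_group(matrix, meta)
  if (!any(grp == "query")) {
    warning("no query specimens; returning empty set")
    return(character(0))
  }
  v <- matrix$values
  presQ <- colSums(v[grp == "query", , drop = FALSE])
  presP <- colSums(v[grp %in% c("parent_A", "parent_B"), , drop = FALSE])
  locus_ids(matrix)[presQ >= 1 & presP == 0]
}

#' Export a band classification as a JSON report
#'
#' @param x a [classify_bands()] result.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_band_report <- function(x, path) {
  stopifnot(inherits(x, "band_classification"))
  rep <- list(
    counts = as.list(x$counts),
    monomorphic = x$locus_ids[x$category == "monomorphic"],
    polymorphic = x$locus_ids[x$category == "polymorphic"],
    unique_to_A = names(which(x$unique_to_A)),
    unique_to_B = names(which(x$unique_to_B)),
    diagnostic_A = names(which(x$diagnostic_A)),
    diagnostic_B = names(which(x$diagnostic_B)),
    novel_in_query = names(which(x$novel_in_query)),
    excluded_loci = x$excluded_loci)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
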