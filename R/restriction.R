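#' Built-in restriction enzyme panel
#'
#' The ten-enzyme PCR-RFLP panel: recognition sequence and cut offset
#' (bases 5' of the cut on the forward strand). All panel enzymes are
#' palindromic cutters, so forward-strand matching covers both strands;
#' `N` in a recognition site (HinfI) means any of A/C/G/T in the substrate,
#' but `N` in the substrate never matches (conservative digestion; the same
#' holds for any IUPAC ambiguity code in the input).
#'
#' @return `data.frame` with columns `enzyme`, `recognition`, `cut_offset`.
#' @export
enzyme_panel <- function() {
  data.frame(
    enzyme = c("AluI", "DraI", "HindIII", "HinfI", "MboI",
               "MseI", "MspI", "PstI", "TaqI", "XbaI"),
    recognition = c("AGCT", "TTTAAA", "AAGCTT", "GANTC", "GATC",
                    "TTAA", "CCGG", "CTGCAG", "TCGA", "TCTAGA"),
    cut_offset = c(2L, 3L, 1L, 1L, 0L, 1L, 1L, 5L, 1L, 1L),
    stringsAsFactors = FALSE)
}

#' In-silico restriction digest of a linear sequence
#'
#' Cuts at every exact occurrence of the enzyme's recognition site, at the
#' enzyme's cut offset. Fragments are returned 5' to 3' and always sum to
#' the sequence length.
#'
#' @param seq nucleotide sequence over A/C/G/T/N (character scalar).
#' @param enzyme enzyme name from [enzyme_panel()], or a custom panel row.
#' @param panel enzyme table (default the built-in panel); extensible with
#'   rows `enzyme`, `recognition`, `cut_offset`.
#' @return integer vector of fragment lengths in 5'->3' order.
#' @export
restriction_digest <- function(seq, enzyme, panel = enzyme_panel()) {
  seq <- toupper(seq)
  if (!grepl("^[ACGTN]*$", seq))
    stop_hb("sequence must be over A/C/G/T/N", class = "input_error")
  row <- panel[panel$enzyme == enzyme, ]
  if (nrow(row) != 1)
    stop_hb("unknown enzyme '%s'; panel: %s", enzyme,
            paste(panel$enzyme, collapse = ", "), class = "input_error")
  # N in the recognition site is a wildcard over real bases only;
  # lookahead regex catches overlapping occurrences
  pat <- gsub("N", "[ACGT]", row$recognition, fixed = TRUE)
  hits <- gregexpr(paste0("(?=", pat, ")"), seq, perl = TRUE)[[1]]
  n <- nchar(seq)
  if (hits[1] == -1) return(n)
  cuts <- sort(unique(as.integer(hits) - 1L + row$cut_offset))
  cuts <- cuts[cuts > 0 & cuts < n]
  if (!length(cuts)) return(n)
  diff(c(0L, cuts, n))
}

#' Multi-enzyme RFLP profile of one sequence
#'
#' @param seq nucleotide sequence.
#' @param enzymes enzyme names (default: the full built-in panel).
#' @param panel enzyme table.
#' @return named list of fragment-length vectors, one per enzyme.
#' @export
rflp_profile <- function(seq, enzymes = enzyme_panel()$enzyme,
                         panel = enzyme_panel()) {
  setNames(lapply(enzymes, function(e) restriction_digest(seq, e, panel)),
           enzymes)
}

#' Group specimens into restriction-fragment haplotypes
#'
#' Specimens whose multi-enzyme fragment-length profiles are identical
#' (within `tolerance` bp per fragment) share a haplotype id. The
#' haplotype-to-group concordance table supports maternal-parent inference:
#' a chlorotype shared by one parental species and all hybrids points to
#' that species as the seed parent.
#'
#' @param seqs named character vector of (plastid) sequences per specimen.
#' @param enzymes enzyme names applied to every specimen (same panel for
#'   all).
#' @param groups optional named group vector (same names as `seqs`) for the
#'   concordance table.
#' @param tolerance fragment-length tolerance in bp (default 0, exact).
#' @param panel enzyme table.
#' @return list of class `rflp_haplotypes`: `haplotype` (named integer id
#'   per specimen), `profiles`, and `concordance` (haplotype x group count
#'   table, when `groups` given).
#' @export
rflp_haplotypes <- function(seqs, enzymes = enzyme_panel()$enzyme,
                            groups = NULL, tolerance = 0,
                            panel = enzyme_panel()) {
  stopifnot(length(seqs) >= 1, !is.null(names(seqs)))
  profiles <- lapply(seqs, rflp_profile, enzymes = enzymes, panel = panel)
  same <- function(p1, p2) {
    all(vapply(enzymes, function(e) {
      f1 <- p1[[e]]; f2 <- p2[[e]]
      length(f1) == length(f2) && all(abs(f1 - f2) <= tolerance)
    }, TRUE))
  }
  # assign ids in a canonical order (sorted specimen names) so the grouping
  # is invariant under input reordering
  ord <- order(names(seqs))
  hap <- setNames(rep(NA_integer_, length(seqs)), names(seqs))
  reps <- list()
  for (i in ord) {
    assigned <- FALSE
    for (h in seq_along(reps)) {
      if (same(profiles[[i]], reps[[h]])) {
        hap[i] <- h; assigned <- TRUE; break
      }
    }
    if (!assigned) {
      reps[[length(reps) + 1]] <- profiles[[i]]
      hap[i] <- length(reps)
    }
  }
  conc <- NULL
  if (!is.null(groups)) {
    if (!all(names(seqs) %in% names(groups)))
      stop_hb("groups must cover all specimens", class = "input_error")
    conc <- table(haplotype = hap, group = groups[names(seqs)])
  }
  structure(list(haplotype = hap, profiles = profiles, concordance = conc),
            class = "rflp_haplotypes")
}

#' @export
print.rflp_haplotypes <- function(x, ...) {
  cat(sprintf("rflp_haplotypes: %d specimens, %d haplotype(s)\n",
              length(x$haplotype), length(unique(x$haplotype))))
  if (!is.null(x$concordance)) print(x$concordance)
  invisible(x)
}
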