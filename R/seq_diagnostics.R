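#' Read sequences from a FASTA file
#'
#' Lowercase bases are normalized to uppercase; gap characters (`-`) are
#' preserved so pre-aligned input keeps its coordinate frame.
#'
#' @param path FASTA file.
#' @param aligned if `TRUE`, all records must have equal length.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path, aligned = FALSE) {
  ss <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(ss))
  if (aligned && length(unique(nchar(seqs))) > 1)
    stop_hb("alignment required but sequence lengths differ: %s",
            paste(unique(nchar(seqs)), collapse = ", "),
            class = "alignment_error")
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path, width = 70)
  invisible(path)
}

#' Build a grouped alignment
#'
#' Equal-length aligned sequences (IUPAC nucleotides plus `-` gaps), each
#' assigned to parental group A, parental group B, or query (e.g. cloned
#' hybrid sequences).
#'
#' @param seqs named character vector of aligned sequences.
#' @param group character vector (`parent_A`, `parent_B`, `query`), one per
#'   sequence.
#' @return list of class `grouped_alignment` with a character matrix `mat`
#'   (sequences x columns) and `group`.
#' @export
grouped_alignment <- function(seqs, group) {
  if (length(group) != length(seqs))
    stop_hb("one group per sequence required", class = "alignment_error")
  if (length(unique(nchar(seqs))) > 1)
    stop_hb("sequences must be aligned to equal length", class = "alignment_error")
  ok <- c("parent_A", "parent_B", "query")
  if (!all(group %in% ok))
    stop_hb("groups must be in {%s}", paste(ok, collapse = ", "),
            class = "alignment_error")
  if (sum(group == "parent_A") < 1 || sum(group == "parent_B") < 1)
    stop_hb("need >= 1 sequence per parental group", class = "alignment_error")
  mat <- do.call(rbind, strsplit(toupper(seqs), ""))
  rownames(mat) <- names(seqs) %||% paste0("seq", seq_along(seqs))
  structure(list(mat = mat, group = setNames(group, rownames(mat))),
            class = "grouped_alignment")
}

consensus_state <- function(col, min_fixation) {
  tab <- table(col)
  top <- names(tab)[which.max(tab)]
  if (tab[top] / length(col) >= min_fixation) top else NA_character_
}

#' Diagnostic SNPs between the parental groups of an alignment
#'
#' Alignment columns where the parent-A sequences share one non-gap state
#' and the parent-B sequences share a different non-gap state, at the given
#' fixation threshold. Query sequences never affect discovery. Positions
#' are 1-based alignment columns.
#'
#' @param aln a [grouped_alignment()].
#' @param min_group_fixation minimum fraction of a parental group required
#'   to share the modal state (default 1, strict fixation).
#' @return `data.frame` with columns `position`, `state_A`, `state_B`.
#' @export
find_diagnostic_snps <- function(aln, min_group_fixation = 1) {
  stopifnot(inherits(aln, "grouped_alignment"))
  A <- aln$mat[aln$group == "parent_A", , drop = FALSE]
  B <- aln$mat[aln$group == "parent_B", , drop = FALSE]
  out <- list()
  for (j in seq_len(ncol(aln$mat))) {
    sA <- consensus_state(A[, j], min_group_fixation)
    sB <- consensus_state(B[, j], min_group_fixation)
    if (!is.na(sA) && !is.na(sB) && sA != sB && sA != "-" && sB != "-")
      out[[length(out) + 1]] <- data.frame(position = j, state_A = sA,
                                           state_B = sB,
                                           stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(position = integer(0), state_A = character(0),
                      state_B = character(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

gap_runs <- function(x) {
  r <- rle(x == "-")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  data.frame(start = starts[r$values], end = ends[r$values])
}

#' Diagnostic indels between the parental groups of an alignment
#'
#' Maximal gap runs carried by every sequence of one parental group (with
#' identical boundaries) and absent, as gaps, from every sequence of the
#' other group. The carrier group is the one bearing the deletion.
#' Positions are 1-based alignment columns. Partially overlapping gaps that
#' are not fixed with identical boundaries are excluded.
#'
#' @param aln a [grouped_alignment()].
#' @return `data.frame` with columns `start`, `end`, `length`,
#'   `carrier_group` (`"parent_A"` or `"parent_B"`).
#' @export
find_diagnostic_indels <- function(aln) {
  stopifnot(inherits(aln, "grouped_alignment"))
  A <- aln$mat[aln$group == "parent_A", , drop = FALSE]
  B <- aln$mat[aln$group == "parent_B", , drop = FALSE]
  one_side <- function(carrier, other, label) {
    runs <- gap_runs(carrier[1, ])
    keep <- logical(nrow(runs))
    for (r in seq_len(nrow(runs))) {
      cols <- runs$start[r]:runs$end[r]
      fixed_in <- all(carrier[, cols] == "-")
      # boundaries identical: columns adjacent to the run are non-gap
      left_ok <- runs$start[r] == 1 || all(carrier[, runs$start[r] - 1] != "-")
      right_ok <- runs$end[r] == ncol(carrier) ||
        all(carrier[, runs$end[r] + 1] != "-")
      absent_in_other <- all(other[, cols] != "-")
      keep[r] <- fixed_in && left_ok && right_ok && absent_in_other
    }
    runs <- runs[keep, , drop = FALSE]
    if (!nrow(runs))
      return(data.frame(start = integer(0), end = integer(0),
                        length = integer(0), carrier_group = character(0),
                        stringsAsFactors = FALSE))
    data.frame(start = runs$start, end = runs$end,
               length = runs$end - runs$start + 1,
               carrier_group = label, stringsAsFactors = FALSE)
  }
  out <- rbind(one_side(A, B, "parent_A"), one_side(B, A, "parent_B"))
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Diagnostic sites (SNPs + indels) of a grouped alignment
#'
#' @param aln a [grouped_alignment()].
#' @param min_group_fixation passed to [find_diagnostic_snps()].
#' @return list of class `diagnostic_sites` with `snp` and `indel` data
#'   frames.
#' @export
diagnostic_sites <- function(aln, min_group_fixation = 1) {
  snp <- find_diagnostic_snps(aln, min_group_fixation)
  indel <- find_diagnostic_indels(aln)
  # a column inside a diagnostic indel cannot also be a diagnostic SNP
  if (nrow(indel)) {
    in_indel <- unlist(mapply(seq, indel$start, indel$end, SIMPLIFY = FALSE))
    snp <- snp[!(snp$position %in% in_indel), , drop = FALSE]
  }
  structure(list(snp = snp, indel = indel), class = "diagnostic_sites")
}

#' Score a clone sequence at the diagnostic sites
#'
#' Per diagnostic SNP the clone state is called `A`, `B` or `novel`
#' (neither parental state); per diagnostic indel, `A`/`B` according to
#' whether the clone carries the carrier group's gap, or `novel` for a
#' partial gap. Counts sum to the number of diagnostic sites.
#'
#' @param clone a single aligned sequence (same coordinate frame as the
#'   alignment the sites came from).
#' @param sites a [diagnostic_sites()] result.
#' @return list of class `clone_score`: `calls` (data frame with `site`,
#'   `type`, `call`), `n_A`, `n_B`, `n_novel`.
#' @export
score_clone <- function(clone, sites) {
  stopifnot(inherits(sites, "diagnostic_sites"))
  x <- strsplit(toupper(clone), "")[[1]]
  need <- max(c(sites$snp$position, sites$indel$end, 0))
  if (length(x) < need)
    stop_hb("clone length (%d) shorter than the diagnostic coordinate frame (%d)",
            length(x), need, class = "alignment_error")
  calls <- list()
  if (nrow(sites$snp)) {
    for (i in seq_len(nrow(sites$snp))) {
      s <- sites$snp[i, ]
      st <- x[s$position]
      call <- if (st == s$state_A) "A" else if (st == s$state_B) "B" else "novel"
      calls[[length(calls) + 1]] <- data.frame(
        site = s$position, type = "snp", call = call,
        stringsAsFactors = FALSE)
    }
  }
  if (nrow(sites$indel)) {
    for (i in seq_len(nrow(sites$indel))) {
      s <- sites$indel[i, ]
      cols <- s$start:s$end
      gapped <- x[cols] == "-"
      call <- if (all(gapped)) {
        if (s$carrier_group == "parent_A") "A" else "B"
      } else if (all(!gapped)) {
        if (s$carrier_group == "parent_A") "B" else "A"
      } else "novel"
      calls[[length(calls) + 1]] <- data.frame(
        site = s$start, type = "indel", call = call, stringsAsFactors = FALSE)
    }
  }
  calls <- if (length(calls)) do.call(rbind, calls) else
    data.frame(site = integer(0), type = character(0), call = character(0),
               stringsAsFactors = FALSE)
  structure(list(calls = calls,
                 n_A = sum(calls$call == "A"),
                 n_B = sum(calls$call == "B"),
                 n_novel = sum(calls$call == "novel")),
            class = "clone_score")
}

#' @export
print.clone_score <- function(x, ...) {
  cat(sprintf("clone_score: A = %d, B = %d, novel = %d (of %d diagnostic sites)\n",
              x$n_A, x$n_B, x$n_novel, nrow(x$calls)))
  invisible(x)
}
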