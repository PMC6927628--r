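#' Simulation configuration for dominant-marker datasets
#'
#' Defaults emulate the study conditions of a two-species hybrid survey:
#' two parental pools, 51 loci diagnostic for parent A and 44 for parent B
#' among several hundred polymorphic background loci, F1s carrying both
#' diagnostic sets, and first backcrosses with 1:1 segregation of the
#' non-recurrent parent's dominant markers. Background band-allele
#' frequencies are drawn per species from `background_presence_freq_range`
#' (bounded away from 0 and 1 so no background locus is fixed-diagnostic by
#' construction).
#'
#' @param n_parent_A,n_parent_B specimens per parental pool.
#' @param n_F1,n_BC1_A,n_BC1_B hybrid-class counts (BC1_A = first backcross
#'   to parent A).
#' @param n_loci total dominant loci (diagnostic + background).
#' @param n_diag_A,n_diag_B diagnostic locus counts (defaults 51 and 44).
#' @param background_presence_freq_range band-allele frequency range for
#'   background loci, strictly inside (0, 1).
#' @param novel_band_rate per-locus probability of a hybrid-only band being
#'   added to each hybrid specimen.
#' @param scoring_error_rate per-cell probability of a phenotype flip.
#' @param seed integer seed.
#' @return named list of class `sim_config`.
#' @export
sim_config <- function(n_parent_A = 10, n_parent_B = 10, n_F1 = 5,
                       n_BC1_A = 0, n_BC1_B = 0, n_loci = 600,
                       n_diag_A = 51, n_diag_B = 44,
                       background_presence_freq_range = c(0.1, 0.9),
                       novel_band_rate = 0, scoring_error_rate = 0,
                       seed = 1) {
  cfg <- list(n_parent_A = n_parent_A, n_parent_B = n_parent_B, n_F1 = n_F1,
              n_BC1_A = n_BC1_A, n_BC1_B = n_BC1_B, n_loci = n_loci,
              n_diag_A = n_diag_A, n_diag_B = n_diag_B,
              background_presence_freq_range = background_presence_freq_range,
              novel_band_rate = novel_band_rate,
              scoring_error_rate = scoring_error_rate, seed = as.integer(seed))
  if (n_diag_A + n_diag_B > n_loci)
    stop_hb("n_diag_A + n_diag_B (%d) exceeds n_loci (%d)",
            n_diag_A + n_diag_B, n_loci, class = "config_error")
  if (n_parent_A < 1 || n_parent_B < 1)
    stop_hb("need >= 1 specimen per parental pool", class = "config_error")
  r <- background_presence_freq_range
  if (length(r) != 2 || r[1] <= 0 || r[2] >= 1 || r[1] > r[2])
    stop_hb("background_presence_freq_range must lie strictly inside (0, 1)",
            class = "config_error")
  if (novel_band_rate < 0 || novel_band_rate > 1 ||
      scoring_error_rate < 0 || scoring_error_rate > 1)
    stop_hb("rates must be in [0, 1]", class = "config_error")
  structure(cfg, class = "sim_config")
}

# one gamete (presence-allele indicator per locus) from a diploid genotype
# coded as presence-allele dosage 0/1/2; Mendelian: heterozygotes transmit
# the presence allele with probability 1/2
draw_gamete <- function(dosage) {
  g <- integer(length(dosage))
  g[dosage == 2] <- 1L
  het <- dosage == 1
  g[het] <- stats::rbinom(sum(het), 1, 0.5)
  g
}

#' Simulate a dominant-marker dataset with known hybrid classes
#'
#' Diagnostic loci are fixed homozygous-presence in the owning species and
#' homozygous-null in the other; background loci receive independent
#' band-allele frequencies per species and parental genotypes are drawn in
#' Hardy-Weinberg proportions. F1 = one gamete from each species;
#' BC1 = an F1 gamete crossed with a recurrent-parent gamete, so
#' non-recurrent diagnostic presence alleles are transmitted with
#' probability 1/2. Band phenotypes follow by dominance (band iff dosage
#' >= 1). Novel bands are then added to hybrid specimens at
#' `novel_band_rate` per locus (as extra hybrid-only loci columns appended
#' to the matrix would change locus counts, novelty is instead expressed on
#' background loci that are absent from all parents of both pools: here
#' novel bands are modeled as flips 0->1 on a dedicated set of all-null
#' loci; when `novel_band_rate > 0` a fraction of background loci is
#' reserved all-null for this purpose). Scoring errors finally flip cells
#' at `scoring_error_rate`. Fully seeded and reproducible.
#'
#' @param config a [sim_config()].
#' @return list with `matrix` (a [marker_matrix()]), `meta` (a
#'   [specimen_meta()], parents as `parent_A`/`parent_B`, hybrids as
#'   `query`), and `truth` (list of class `sim_truth`: per-specimen `class`,
#'   `parent_A_fraction`, the diagnostic locus ids, and the genotype dosage
#'   matrix).
#' @export
simulate_marker_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  nA <- config$n_parent_A; nB <- config$n_parent_B
  nF1 <- config$n_F1; nBA <- config$n_BC1_A; nBB <- config$n_BC1_B
  L <- config$n_loci
  dA <- config$n_diag_A; dB <- config$n_diag_B
  n_bg <- L - dA - dB
  n_novel <- if (config$novel_band_rate > 0) max(1L, round(0.05 * n_bg)) else 0L
  if (n_novel > n_bg)
    stop_hb("no background loci left to host novel bands", class = "config_error")

  loci <- c(sprintf("diagA_%03d", seq_len(dA)),
            sprintf("diagB_%03d", seq_len(dB)),
            if (n_bg) sprintf("bg_%03d", seq_len(n_bg)))
  idx_dA <- seq_len(dA)
  idx_dB <- dA + seq_len(dB)
  idx_bg <- if (n_bg) dA + dB + seq_len(n_bg) else integer(0)
  idx_novel <- if (n_novel) utils::head(idx_bg, n_novel) else integer(0)
  idx_free_bg <- setdiff(idx_bg, idx_novel)

  r <- config$background_presence_freq_range
  # per-species presence-allele frequency per locus
  fA <- fB <- numeric(L)
  fA[idx_dA] <- 1; fB[idx_dA] <- 0
  fA[idx_dB] <- 0; fB[idx_dB] <- 1
  fA[idx_free_bg] <- stats::runif(length(idx_free_bg), r[1], r[2])
  fB[idx_free_bg] <- stats::runif(length(idx_free_bg), r[1], r[2])
  # novel-band host loci: allele absent in both species
  fA[idx_novel] <- 0; fB[idx_novel] <- 0

  hw_genotype <- function(f) stats::rbinom(length(f), 2, f)
  ids <- c(sprintf("A%02d", seq_len(nA)), sprintf("B%02d", seq_len(nB)),
           if (nF1) sprintf("F1_%02d", seq_len(nF1)),
           if (nBA) sprintf("BCA_%02d", seq_len(nBA)),
           if (nBB) sprintf("BCB_%02d", seq_len(nBB)))
  classes <- c(rep("parent_A", nA), rep("parent_B", nB),
               rep("F1", nF1), rep("BC1_A", nBA), rep("BC1_B", nBB))
  n_tot <- length(ids)
  dosage <- matrix(0L, n_tot, L, dimnames = list(ids, loci))

  for (i in seq_len(nA)) dosage[i, ] <- hw_genotype(fA)
  for (i in seq_len(nB)) dosage[nA + i, ] <- hw_genotype(fB)
  make_F1 <- function() draw_gamete(hw_genotype(fA)) + draw_gamete(hw_genotype(fB))
  row0 <- nA + nB
  for (i in seq_len(nF1)) dosage[row0 + i, ] <- make_F1()
  row0 <- row0 + nF1
  for (i in seq_len(nBA))
    dosage[row0 + i, ] <- draw_gamete(make_F1()) + draw_gamete(hw_genotype(fA))
  row0 <- row0 + nBA
  for (i in seq_len(nBB))
    dosage[row0 + i, ] <- draw_gamete(make_F1()) + draw_gamete(hw_genotype(fB))

  pheno <- (dosage >= 1) * 1L

  is_hybrid <- classes %in% c("F1", "BC1_A", "BC1_B")
  if (config$novel_band_rate > 0 && any(is_hybrid)) {
    for (i in which(is_hybrid)) {
      add <- stats::rbinom(length(idx_novel), 1, config$novel_band_rate) == 1
      pheno[i, idx_novel[add]] <- 1L
    }
  }
  if (config$scoring_error_rate > 0) {
    flip <- matrix(stats::rbinom(length(pheno), 1, config$scoring_error_rate),
                   nrow(pheno)) == 1
    pheno[flip] <- 1L - pheno[flip]
  }

  meta <- specimen_meta(ids,
                        ifelse(classes == "parent_A", "parent_A",
                               ifelse(classes == "parent_B", "parent_B", "query")),
                        label = classes)
  frac_A <- c(parent_A = 1, parent_B = 0, F1 = 0.5, BC1_A = 0.75, BC1_B = 0.25)
  truth <- structure(list(class = setNames(classes, ids),
                          parent_A_fraction = setNames(frac_A[classes], ids),
                          diag_A_loci = loci[idx_dA],
                          diag_B_loci = loci[idx_dB],
                          novel_host_loci = loci[idx_novel],
                          dosage = dosage),
                     class = "sim_truth")
  list(matrix = marker_matrix(pheno, ids, loci), meta = meta, truth = truth)
}

#' Simulate a grouped alignment with planted diagnostic features
#'
#' Parental groups differ by exactly `n_diag_snps` fixed substitutions and
#' by the given group-specific gap runs; decoy within-group polymorphic
#' columns are added at `within_group_poly_rate` (never on planted
#' features). Clones are parental mosaics: each diagnostic SNP takes the
#' parental state named in `clone_origins` and novel states can be planted
#' via `clone_novel_sites`.
#'
#' @param n_A,n_B parental sequences per group.
#' @param n_clones number of query clone sequences.
#' @param length alignment length in columns.
#' @param n_diag_snps number of planted fixed SNP differences.
#' @param indel_lengths integer vector of planted group-specific deletion
#'   lengths; names `"A"`/`"B"` give the carrier group (default alternating
#'   starting with B, mirroring one 8-bp deletion in one parent and 6/2/1-bp
#'   deletions in the other as `c(A = 8, B = 6, B = 2, B = 1)` would).
#' @param within_group_poly_rate fraction of free columns receiving decoy
#'   within-group polymorphism.
#' @param clone_origins per-clone character vector (or single vector reused
#'   for all clones) of `"A"`/`"B"` origins, one per diagnostic SNP;
#'   default all `"B"`.
#' @param clone_novel_sites integer vector: for each clone (recycled), how
#'   many diagnostic SNP sites carry a novel (non-parental) base.
#' @param seed integer seed.
#' @return list with `alignment` (a [grouped_alignment()]) and `truth`
#'   (planted SNP positions, indel table, clone origin vectors).
#' @export
simulate_alignment <- function(n_A = 3, n_B = 3, n_clones = 0, length = 550,
                               n_diag_snps = 9, indel_lengths = integer(0),
                               within_group_poly_rate = 0.02,
                               clone_origins = NULL, clone_novel_sites = 0,
                               seed = 1) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  need <- n_diag_snps + sum(indel_lengths) + sum(indel_lengths > 0)
  if (need > length)
    stop_hb("planted features (%d columns) do not fit in length %d",
            need, length, class = "config_error")
  base_seq <- sample(bases, length, replace = TRUE)

  # reserve non-overlapping blocks for indels, then SNP columns outside them
  free <- seq_len(length)
  indel_tab <- data.frame(start = integer(0), end = integer(0),
                          carrier = character(0), stringsAsFactors = FALSE)
  carriers <- names(indel_lengths) %||% rep(c("B", "A"),
                                            length.out = length(indel_lengths))
  if (length(indel_lengths)) {
    if (is.null(names(indel_lengths)))
      names(indel_lengths) <- carriers
    for (j in seq_along(indel_lengths)) {
      len <- indel_lengths[j]
      # candidate starts whose whole block plus 1-column flank is free
      ok <- free[vapply(free, function(s)
        s + len - 1 <= length && all(s:(s + len - 1) %in% free) &&
          !((s - 1) %in% unlist(mapply(seq, indel_tab$start, indel_tab$end,
                                       SIMPLIFY = FALSE))), TRUE)]
      if (!length(ok))
        stop_hb("cannot place a %d-bp indel without overlap", len,
                class = "config_error")
      s <- ok[sample.int(length(ok), 1)]
      indel_tab <- rbind(indel_tab,
                         data.frame(start = s, end = s + len - 1,
                                    carrier = names(indel_lengths)[j],
                                    stringsAsFactors = FALSE))
      drop <- max(1, s - 1):min(length, s + len)  # block plus flanks
      free <- setdiff(free, drop)
    }
  }
  snp_pos <- sort(sample(free, n_diag_snps))
  free <- setdiff(free, snp_pos)

  state_A <- base_seq[snp_pos]
  state_B <- vapply(state_A, function(b) sample(setdiff(bases, b), 1), "x")

  seq_for <- function(group) {
    s <- base_seq
    if (group == "B") s[snp_pos] <- state_B
    for (j in seq_len(nrow(indel_tab)))
      if (indel_tab$carrier[j] == group)
        s[indel_tab$start[j]:indel_tab$end[j]] <- "-"
    s
  }
  sA <- seq_for("A"); sB <- seq_for("B")
  seqs <- c(lapply(seq_len(n_A), function(i) sA),
            lapply(seq_len(n_B), function(i) sB))
  group <- c(rep("parent_A", n_A), rep("parent_B", n_B))

  # decoy within-group polymorphism on free columns
  n_poly <- round(within_group_poly_rate * base::length(free))
  poly_pos <- if (n_poly) sort(sample(free, n_poly)) else integer(0)
  for (p in poly_pos) {
    gi <- if (stats::runif(1) < 0.5) which(group == "parent_A") else
      which(group == "parent_B")
    if (base::length(gi) < 2) next
    carrier <- sample(gi, max(1, base::length(gi) %/% 2))
    alt <- sample(setdiff(bases, base_seq[p]), 1)
    for (i in carrier) seqs[[i]][p] <- alt
  }

  # clones: parental mosaics over the diagnostic SNPs on an A backbone with
  # B indel pattern chosen per majority origin
  clone_truth <- list()
  if (n_clones > 0) {
    if (is.null(clone_origins)) clone_origins <- rep("B", n_diag_snps)
    if (!is.list(clone_origins))
      clone_origins <- rep(list(clone_origins), n_clones)
    clone_novel_sites <- rep(clone_novel_sites, length.out = n_clones)
    for (ci in seq_len(n_clones)) {
      ov <- clone_origins[[ci]]
      stopifnot(base::length(ov) == n_diag_snps)
      s <- base_seq
      s[snp_pos[ov == "B"]] <- state_B[ov == "B"]
      maj <- if (mean(ov == "B") > 0.5) "B" else "A"
      for (j in seq_len(nrow(indel_tab)))
        if (indel_tab$carrier[j] == maj)
          s[indel_tab$start[j]:indel_tab$end[j]] <- "-"
      nn <- clone_novel_sites[ci]
      if (nn > 0) {
        at <- sample(seq_len(n_diag_snps), nn)
        for (a in at)
          s[snp_pos[a]] <- sample(setdiff(bases, c(state_A[a], state_B[a])), 1)
        ov[at] <- "novel"
      }
      seqs[[base::length(seqs) + 1]] <- s
      group <- c(group, "query")
      clone_truth[[ci]] <- ov
    }
  }
  seq_chr <- vapply(seqs, paste, "x", collapse = "")
  names(seq_chr) <- c(sprintf("A_%02d", seq_len(n_A)),
                      sprintf("B_%02d", seq_len(n_B)),
                      if (n_clones) sprintf("clone_%02d", seq_len(n_clones)))
  list(alignment = grouped_alignment(seq_chr, group),
       truth = list(snp_positions = snp_pos, state_A = state_A,
                    state_B = state_B, indels = indel_tab,
                    poly_positions = poly_pos, clone_origins = clone_truth))
}

#' Simulate plastid (cpDNA) sequences under maternal inheritance
#'
#' Builds a base sequence, derives haplotypes by applying the given site
#' edits (point substitutions that create or destroy restriction sites),
#' and hands each specimen its maternal lineage's haplotype verbatim;
#' hybrids inherit the haplotype of their configured maternal parent.
#'
#' @param length sequence length.
#' @param haplotype_edits list per haplotype id of named integer vectors
#'   `position = ` with base characters as values (e.g.
#'   `list(h1 = c(), h2 = c("101" = "A"))`); haplotype 1 is the unedited
#'   base sequence if its entry is empty.
#' @param inheritance named character vector mapping specimen id to
#'   haplotype id.
#' @param seed integer seed.
#' @return list with `sequences` (named character vector per specimen) and
#'   `haplotype_seqs`.
#' @export
simulate_cpdna <- function(length = 1000,
                           haplotype_edits = list(h1 = character(0)),
                           inheritance, seed = 1) {
  set.seed(seed)
  base_seq <- sample(c("A", "C", "G", "T"), length, replace = TRUE)
  hseqs <- lapply(haplotype_edits, function(ed) {
    s <- base_seq
    if (base::length(ed)) {
      pos <- as.integer(names(ed))
      if (any(pos < 1 | pos > length))
        stop_hb("haplotype edit outside sequence (length %d)", length,
                class = "config_error")
      s[pos] <- toupper(as.character(ed))
    }
    paste(s, collapse = "")
  })
  bad <- setdiff(unique(inheritance), names(hseqs))
  if (base::length(bad))
    stop_hb("inheritance references unknown haplotype(s): %s",
            paste(bad, collapse = ", "), class = "config_error")
  seqs <- setNames(unlist(hseqs[inheritance]), names(inheritance))
  list(sequences = seqs, haplotype_seqs = unlist(hseqs))
}
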