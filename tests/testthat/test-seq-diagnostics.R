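test_that("FASTA round trip preserves ids and normalizes case", {
  seqs <- c(one = "ACGTacgt", two = "ggnn-TTA")
  f <- tempfile(fileext = ".fasta")
  write_fasta(seqs, f)
  back <- read_fasta(f)
  expect_identical(back, c(one = "ACGTACGT", two = "GGNN-TTA"))
  expect_error(read_fasta(f, aligned = FALSE), NA)
  writeLines(c(">a", "ACGT", ">b", "ACG"), f)
  expect_error(read_fasta(f, aligned = TRUE), class = "alignment_error")
})

test_that("diagnostic SNPs are fixed differences between parental groups", {
  aln <- grouped_alignment(
    c(a1 = "ACGTACGT", a2 = "ACGTACGT", b1 = "ACGAACGT", b2 = "ACGAACGT"),
    c("parent_A", "parent_A", "parent_B", "parent_B"))
  snp <- find_diagnostic_snps(aln)
  expect_equal(snp$position, 4)
  expect_equal(snp$state_A, "T")
  expect_equal(snp$state_B, "A")
  # within-group polymorphism excludes a column at strict fixation
  aln2 <- grouped_alignment(
    c(a1 = "ACGTACGT", a2 = "ACCTACGT", b1 = "ACGAACGT", b2 = "ACGAACGT"),
    c("parent_A", "parent_A", "parent_B", "parent_B"))
  snp2 <- find_diagnostic_snps(aln2)
  expect_equal(snp2$position, 4)
  expect_false(3 %in% snp2$position)
  # query sequences never influence discovery
  aln3 <- grouped_alignment(
    c(a1 = "ACGTACGT", b1 = "ACGAACGT", q = "TTTTTTTT"),
    c("parent_A", "parent_B", "query"))
  expect_equal(find_diagnostic_snps(aln3)$position, 4)
})

test_that("planted diagnostic SNPs are recovered exactly among decoys", {
  sim <- simulate_alignment(n_A = 4, n_B = 4, length = 550, n_diag_snps = 9,
                            within_group_poly_rate = 0.05, seed = 41)
  snp <- find_diagnostic_snps(sim$alignment)
  expect_equal(nrow(snp), 9)
  expect_equal(snp$position, sim$truth$snp_positions)
  # zero planted features -> nothing found
  sim0 <- simulate_alignment(n_A = 3, n_B = 3, length = 300, n_diag_snps = 0,
                             within_group_poly_rate = 0.05, seed = 42)
  expect_equal(nrow(find_diagnostic_snps(sim0$alignment)), 0)
})

test_that("group-specific indels are recovered with their planted lengths", {
  sim <- simulate_alignment(n_A = 3, n_B = 3, length = 550, n_diag_snps = 9,
                            indel_lengths = c(A = 8, B = 6, B = 2, B = 1),
                            within_group_poly_rate = 0.03, seed = 43)
  ind <- find_diagnostic_indels(sim$alignment)
  expect_setequal(ind$length, c(8, 6, 2, 1))
  expect_equal(sort(ind$length[ind$carrier_group == "parent_A"]), 8)
  expect_equal(sort(ind$length[ind$carrier_group == "parent_B"]), c(1, 2, 6))
  # a gap shared by both groups is not diagnostic
  aln <- grouped_alignment(c(a = "AC--GT", b = "AC--GT"),
                           c("parent_A", "parent_B"))
  expect_equal(nrow(find_diagnostic_indels(aln)), 0)
  # direct 8-column case
  aln8 <- grouped_alignment(
    c(a1 = "ACGTACGTACGT", a2 = "ACGTACGTACGT",
      b1 = "AC--------GT", b2 = "AC--------GT"),
    c("parent_A", "parent_A", "parent_B", "parent_B"))
  ind8 <- find_diagnostic_indels(aln8)
  expect_equal(ind8$length, 8)
  expect_equal(ind8$carrier_group, "parent_B")
})

test_that("swapping group labels maps diagnostic sites onto themselves", {
  sim <- simulate_alignment(n_A = 3, n_B = 3, length = 400, n_diag_snps = 7,
                            indel_lengths = c(A = 5, B = 3),
                            within_group_poly_rate = 0.04, seed = 44)
  aln <- sim$alignment
  swapped <- aln
  swapped$group <- ifelse(aln$group == "parent_A", "parent_B",
                          ifelse(aln$group == "parent_B", "parent_A",
                                 aln$group))
  s1 <- diagnostic_sites(aln); s2 <- diagnostic_sites(swapped)
  expect_equal(s2$snp$position, s1$snp$position)
  expect_equal(s2$snp$state_A, s1$snp$state_B)
  expect_equal(s2$snp$state_B, s1$snp$state_A)
  expect_equal(s2$indel$length, s1$indel$length)
  expect_equal(s2$indel$carrier_group,
               ifelse(s1$indel$carrier_group == "parent_A", "parent_B",
                      "parent_A"))
})

test_that("clone scoring counts parental states and novelties", {
  sim <- simulate_alignment(n_A = 3, n_B = 3, n_clones = 1, length = 550,
                            n_diag_snps = 9,
                            clone_origins = c(rep("B", 8), "A"), seed = 45)
  sites <- diagnostic_sites(sim$alignment)
  clone <- paste(sim$alignment$mat[sim$alignment$group == "query", ],
                 collapse = "")
  sc <- score_clone(clone, sites)
  expect_equal(sc$n_A, 1); expect_equal(sc$n_B, 8); expect_equal(sc$n_novel, 0)
  expect_equal(sc$n_A + sc$n_B + sc$n_novel, nrow(sc$calls))
  # a clone equal to a parent scores all sites for that parent
  parentA <- paste(sim$alignment$mat[1, ], collapse = "")
  scA <- score_clone(parentA, sites)
  expect_equal(scA$n_A, nrow(scA$calls))
  # planted novel substitutions are called novel
  sim2 <- simulate_alignment(n_A = 3, n_B = 3, n_clones = 1, length = 550,
                             n_diag_snps = 9,
                             clone_origins = rep("B", 9),
                             clone_novel_sites = 1, seed = 46)
  sites2 <- diagnostic_sites(sim2$alignment)
  clone2 <- paste(sim2$alignment$mat[sim2$alignment$group == "query", ],
                  collapse = "")
  expect_equal(score_clone(clone2, sites2)$n_novel, 1)
  expect_error(score_clone("ACGT", sites), class = "alignment_error")
})

test_that("restriction digests match hand results and conserve length", {
  expect_equal(restriction_digest("AAAAGCTTTT", "AluI"), c(5, 5))
  expect_equal(restriction_digest("ACGTACGT", "XbaI"), 8)
  # MboI cuts before GATC
  expect_equal(restriction_digest("AAGATCAA", "MboI"), c(2, 6))
  # HinfI GANTC with wildcard N
  expect_equal(restriction_digest("AAGACTCAA", "HinfI"), c(3, 6))
  # substrate N never matches a site
  expect_equal(restriction_digest("AAGANTCAA", "HinfI"), 9)
  expect_error(restriction_digest("ACGT", "EcoRI"), class = "input_error")
  set.seed(47)
  panel <- enzyme_panel()
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
    for (e in panel$enzyme)
      expect_equal(sum(restriction_digest(s, e)), 200)
  }
})

test_that("concatenation only changes fragments at the junction", {
  set.seed(48)
  s1 <- paste(sample(c("A", "C", "G", "T"), 150, TRUE), collapse = "")
  s2 <- paste(sample(c("A", "C", "G", "T"), 150, TRUE), collapse = "")
  for (e in c("AluI", "MboI", "TaqI")) {
    f1 <- restriction_digest(s1, e); f2 <- restriction_digest(s2, e)
    fc <- restriction_digest(paste0(s1, s2), e)
    # every cut of the parts is also a cut of the concatenation (new cuts
    # can only appear at the junction)
    cuts <- function(f) cumsum(f[-length(f)])
    expect_true(all(cuts(f1) %in% cuts(fc)))
    expect_true(all((150 + cuts(f2)) %in% cuts(fc)))
    expect_equal(sum(fc), 300)
  }
})

test_that("RFLP haplotype grouping is exact and order-invariant", {
  base <- paste(rep(c("ACGGATCCGT"), 20), collapse = "")  # many MboI sites
  # destroy one GATC occurrence -> different MboI profile
  alt <- sub("GATC", "GTTC", base)
  seqs <- c(x1 = base, x2 = base, y1 = alt)
  hap <- rflp_haplotypes(seqs)
  expect_equal(unname(hap$haplotype["x1"]), unname(hap$haplotype["x2"]))
  expect_false(hap$haplotype["x1"] == hap$haplotype["y1"])
  # identical sequences form one haplotype
  hap1 <- rflp_haplotypes(c(a = base, b = base))
  expect_equal(length(unique(hap1$haplotype)), 1)
  # grouping invariant under specimen reordering
  hap_r <- rflp_haplotypes(seqs[c(3, 1, 2)])
  expect_equal(hap_r$haplotype[names(seqs)], hap$haplotype[names(seqs)])
  # concordance table ties chlorotype to maternal group
  groups <- c(x1 = "parent_B", x2 = "query", y1 = "parent_A")
  hap_c <- rflp_haplotypes(seqs, groups = groups)
  conc <- hap_c$concordance
  hB <- hap_c$haplotype["x1"]
  expect_equal(unname(conc[as.character(hB), "query"]), 1)
  expect_equal(unname(conc[as.character(hB), "parent_A"]), 0)
})

test_that("maternally inherited plastid haplotypes group hybrids with the seed parent", {
  # haplotype 2 differs by edits that destroy an MboI site
  cp <- simulate_cpdna(
    length = 800,
    haplotype_edits = list(hA = character(0), hB = c("101" = "G")),
    inheritance = c(A1 = "hA", A2 = "hA", B1 = "hB", B2 = "hB", F1 = "hB"),
    seed = 49)
  hap <- rflp_haplotypes(cp$sequences)
  # every specimen carries its lineage's sequence verbatim
  expect_identical(unname(cp$sequences["F1"]), unname(cp$sequences["B1"]))
  expect_equal(unname(hap$haplotype["F1"]), unname(hap$haplotype["B1"]))
  same <- simulate_cpdna(length = 300,
                         haplotype_edits = list(h = character(0)),
                         inheritance = c(s1 = "h", s2 = "h"), seed = 50)
  expect_equal(length(unique(rflp_haplotypes(same$sequences)$haplotype)), 1)
  expect_error(simulate_cpdna(length = 10,
                              haplotype_edits = list(h = c("99" = "A")),
                              inheritance = c(s1 = "h")),
               class = "config_error")
})
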