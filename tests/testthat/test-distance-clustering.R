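test_that("Dice similarity matches hand counts and its edge cases", {
  # a = 2 shared presences, b = c = 1 exclusive each -> 4/6
  expect_equal(dice_similarity(c(1, 1, 0, 1), c(1, 0, 1, 1)), 2 / 3)
  expect_equal(dice_similarity(c(1, 0, 1), c(1, 0, 1)), 1)
  expect_equal(dice_similarity(c(1, 1, 0, 0), c(0, 0, 1, 1)), 0)
  expect_error(dice_similarity(c(0, 0), c(0, 0)),
               class = "undefined_similarity_error")
  expect_error(dice_similarity(c(1, 0), c(1, 0, 1)), class = "input_error")
})

test_that("Dice similarity is symmetric and bounded on random profiles", {
  set.seed(11)
  for (i in 1:1000) {
    n <- sample(3:20, 1)
    x <- rbinom(n, 1, 0.5); y <- rbinom(n, 1, 0.5)
    if (sum(x) + sum(y) == 0) next
    s <- dice_similarity(x, y)
    expect_identical(s, dice_similarity(y, x))
    expect_gte(s, 0); expect_lte(s, 1)
  }
})

test_that("distance matrix is 1 - Dice and agrees with vegan", {
  m <- marker_matrix(rbind(s1 = c(1, 1, 0, 1), s2 = c(1, 0, 1, 1)))
  D <- distance_matrix(m)
  expect_equal(D["s1", "s2"], 1 / 3)
  expect_equal(diag(D), c(s1 = 0, s2 = 0))
  skip_if_not_installed("vegan")
  set.seed(12)
  for (i in 1:20) {
    mm <- random_binary_matrix(sample(3:8, 1), sample(10:40, 1))
    D <- distance_matrix(mm)
    expect_true(all(D >= 0 & D <= 1))
    # binary Bray-Curtis is (b+c)/(2a+b+c) = 1 - Dice
    Dv <- as.matrix(vegan::vegdist(mm$values, method = "bray"))
    expect_equal(unclass(D), Dv, ignore_attr = TRUE, tolerance = 1e-12)
  }
})

test_that("UPGMA reproduces the hand-computed merge heights", {
  D <- matrix(c(0, 2, 8, 2, 0, 8, 8, 8, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- upgma(D)
  expect_identical(ape::write.tree(tr), "(C:4,(A:1,B:1):3);")
  # n = 2 cherry at D/2
  D2 <- matrix(c(0, 0.4, 0.4, 0), 2, dimnames = list(c("x", "y"), c("x", "y")))
  tr2 <- upgma(D2)
  expect_equal(tr2$edge.length, c(0.2, 0.2))
  expect_error(upgma(D2[1, 1, drop = FALSE]), class = "input_error")
})

test_that("UPGMA trees are ultrametric on random Dice matrices", {
  set.seed(13)
  for (i in 1:10) {
    m <- random_binary_matrix(sample(4:8, 1), 30)
    tr <- upgma(distance_matrix(m))
    expect_true(ape::is.ultrametric(tr, tol = 1e-9))
  }
})

test_that("NJ solves the three-point configuration and additive matrices", {
  D <- matrix(c(0, 2, 8, 2, 0, 8, 8, 8, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(D)
  v <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(v[c("A", "B", "C")], c(A = 1, B = 1, C = 7))
  expect_error(nj_tree(D[1:2, 1:2]), class = "input_error")
  # additive matrices are reproduced exactly (tree metric recovery)
  set.seed(14)
  for (i in 1:10) {
    n <- sample(4:6, 1)
    ref <- ape::rtree(n, br = function(k) runif(k, 0.1, 1))
    ref <- ape::unroot(ref)
    D <- cophenetic(ref)
    tr <- nj_tree(D)
    expect_equal(cophenetic(tr)[rownames(D), colnames(D)], D,
                 tolerance = 1e-8)
  }
})

test_that("NJ topology is invariant under tip order permutation", {
  set.seed(15)
  m <- random_binary_matrix(6, 40)
  tr1 <- nj_tree(distance_matrix(m))
  perm <- c(4, 1, 6, 2, 5, 3)
  mp <- marker_matrix(m$values[perm, , drop = FALSE])
  tr2 <- nj_tree(distance_matrix(mp))
  expect_equal(ape::dist.topo(ape::unroot(tr1), ape::unroot(tr2))[1], 0)
})

test_that("bootstrap supports are deterministic and detect identical pairs", {
  set.seed(16)
  base <- random_binary_matrix(5, 40)
  v <- rbind(base$values, twin = base$values[1, ])
  rownames(v) <- c(paste0("s", 1:5), "twin")
  m <- marker_matrix(v)
  tr <- bootstrap_support(m, method = "upgma", n_reps = 50, seed = 99)
  sup <- attr(tr, "bootstrap")
  # the s1/twin cherry is preserved in every resample
  cherry_node <- ape::getMRCA(tr, c("s1", "twin"))
  expect_equal(sup[cherry_node - ape::Ntip(tr)], 100)
  tr2 <- bootstrap_support(m, method = "upgma", n_reps = 50, seed = 99)
  expect_identical(attr(tr2, "bootstrap"), sup)
  expect_true(all(sup[!is.na(sup)] >= 0 & sup[!is.na(sup)] <= 100))
  # single replicate -> supports in {0, 100}
  tr3 <- bootstrap_support(m, method = "nj", n_reps = 1, seed = 5)
  s3 <- attr(tr3, "bootstrap")
  expect_true(all(s3[!is.na(s3)] %in% c(0, 100)))
})

test_that("PCoA closed forms and the embedding oracle hold", {
  # two specimens at distance 0.4 -> one axis, coords +/- 0.2, 100% variance
  D2 <- matrix(c(0, 0.4, 0.4, 0), 2, dimnames = list(c("x", "y"), c("x", "y")))
  p <- pcoa(D2, 1)
  expect_equal(sort(as.numeric(p$coordinates)), c(-0.2, 0.2))
  expect_equal(as.numeric(p$proportion), 1)
  # three equidistant specimens -> two equal eigenvalues, 50%/50%
  D3 <- matrix(0.3, 3, 3); diag(D3) <- 0
  dimnames(D3) <- list(paste0("s", 1:3), paste0("s", 1:3))
  p3 <- pcoa(D3, 2)
  expect_equal(as.numeric(p3$proportion), c(0.5, 0.5), tolerance = 1e-9)
  # Euclidean-embeddable distances are reproduced by the coordinates
  set.seed(17)
  coords <- matrix(rnorm(12), 6, 2)
  D <- euclidean_distance_matrix(coords)
  p6 <- pcoa(D, 2)
  expect_equal(as.matrix(dist(p6$coordinates)), unclass(D),
               ignore_attr = TRUE, tolerance = 1e-8)
  expect_warning(pcoa(D2, 5), "truncating")
})

test_that("phylip and newick exports are written", {
  m <- random_binary_matrix(4, 20)
  D <- distance_matrix(m)
  f <- tempfile()
  write_phylip(D, f)
  lines <- readLines(f)
  expect_equal(as.integer(trimws(lines[1])), 4)
  expect_length(lines, 5)
  f2 <- tempfile()
  write_newick(upgma(D), f2)
  expect_match(readLines(f2)[1], "^\\(.*\\);$")
})
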