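# The diagnostic-set sizes of the motivating study: 51 markers fixed in
# parent A (C. alternifolia), 44 in parent B (C. controversa).
M_A <- 51
M_B <- 44

test_that("raw hybrid index reproduces the published worked examples", {
  # lacking 15 of 51 A-markers, no B-markers -> 15/95 -> 0.16
  expect_equal(round_half_up(hybrid_index(0, 15, M_A, M_B, "raw"), 2), 0.16)
  # lacking 9 -> 0.09
  expect_equal(round_half_up(hybrid_index(0, 9, M_A, M_B, "raw"), 2), 0.09)
  # lacking 10 with 4 foreign markers -> 14/95 -> 0.15
  expect_equal(round_half_up(hybrid_index(4, 10, M_A, M_B, "raw"), 2), 0.15)
})

test_that("normalized index is exactly 0.5 at full marker additivity", {
  expect_equal(hybrid_index(M_B, 0, M_A, M_B, "normalized"), 0.5)
  # one marker short of additivity -> 0.49
  expect_equal(round_half_up(hybrid_index(43, 0, M_A, M_B, "normalized"), 2),
               0.49)
})

test_that("index endpoints are 0 and 1 for pure parents in both variants", {
  for (variant in c("raw", "normalized")) {
    expect_equal(hybrid_index(0, 0, M_A, M_B, variant), 0)
    expect_equal(hybrid_index(M_B, M_A, M_A, M_B, variant), 1)
  }
  expect_error(hybrid_index(M_B + 1, 0, M_A, M_B), class = "domain_error")
  expect_error(hybrid_index(0, -1, M_A, M_B), class = "domain_error")
})

test_that("both variants are monotone in each count and agree when m_A = m_B", {
  for (variant in c("raw", "normalized")) {
    prev <- -1
    for (c_ in 0:M_B) {
      cur <- hybrid_index(c_, 5, M_A, M_B, variant)
      expect_gt(cur, prev); prev <- cur
    }
    prev <- -1
    for (a_ in 0:M_A) {
      cur <- hybrid_index(10, a_, M_A, M_B, variant)
      expect_gt(cur, prev); prev <- cur
    }
  }
  set.seed(21)
  for (i in 1:50) {
    m <- sample(5:60, 1)
    c_ <- sample(0:m, 1); a_ <- sample(0:m, 1)
    expect_equal(hybrid_index(c_, a_, m, m, "raw"),
                 hybrid_index(c_, a_, m, m, "normalized"))
  }
})

test_that("specimen scoring equals brute-force set intersections", {
  set.seed(22)
  m <- random_binary_matrix(6, 40)
  dset <- diagnostic_marker_set(paste0("L", 1:12), paste0("L", 21:30))
  for (s in rownames(m$values)) {
    sc <- score_specimen_markers(m, dset, s)
    present <- colnames(m$values)[m$values[s, ] == 1]
    expect_equal(unname(sc["c_present"]),
                 length(intersect(present, dset$loci_B)))
    expect_equal(unname(sc["a_absent"]),
                 length(setdiff(dset$loci_A, present)))
  }
  expect_error(score_specimen_markers(m, dset, "nope"), class = "input_error")
  bad <- diagnostic_marker_set("L1", "Lmissing")
  expect_error(score_specimen_markers(m, bad, "s1"), class = "input_error")
})

test_that("class calls follow the index intervals and marker evidence", {
  # synthetic rows: pure A, F1 (full additivity), introgressed near-pure A
  v <- rbind(pure = c(rep(1, 5), rep(0, 4)),
             f1 = rep(1, 9),
             intro = c(rep(1, 5), 1, 1, 0, 0),
             bc = c(rep(1, 5), 1, 1, 1, 0))
  colnames(v) <- paste0("L", 1:9)
  m <- marker_matrix(v)
  dset <- diagnostic_marker_set(paste0("L", 1:5), paste0("L", 6:9))
  res <- classify_specimens(m, dset)
  calls <- setNames(res$class_call, res$specimen_id)
  expect_equal(unname(calls["pure"]), "pure_A")
  expect_equal(unname(calls["f1"]), "F1_type")
  expect_false(res$introgressed[res$specimen_id == "pure"])
  # intro: index = (2/4)/2 = 0.25 -> backcross range with foreign markers
  expect_equal(unname(calls["intro"]), "backcross_A")
  # an A3-like case: pure-range index yet foreign markers present
  v2 <- rbind(a3 = c(rep(1, 41), rep(0, 10), rep(1, 4), rep(0, 40)))
  colnames(v2) <- c(paste0("A", 1:51), paste0("B", 1:44))
  m2 <- marker_matrix(v2)
  d2 <- diagnostic_marker_set(paste0("A", 1:51), paste0("B", 1:44))
  r2 <- classify_specimens(m2, d2, class_variant = "raw")
  expect_equal(r2$class_call, "pure_A")
  expect_true(r2$introgressed)
  expect_equal(round_half_up(r2$index_raw, 2), 0.15)
  expect_error(hybrid_thresholds(pure_low = 0.5, f1_low = 0.4),
               class = "config_error")
})

test_that("marker report grid is consistent with the scoring counts", {
  d <- simulate_marker_dataset(sim_config(n_parent_A = 6, n_parent_B = 6,
                                          n_F1 = 3, n_loci = 120,
                                          n_diag_A = 20, n_diag_B = 15,
                                          seed = 23))
  cls <- classify_bands(d$matrix, d$meta)
  dset <- diagnostic_set_from_classification(cls)
  rep_ <- marker_report(d$matrix, d$meta, dset)
  expect_equal(nrow(rep_$grid), 3)
  # F1 rows carry every diagnostic marker of both sets
  expect_true(all(rep_$grid[, dset$loci_A] == 1))
  expect_true(all(rep_$grid[, dset$loci_B] == 1))
  # row sums equal the scoring counts
  for (s in rownames(rep_$grid)) {
    sc <- score_specimen_markers(d$matrix, dset, s)
    expect_equal(sum(rep_$grid[s, dset$loci_B]), unname(sc["c_present"]))
    expect_equal(sum(rep_$grid[s, dset$loci_A] == 0), unname(sc["a_absent"]))
  }
  # report files are written; empty query set gives header-only tables
  prefix <- tempfile()
  write_marker_report(rep_, prefix)
  expect_true(file.exists(paste0(prefix, ".json")))
  meta_nq <- specimen_meta(d$meta$specimen_id,
                           ifelse(d$meta$group == "query", "outgroup",
                                  d$meta$group))
  rep0 <- marker_report(d$matrix, meta_nq, dset)
  expect_equal(nrow(rep0$table), 0)
})

test_that("simulated F1 and BC1 cohorts recover their expected indices", {
  d <- simulate_marker_dataset(sim_config(n_parent_A = 12, n_parent_B = 12,
                                          n_F1 = 200, n_BC1_A = 200,
                                          n_loci = 595, seed = 24))
  truth <- d$truth
  dset <- diagnostic_marker_set(truth$diag_A_loci, truth$diag_B_loci)
  res <- classify_specimens(d$matrix, dset,
                            specimens = names(truth$class)[truth$class %in%
                                                             c("F1", "BC1_A")])
  idx <- setNames(res$index_normalized, res$specimen_id)
  f1 <- idx[truth$class[names(idx)] == "F1"]
  bc <- idx[truth$class[names(idx)] == "BC1_A"]
  expect_equal(mean(f1), 0.5, tolerance = 0.02 / 0.5)
  expect_gte(mean(bc), 0.22); expect_lte(mean(bc), 0.28)
})
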