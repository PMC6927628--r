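# Small in-code fixtures shared across test files.

# 4 specimens (2 per parental group) x 4 loci covering the band categories:
# L1 monomorphic, L2 diagnostic for A, L3 unique (not diagnostic) to A,
# L4 diagnostic for B.
toy_matrix <- function() {
  v <- rbind(a1 = c(1, 1, 1, 0),
             a2 = c(1, 1, 0, 0),
             b1 = c(1, 0, 0, 1),
             b2 = c(1, 0, 0, 1))
  colnames(v) <- paste0("L", 1:4)
  marker_matrix(v)
}

toy_meta <- function() {
  specimen_meta(c("a1", "a2", "b1", "b2"),
                c("parent_A", "parent_A", "parent_B", "parent_B"))
}

random_binary_matrix <- function(n, L, p = 0.5) {
  repeat {
    v <- matrix(rbinom(n * L, 1, p), n, L,
                dimnames = list(paste0("s", seq_len(n)),
                                paste0("L", seq_len(L))))
    if (all(rowSums(v) > 0)) return(marker_matrix(v))
  }
}

# independent brute-force permutation enumerator (oracle for alignment)
combinat_perms <- function(n) {
  if (n == 1) return(list(1L))
  grid <- expand.grid(rep(list(seq_len(n)), n))
  keep <- apply(grid, 1, function(r) !anyDuplicated(r))
  lapply(which(keep), function(i) as.integer(grid[i, ]))
}

# distance matrix of points placed on a line/plane -> Euclidean-embeddable
euclidean_distance_matrix <- function(coords) {
  D <- as.matrix(dist(coords))
  dimnames(D) <- list(paste0("s", seq_len(nrow(D))),
                      paste0("s", seq_len(nrow(D))))
  D
}
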