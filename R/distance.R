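#' Dice similarity between two binary band profiles
#'
#' S = 2a / (2a + b + c), where a is the number of shared band presences and
#' b, c the presences exclusive to each specimen. Shared absences are
#' ignored, the standard convention for dominant markers where a shared
#' missing band carries no homology signal.
#'
#' @param x,y binary vectors of equal length.
#' @return similarity in \[0, 1\].
#' @export
dice_similarity <- function(x, y) {
  if (length(x) != length(y))
    stop_hb("profiles differ in length (%d vs %d)", length(x), length(y),
            class = "input_error")
  if (!all(x %in% c(0, 1)) || !all(y %in% c(0, 1)))
    stop_hb("profiles must be binary 0/1", class = "input_error")
  a <- sum(x == 1 & y == 1)
  b <- sum(x == 1 & y == 0)
  c_ <- sum(x == 0 & y == 1)
  if (a + b + c_ == 0)
    stop_hb("Dice similarity undefined: both profiles are all-absent",
            class = "undefined_similarity_error")
  2 * a / (2 * a + b + c_)
}

#' Pairwise Dice genetic distance for a marker matrix
#'
#' D_ij = 1 - S_ij, with S_ij the Dice similarity of the band profiles of
#' specimens i and j.
#'
#' @param matrix a [marker_matrix()].
#' @return a symmetric numeric matrix of class `dist_matrix` with zero
#'   diagonal and specimen ids as dimnames.
#' @export
distance_matrix <- function(matrix) {
  stopifnot(inherits(matrix, "marker_matrix"))
  v <- matrix$values
  n <- nrow(v)
  if (n < 2) stop_hb("need >= 2 specimens", class = "input_error")
  if (any(rowSums(v) == 0))
    stop_hb("Dice similarity undefined: all-absent specimen(s): %s",
            paste(rownames(v)[rowSums(v) == 0], collapse = ", "),
            class = "undefined_similarity_error")
  # a_ij = shared presences; row sums give a + b and a + c
  A <- v %*% t(v)
  rs <- rowSums(v)
  S <- 2 * A / outer(rs, rs, `+`)
  D <- 1 - S
  diag(D) <- 0
  structure(D, class = c("dist_matrix", "matrix"))
}

as_dist_matrix <- function(D, ids = NULL) {
  D <- as.matrix(D)
  if (!is.null(ids)) dimnames(D) <- list(ids, ids)
  if (is.null(rownames(D)))
    dimnames(D) <- list(paste0("S", seq_len(nrow(D))),
                        paste0("S", seq_len(nrow(D))))
  if (!isTRUE(all.equal(D, t(D))))
    stop_hb("distance matrix must be symmetric", class = "input_error")
  if (any(diag(D) != 0))
    stop_hb("distance matrix must have zero diagonal", class = "input_error")
  structure(D, class = c("dist_matrix", "matrix"))
}

#' Write a distance matrix in PHYLIP square format
#'
#' For import into external split-network software (e.g. SplitsTree), which
#' replaces in-package Neighbor-Net construction.
#'
#' @param D symmetric distance matrix with specimen dimnames.
#' @param path output path.
#' @param digits significant digits (default 6).
#' @return invisibly, the path.
#' @export
write_phylip <- function(D, path, digits = 6) {
  D <- as.matrix(D)
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(D)), con)
  for (i in seq_len(nrow(D))) {
    nm <- formatC(substr(rownames(D)[i], 1, 10), width = -10)
    writeLines(paste0(nm, paste(signif(D[i, ], digits), collapse = "  ")), con)
  }
  invisible(path)
}
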