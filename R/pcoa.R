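#' Principal coordinate analysis (classical metric scaling)
#'
#' Double-centers the squared distance matrix (Gower transform) and
#' eigendecomposes it. Axes are ordered by decreasing eigenvalue; the
#' proportion of variance per axis uses only the positive eigenvalues in
#' its denominator. Dice distances are mildly non-Euclidean, so some
#' negative eigenvalues are expected; their total magnitude is reported as
#' `negative_mass` (no Cailliez/Lingoes correction is applied) so users can
#' judge the distortion.
#'
#' @param D symmetric distance matrix.
#' @param n_axes number of axes requested (>= 1); silently truncated (with a
#'   warning) to the number of positive eigenvalues available.
#' @return an object of class `pcoa_result`: list with `coordinates`
#'   (specimens x axes), `eigenvalues` (all, decreasing), `proportion`
#'   (variance share per returned axis), `negative_mass`.
#' @export
pcoa <- function(D, n_axes = 2) {
  D <- as_dist_matrix(D)
  if (n_axes < 1) stop_hb("n_axes must be >= 1", class = "input_error")
  n <- nrow(D)
  # cmdscale warns when fewer than k eigenvalues are positive; the
  # truncation is handled (and warned about) below
  fit <- suppressWarnings(stats::cmdscale(stats::as.dist(D), k = n - 1,
                                          eig = TRUE))
  eig <- fit$eig
  pos <- eig[eig > 1e-12]
  if (n_axes > length(pos)) {
    warning(sprintf("only %d positive eigenvalue(s); truncating n_axes from %d",
                    length(pos), n_axes))
    n_axes <- length(pos)
  }
  coords <- fit$points[, seq_len(n_axes), drop = FALSE]
  colnames(coords) <- paste0("Axis", seq_len(n_axes))
  structure(list(coordinates = coords,
                 eigenvalues = eig,
                 proportion = pos[seq_len(n_axes)] / sum(pos),
                 negative_mass = sum(abs(eig[eig < 0]))),
            class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat(sprintf("pcoa_result: %d specimens, %d axes; variance explained: %s\n",
              nrow(x$coordinates), ncol(x$coordinates),
              paste(sprintf("%.1f%%", 100 * x$proportion), collapse = ", ")))
  if (x$negative_mass > 0)
    cat(sprintf("negative eigenvalue mass: %.4g\n", x$negative_mass))
  invisible(x)
}
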