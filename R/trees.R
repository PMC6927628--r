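#' UPGMA dendrogram from a distance matrix
#'
#' Average-linkage agglomeration; merge heights are half the mean
#' inter-cluster distance, so the returned tree is rooted and ultrametric
#' (all root-to-tip path lengths equal).
#'
#' @param D symmetric distance matrix (specimen ids as dimnames).
#' @return an [ape::phylo] tree, rooted, with branch lengths.
#' @export
upgma <- function(D) {
  D <- as_dist_matrix(D)
  if (nrow(D) < 2) stop_hb("UPGMA needs >= 2 specimens", class = "input_error")
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  phy <- ape::as.phylo(hc)   # divides merge heights by 2 -> ultrametric
  phy
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration via [ape::nj()]; the result is unrooted.
#' Negative branch lengths (possible on non-additive input) are clamped to
#' zero with a message.
#'
#' @param D symmetric distance matrix (specimen ids as dimnames).
#' @return an unrooted [ape::phylo] tree.
#' @export
nj_tree <- function(D) {
  D <- as_dist_matrix(D)
  if (nrow(D) < 3) stop_hb("NJ needs >= 3 specimens", class = "input_error")
  phy <- ape::nj(stats::as.dist(D))
  if (any(phy$edge.length < 0)) {
    message(sprintf("clamping %d negative NJ branch length(s) to 0",
                    sum(phy$edge.length < 0)))
    phy$edge.length[phy$edge.length < 0] <- 0
  }
  phy
}

build_tree <- function(D, method = c("nj", "upgma")) {
  method <- match.arg(method)
  if (method == "nj") nj_tree(D) else upgma(D)
}

#' Bootstrap support for dendrogram nodes by locus resampling
#'
#' Loci (matrix columns) are resampled with replacement, the tree is rebuilt
#' on each pseudo-replicate, and each internal node of the point-estimate
#' tree receives the percentage of replicate trees containing its
#' bipartition (unrooted splits for NJ, rooted clades for UPGMA). A
#' replicate that leaves some specimen with no bands (undefined Dice) is
#' redrawn, up to 100 retries.
#'
#' @param matrix a [marker_matrix()].
#' @param meta optional [specimen_meta()]; when given, groups in
#'   `exclude_groups` are dropped first.
#' @param method `"nj"` or `"upgma"`.
#' @param n_reps number of bootstrap replicates (the classical choice is
#'   1000).
#' @param seed integer seed; fixed seed gives bit-identical supports.
#' @param exclude_groups groups dropped before analysis (default none).
#' @return the point-estimate [ape::phylo] tree with `node.label` set to
#'   integer support percentages (root label empty).
#' @export
bootstrap_support <- function(matrix, meta = NULL, method = c("nj", "upgma"),
                              n_reps = 1000, seed = 1,
                              exclude_groups = character(0)) {
  method <- match.arg(method)
  stopifnot(n_reps >= 1)
  if (!is.null(meta) && length(exclude_groups)) {
    grp <- meta_group(matrix, meta)
    matrix <- subset_matrix(matrix,
                            specimens = names(grp)[!(grp %in% exclude_groups)])
  }
  v <- matrix$values
  point <- build_tree(distance_matrix(matrix), method)
  set.seed(seed)
  boots <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    for (try in seq_len(100)) {
      idx <- sample.int(ncol(v), ncol(v), replace = TRUE)
      vb <- v[, idx, drop = FALSE]
      if (all(rowSums(vb) > 0)) break
      if (try == 100)
        stop_hb("could not draw a bootstrap replicate without an all-absent specimen in 100 tries",
                class = "bootstrap_error")
    }
    mb <- marker_matrix(vb, rownames(v), paste0("bs", seq_len(ncol(vb))))
    boots[[r]] <- build_tree(distance_matrix(mb), method)
  }
  counts <- ape::prop.clades(point, boots, rooted = (method == "upgma"))
  counts[is.na(counts)] <- 0L
  support <- round(100 * counts / n_reps)
  support[1] <- NA  # root (or arbitrary NJ basal node) carries no split
  point$node.label <- ifelse(is.na(support), "", as.character(support))
  attr(point, "bootstrap") <- support
  attr(point, "n_reps") <- n_reps
  point
}

#' Write a tree in Newick format
#'
#' Branch lengths at 6 significant digits; bootstrap supports (if present)
#' as internal node labels.
#'
#' @param tree an [ape::phylo] tree.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 6)
  invisible(path)
}
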