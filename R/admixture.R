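#' Admixture model configuration
#'
#' Desk-scale defaults (burn-in 2000, 10000 sweeps) are deliberately smaller
#' than the classical STRUCTURE settings (1e5 burn-in, 2e5 sweeps), which
#' remain available by overriding the fields.
#'
#' @param K number of clusters (>= 1).
#' @param n_burnin burn-in sweeps.
#' @param n_iter retained sweeps after burn-in (>= 1).
#' @param alpha Dirichlet admixture prior parameter (> 0; default 1).
#' @param seed integer seed.
#' @param thinning keep every `thinning`-th log-likelihood value.
#' @return a named list of class `admixture_config`.
#' @export
admixture_config <- function(K, n_burnin = 2000, n_iter = 10000, alpha = 1,
                             seed = 1, thinning = 1) {
  if (K < 1) stop_hb("K must be >= 1", class = "config_error")
  if (n_iter < 1) stop_hb("n_iter must be >= 1", class = "config_error")
  if (alpha <= 0) stop_hb("alpha must be > 0", class = "config_error")
  structure(list(K = as.integer(K), n_burnin = as.integer(n_burnin),
                 n_iter = as.integer(n_iter), alpha = alpha,
                 seed = as.integer(seed), thinning = as.integer(thinning)),
            class = "admixture_config")
}

#' Bayesian admixture inference for dominant markers
#'
#' Fits a STRUCTURE-like admixture model treating each locus as an
#' independent biallelic dominant marker in diploids: band absent means
#' homozygous null, band present means at least one presence allele (the
#' "recessive alleles" coding appropriate for RAPD/AFLP data). Inference is
#' by Gibbs sampling with latent-variable augmentation: per individual and
#' locus the unobserved diploid genotype consistent with the phenotype is
#' sampled given the current admixture proportions Q and cluster band-allele
#' frequencies P (phenotype presence probability
#' 1 - (sum_k q_ik (1 - p_kl))^2), each allele copy receives a
#' cluster-of-origin, then P is updated from its Beta(1,1) posterior and
#' each Q row from its Dirichlet(alpha) posterior. Correlated frequencies
#' are not modeled; alpha is fixed.
#'
#' @param matrix a [marker_matrix()].
#' @param meta optional [specimen_meta()]; groups in `exclude_groups` are
#'   dropped first.
#' @param config an [admixture_config()].
#' @param exclude_groups groups to drop (default `"outgroup"` when `meta`
#'   is given).
#' @return an object of class `admixture_result`: list with `Q` (specimens
#'   x K, rows sum to 1), `P` (K x loci, in (0,1)), `loglik_trace`,
#'   `mean_loglik`, `sd_loglik`, `config`.
#' @export
run_admixture <- function(matrix, meta = NULL, config = admixture_config(2),
                          exclude_groups = "outgroup") {
  stopifnot(inherits(matrix, "marker_matrix"),
            inherits(config, "admixture_config"))
  if (!is.null(meta)) {
    grp <- meta_group(matrix, meta)
    matrix <- subset_matrix(matrix,
                            specimens = names(grp)[!(grp %in% exclude_groups)])
  }
  y <- matrix$values
  if (config$K > nrow(y))
    stop_hb("K (%d) exceeds number of specimens (%d)", config$K, nrow(y),
            class = "config_error")
  set.seed(config$seed)
  fit <- .admixture_gibbs_cpp(y, config$K, config$n_burnin, config$n_iter,
                              config$alpha, config$thinning)
  Q <- fit$Q; P <- fit$P
  dimnames(Q) <- list(rownames(y), paste0("cluster", seq_len(config$K)))
  dimnames(P) <- list(paste0("cluster", seq_len(config$K)), colnames(y))
  structure(list(Q = Q, P = P, loglik_trace = as.numeric(fit$loglik_trace),
                 mean_loglik = mean(fit$loglik_trace),
                 sd_loglik = stats::sd(fit$loglik_trace),
                 config = config),
            class = "admixture_result")
}

#' @export
print.admixture_result <- function(x, ...) {
  cat(sprintf("admixture_result: K = %d, %d specimens, %d loci; mean log-likelihood %.2f\n",
              x$config$K, nrow(x$Q), ncol(x$P), x$mean_loglik))
  invisible(x)
}

#' Run replicate admixture analyses over a range of K
#'
#' @param matrix a [marker_matrix()].
#' @param meta optional [specimen_meta()].
#' @param K_range integer vector of K values (e.g. `1:5`).
#' @param n_reps replicates per K.
#' @param seed global seed; replicate r at cluster count K runs with a seed
#'   derived from `(seed, K, r)` so streams are independent and stable.
#' @param ... further arguments to [admixture_config()] (`n_burnin`,
#'   `n_iter`, `alpha`, `thinning`).
#' @param exclude_groups groups to drop.
#' @return list of class `admixture_scan`: per K, a list of
#'   [run_admixture()] results.
#' @export
run_admixture_scan <- function(matrix, meta = NULL, K_range = 1:5,
                               n_reps = 10, seed = 1, ...,
                               exclude_groups = "outgroup") {
  runs <- lapply(K_range, function(K) {
    lapply(seq_len(n_reps), function(r) {
      s <- derive_seed(seed, sprintf("admixture_K%d_rep%d", K, r))
      run_admixture(matrix, meta,
                    admixture_config(K = K, seed = s, ...),
                    exclude_groups = exclude_groups)
    })
  })
  names(runs) <- paste0("K", K_range)
  structure(list(runs = runs, K_range = K_range, n_reps = n_reps),
            class = "admixture_scan")
}

#' Evanno delta-K cluster-number selection
#'
#' For replicate log-likelihood means L(K), computes
#' dK = |mean L(K+1) - 2 mean L(K) + mean L(K-1)| / sd L(K)
#' at every interior K; the selected K maximises dK. A K with zero
#' replicate standard deviation has undefined dK there (flagged, excluded
#' from the argmax).
#'
#' @param scan an [run_admixture_scan()] result, or a named list
#'   (names `"K<k>"`) of lists of numeric replicate log-likelihoods.
#' @return a `data.frame` of class `delta_k_table` with columns `K`,
#'   `mean_loglik`, `sd_loglik`, `delta_K`, and attribute `selected_K`.
#' @export
evanno_deltaK <- function(scan) {
  if (inherits(scan, "admixture_scan")) {
    Ks <- scan$K_range
    L <- lapply(scan$runs, function(reps)
      vapply(reps, function(r) r$mean_loglik, 0))
  } else {
    Ks <- as.integer(sub("^K", "", names(scan)))
    L <- lapply(scan, as.numeric)
  }
  ord <- order(Ks); Ks <- Ks[ord]; L <- L[ord]
  if (length(Ks) < 3)
    stop_hb("delta-K needs >= 3 consecutive K values (no interior K with only %d)",
            length(Ks), class = "input_error")
  if (any(diff(Ks) != 1))
    stop_hb("K values must be consecutive", class = "input_error")
  if (any(vapply(L, length, 0L) < 2))
    stop_hb("need >= 2 replicates per K for a standard deviation",
            class = "input_error")
  mL <- vapply(L, mean, 0)
  sL <- vapply(L, stats::sd, 0)
  dK <- rep(NA_real_, length(Ks))
  for (j in seq_along(Ks)[-c(1, length(Ks))]) {
    if (sL[j] > 0)
      dK[j] <- abs(mL[j + 1] - 2 * mL[j] + mL[j - 1]) / sL[j]
  }
  if (all(is.na(dK)))
    stop_hb("delta-K undefined at every interior K (zero replicate sd)",
            class = "input_error")
  tab <- data.frame(K = Ks, mean_loglik = mL, sd_loglik = sL, delta_K = dK)
  rownames(tab) <- NULL
  attr(tab, "selected_K") <- Ks[which.max(dK)]
  class(tab) <- c("delta_k_table", "data.frame")
  tab
}

#' @export
print.delta_k_table <- function(x, ...) {
  print.data.frame(x)
  cat("selected K:", attr(x, "selected_K"), "\n")
  invisible(x)
}

perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in perms(n - 1))
    for (pos in seq_len(n))
      out[[length(out) + 1]] <- append(p, n, after = pos - 1)
  out
}

#' Align replicate membership matrices across label switching
#'
#' Cluster labels are arbitrary across MCMC replicates. Each replicate's
#' columns are permuted to minimise the total absolute difference from the
#' reference replicate (exhaustive over the K! permutations for K <= 8;
#' greedy column matching, with a warning, beyond that). Returns the
#' aligned replicates and their element-wise mean.
#'
#' @param Q_list list of specimens x K membership matrices, equal shapes.
#' @param reference index of the reference replicate (default 1).
#' @return list with `aligned` (list of matrices) and `mean_Q`.
#' @export
align_replicates <- function(Q_list, reference = 1) {
  stopifnot(length(Q_list) >= 1)
  dims <- vapply(Q_list, dim, c(0L, 0L))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop_hb("replicate Q matrices must have identical shapes",
            class = "input_error")
  K <- ncol(Q_list[[1]])
  ref <- Q_list[[reference]]
  align_one <- function(Q) {
    if (K <= 8) {
      best <- NULL; best_cost <- Inf
      for (p in perms(K)) {
        cost <- sum(abs(Q[, p, drop = FALSE] - ref))
        if (cost < best_cost) { best_cost <- cost; best <- p }
      }
      Q[, best, drop = FALSE]
    } else {
      warning("K > 8: falling back to greedy column assignment")
      p <- integer(K); taken <- logical(K)
      for (k in seq_len(K)) {
        costs <- vapply(seq_len(K), function(j)
          if (taken[j]) Inf else sum(abs(Q[, j] - ref[, k])), 0)
        p[k] <- which.min(costs); taken[p[k]] <- TRUE
      }
      Q[, p, drop = FALSE]
    }
  }
  aligned <- lapply(Q_list, align_one)
  aligned <- lapply(aligned, function(Q) {
    colnames(Q) <- colnames(ref); Q
  })
  mean_Q <- Reduce(`+`, aligned) / length(aligned)
  list(aligned = aligned, mean_Q = mean_Q)
}
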