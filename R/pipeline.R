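#' Validate and normalize a pipeline configuration
#'
#' Fills defaults and rejects unknown keys. The configuration is a plain
#' named list (or a YAML/JSON file read into one); `seed` governs every
#' stochastic stage through stage-derived seeds, so one global seed fully
#' determines a run.
#'
#' @param config named list, or a path to a JSON config file.
#' @return normalized list of class `pipeline_config`.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  defaults <- list(
    matrix_path = NULL, meta_path = NULL,       # or simulate = TRUE
    simulate = FALSE, sim = list(),             # sim_config overrides
    out_dir = NULL, seed = 1,
    stages = c("classify", "distance", "tree", "pcoa", "hybrid_index",
               "admixture"),
    tree_method = "nj", bootstrap_reps = 100,
    K_range = 1:4, admixture_reps = 3,
    n_burnin = 2000, n_iter = 10000,
    thresholds = list(pure_low = 0.2, f1_low = 0.4, f1_high = 0.6,
                      pure_high = 0.8))
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop_hb("unknown config key(s): %s", paste(unknown, collapse = ", "),
            class = "validation_error")
  cfg <- utils::modifyList(defaults, config)
  known_stages <- c("classify", "distance", "tree", "pcoa", "hybrid_index",
                    "admixture")
  bad <- setdiff(cfg$stages, known_stages)
  if (length(bad))
    stop_hb("unknown stage(s): %s", paste(bad, collapse = ", "),
            class = "validation_error")
  if (length(cfg$K_range) < 1 || any(diff(cfg$K_range) <= 0))
    stop_hb("K_range must be increasing (got %s)",
            paste(cfg$K_range, collapse = ":"), class = "validation_error")
  cfg$thresholds <- do.call(hybrid_thresholds, cfg$thresholds)
  if (!cfg$simulate && (is.null(cfg$matrix_path) || is.null(cfg$meta_path)))
    stop_hb("either simulate = TRUE or matrix_path + meta_path are required",
            class = "validation_error")
  structure(cfg, class = "pipeline_config")
}

#' Run the full marker-based hybrid-detection pipeline
#'
#' Stages run in dependency order: input (read or simulate) -> band
#' classification -> distance matrix -> tree with bootstrap -> PCoA ->
#' hybrid index + class calls -> admixture scan with delta-K. Disabled
#' stages are skipped, and stages that need a disabled prerequisite are
#' skipped with a warning recorded in the report. All numeric results in
#' the report equal the module-level outputs (2-decimal display rounding is
#' applied only in delimited exports).
#'
#' @param config a [validate_config()] result or raw list.
#' @return list of class `run_report`: configuration echo, per-stage
#'   summaries, and (when `out_dir` is set) the paths of written artifacts.
#' @export
run_pipeline <- function(config = list()) {
  if (!inherits(config, "pipeline_config")) config <- validate_config(config)
  report <- list(package_version = as.character(utils::packageVersion("hybridband")),
                 config = unclass(config), stages = list(), warnings = character(0))
  out <- function(name) if (!is.null(config$out_dir))
    file.path(config$out_dir, name) else NULL
  if (!is.null(config$out_dir) && !dir.exists(config$out_dir))
    dir.create(config$out_dir, recursive = TRUE)

  if (config$simulate) {
    sim_args <- utils::modifyList(
      list(seed = derive_seed(config$seed, "simulate")), config$sim)
    ds <- simulate_marker_dataset(do.call(sim_config, sim_args))
    m <- ds$matrix; meta <- ds$meta
    report$stages$simulate <- list(
      n_specimens = nrow(m$values), n_loci = ncol(m$values),
      classes = as.list(table(ds$truth$class)))
    if (!is.null(config$out_dir)) {
      write_matrix(m, out("matrix.csv"))
      write_meta(meta, out("meta.csv"))
    }
  } else {
    rd <- read_matrix(config$matrix_path, config$meta_path)
    m <- rd$matrix; meta <- rd$meta
  }

  cls <- NULL
  if ("classify" %in% config$stages) {
    cls <- classify_bands(m, meta)
    report$stages$classify <- as.list(cls$counts)
    if (!is.null(config$out_dir)) write_band_report(cls, out("bands.json"))
  }

  D <- NULL
  if ("distance" %in% config$stages) {
    D <- distance_matrix(m)
    off <- D[upper.tri(D)]
    report$stages$distance <- list(min = min(off), max = max(off),
                                   mean = mean(off))
    if (!is.null(config$out_dir)) write_phylip(D, out("distances.phy"))
  }

  if ("tree" %in% config$stages) {
    if (is.null(D)) {
      report$warnings <- c(report$warnings, "tree skipped: distance stage disabled")
    } else {
      tr <- bootstrap_support(m, meta, method = config$tree_method,
                              n_reps = config$bootstrap_reps,
                              seed = derive_seed(config$seed, "bootstrap"))
      report$stages$tree <- list(method = config$tree_method,
                                 n_reps = config$bootstrap_reps,
                                 newick = ape::write.tree(tr, digits = 6))
      if (!is.null(config$out_dir)) write_newick(tr, out("tree.nwk"))
    }
  }

  if ("pcoa" %in% config$stages) {
    if (is.null(D)) {
      report$warnings <- c(report$warnings, "pcoa skipped: distance stage disabled")
    } else {
      pc <- pcoa(D, n_axes = 2)
      report$stages$pcoa <- list(
        proportion = as.numeric(pc$proportion),
        negative_mass = pc$negative_mass)
    }
  }

  if ("hybrid_index" %in% config$stages) {
    if (is.null(cls)) {
      report$warnings <- c(report$warnings,
                           "hybrid_index skipped: classify stage disabled")
    } else {
      dset <- diagnostic_set_from_classification(cls)
      rep_m <- marker_report(m, meta, dset)
      tab <- rep_m$table
      report$stages$hybrid_index <- list(
        m_A = dset$m_A, m_B = dset$m_B,
        table = lapply(seq_len(nrow(tab)), function(i) as.list(tab[i, ])))
      if (!is.null(config$out_dir))
        write_marker_report(rep_m, out("hybrid_index"))
    }
  }

  if ("admixture" %in% config$stages) {
    scan <- run_admixture_scan(m, meta, K_range = config$K_range,
                               n_reps = config$admixture_reps,
                               seed = config$seed,
                               n_burnin = config$n_burnin,
                               n_iter = config$n_iter)
    dk <- evanno_deltaK(scan)
    sel <- attr(dk, "selected_K")
    al <- align_replicates(lapply(scan$runs[[paste0("K", sel)]],
                                  function(r) r$Q))
    report$stages$admixture <- list(
      delta_K = lapply(seq_len(nrow(dk)), function(i) as.list(dk[i, ])),
      selected_K = sel,
      mean_Q = apply(al$mean_Q, 1, function(q) as.list(q)))
    if (!is.null(config$out_dir)) {
      utils::write.table(
        data.frame(specimen_id = rownames(al$mean_Q), al$mean_Q),
        out("admixture_Q.csv"), sep = ",", row.names = FALSE, quote = FALSE)
      jsonlite::write_json(report$stages$admixture$delta_K,
                           out("delta_k.json"), auto_unbox = TRUE,
                           digits = NA, pretty = TRUE)
    }
  }

  class(report) <- "run_report"
  if (!is.null(config$out_dir)) {
    jsonlite::write_json(unclass(report), out("run_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("run_report (hybridband", x$package_version, ")\n")
  cat("stages:", paste(names(x$stages), collapse = ", "), "\n")
  if (length(x$warnings)) cat("warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}
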