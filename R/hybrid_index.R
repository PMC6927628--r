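#' Build a diagnostic marker set
#'
#' The per-parent lists of species-diagnostic loci underlying the hybrid
#' index: `loci_A` are fixed-present in parent A and absent in parent B
#' (count m_A), `loci_B` the reverse (count m_B). In the motivating dogwood
#' system, parent A (Cornus alternifolia) contributed 51 diagnostic markers
#' and parent B (C. controversa) 44.
#'
#' @param loci_A,loci_B character vectors of locus ids; must be disjoint
#'   and non-empty.
#' @return an object of class `diagnostic_marker_set`.
#' @export
diagnostic_marker_set <- function(loci_A, loci_B) {
  loci_A <- as.character(loci_A); loci_B <- as.character(loci_B)
  if (length(loci_A) < 1 || length(loci_B) < 1)
    stop_hb("need >= 1 diagnostic locus per parent (got %d, %d)",
            length(loci_A), length(loci_B), class = "input_error")
  both <- intersect(loci_A, loci_B)
  if (length(both))
    stop_hb("loci diagnostic for both parents: %s", paste(both, collapse = ", "),
            class = "input_error")
  structure(list(loci_A = loci_A, loci_B = loci_B,
                 m_A = length(loci_A), m_B = length(loci_B)),
            class = "diagnostic_marker_set")
}

#' Extract the diagnostic marker set from a band classification
#'
#' @param classification a [classify_bands()] result.
#' @return a [diagnostic_marker_set()].
#' @export
diagnostic_set_from_classification <- function(classification) {
  stopifnot(inherits(classification, "band_classification"))
  diagnostic_marker_set(names(which(classification$diagnostic_A)),
                        names(which(classification$diagnostic_B)))
}

#' @export
print.diagnostic_marker_set <- function(x, ...) {
  cat(sprintf("diagnostic_marker_set: m_A = %d, m_B = %d\n", x$m_A, x$m_B))
  invisible(x)
}

#' Score one specimen against the diagnostic marker sets
#'
#' Counts `c_present`, the parent-B diagnostic markers the specimen carries,
#' and `a_absent`, the parent-A diagnostic markers it lacks. These two
#' counts drive the hybrid index: each foreign (B) band carried and each
#' own (A) band missing moves the specimen away from pure parent A.
#'
#' @param matrix a [marker_matrix()].
#' @param dset a [diagnostic_marker_set()]; all its loci must be columns of
#'   `matrix`.
#' @param specimen_id a specimen in the matrix.
#' @return named integer vector `c(c_present=, a_absent=)`.
#' @export
score_specimen_markers <- function(matrix, dset, specimen_id) {
  stopifnot(inherits(matrix, "marker_matrix"),
            inherits(dset, "diagnostic_marker_set"))
  if (!specimen_id %in% specimen_ids(matrix))
    stop_hb("specimen '%s' not in matrix", specimen_id, class = "input_error")
  miss <- setdiff(c(dset$loci_A, dset$loci_B), locus_ids(matrix))
  if (length(miss))
    stop_hb("diagnostic locus/loci absent from matrix: %s",
            paste(miss, collapse = ", "), class = "input_error")
  row <- matrix$values[specimen_id, ]
  c(c_present = sum(row[dset$loci_B] == 1),
    a_absent = sum(row[dset$loci_A] == 0))
}

#' Hybrid index from diagnostic-marker counts
#'
#' Position of a specimen between the two parental species on a 0-1 scale
#' (distance from pure parent A). A pure parent-A plant, carrying every A
#' marker and no B marker, scores 0; the presence of any B marker or the
#' lack of any A marker increases the index, up to 1 for pure parent B.
#' Two variants are provided:
#' \describe{
#'   \item{raw}{(c_present + a_absent) / (m_A + m_B) — pooled count over
#'     all 95 markers in the motivating study.}
#'   \item{normalized}{(c_present/m_B + a_absent/m_A) / 2 — mean of the two
#'     per-parent proportions; exactly 0.5 at full marker additivity (an F1
#'     carrying all markers of both parents), regardless of m_A, m_B.}
#' }
#' The variants agree exactly when m_A = m_B.
#'
#' @param c_present count of parent-B diagnostic markers present (0..m_B).
#' @param a_absent count of parent-A diagnostic markers absent (0..m_A).
#' @param m_A,m_B diagnostic marker counts per parent.
#' @param variant `"raw"` or `"normalized"`.
#' @return index value in \[0, 1\] (vectorized over counts).
#' @export
hybrid_index <- function(c_present, a_absent, m_A, m_B,
                         variant = c("raw", "normalized")) {
  variant <- match.arg(variant)
  if (any(c_present < 0 | c_present > m_B))
    stop_hb("c_present out of range [0, m_B = %d]", m_B, class = "domain_error")
  if (any(a_absent < 0 | a_absent > m_A))
    stop_hb("a_absent out of range [0, m_A = %d]", m_A, class = "domain_error")
  if (variant == "raw")
    (c_present + a_absent) / (m_A + m_B)
  else
    (c_present / m_B + a_absent / m_A) / 2
}

#' Hybrid-class thresholds
#'
#' Interval configuration for [classify_specimens()]. Defaults: pure below
#' 0.2 / above 0.8, F1-type inside \[0.4, 0.6\] when markers from both
#' parents are carried, backcross in between. The intervals must be
#' non-overlapping and ordered.
#'
#' @param pure_low,f1_low,f1_high,pure_high interval boundaries on the
#'   index scale.
#' @return a named list of thresholds.
#' @export
hybrid_thresholds <- function(pure_low = 0.2, f1_low = 0.4,
                              f1_high = 0.6, pure_high = 0.8) {
  th <- list(pure_low = pure_low, f1_low = f1_low,
             f1_high = f1_high, pure_high = pure_high)
  if (!(pure_low < f1_low && f1_low <= f1_high && f1_high < pure_high))
    stop_hb("overlapping/unordered class thresholds: need pure_low < f1_low <= f1_high < pure_high",
            class = "config_error")
  th
}

#' Compute hybrid indices and class calls for query specimens
#'
#' Scores every requested specimen against the diagnostic sets, computes
#' both index variants and assigns a hybrid class:
#' `pure_A`/`pure_B` in the outer intervals, `F1_type` in the central
#' interval when the specimen carries at least one diagnostic marker from
#' each parent, `backcross_A`/`backcross_B` in between, `ambiguous` for a
#' central index lacking one parental set. A specimen with a pure-range
#' index that nevertheless carries opposite-parent markers keeps its pure
#' call but is flagged `introgressed` (the signature of an old backcross).
#'
#' @param matrix a [marker_matrix()].
#' @param dset a [diagnostic_marker_set()].
#' @param specimens specimen ids to score (default: all in the matrix).
#' @param thresholds a [hybrid_thresholds()] list.
#' @param class_variant which index variant drives the class call
#'   (default `"normalized"`).
#' @return a `data.frame` of class `hybrid_index_result` with columns
#'   `specimen_id`, `c_present`, `a_absent`, `m_A`, `m_B`, `index_raw`,
#'   `index_normalized`, `class_call`, `introgressed`.
#' @export
classify_specimens <- function(matrix, dset, specimens = specimen_ids(matrix),
                               thresholds = hybrid_thresholds(),
                               class_variant = c("normalized", "raw")) {
  class_variant <- match.arg(class_variant)
  thresholds <- do.call(hybrid_thresholds, thresholds)  # re-validate
  if (length(specimens) == 0L) {
    res <- data.frame(specimen_id = character(0), c_present = integer(0),
                      a_absent = integer(0), m_A = integer(0),
                      m_B = integer(0), index_raw = numeric(0),
                      index_normalized = numeric(0),
                      class_call = character(0), introgressed = logical(0),
                      stringsAsFactors = FALSE)
    class(res) <- c("hybrid_index_result", "data.frame")
    return(res)
  }
  scores <- t(vapply(specimens,
                     function(s) score_specimen_markers(matrix, dset, s),
                     c(c_present = 0, a_absent = 0)))
  res <- data.frame(
    specimen_id = specimens,
    c_present = as.integer(scores[, "c_present"]),
    a_absent = as.integer(scores[, "a_absent"]),
    m_A = dset$m_A, m_B = dset$m_B,
    stringsAsFactors = FALSE)
  res$index_raw <- hybrid_index(res$c_present, res$a_absent, dset$m_A,
                                dset$m_B, "raw")
  res$index_normalized <- hybrid_index(res$c_present, res$a_absent, dset$m_A,
                                       dset$m_B, "normalized")
  idx <- if (class_variant == "raw") res$index_raw else res$index_normalized
  carries_A <- res$a_absent < dset$m_A
  carries_B <- res$c_present > 0
  cls <- character(length(idx)); intro <- logical(length(idx))
  for (i in seq_along(idx)) {
    if (idx[i] <= thresholds$pure_low) {
      cls[i] <- "pure_A"; intro[i] <- carries_B[i]
    } else if (idx[i] >= thresholds$pure_high) {
      cls[i] <- "pure_B"; intro[i] <- carries_A[i]
    } else if (idx[i] >= thresholds$f1_low && idx[i] <= thresholds$f1_high) {
      cls[i] <- if (carries_A[i] && carries_B[i]) "F1_type" else "ambiguous"
    } else if (idx[i] < thresholds$f1_low) {
      cls[i] <- "backcross_A"
    } else {
      cls[i] <- "backcross_B"
    }
  }
  res$class_call <- cls
  res$introgressed <- intro
  class(res) <- c("hybrid_index_result", "data.frame")
  res
}

#' Per-specimen diagnostic-marker presence grid and index report
#'
#' The tabular counterpart of a diagnostic-marker figure: for each query
#' specimen, the presence/absence of every diagnostic locus of both
#' parental sets, the two marker counts, and both index variants (displayed
#' half-up at 2 decimals in the delimited export; full precision in the
#' returned object).
#'
#' @param matrix a [marker_matrix()].
#' @param meta a [specimen_meta()]; the report covers `group == "query"`
#'   specimens.
#' @param dset a [diagnostic_marker_set()].
#' @return list of class `marker_report`: `grid` (query specimens x
#'   diagnostic loci 0/1 matrix, A loci first), `table` (a
#'   [classify_specimens()] data frame for the query specimens).
#' @export
marker_report <- function(matrix, meta, dset) {
  grp <- meta_group(matrix, meta)
  queries <- names(grp)[grp == "query"]
  loci <- c(dset$loci_A, dset$loci_B)
  grid <- matrix$values[queries, loci, drop = FALSE]
  tab <- if (length(queries)) classify_specimens(matrix, dset, queries) else
    classify_specimens(matrix, dset, character(0))
  structure(list(grid = grid, table = tab, dset = dset),
            class = "marker_report")
}

#' Write a marker report as delimited text and JSON
#'
#' @param report a [marker_report()].
#' @param path_prefix files `<prefix>_grid.csv`, `<prefix>_index.csv` and
#'   `<prefix>.json` are written.
#' @return invisibly, the JSON path.
#' @export
write_marker_report <- function(report, path_prefix) {
  stopifnot(inherits(report, "marker_report"))
  grid_df <- data.frame(specimen_id = rownames(report$grid), report$grid,
                        check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(grid_df, paste0(path_prefix, "_grid.csv"), sep = ",",
                     row.names = FALSE, quote = FALSE)
  tab <- report$table
  tab$index_raw <- round_half_up(tab$index_raw, 2)
  tab$index_normalized <- round_half_up(tab$index_normalized, 2)
  utils::write.table(tab, paste0(path_prefix, "_index.csv"), sep = ",",
                     row.names = FALSE, quote = FALSE)
  json <- lapply(seq_len(nrow(report$table)), function(i) {
    r <- report$table[i, ]
    foreign <- names(which(report$grid[r$specimen_id, report$dset$loci_B] == 1))
    list(specimen = r$specimen_id, c_present = r$c_present,
         a_absent = r$a_absent, m_A = r$m_A, m_B = r$m_B,
         index_raw = r$index_raw, index_normalized = r$index_normalized,
         class_call = r$class_call, introgressed = r$introgressed,
         foreign_marker_ids = foreign)
  })
  jpath <- paste0(path_prefix, ".json")
  jsonlite::write_json(json, jpath, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(jpath)
}
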