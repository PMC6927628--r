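#' Construct a dominant-marker matrix
#'
#' A `marker_matrix` holds a specimens x loci binary table of dominant-marker
#' phenotypes: 1 = band present, 0 = band absent. Heterozygotes are
#' indistinguishable from presence homozygotes (RAPD/AFLP dominance), so the
#' cell is the band phenotype, not a genotype. Missing data are not modeled;
#' every cell must be 0 or 1.
#'
#' @param values integer/numeric matrix of 0/1 values, specimens in rows.
#' @param specimen_ids character vector of unique specimen identifiers
#'   (defaults to rownames of `values`).
#' @param locus_ids character vector of unique locus identifiers (defaults
#'   to colnames of `values`).
#' @param locus_source optional character vector, one label per locus, e.g.
#'   the RAPD primer or AFLP primer-combination that produced the band.
#' @param locus_size_bp optional positive integer fragment size per locus.
#' @return an object of class `marker_matrix`: a list with elements
#'   `values` (binary matrix with dimnames), `locus_source`, `locus_size_bp`.
#' @export
marker_matrix <- function(values, specimen_ids = rownames(values),
                          locus_ids = colnames(values),
                          locus_source = NULL, locus_size_bp = NULL) {
  values <- as.matrix(values)
  if (is.null(specimen_ids))
    specimen_ids <- sprintf("S%d", seq_len(nrow(values)))
  if (is.null(locus_ids))
    locus_ids <- sprintf("L%d", seq_len(ncol(values)))
  specimen_ids <- as.character(specimen_ids)
  locus_ids <- as.character(locus_ids)
  if (length(specimen_ids) != nrow(values))
    stop_hb("specimen_ids length (%d) != number of rows (%d)",
            length(specimen_ids), nrow(values), class = "format_error")
  if (length(locus_ids) != ncol(values))
    stop_hb("locus_ids length (%d) != number of columns (%d)",
            length(locus_ids), ncol(values), class = "format_error")
  if (anyDuplicated(specimen_ids))
    stop_hb("duplicate specimen ids: %s",
            paste(unique(specimen_ids[duplicated(specimen_ids)]), collapse = ", "),
            class = "format_error")
  if (anyDuplicated(locus_ids))
    stop_hb("duplicate locus ids: %s",
            paste(unique(locus_ids[duplicated(locus_ids)]), collapse = ", "),
            class = "format_error")
  bad <- which(!(values %in% c(0, 1)))
  if (length(bad)) {
    i <- ((bad[1] - 1) %% nrow(values)) + 1
    j <- ((bad[1] - 1) %/% nrow(values)) + 1
    stop_hb("non-binary cell value '%s' at specimen '%s' (row %d), locus '%s' (column %d)",
            as.character(values[i, j]), specimen_ids[i], i, locus_ids[j], j,
            class = "format_error")
  }
  storage.mode(values) <- "integer"
  dimnames(values) <- list(specimen_ids, locus_ids)
  if (!is.null(locus_source)) {
    if (length(locus_source) != ncol(values))
      stop_hb("locus_source length != number of loci", class = "format_error")
    locus_source <- as.character(locus_source)
    names(locus_source) <- locus_ids
  }
  if (!is.null(locus_size_bp)) {
    if (length(locus_size_bp) != ncol(values))
      stop_hb("locus_size_bp length != number of loci", class = "format_error")
    if (any(!is.na(locus_size_bp) & locus_size_bp <= 0))
      stop_hb("locus_size_bp must be positive", class = "format_error")
    locus_size_bp <- as.integer(locus_size_bp)
    names(locus_size_bp) <- locus_ids
  }
  structure(list(values = values, locus_source = locus_source,
                 locus_size_bp = locus_size_bp),
            class = "marker_matrix")
}

#' @export
print.marker_matrix <- function(x, ...) {
  cat(sprintf("marker_matrix: %d specimens x %d loci (1 = band present)\n",
              nrow(x$values), ncol(x$values)))
  if (!is.null(x$locus_source))
    cat("locus sources:", paste(unique(x$locus_source), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.marker_matrix <- function(x) dim(x$values)

specimen_ids <- function(m) rownames(m$values)
locus_ids <- function(m) colnames(m$values)

#' Construct specimen metadata
#'
#' Assigns each specimen to a role: `parent_A`, `parent_B`, `query`
#' (putative hybrid or specimen of unknown origin) or `outgroup`.
#'
#' @param specimen_id character vector of specimen ids.
#' @param group character vector of groups, one per specimen.
#' @param label optional free-text label per specimen.
#' @return a `data.frame` of class `specimen_meta`.
#' @export
specimen_meta <- function(specimen_id, group, label = specimen_id) {
  groups_ok <- c("parent_A", "parent_B", "query", "outgroup")
  specimen_id <- as.character(specimen_id)
  group <- as.character(group)
  if (length(group) != length(specimen_id))
    stop_hb("group must have one entry per specimen", class = "metadata_error")
  bad <- setdiff(unique(group), groups_ok)
  if (length(bad))
    stop_hb("unknown group(s): %s (allowed: %s)",
            paste(bad, collapse = ", "), paste(groups_ok, collapse = ", "),
            class = "metadata_error")
  if (anyDuplicated(specimen_id))
    stop_hb("duplicate specimen ids in metadata", class = "metadata_error")
  structure(data.frame(specimen_id = specimen_id, group = group,
                       label = as.character(label),
                       stringsAsFactors = FALSE),
            class = c("specimen_meta", "data.frame"))
}

check_meta_covers <- function(m, meta) {
  missing <- setdiff(specimen_ids(m), meta$specimen_id)
  if (length(missing))
    stop_hb("specimens missing from metadata: %s",
            paste(missing, collapse = ", "), class = "metadata_error")
  invisible(TRUE)
}

meta_group <- function(m, meta) {
  check_meta_covers(m, meta)
  setNames(meta$group[match(specimen_ids(m), meta$specimen_id)],
           specimen_ids(m))
}

detect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

#' Read a dominant-marker matrix and specimen metadata from delimited text
#'
#' The matrix file has a header row of locus ids, a first column of specimen
#' ids and 0/1 cells; the metadata file has columns `specimen_id`, `group`
#' and optionally `label`. Comma or tab delimiters are auto-detected from
#' the header line of each file.
#'
#' @param path path to the marker-matrix file.
#' @param meta_path path to the specimen-metadata file.
#' @return a list with components `matrix` (a [marker_matrix()]) and
#'   `meta` (a [specimen_meta()]).
#' @export
read_matrix <- function(path, meta_path) {
  sep <- detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                          check.names = FALSE, colClasses = "character",
                          comment.char = "", quote = "\"")
  vals <- as.matrix(df)
  suppressWarnings(num <- matrix(as.numeric(vals), nrow(vals), ncol(vals)))
  bad <- which(is.na(num) | !(num %in% c(0, 1)))
  if (length(bad)) {
    i <- ((bad[1] - 1) %% nrow(vals)) + 1
    j <- ((bad[1] - 1) %/% nrow(vals)) + 1
    stop_hb("non-binary cell value '%s' at row %d (specimen '%s'), column %d (locus '%s') in %s",
            vals[i, j], i, rownames(df)[i], j, colnames(df)[j], path,
            class = "format_error")
  }
  dimnames(num) <- dimnames(vals)
  m <- marker_matrix(num, rownames(df), colnames(df))
  sep2 <- detect_sep(meta_path)
  md <- utils::read.table(meta_path, header = TRUE, sep = sep2,
                          stringsAsFactors = FALSE, comment.char = "",
                          quote = "\"")
  need <- c("specimen_id", "group")
  if (!all(need %in% names(md)))
    stop_hb("metadata file must have columns: %s", paste(need, collapse = ", "),
            class = "metadata_error")
  meta <- specimen_meta(md$specimen_id, md$group,
                        label = md$label %||% md$specimen_id)
  check_meta_covers(m, meta)
  list(matrix = m, meta = meta)
}

#' Write a marker matrix as canonical delimited text
#'
#' Canonical form: comma-delimited, header `specimen_id` then locus ids in
#' stored order, one row per specimen in stored order. Deterministic, so
#' read/write round trips are byte-identical.
#'
#' @param matrix a [marker_matrix()].
#' @param path output file path.
#' @param sep field separator, `","` (default) or `"\t"`.
#' @return invisibly, the path.
#' @export
write_matrix <- function(matrix, path, sep = ",") {
  stopifnot(inherits(matrix, "marker_matrix"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(c("specimen_id", locus_ids(matrix)), collapse = sep), con)
  v <- matrix$values
  for (i in seq_len(nrow(v)))
    writeLines(paste(c(rownames(v)[i], v[i, ]), collapse = sep), con)
  invisible(path)
}

#' Write specimen metadata as delimited text
#'
#' @param meta a [specimen_meta()].
#' @param path output file path.
#' @return invisibly, the path.
#' @export
write_meta <- function(meta, path) {
  utils::write.table(meta, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Column-concatenate marker matrices scored on the same specimens
#'
#' Combines fingerprints from several marker systems (e.g. RAPD and AFLP
#' runs) into one matrix so that downstream analyses operate on the combined
#' binary data. Specimen sets must be identical; rows are reordered to the
#' first matrix's order. Locus-id collisions across inputs are resolved by
#' prefixing with the locus source (`"src:locus"`), or the input index when
#' no source label exists.
#'
#' @param matrices list of [marker_matrix()] objects.
#' @return a single merged [marker_matrix()].
#' @export
merge_matrices <- function(matrices) {
  stopifnot(is.list(matrices), length(matrices) >= 1,
            all(vapply(matrices, inherits, TRUE, "marker_matrix")))
  if (length(matrices) == 1L) return(matrices[[1]])
  ref <- specimen_ids(matrices[[1]])
  for (k in seq_along(matrices)[-1]) {
    ids <- specimen_ids(matrices[[k]])
    if (!setequal(ids, ref)) {
      stop_hb("specimen sets differ: only in input 1: {%s}; only in input %d: {%s}",
              paste(setdiff(ref, ids), collapse = ", "), k,
              paste(setdiff(ids, ref), collapse = ", "), class = "merge_error")
    }
  }
  all_loci <- unlist(lapply(matrices, locus_ids))
  dup <- unique(all_loci[duplicated(all_loci)])
  pieces <- lapply(seq_along(matrices), function(k) {
    m <- matrices[[k]]
    v <- m$values[ref, , drop = FALSE]
    lid <- locus_ids(m)
    clash <- lid %in% dup
    if (any(clash)) {
      src <- if (!is.null(m$locus_source)) m$locus_source else
        rep(paste0("m", k), ncol(v))
      lid[clash] <- paste0(src[clash], ":", lid[clash])
    }
    colnames(v) <- lid
    list(values = v,
         source = if (!is.null(m$locus_source)) unname(m$locus_source) else
           rep(NA_character_, ncol(v)),
         size = if (!is.null(m$locus_size_bp)) unname(m$locus_size_bp) else
           rep(NA_integer_, ncol(v)))
  })
  vals <- do.call(cbind, lapply(pieces, `[[`, "values"))
  src <- unlist(lapply(pieces, `[[`, "source"))
  size <- unlist(lapply(pieces, `[[`, "size"))
  marker_matrix(vals, ref, colnames(vals),
                locus_source = if (all(is.na(src))) NULL else src,
                locus_size_bp = if (all(is.na(size))) NULL else size)
}

#' Subset a marker matrix by specimens and/or loci
#'
#' @param matrix a [marker_matrix()].
#' @param specimens,loci character vectors of ids to keep (default all).
#' @return a [marker_matrix()].
#' @export
subset_matrix <- function(matrix, specimens = specimen_ids(matrix),
                          loci = locus_ids(matrix)) {
  stopifnot(inherits(matrix, "marker_matrix"))
  missing_s <- setdiff(specimens, specimen_ids(matrix))
  if (length(missing_s))
    stop_hb("unknown specimens: %s", paste(missing_s, collapse = ", "),
            class = "format_error")
  missing_l <- setdiff(loci, locus_ids(matrix))
  if (length(missing_l))
    stop_hb("unknown loci: %s", paste(missing_l, collapse = ", "),
            class = "format_error")
  marker_matrix(matrix$values[specimens, loci, drop = FALSE],
                specimens, loci,
                locus_source = matrix$locus_source[loci],
                locus_size_bp = matrix$locus_size_bp[loci])
}
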