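#' Assemble a feature table from features and a sample manifest
#'
#' The central container for post-peak-picking LC-HRMS data: one row per
#' feature (`feature_id`, `mz` in Th, `rt` in seconds, `ion_mode`) with one
#' intensity column per sample, plus a manifest mapping each sample to its
#' group (genotype, blank, labeled, control, ...). Tables hold a single ion
#' mode; negative- and positive-mode data are kept separate because each is
#' normalized to a different internal reference.
#'
#' @param features Tibble/data frame with columns `feature_id`, `mz`, `rt`,
#'   `ion_mode`, followed by one numeric column per sample.
#' @param manifest Tibble/data frame with columns `sample_id`, `group`, and
#'   optionally `experiment`.
#' @param normalized Logical; whether intensities have been reference-normalized.
#' @param provenance Character vector of processing notes, grown by each stage.
#' @return A `feature_table` object.
#' @export
feature_table <- function(features, manifest, normalized = FALSE, provenance = character()) {
  features <- tibble::as_tibble(features)
  manifest <- tibble::as_tibble(manifest)
  if (!"experiment" %in% names(manifest)) manifest$experiment <- 1L
  x <- structure(
    list(
      features = features,
      manifest = manifest,
      normalized = isTRUE(normalized),
      provenance = provenance,
      excluded = character()
    ),
    class = "feature_table"
  )
  validate_feature_table(x)
}

#' @export
print.feature_table <- function(x, ...) {
  cat(
    "<feature_table> ", nrow(x$features), " features x ", length(sample_ids(x)),
    " samples (", paste(unique(x$manifest$group), collapse = ", "), "); ",
    if (x$normalized) "normalized" else "raw", " intensities\n",
    sep = ""
  )
  if (length(x$provenance)) cat(paste0("  - ", x$provenance, "\n"), sep = "")
  invisible(x)
}

#' Validate feature-table invariants
#'
#' Checks the structural invariants: required columns present, unique feature
#' ids, positive m/z, non-negative retention times and intensities, a single
#' ion mode, and a manifest entry for every sample column.
#'
#' @param x A `feature_table`.
#' @return `x`, invisibly usable; errors describe the first violation found.
#' @export
validate_feature_table <- function(x) {
  stopifnot(inherits(x, "feature_table"))
  meta <- c("feature_id", "mz", "rt", "ion_mode")
  missing_cols <- setdiff(meta, names(x$features))
  if (length(missing_cols)) {
    stop("feature table is missing column(s): ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!all(c("sample_id", "group") %in% names(x$manifest))) {
    stop("manifest must have columns sample_id and group", call. = FALSE)
  }
  if (anyDuplicated(x$features$feature_id)) {
    stop("feature_id values must be unique", call. = FALSE)
  }
  samples <- setdiff(names(x$features), meta)
  if (length(samples) == 0L) stop("feature table has no sample columns", call. = FALSE)
  unmapped <- setdiff(samples, x$manifest$sample_id)
  if (length(unmapped)) {
    stop("sample column(s) absent from manifest: ", paste(unmapped, collapse = ", "), call. = FALSE)
  }
  if (nrow(x$features) > 0L) {
    if (any(!is.finite(x$features$mz)) || any(x$features$mz <= 0)) {
      stop("all mz must be finite and positive", call. = FALSE)
    }
    if (any(!is.finite(x$features$rt)) || any(x$features$rt < 0)) {
      stop("all rt must be finite and non-negative (seconds)", call. = FALSE)
    }
    if (length(unique(x$features$ion_mode)) > 1L) {
      stop("a feature table must hold a single ion mode", call. = FALSE)
    }
    if (!all(x$features$ion_mode %in% c("neg", "pos"))) {
      stop("ion_mode must be 'neg' or 'pos'", call. = FALSE)
    }
    ints <- as.matrix(x$features[samples])
    if (any(!is.finite(ints))) stop("missing or non-finite intensity values", call. = FALSE)
    if (any(ints < 0)) stop("negative intensity values", call. = FALSE)
  }
  if (any(!nzchar(x$manifest$group))) stop("manifest group labels must be non-empty", call. = FALSE)
  x
}

#' Sample ids of a feature table
#' @param x A `feature_table`.
#' @return Character vector of sample column names, in table order.
#' @export
sample_ids <- function(x) {
  setdiff(names(x$features), c("feature_id", "mz", "rt", "ion_mode"))
}

#' Sample ids belonging to a manifest group
#' @param x A `feature_table`.
#' @param group Group label to look up.
#' @return Character vector of sample ids.
#' @export
samples_in_group <- function(x, group) {
  ids <- x$manifest$sample_id[x$manifest$group == group]
  ids <- intersect(sample_ids(x), ids)
  if (length(ids) == 0L) {
    stop("no samples in group '", group, "'", call. = FALSE)
  }
  ids
}

#' Intensity matrix of a feature table
#' @param x A `feature_table`.
#' @param samples Optional subset of sample ids.
#' @return Numeric matrix, features x samples, rownames = feature ids.
#' @export
intensity_matrix <- function(x, samples = NULL) {
  if (is.null(samples)) samples <- sample_ids(x)
  m <- as.matrix(x$features[samples])
  rownames(m) <- x$features$feature_id
  m
}

note_provenance <- function(x, msg) {
  x$provenance <- c(x$provenance, msg)
  x
}

sniff_delim <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header, fixed = TRUE)) "\t" else ","
}

#' Read a feature table and its sample manifest from delimited text
#'
#' Reads CSV or TSV (delimiter sniffed from the header line). The feature
#' file must have columns `feature_id, mz, rt, ion_mode, <sample...>`; the
#' manifest must map every sample column to a group. Retention times are
#' stored in seconds; pass `rt_unit = "min"` to convert minute-scale tables
#' on ingest. Zero intensities are kept as true zeros; missing cells are an
#' error (peak-filled tables are dense).
#'
#' @param path Feature-table file.
#' @param manifest_path Manifest file with columns `sample_id, group[, experiment]`.
#' @param rt_unit `"s"` (default) or `"min"`.
#' @return A validated [feature_table()].
#' @export
read_feature_table <- function(path, manifest_path, rt_unit = c("s", "min")) {
  rt_unit <- match.arg(rt_unit)
  for (p in c(path, manifest_path)) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  }
  features <- readr::read_delim(
    path,
    delim = sniff_delim(path), show_col_types = FALSE, progress = FALSE
  )
  manifest <- readr::read_delim(
    manifest_path,
    delim = sniff_delim(manifest_path), show_col_types = FALSE, progress = FALSE
  )
  if (anyNA(features)) {
    bad <- which(rowSums(is.na(features)) > 0)
    stop(
      "missing values in feature table at data row(s): ",
      paste(utils::head(bad, 5), collapse = ", "),
      " (dense, peak-filled tables expected)",
      call. = FALSE
    )
  }
  if (rt_unit == "min" && "rt" %in% names(features)) features$rt <- features$rt * 60
  x <- feature_table(features, manifest)
  note_provenance(x, paste0("read ", basename(path), " (", nrow(features), " features)"))
}

#' Write a feature table (and optionally its manifest) to delimited text
#'
#' Inverse of [read_feature_table()]; numeric fields round-trip losslessly at
#' full double precision.
#'
#' @param x A `feature_table`.
#' @param path Output file for the feature rows (`.tsv` extension writes TSV,
#'   anything else CSV).
#' @param manifest_path Optional output file for the manifest.
#' @return `x`, invisibly.
#' @export
write_feature_table <- function(x, path, manifest_path = NULL) {
  validate_feature_table(x)
  writer <- if (grepl("\\.tsv$", path)) readr::write_tsv else readr::write_csv
  writer(x$features, path)
  if (!is.null(manifest_path)) {
    mwriter <- if (grepl("\\.tsv$", manifest_path)) readr::write_tsv else readr::write_csv
    mwriter(x$manifest, manifest_path)
  }
  invisible(x)
}

#' EIC-style lookup: features within a ppm window (and RT range)
#'
#' Returns the features whose m/z falls inside [ppm_window()]`(mz, tol_ppm)`,
#' optionally restricted to an RT interval, sorted by absolute ppm error.
#' Equivalent to a linear scan over the table; row order does not affect the
#' result.
#'
#' @param x A `feature_table`.
#' @param mz Target m/z (Th).
#' @param tol_ppm Tolerance in ppm (quantification windows default to 3).
#' @param rt_range Optional closed interval `c(lo, hi)` in seconds.
#' @return Tibble of matching feature rows with a `ppm_error` column; zero
#'   rows is a valid result.
#' @export
query_mz <- function(x, mz, tol_ppm = 3, rt_range = NULL) {
  validate_feature_table(x)
  win <- ppm_window(mz, tol_ppm)
  hit <- x$features$mz >= win[1] & x$features$mz <= win[2]
  if (!is.null(rt_range)) {
    stopifnot(length(rt_range) == 2L)
    hit <- hit & x$features$rt >= rt_range[1] & x$features$rt <= rt_range[2]
  }
  out <- x$features[hit, , drop = FALSE]
  out$ppm_error <- ppm_error(out$mz, mz)
  out[order(abs(out$ppm_error)), , drop = FALSE]
}

#' Drop all samples of a manifest group
#'
#' Removes the group's intensity columns and manifest rows (e.g. discarding
#' blank injections once blank subtraction has used them).
#'
#' @param x A `feature_table`.
#' @param group Group label to drop.
#' @return The reduced `feature_table`.
#' @export
drop_group <- function(x, group) {
  ids <- x$manifest$sample_id[x$manifest$group == group]
  x$features <- x$features[setdiff(names(x$features), ids)]
  x$manifest <- x$manifest[x$manifest$group != group, , drop = FALSE]
  validate_feature_table(x)
}

#' Subset a feature table by a logical or id vector
#' @param x A `feature_table`.
#' @param keep Logical vector over rows, or character vector of feature ids.
#' @param note Provenance note describing the subset.
#' @return The filtered `feature_table`.
#' @export
filter_features <- function(x, keep, note = NULL) {
  if (is.character(keep)) keep <- x$features$feature_id %in% keep
  stopifnot(is.logical(keep), length(keep) == nrow(x$features))
  x$features <- x$features[keep, , drop = FALSE]
  if (!is.null(note)) x <- note_provenance(x, note)
  x
}
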