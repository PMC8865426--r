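#' Delimited-text input/output
#'
#' On disk, feature matrices follow the dominant omics convention: tab
#' delimited, features in rows, samples in columns, first column = feature
#' id, header = sample ids, empty field or "NA" = missing. In memory the
#' package works with the transpose (samples x features). Numbers are
#' written with 12 significant digits so a write/read round trip is
#' value-identical at that precision.
#'
#' @name io
NULL

#' Read a feature matrix from delimited text
#'
#' @param path File path (tab-delimited, features x samples).
#' @return Numeric matrix, samples x features.
#' @export
read_feature_matrix <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L) stop(sprintf("%s: expected a header and at least one feature row", path), call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  sample_ids <- header[-1L]
  if (anyDuplicated(sample_ids)) {
    stop(sprintf("%s: duplicate sample ids in header", path), call. = FALSE)
  }
  want <- length(header)
  n_feat <- length(lines) - 1L
  vals <- matrix(NA_real_, nrow = n_feat, ncol = length(sample_ids))
  feature_ids <- character(n_feat)
  for (i in seq_len(n_feat)) {
    f <- fields[[i + 1L]]
    if (length(f) != want) {
      stop(sprintf("%s: line %d has %d fields, expected %d", path, i + 1L,
                   length(f), want), call. = FALSE)
    }
    feature_ids[i] <- f[1L]
    v <- f[-1L]
    v[v == "" | v == "NA"] <- NA
    num <- suppressWarnings(as.numeric(v))
    if (any(is.na(num) & !is.na(v))) {
      stop(sprintf("%s: line %d contains a non-numeric value", path, i + 1L),
           call. = FALSE)
    }
    vals[i, ] <- num
  }
  if (anyDuplicated(feature_ids)) {
    stop(sprintf("%s: duplicate feature ids", path), call. = FALSE)
  }
  dimnames(vals) <- list(feature_ids, sample_ids)
  t(vals)
}

#' Write a feature matrix to delimited text
#'
#' @param m Numeric matrix, samples x features.
#' @param path Output path.
#' @export
write_feature_matrix <- function(m, path) {
  check_feature_matrix(m)
  if (is.null(rownames(m))) rownames(m) <- sprintf("S%d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("F%d", seq_len(ncol(m)))
  tm <- t(m)
  txt <- format(tm, digits = 12, trim = TRUE, scientific = NA)
  txt[is.na(tm)] <- "NA"
  lines <- c(paste(c("feature", colnames(tm)), collapse = "\t"),
             vapply(seq_len(nrow(tm)), function(i) {
               paste(c(rownames(tm)[i], txt[i, ]), collapse = "\t")
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a two-column label file (sample_id, cluster)
#'
#' @param path File path.
#' @return Labels named by sample id.
#' @export
read_labels <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop(sprintf("%s: expected two columns (sample_id, cluster)", path), call. = FALSE)
  stats::setNames(df[[2L]], as.character(df[[1L]]))
}

#' Write a two-column label file
#'
#' @param labels Labels named by sample id.
#' @param path Output path.
#' @export
write_labels <- function(labels, path) {
  ids <- names(labels)
  if (is.null(ids)) ids <- sprintf("S%d", seq_along(labels))
  writeLines(c("sample_id\tcluster",
               paste(ids, labels, sep = "\t")), path)
  invisible(path)
}

#' Write a run manifest
#'
#' Records the full configuration, input digests, package version, and a
#' timestamp so an output directory can be reproduced bit-for-bit from its
#' inputs.
#'
#' @param path Output JSON path.
#' @param config Named list of hyperparameters.
#' @param inputs Character vector of input file paths (md5-digested).
#' @export
write_manifest <- function(path, config, inputs = character(0)) {
  digests <- if (length(inputs)) {
    as.list(tools::md5sum(inputs))
  } else {
    list()
  }
  manifest <- list(
    tool = "snmtf",
    version = as.character(utils::packageVersion("snmtf")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config,
    input_md5 = digests
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
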