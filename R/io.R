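# Serialization of pattern datasets: UTF-8 TSV (one record per row) and JSON
# (pattern -> method -> array of terms). Both round-trip exactly.

#' Read a pattern dataset from disk
#'
#' The TSV format has a header `pattern<TAB>method<TAB>manifestation` and one
#' term per row; the JSON format maps pattern names to objects mapping method
#' codes to arrays of terms. Validators run on read; consistency violations
#' are reported as warnings (validation reports, it does not throw).
#'
#' @param path File path.
#' @param format `"tsv"` or `"json"`; by default inferred from the file
#'   extension.
#' @return A `pattern_dataset`.
#' @seealso [write_pattern_dataset()]
#' @export
read_pattern_dataset <- function(path, format = c("auto", "tsv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv"
  }
  if (format == "json") {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (anyDuplicated(names(obj))) {
      stop("duplicate pattern names in ", path, call. = FALSE)
    }
    obj <- lapply(obj, function(sets) lapply(sets, as.character))
    d <- pattern_dataset(obj)
  } else {
    raw <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                             colClasses = "character", fileEncoding = "UTF-8")
    need <- c("pattern", "method", "manifestation")
    if (!all(need %in% names(raw))) {
      stop("malformed dataset file ", path, ": expected header ",
           paste(need, collapse = "\t"), call. = FALSE)
    }
    bad <- !raw$method %in% exam_methods()
    if (any(bad)) {
      stop("unknown method code(s) in ", path, " at data row(s) ",
           paste(utils::head(which(bad), 5L), collapse = ", "),
           call. = FALSE)
    }
    d <- pattern_dataset(raw)
  }
  v <- validate_dataset(d)
  if (!v$valid) {
    warning("dataset has ", nrow(v$intra), " intra-pattern and ",
            nrow(v$inter), " inter-pattern consistency violation(s)")
  }
  d
}

#' Write a pattern dataset to disk
#'
#' @param d A `pattern_dataset`.
#' @param path File path.
#' @param format `"tsv"` or `"json"`; by default inferred from the file
#'   extension.
#' @return `path`, invisibly.
#' @export
write_pattern_dataset <- function(d, path, format = c("auto", "tsv", "json")) {
  stopifnot(inherits(d, "pattern_dataset"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv"
  }
  if (format == "json") {
    obj <- lapply(d$patterns, function(sets) {
      sets[vapply(sets, length, integer(1L)) >= 0L]
    })
    jsonlite::write_json(obj, path, pretty = TRUE, auto_unbox = FALSE)
  } else {
    long <- as.data.frame(d)
    con <- file(path, open = "w", encoding = "UTF-8")
    on.exit(close(con))
    utils::write.table(long, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  }
  invisible(path)
}
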