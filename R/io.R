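#' Read a labeled time-series dataset from delimited text
#'
#' One series per row: the first field is the binary 0/1 label, the
#' remaining fields the series values. The delimiter (comma or tab) is
#' auto-detected from the first non-empty line. Rows may have different
#' lengths; blank or NaN trailing fields are dropped. Parse failures
#' report the offending line number.
#'
#' @param path path to the file.
#' @return A [series_dataset()].
#' @export
read_series_dataset <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("no data rows in ", path)
  sep <- if (grepl("\t", lines[[1L]])) "\t" else ","
  values <- vector("list", length(lines))
  labels <- integer(length(lines))
  for (i in seq_along(lines)) {
    fields <- trimws(strsplit(lines[[i]], sep, fixed = TRUE)[[1L]])
    while (length(fields) > 0L &&
           (fields[length(fields)] == "" ||
              toupper(fields[length(fields)]) %in% c("NA", "NAN")))
      fields <- fields[-length(fields)]
    if (length(fields) < 2L)
      stop("line ", i, ": need a label and at least one value")
    lab <- suppressWarnings(as.numeric(fields[[1L]]))
    if (is.na(lab) || !lab %in% c(0, 1))
      stop("line ", i, ": label must be 0 or 1, got '", fields[[1L]], "'")
    vals <- suppressWarnings(as.numeric(fields[-1L]))
    if (anyNA(vals))
      stop("line ", i, ": non-numeric value '",
           fields[-1L][which(is.na(vals))[1L]], "'")
    values[[i]] <- vals
    labels[i] <- as.integer(lab)
  }
  series_dataset(values, labels)
}

#' Write a labeled dataset as delimited text
#'
#' Inverse of [read_series_dataset()]: label-first rows, one series per
#' line.
#'
#' @param dataset a [series_dataset()].
#' @param path output path.
#' @param sep field separator, `","` (default) or `"\t"`.
#' @return `path`, invisibly.
#' @export
write_series_dataset <- function(dataset, path, sep = ",") {
  stopifnot(inherits(dataset, "series_dataset"))
  lines <- vapply(seq_len(dataset$n), function(i)
    paste(c(dataset$labels[i],
            format(dataset$values[[i]], digits = 17, trim = TRUE,
                   scientific = FALSE)),
          collapse = sep),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Serialize a mining result to structured text
#'
#' Writes the result as JSON: the echoed run configuration, the final
#' corrected threshold, rejection counts, and per-shapelet values,
#' optimal threshold, minimum p-value and source coordinates. Round-trips
#' through [read_mining_result()].
#'
#' @param result a `mining_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mining_result <- function(result, path) {
  stopifnot(inherits(result, "mining_result"))
  sig <- result$significant
  payload <- list(
    method = result$method,
    alpha = result$alpha,
    delta = result$delta,
    seed = result$seed,
    candidate_count = result$candidate_count,
    n = result$n,
    counts = result$counts,
    config = result$config,
    shapelets = lapply(seq_len(nrow(sig)), function(i) list(
      source_id = sig$source_id[i], series = sig$series[i],
      start = sig$start[i], length = sig$length[i],
      theta = sig$theta[i], p_min = sig$p_min[i],
      values = sig$values[[i]]
    ))
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read back a serialized mining result
#'
#' @param path path written by [write_mining_result()].
#' @return A `mining_result` (config entries restored as a plain list).
#' @export
read_mining_result <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  sh <- x$shapelets
  sig <- data.frame(
    source_id = vapply(sh, function(s) as.character(s$source_id), character(1)),
    series = vapply(sh, function(s) as.integer(s$series), integer(1)),
    start = vapply(sh, function(s) as.integer(s$start), integer(1)),
    length = vapply(sh, function(s) as.integer(s$length), integer(1)),
    theta = vapply(sh, function(s) as.numeric(s$theta), numeric(1)),
    p_min = vapply(sh, function(s) as.numeric(s$p_min), numeric(1)),
    stringsAsFactors = FALSE
  )
  sig$values <- lapply(sh, function(s) as.numeric(unlist(s$values)))
  structure(list(
    method = x$method, significant = sig, delta = as.numeric(x$delta),
    alpha = as.numeric(x$alpha), seed = as.integer(x$seed),
    candidate_count = as.integer(x$candidate_count), n = as.integer(x$n),
    counts = lapply(x$counts, function(v) if (is.numeric(v)) as.integer(v) else v),
    config = x$config
  ), class = "mining_result")
}

#' Write or read a simulation annotation sidecar
#'
#' The annotation records, for every case series, which prototype was
#' injected and at which offset; tab-separated text.
#'
#' @param annotation the annotation data.frame of
#'   [generate_labeled_dataset()].
#' @param path file path.
#' @return `path` (write) or the annotation data.frame (read).
#' @export
write_annotation <- function(annotation, path) {
  utils::write.table(annotation, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_annotation
#' @export
read_annotation <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}
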