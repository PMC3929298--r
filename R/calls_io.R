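#' Write de novo calls to a BED-like file
#'
#' Tab-separated with a documented header line. Genomic coordinates are
#' written BED-style 0-based half-open (`start = start_bp - 1`); marker
#' indices are carried alongside so a call file can be validated against a
#' panel on re-import. [read_calls()] is a bit-exact inverse.
#'
#' @param calls A `denovo_calls` data.frame.
#' @param path Output file path.
#' @export
write_calls <- function(calls, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#chrom\tstart\tend\ttrio_id\tstate\tn_markers\t",
                    "offspring_median_lrr\tstart_marker\tend_marker"), con)
  if (nrow(calls)) {
    out <- data.frame(chrom = calls$chromosome,
                      start = calls$start_bp - 1L, end = calls$end_bp,
                      trio_id = calls$trio_id, state = calls$state,
                      n_markers = calls$n_markers,
                      offspring_median_lrr = sprintf("%.6g", calls$offspring_median_lrr),
                      start_marker = calls$start_marker,
                      end_marker = calls$end_marker)
    utils::write.table(out, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read de novo calls from a BED-like file
#'
#' Parses the dialect written by [write_calls()] (also the adapter for call
#' sets produced by external trio callers). Each line must have 9
#' tab-separated fields; states are restricted to `331`/`332`; `end` must
#' exceed `start`. When a panel is supplied, marker indices are validated
#' against it.
#'
#' @param path Input file path.
#' @param panel Optional `marker_panel` for validation.
#' @return A `denovo_calls` data.frame (median-LRR columns other than the
#'   offspring's, and the BAF summary, are `NA` for imported calls).
#' @export
read_calls <- function(path, panel = NULL) {
  lines <- readLines(path)
  body <- which(!startsWith(lines, "#") & nzchar(lines))
  rows <- lapply(body, function(ln) {
    fields <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(fields) != 9L)
      stop(sprintf("parse error at line %d: expected 9 tab-separated fields, got %d",
                   ln, length(fields)))
    start <- suppressWarnings(as.integer(fields[2]))
    end <- suppressWarnings(as.integer(fields[3]))
    if (is.na(start) || is.na(end))
      stop(sprintf("parse error at line %d: non-integer coordinates", ln))
    if (end <= start)
      stop(sprintf("validation error at line %d: end <= start", ln))
    if (!fields[5] %in% c("331", "332"))
      stop(sprintf("validation error at line %d: unknown state code '%s'",
                   ln, fields[5]))
    data.frame(trio_id = fields[4], chromosome = fields[1],
               start_bp = start + 1L, end_bp = end,
               start_marker = as.integer(fields[8]),
               end_marker = as.integer(fields[9]),
               state = fields[5], n_markers = as.integer(fields[6]),
               offspring_median_lrr = as.numeric(fields[7]),
               father_median_lrr = NA_real_, mother_median_lrr = NA_real_,
               het_fraction = NA_real_, stringsAsFactors = FALSE)
  })
  calls <- if (length(rows)) do.call(rbind, rows) else .empty_calls()
  rownames(calls) <- NULL
  if (!is.null(panel)) {
    bad <- calls$start_marker < 0L | calls$end_marker > nrow(panel) |
      calls$end_marker <= calls$start_marker
    if (any(bad)) stop("validation error: call marker span outside panel")
  }
  class(calls) <- c("denovo_calls", "data.frame")
  calls
}
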