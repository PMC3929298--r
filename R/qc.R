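#' Median absolute deviation of a log R ratio vector
#'
#' Computes the raw (unscaled) MAD, `median(|x - median(x)|)`, over finite
#' entries. This is the per-sample intensity-noise statistic used for trio
#' exclusion; no 1.4826 Gaussian consistency factor is applied.
#'
#' @param lrr Numeric vector of log R ratios; non-finite values are ignored.
#' @return The unscaled MAD.
#' @export
lrr_mad <- function(lrr) {
  x <- lrr[is.finite(lrr)]
  if (!length(x)) stop("data error: no finite LRR values")
  stats::median(abs(x - stats::median(x)))
}

#' Trio-level intensity quality control
#'
#' Excludes a trio when any member has an LRR MAD above the threshold, was
#' whole-genome amplified, or carries an external QC flag. Exclusion is
#' trio-wise: all three members are removed together.
#'
#' @param trios List of `trio_intensities` objects (or a `trio_cohort`).
#' @param mad_threshold Exclusion threshold on the unscaled LRR MAD; a trio is
#'   excluded only when a member's MAD is strictly greater (boundary values
#'   are kept). Default 0.3.
#' @return A list with `kept` (the retained trios) and `report`, a data.frame
#'   of class `qc_report` with one row per trio: per-member MADs, flags,
#'   `excluded` and `reason` (`mad`, `wga`, `external` or `none`; the first
#'   matching rule in that order).
#' @export
qc_filter <- function(trios, mad_threshold = 0.3) {
  if (inherits(trios, "trio_cohort")) trios <- trios$trios
  rows <- lapply(trios, function(trio) {
    mads <- vapply(.member_names, function(m) lrr_mad(trio[[m]]$lrr), 0)
    wga <- any(vapply(.member_names, function(m) isTRUE(trio[[m]]$wga_flag), NA))
    ext <- any(vapply(.member_names, function(m) isTRUE(trio[[m]]$external_qc_flag), NA))
    reason <- if (any(mads > mad_threshold)) "mad"
              else if (wga) "wga"
              else if (ext) "external"
              else "none"
    data.frame(trio_id = trio$trio_id,
               father_mad = mads[["father"]], mother_mad = mads[["mother"]],
               offspring_mad = mads[["offspring"]],
               wga_flag = wga, external_qc_flag = ext,
               excluded = reason != "none", reason = reason,
               stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  class(report) <- c("qc_report", "data.frame")
  list(kept = trios[!report$excluded], report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("Trio QC report: %d trios, %d excluded (%d mad, %d wga, %d external)\n",
              nrow(x), sum(x$excluded), sum(x$reason == "mad"),
              sum(x$reason == "wga"), sum(x$reason == "external")))
  print.data.frame(x, ...)
  invisible(x)
}

#' Write a QC report as a tab-separated table
#'
#' @param report A `qc_report`.
#' @param path Output file path.
#' @export
write_qc_report <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# trio QC report; MAD is the unscaled median absolute deviation of LRR", con)
  utils::write.table(report, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
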