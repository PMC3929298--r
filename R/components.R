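#' Delineate de novo calls into homogeneous CNV components
#'
#' Cuts the union of all trios' call spans at every call boundary and merges
#' adjacent runs whose carrier set and state composition are identical,
#' yielding maximal runs of consecutive markers over which no trio's deletion
#' membership changes. These components are the units of association testing;
#' markers covered by no call are not emitted. Hemizygous and homozygous
#' calls both count as de novo deletions for carrier membership; the state
#' mix is kept as an annotation.
#'
#' @param calls A `denovo_calls` data.frame (marker indices are global
#'   0-based half-open panel coordinates).
#' @param panel The `marker_panel` the calls refer to.
#' @param labels Named character vector mapping every trio id to `case` or
#'   `control`.
#' @return A data.frame of class `cnv_components`: `chromosome`,
#'   `start_marker`, `end_marker`, `start_bp`, `end_bp`, `n_markers`,
#'   `n_case_carriers`, `n_control_carriers`, `states`, plus list columns
#'   `carriers_case` and `carriers_control`. Components on a chromosome are
#'   disjoint and ordered.
#' @export
delineate_components <- function(calls, panel, labels) {
  if (!all(calls$trio_id %in% names(labels)))
    stop("validation error: call references a trio missing from labels")
  if (!nrow(calls)) return(.empty_components())
  ir <- IRanges::IRanges(start = calls$start_marker + 1L, end = calls$end_marker)
  disj <- IRanges::disjoin(ir)
  hits <- IRanges::findOverlaps(disj, ir)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  rows <- lapply(seq_along(disj), function(k) {
    covering <- sh[qh == k]
    ids <- calls$trio_id[covering]
    ord <- order(ids)
    data.frame(start_marker = IRanges::start(disj)[k] - 1L,
               end_marker = IRanges::end(disj)[k],
               key = paste(ids[ord], calls$state[covering][ord],
                           sep = ":", collapse = ","),
               stringsAsFactors = FALSE)
  })
  runs <- do.call(rbind, rows)
  runs <- runs[order(runs$start_marker), , drop = FALSE]
  # merge marker-contiguous runs with identical carrier/state composition
  keep <- logical(nrow(runs))
  keep[1] <- TRUE
  for (k in seq_len(nrow(runs))[-1]) {
    prev <- max(which(keep))
    if (runs$start_marker[k] == runs$end_marker[prev] &&
        runs$key[k] == runs$key[prev] &&
        panel$chromosome[runs$start_marker[k] + 1L] ==
          panel$chromosome[runs$start_marker[prev] + 1L]) {
      runs$end_marker[prev] <- runs$end_marker[k]
    } else keep[k] <- TRUE
  }
  runs <- runs[keep, , drop = FALSE]
  comp <- lapply(seq_len(nrow(runs)), function(k) {
    parts <- strsplit(strsplit(runs$key[k], ",", fixed = TRUE)[[1]], ":", fixed = TRUE)
    ids <- vapply(parts, `[[`, "", 1L)
    states <- vapply(parts, `[[`, "", 2L)
    grp <- labels[ids]
    lo <- runs$start_marker[k]; hi <- runs$end_marker[k]
    data.frame(chromosome = panel$chromosome[lo + 1L],
               start_marker = lo, end_marker = hi,
               start_bp = panel$position[lo + 1L], end_bp = panel$position[hi],
               n_markers = hi - lo,
               n_case_carriers = sum(grp == "case"),
               n_control_carriers = sum(grp == "control"),
               states = paste(sort(unique(states)), collapse = ","),
               carriers_case = I(list(sort(ids[grp == "case"]))),
               carriers_control = I(list(sort(ids[grp == "control"]))),
               stringsAsFactors = FALSE)
  })
  comp <- do.call(rbind, comp)
  rownames(comp) <- NULL
  class(comp) <- c("cnv_components", "data.frame")
  comp
}

.empty_components <- function() {
  comp <- data.frame(chromosome = character(), start_marker = integer(),
                     end_marker = integer(), start_bp = integer(),
                     end_bp = integer(), n_markers = integer(),
                     n_case_carriers = integer(), n_control_carriers = integer(),
                     states = character(), stringsAsFactors = FALSE)
  comp$carriers_case <- I(list())
  comp$carriers_control <- I(list())
  class(comp) <- c("cnv_components", "data.frame")
  comp
}

#' @export
print.cnv_components <- function(x, ...) {
  cat(sprintf("CNV components: %d on %d chromosome(s); carriers per component %s\n",
              nrow(x), length(unique(x$chromosome)),
              if (nrow(x)) paste0("1-", max(x$n_case_carriers + x$n_control_carriers))
              else "0"))
  if (nrow(x)) {
    show <- x[, c("chromosome", "start_marker", "end_marker", "n_markers",
                  "n_case_carriers", "n_control_carriers", "states")]
    print.data.frame(show, ...)
  }
  invisible(x)
}

#' Write a component table
#'
#' @param components A `cnv_components` data.frame.
#' @param path Output file path.
#' @export
write_components <- function(components, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# CNV components: maximal marker runs with constant deletion membership; markers 0-based half-open", con)
  out <- components[, c("chromosome", "start_marker", "end_marker", "start_bp",
                        "end_bp", "n_markers", "n_case_carriers",
                        "n_control_carriers", "states")]
  out$carriers_case <- vapply(components$carriers_case, paste, "", collapse = ",")
  out$carriers_control <- vapply(components$carriers_control, paste, "", collapse = ",")
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
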