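#' Per-child de novo deletion rate summary
#'
#' For each group (`control`, `cleft`, and the cleft-type strata `CL`, `CP`,
#' `CLP`) reports the total number of calls, the number of children, the
#' average number of calls per child (rounded half-up to 2 decimals for the
#' report) and a per-child call-count histogram with a `5+` overflow bin.
#'
#' @param calls A `denovo_calls` data.frame.
#' @param labels Named character vector trio id -> `case`/`control`; its
#'   names define the denominator of children per group.
#' @param cleft_types Named character vector trio id -> `CL`/`CP`/`CLP`/`none`.
#' @return A data.frame of class `rate_summary` with columns `group`,
#'   `total_calls`, `n_children`, `average_per_child` and histogram columns
#'   `calls_0` .. `calls_4`, `calls_5plus`.
#' @export
summarize_rates <- function(calls, labels, cleft_types) {
  ids <- names(labels)
  per_child <- table(factor(calls$trio_id, levels = ids))
  groups <- list(control = ids[labels == "control"],
                 cleft = ids[labels == "case"],
                 CL = ids[cleft_types[ids] == "CL"],
                 CP = ids[cleft_types[ids] == "CP"],
                 CLP = ids[cleft_types[ids] == "CLP"])
  rows <- lapply(names(groups), function(g) {
    members <- groups[[g]]
    counts <- as.integer(per_child[members])
    total <- sum(counts)
    n <- length(members)
    hist <- vapply(0:4, function(k) sum(counts == k), 0L)
    data.frame(group = g, total_calls = total, n_children = n,
               average_per_child = if (n) round_half_up(total / n, 2) else NA_real_,
               calls_0 = hist[1], calls_1 = hist[2], calls_2 = hist[3],
               calls_3 = hist[4], calls_4 = hist[5],
               calls_5plus = sum(counts >= 5L),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("rate_summary", "data.frame")
  out
}

#' DNA-source summary by group
#'
#' Counts DNA sources over all subjects (both parents and the child of every
#' trio) per proband group and reports per-group proportions rounded half-up
#' to 3 decimals.
#'
#' @param trios List of `trio_intensities` (or a `trio_cohort`).
#' @return A data.frame of class `source_summary`: `group`, `source`,
#'   `count`, `proportion`.
#' @export
summarize_sources <- function(trios) {
  if (inherits(trios, "trio_cohort")) trios <- trios$trios
  known <- c("blood", "buccal", "mouthwash", "saliva")
  rows <- lapply(trios, function(trio) {
    src <- vapply(.member_names, function(m) trio[[m]]$dna_source, "")
    if (!all(src %in% known))
      stop("validation error: unknown DNA source label")
    data.frame(group = if (trio$label == "case") "cleft" else "control",
               source = src, stringsAsFactors = FALSE)
  })
  subj <- do.call(rbind, rows)
  out <- do.call(rbind, lapply(c("control", "cleft"), function(g) {
    sub <- subj[subj$group == g, , drop = FALSE]
    counts <- vapply(known, function(s) sum(sub$source == s), 0L)
    data.frame(group = g, source = known, count = counts,
               proportion = if (nrow(sub)) round_half_up(counts / nrow(sub), 3)
                            else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("source_summary", "data.frame")
  out
}

#' Run the whole pipeline end to end
#'
#' Simulates (or loads) a cohort, applies trio QC, calls de novo deletions,
#' delineates CNV components, runs the filtered one-sided Fisher tests with
#' permutation family-wise error control, compares deletion widths, and
#' writes every stage's table plus a log to the run directory. Re-running
#' with the same configuration reproduces all stochastic outputs.
#'
#' @param config A [sim_config()] for simulation, or a `trio_cohort` already
#'   in memory.
#' @param out_dir Run directory (created).
#' @param settings Caller settings ([md_settings()]).
#' @param n_perm Permutations for the association stage.
#' @param n_sim_qq Null resplits for the width QQ envelope.
#' @param min_total Minimum combined carrier count per tested component.
#' @param seed Integer seed driving every stochastic stage.
#' @return Invisibly, a list with the in-memory stage results (`cohort`,
#'   `qc`, `calls`, `components`, `tested`, `assoc`, `widths`, `rates`,
#'   `sources`).
#' @export
run_pipeline <- function(config, out_dir, settings = md_settings(),
                         n_perm = 10000L, n_sim_qq = 1000L, min_total = 5L,
                         seed = 1L) {
  if (n_perm < 1000L)
    stop("validation error: n_perm must be at least 1000")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "log.txt")
  log_lines <- c(sprintf("triodel pipeline run, seed %d", seed),
                 sprintf("n_perm=%d n_sim_qq=%d min_total=%d", n_perm,
                         n_sim_qq, min_total))

  cohort <- if (inherits(config, "trio_cohort")) config else simulate_cohort(config)
  labels <- cohort_labels(cohort)
  cleft_types <- cohort_cleft_types(cohort)
  log_lines <- c(log_lines, sprintf("cohort: %d trios, %d markers",
                                    length(cohort$trios), nrow(cohort$panel)))

  qc <- qc_filter(cohort$trios)
  write_qc_report(qc$report, file.path(out_dir, "qc_report.tsv"))
  log_lines <- c(log_lines, sprintf("qc: excluded %d of %d trios",
                                    sum(qc$report$excluded), nrow(qc$report)))
  kept <- structure(list(panel = cohort$panel, trios = qc$kept,
                         config = cohort$config), class = "trio_cohort")

  calls <- call_cohort(kept, settings, seed = seed)
  write_calls(calls, file.path(out_dir, "calls.tsv"))
  log_lines <- c(log_lines, sprintf("caller: %d de novo deletion calls", nrow(calls)))

  kept_ids <- vapply(qc$kept, `[[`, "", "trio_id")
  labels <- labels[kept_ids]
  cleft_types <- cleft_types[kept_ids]
  components <- delineate_components(calls, cohort$panel, labels)
  write_components(components, file.path(out_dir, "components.tsv"))
  tested <- min_count_filter(components, min_total)
  log_lines <- c(log_lines, sprintf("components: %d delineated, %d with >= %d events",
                                    nrow(components), nrow(tested), min_total))

  assoc <- NULL
  if (nrow(tested)) {
    assoc <- permutation_fwer(tested, labels, n_perm = n_perm, seed = seed)
    utils::write.table(assoc$results, file.path(out_dir, "association.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    log_lines <- c(log_lines,
                   sprintf("association: threshold -log10 p = %.3f, %d significant",
                           assoc$null$threshold_neg_log10,
                           sum(assoc$results$significant)))
  } else log_lines <- c(log_lines, "association: no component passed the event filter")

  widths <- median_width_table(calls, labels, cleft_types)
  grp <- labels[calls$trio_id]
  tests <- NULL
  qq <- NULL
  if (sum(grp == "case", na.rm = TRUE) && sum(grp == "control", na.rm = TRUE)) {
    w <- widths_kb(calls)
    tests <- list(ks = ks_one_sided(w[grp == "case"], w[grp == "control"]),
                  wilcoxon = wilcoxon_one_sided(w[grp == "case"], w[grp == "control"]))
    qq <- qq_null_envelope(w[grp == "case"], w[grp == "control"],
                           n_sim = n_sim_qq, seed = seed)
  }
  width_tab <- data.frame(group = names(widths$medians_kb),
                          n_calls = as.integer(widths$n_calls),
                          median_kb = unname(widths$medians_kb))
  con <- file(file.path(out_dir, "widths.tsv"), "w")
  writeLines(sprintf("# percent_increase=%s ks_p=%s wilcoxon_p=%s",
                     format(widths$percent_increase),
                     if (is.null(tests)) NA else format(tests$ks$p),
                     if (is.null(tests)) NA else format(tests$wilcoxon$p)), con)
  utils::write.table(width_tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)

  rates <- summarize_rates(calls, labels, cleft_types)
  utils::write.table(rates, file.path(out_dir, "rates.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  sources <- summarize_sources(qc$kept)
  utils::write.table(sources, file.path(out_dir, "sources.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  writeLines(log_lines, log_path)
  invisible(list(cohort = cohort, qc = qc, calls = calls,
                 components = components, tested = tested, assoc = assoc,
                 widths = widths, width_tests = tests, qq = qq,
                 rates = rates, sources = sources))
}
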