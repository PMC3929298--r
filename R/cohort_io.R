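#' Write a trio cohort to a directory
#'
#' Writes one panel table (`panel.tsv`: name, chromosome, position, pop_baf),
#' one intensity table per trio (`<trio_id>.tsv`: marker name, member, LRR,
#' BAF) and a manifest (`manifest.yaml`) recording labels, cleft types, DNA
#' sources, QC flags and the realized truth spans. [read_cohort()] inverts
#' this layout.
#'
#' @param cohort A `trio_cohort`.
#' @param dir Output directory (created if missing).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(as.data.frame(cohort$panel), file.path(dir, "panel.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- lapply(cohort$trios, function(trio) {
    tab <- do.call(rbind, lapply(.member_names, function(m)
      data.frame(name = cohort$panel$name, member = m,
                 lrr = trio[[m]]$lrr, baf = trio[[m]]$baf,
                 stringsAsFactors = FALSE)))
    utils::write.table(tab, file.path(dir, paste0(trio$trio_id, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(trio_id = trio$trio_id, label = trio$label,
         cleft_type = trio$cleft_type,
         dna_source = trio$offspring$dna_source,
         wga_flag = as.list(vapply(.member_names, function(m)
           trio[[m]]$wga_flag, NA)),
         external_qc_flag = as.list(vapply(.member_names, function(m)
           trio[[m]]$external_qc_flag, NA)),
         truth = if (nrow(trio$truth)) as.list(trio$truth) else NULL)
  })
  yaml::write_yaml(list(trios = manifest), file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' Read a trio cohort from a directory written by [write_cohort()]
#'
#' @param dir Cohort directory.
#' @return A `trio_cohort` (without the generating `sim_config`).
#' @export
read_cohort <- function(dir) {
  panel <- utils::read.table(file.path(dir, "panel.tsv"), header = TRUE,
                             sep = "\t", colClasses = c("character", "character",
                                                        "integer", "numeric"))
  class(panel) <- c("marker_panel", "data.frame")
  manifest <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  trios <- lapply(manifest$trios, function(m) {
    tab <- utils::read.table(file.path(dir, paste0(m$trio_id, ".tsv")),
                             header = TRUE, sep = "\t",
                             colClasses = c("character", "character",
                                            "numeric", "numeric"))
    members <- lapply(.member_names, function(member) {
      sub <- tab[tab$member == member, ]
      list(lrr = sub$lrr, baf = sub$baf, dna_source = m$dna_source,
           wga_flag = isTRUE(m$wga_flag[[member]]),
           external_qc_flag = isTRUE(m$external_qc_flag[[member]]))
    })
    names(members) <- .member_names
    truth <- if (is.null(m$truth)) {
      data.frame(chromosome = character(), start_marker = integer(),
                 end_marker = integer(), state = character(),
                 kind = character(), stringsAsFactors = FALSE)
    } else as.data.frame(m$truth, stringsAsFactors = FALSE)
    structure(c(list(trio_id = m$trio_id, label = m$label,
                     cleft_type = m$cleft_type, truth = truth), members),
              class = "trio_intensities")
  })
  structure(list(panel = panel, trios = trios, config = NULL),
            class = "trio_cohort")
}
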