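# shared fixture builders; everything is generated in code

# single-chromosome marker panel with regular spacing
make_panel <- function(n, chrom = "1", spacing = 5000L, pop_baf = NULL) {
  panel <- data.frame(name = sprintf("chr%s_m%05d", chrom, seq_len(n)),
                      chromosome = chrom,
                      position = as.integer(seq_len(n)) * spacing,
                      pop_baf = if (is.null(pop_baf)) rep(0.5, n) else pop_baf,
                      stringsAsFactors = FALSE)
  class(panel) <- c("marker_panel", "data.frame")
  panel
}

# trio with fully specified per-member LRR/BAF tracks
make_trio <- function(lrr, baf, trio_id = "trioA", label = "case",
                      cleft_type = "CL", source = "blood",
                      wga = c(FALSE, FALSE, FALSE), ext = c(FALSE, FALSE, FALSE)) {
  members <- lapply(seq_along(c("father", "mother", "offspring")), function(i) {
    m <- c("father", "mother", "offspring")[i]
    list(lrr = lrr[[m]], baf = baf[[m]], dna_source = source,
         wga_flag = wga[i], external_qc_flag = ext[i])
  })
  names(members) <- c("father", "mother", "offspring")
  structure(c(list(trio_id = trio_id, label = label, cleft_type = cleft_type,
                   truth = data.frame()), members),
            class = "trio_intensities")
}

# constant-track trio helper (LRR flat at given levels, BAF all heterozygous)
make_flat_trio <- function(n, father = 0, mother = 0, offspring = 0, ...) {
  lrr <- list(father = rep(father, n), mother = rep(mother, n),
              offspring = rep(offspring, n))
  baf <- list(father = rep(0.5, n), mother = rep(0.5, n),
              offspring = rep(0.5, n))
  make_trio(lrr, baf, ...)
}

# minimal denovo_calls row built from marker indices on a panel
make_call <- function(panel, trio_id, start_marker, end_marker, state = "332") {
  calls <- data.frame(trio_id = trio_id, chromosome = panel$chromosome[start_marker + 1L],
                      start_bp = panel$position[start_marker + 1L],
                      end_bp = panel$position[end_marker],
                      start_marker = start_marker, end_marker = end_marker,
                      state = state, n_markers = end_marker - start_marker,
                      offspring_median_lrr = -0.45, father_median_lrr = 0,
                      mother_median_lrr = 0, het_fraction = 0,
                      stringsAsFactors = FALSE)
  class(calls) <- c("denovo_calls", "data.frame")
  calls
}

# abstract component table from carrier lists (for association tests)
make_components <- function(labels, carrier_sets, n_markers = 50L) {
  rows <- lapply(seq_along(carrier_sets), function(k) {
    carriers <- carrier_sets[[k]]
    grp <- labels[carriers]
    data.frame(chromosome = as.character(k),
               start_marker = (k - 1L) * 100L,
               end_marker = (k - 1L) * 100L + n_markers,
               start_bp = 1L, end_bp = n_markers * 1000L,
               n_markers = n_markers,
               n_case_carriers = sum(grp == "case"),
               n_control_carriers = sum(grp == "control"),
               states = "332",
               carriers_case = I(list(sort(carriers[grp == "case"]))),
               carriers_control = I(list(sort(carriers[grp == "control"]))),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("cnv_components", "data.frame")
  out
}

make_labels <- function(n_case, n_control) {
  stats::setNames(rep(c("case", "control"), c(n_case, n_control)),
                  sprintf("t%04d", seq_len(n_case + n_control)))
}

# quantize to a dyadic grid so sums/differences are exact in floating point
dyadic <- function(x, bits = 12) round(x * 2^bits) / 2^bits
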