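#' Per-marker minimum-distance statistic for a trio
#'
#' At each marker the offspring-minus-father and offspring-minus-mother LRR
#' differences are formed and the one with the smaller absolute value is kept,
#' sign preserved (ties go to the father difference). Because any intensity
#' artifact shared by all three trio members cancels in both differences, the
#' track is robust to genomic waves by construction.
#'
#' @param offspring_lrr,father_lrr,mother_lrr Aligned LRR vectors of equal
#'   length.
#' @return Numeric vector `d` of the same length.
#' @export
minimum_distance <- function(offspring_lrr, father_lrr, mother_lrr) {
  if (length(offspring_lrr) != length(father_lrr) ||
      length(offspring_lrr) != length(mother_lrr))
    stop("data error: LRR vectors must have equal length")
  dF <- offspring_lrr - father_lrr
  dM <- offspring_lrr - mother_lrr
  ifelse(abs(dF) <= abs(dM), dF, dM)
}

#' Caller settings
#'
#' Thresholds and segmentation parameters for the minimum-distance caller.
#' The posterior step of the original approach is replaced by transparent
#' median/threshold decision rules; every cutoff is a setting here.
#'
#' @param alpha Per-split permutation significance level in CBS.
#' @param n_perm_cbs Permutations per CBS split test.
#' @param prune_tol Adjacent segments whose means differ by less than this are
#'   merged after segmentation.
#' @param min_probes Minimum markers a de novo call must span.
#' @param neutral_band Half-width of the copy-neutral median-LRR band around 0.
#' @param hemi_lrr_max Maximum offspring median LRR for a hemizygous call.
#' @param homo_lrr_max Maximum offspring median LRR for a homozygous call.
#' @param het_max Maximum fraction of offspring BAF in (0.4, 0.6) over the
#'   span for a hemizygous call (a true single-copy span has no heterozygotes).
#' @param candidate_cut Only segments with mean minimum distance at or below
#'   this value are examined as deletion candidates.
#' @param parent_neutral_min For homozygous (`331`) calls, the minimum
#'   fraction of span markers at which each parent's BAF-derived genotype
#'   looks copy-neutral.
#' @return A list of class `md_settings`.
#' @export
md_settings <- function(alpha = 0.01, n_perm_cbs = 1000L, prune_tol = 0.1,
                        min_probes = 10L, neutral_band = 0.15,
                        hemi_lrr_max = -0.3, homo_lrr_max = -2.0,
                        het_max = 0.05, candidate_cut = -0.25,
                        parent_neutral_min = 0.8) {
  structure(list(alpha = alpha, n_perm_cbs = as.integer(n_perm_cbs),
                 prune_tol = prune_tol, min_probes = as.integer(min_probes),
                 neutral_band = neutral_band, hemi_lrr_max = hemi_lrr_max,
                 homo_lrr_max = homo_lrr_max, het_max = het_max,
                 candidate_cut = candidate_cut,
                 parent_neutral_min = parent_neutral_min),
            class = "md_settings")
}

# recursive CBS on one chromosome's values; returns integer boundary vector
# (0-based, includes 0 and n)
.cbs_recurse <- function(x, alpha, n_perm) {
  n <- length(x)
  if (n < 4L || stats::sd(x) == 0) return(c(0L, n))
  arc <- .cbs_max_arc(x)
  p <- .cbs_perm_pvalue(x, arc$stat, n_perm, alpha)
  if (p > alpha) return(c(0L, n))
  i <- arc$i; j <- arc$j
  bounds <- 0L
  for (piece in list(c(0L, i), c(i, j), c(j, n))) {
    if (piece[2] <= piece[1]) next
    sub <- .cbs_recurse(x[(piece[1] + 1L):piece[2]], alpha, n_perm)
    bounds <- c(bounds, piece[1] + sub[-1])
  }
  sort(unique(bounds))
}

# merge adjacent segments whose means differ by less than tol
.prune_bounds <- function(x, bounds, tol) {
  repeat {
    if (length(bounds) <= 2L) return(bounds)
    means <- vapply(seq_len(length(bounds) - 1L), function(k)
      mean(x[(bounds[k] + 1L):bounds[k + 1L]]), 0)
    gaps <- abs(diff(means))
    if (!length(gaps) || all(gaps >= tol)) return(bounds)
    drop <- which.min(gaps) + 1L   # merge the closest pair first
    bounds <- bounds[-drop]
  }
}

#' Circular binary segmentation of a minimum-distance track
#'
#' Recursive change-point search run independently per chromosome: at each
#' step the arc maximizing a two-sample contrast statistic is tested by
#' permutation of the segment's values and accepted when its p-value is at
#' most `alpha`; accepted sub-segments are searched recursively. Adjacent
#' segments with mean difference below the pruning tolerance are merged.
#' Non-finite values are imputed by the chromosome median before searching.
#'
#' @param d Numeric minimum-distance vector aligned to `panel`.
#' @param panel A `marker_panel`.
#' @param alpha Split acceptance level.
#' @param n_perm_cbs Permutations per split test.
#' @param seed Integer seed for the permutation stream.
#' @param prune_tol Mean-difference merge tolerance.
#' @return A data.frame of class `md_segments`: `chromosome`, `start_marker`,
#'   `end_marker` (global 0-based half-open panel indices), `start_bp`,
#'   `end_bp` (positions of the first and last contained marker), `mean_d`,
#'   `n_markers`. Segments partition each chromosome's markers.
#' @export
cbs_segment <- function(d, panel, alpha = 0.01, n_perm_cbs = 1000L,
                        seed = 1L, prune_tol = 0.1) {
  stopifnot(length(d) == nrow(panel))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(.derive_seed(seed, 31L))
  chroms <- unique(panel$chromosome)
  out <- list()
  for (chrom in chroms) {
    idx <- which(panel$chromosome == chrom)
    if (!length(idx)) next
    x <- d[idx]
    if (any(!is.finite(x))) x[!is.finite(x)] <- stats::median(x[is.finite(x)])
    bounds <- .cbs_recurse(x, alpha, n_perm_cbs)
    bounds <- .prune_bounds(x, bounds, prune_tol)
    offset <- idx[1L] - 1L
    for (k in seq_len(length(bounds) - 1L)) {
      lo <- bounds[k]; hi <- bounds[k + 1L]
      out[[length(out) + 1L]] <- data.frame(
        chromosome = chrom,
        start_marker = offset + lo, end_marker = offset + hi,
        start_bp = panel$position[offset + lo + 1L],
        end_bp = panel$position[offset + hi],
        mean_d = mean(x[(lo + 1L):hi]), n_markers = hi - lo,
        stringsAsFactors = FALSE)
    }
  }
  seg <- do.call(rbind, out)
  rownames(seg) <- NULL
  class(seg) <- c("md_segments", "data.frame")
  seg
}

# BAF-derived genotype: 0 = AA (BAF < 1/3), 1 = AB, 2 = BB (BAF > 2/3)
.baf_genotype <- function(baf) {
  ifelse(baf < 1 / 3, 0L, ifelse(baf > 2 / 3, 2L, 1L))
}

# fraction of span markers at which a parent's BAF sits in one of the
# copy-neutral genotype clusters around 0, 0.5 or 1
.parent_neutral_fraction <- function(baf) {
  near <- (baf <= 0.1) | (baf >= 0.9) | (baf >= 0.4 & baf <= 0.6)
  mean(near)
}

#' Classify one segment of a trio into a trio copy-number state
#'
#' Decision rules on median LRRs and offspring BAF over the segment's span:
#' `332` (de novo hemizygous) requires the offspring median LRR at or below
#' `hemi_lrr_max`, both parents inside the copy-neutral band, and an
#' offspring heterozygote fraction at most `het_max`; `331` (de novo
#' homozygous) requires the offspring median at or below `homo_lrr_max`,
#' copy-neutral parents, and parental BAF clusters consistent with two copies
#' at a `parent_neutral_min` fraction of markers; `333` is all-copy-neutral;
#' anything else (including inherited patterns such as `322`/`232`) is
#' `other`.
#'
#' @param segment One-row segment (as from [cbs_segment()]).
#' @param trio A `trio_intensities` object.
#' @param settings An [md_settings()] object.
#' @return One of `"331"`, `"332"`, `"333"`, `"other"`.
#' @export
call_state <- function(segment, trio, settings = md_settings()) {
  idx <- (segment$start_marker + 1L):segment$end_marker
  med <- vapply(.member_names, function(m)
    stats::median(trio[[m]]$lrr[idx], na.rm = TRUE), 0)
  baf_o <- trio$offspring$baf[idx]
  het <- mean(baf_o > 0.4 & baf_o < 0.6)
  band <- settings$neutral_band
  parents_neutral <- abs(med[["father"]]) <= band && abs(med[["mother"]]) <= band
  if (parents_neutral && med[["offspring"]] <= settings$homo_lrr_max) {
    pn <- min(.parent_neutral_fraction(trio$father$baf[idx]),
              .parent_neutral_fraction(trio$mother$baf[idx]))
    if (pn >= settings$parent_neutral_min) return("331")
  }
  if (parents_neutral && med[["offspring"]] <= settings$hemi_lrr_max &&
      het <= settings$het_max) return("332")
  if (parents_neutral && abs(med[["offspring"]]) <= band) return("333")
  "other"
}

#' Call de novo deletions in one trio
#'
#' Runs the full caller: minimum-distance track, circular binary
#' segmentation, state classification of candidate segments (mean minimum
#' distance at or below the candidate cut), and retention of `331`/`332`
#' states spanning at least `min_probes` markers.
#'
#' @param trio A `trio_intensities` object (post-QC).
#' @param panel The `marker_panel` the trio is aligned to.
#' @param settings An [md_settings()] object.
#' @param seed Integer seed for the CBS permutation stream.
#' @return A data.frame of class `denovo_calls`: `trio_id`, `chromosome`,
#'   `start_bp`, `end_bp` (1-based inclusive genomic span of the first and
#'   last marker), `start_marker`, `end_marker` (global 0-based half-open),
#'   `state`, `n_markers`, per-member median LRRs and the offspring
#'   heterozygote fraction over the span.
#' @export
call_trio <- function(trio, panel, settings = md_settings(), seed = 1L) {
  d <- minimum_distance(trio$offspring$lrr, trio$father$lrr, trio$mother$lrr)
  segs <- cbs_segment(d, panel, alpha = settings$alpha,
                      n_perm_cbs = settings$n_perm_cbs, seed = seed,
                      prune_tol = settings$prune_tol)
  rows <- list()
  for (k in seq_len(nrow(segs))) {
    seg <- segs[k, ]
    if (seg$mean_d > settings$candidate_cut) next
    if (seg$n_markers < settings$min_probes) next
    state <- call_state(seg, trio, settings)
    if (!state %in% c("331", "332")) next
    idx <- (seg$start_marker + 1L):seg$end_marker
    baf_o <- trio$offspring$baf[idx]
    rows[[length(rows) + 1L]] <- data.frame(
      trio_id = trio$trio_id, chromosome = seg$chromosome,
      start_bp = seg$start_bp, end_bp = seg$end_bp,
      start_marker = seg$start_marker, end_marker = seg$end_marker,
      state = state, n_markers = seg$n_markers,
      offspring_median_lrr = stats::median(trio$offspring$lrr[idx]),
      father_median_lrr = stats::median(trio$father$lrr[idx]),
      mother_median_lrr = stats::median(trio$mother$lrr[idx]),
      het_fraction = mean(baf_o > 0.4 & baf_o < 0.6),
      stringsAsFactors = FALSE)
  }
  calls <- if (length(rows)) do.call(rbind, rows) else .empty_calls()
  rownames(calls) <- NULL
  class(calls) <- c("denovo_calls", "data.frame")
  calls
}

.empty_calls <- function() {
  data.frame(trio_id = character(), chromosome = character(),
             start_bp = integer(), end_bp = integer(),
             start_marker = integer(), end_marker = integer(),
             state = character(), n_markers = integer(),
             offspring_median_lrr = numeric(), father_median_lrr = numeric(),
             mother_median_lrr = numeric(), het_fraction = numeric(),
             stringsAsFactors = FALSE)
}

#' Call de novo deletions for every trio in a cohort
#'
#' @param cohort A `trio_cohort` (post-QC trios are used as given).
#' @param settings An [md_settings()] object.
#' @param seed Integer seed; each trio gets a derived sub-stream.
#' @return A combined `denovo_calls` data.frame.
#' @export
call_cohort <- function(cohort, settings = md_settings(), seed = 1L) {
  pieces <- lapply(seq_along(cohort$trios), function(i)
    call_trio(cohort$trios[[i]], cohort$panel, settings,
              seed = .derive_seed(seed, i)))
  calls <- do.call(rbind, pieces)
  rownames(calls) <- NULL
  class(calls) <- c("denovo_calls", "data.frame")
  calls
}

#' @export
print.denovo_calls <- function(x, ...) {
  cat(sprintf("De novo deletion calls: %d (%d hemizygous '332', %d homozygous '331') in %d trios\n",
              nrow(x), sum(x$state == "332"), sum(x$state == "331"),
              length(unique(x$trio_id))))
  if (nrow(x)) print.data.frame(x, ...)
  invisible(x)
}

#' Count Mendelian inconsistencies over a marker span
#'
#' Derives biallelic genotypes from BAF (AA below 1/3, BB above 2/3, AB
#' between) for all trio members and counts markers in the span at which the
#' offspring genotype is impossible under Mendelian transmission from the
#' parental genotypes. Clusters of inconsistencies are an orthogonal,
#' genotype-only signal of a deletion; note a hemizygous offspring at
#' low-minor-allele-frequency markers typically produces none.
#'
#' @param trio A `trio_intensities` object.
#' @param span Integer vector `c(start_marker, end_marker)`, global 0-based
#'   half-open.
#' @param baf_cuts Genotype thresholds `c(lower, upper)` on BAF.
#' @return Integer count of Mendelian-inconsistent markers.
#' @export
mendelian_inconsistencies <- function(trio, span, baf_cuts = c(1 / 3, 2 / 3)) {
  idx <- (span[1] + 1L):span[2]
  geno <- function(baf) ifelse(baf < baf_cuts[1], 0L,
                               ifelse(baf > baf_cuts[2], 2L, 1L))
  gf <- geno(trio$father$baf[idx])
  gm <- geno(trio$mother$baf[idx])
  go <- geno(trio$offspring$baf[idx])
  # offspring receives one allele from each parent: possible B-allele counts
  f_alleles <- list(`0` = 0L, `1` = 0:1, `2` = 1L)
  possible <- mapply(function(f, m, o) {
    o %in% outer(f_alleles[[as.character(f)]], f_alleles[[as.character(m)]], `+`)
  }, gf, gm, go)
  sum(!possible)
}
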