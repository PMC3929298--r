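#' Simulation configuration for synthetic trio cohorts
#'
#' Builds the configuration object consumed by [build_panel()],
#' [simulate_trio()] and [simulate_cohort()]. Defaults emulate an
#' Illumina-style autosomal SNP panel and a case-control trio study in which
#' DNA source (and hence intensity noise) differs between groups.
#'
#' @param n_case_trios,n_control_trios Number of case and control trios.
#' @param markers_per_chrom Markers simulated on each of the 22 autosomes.
#' @param mean_spacing_bp Mean inter-marker gap in base pairs; gaps are drawn
#'   from an exponential distribution with this mean.
#' @param lrr_mean_by_cn Named numeric vector mapping copy number
#'   (`"0"`, `"1"`, `"2"`) to the mean log R ratio. LRR is approximately 0 at
#'   two copies and strongly negative at zero copies.
#' @param lrr_sd_by_source Named numeric vector of per-marker LRR standard
#'   deviations for the DNA sources `blood`, `buccal`, `mouthwash`, `saliva`.
#'   Non-blood sources are noisier, which drives excess false calls.
#' @param source_mix_case,source_mix_control Probability vectors (same names
#'   as `lrr_sd_by_source`) from which each trio's DNA source is drawn.
#' @param wave_amplitude_sd Standard deviation of the per-sample amplitude
#'   multiplying the shared smooth genomic-wave profile.
#' @param baf_sd Standard deviation of BAF noise around the genotype cluster
#'   means at copy numbers 1 and 2.
#' @param planted_loci A data.frame with columns `chromosome`,
#'   `start_marker` (0-based index within the chromosome), `width` (markers),
#'   `case_freq`, `control_freq`, `kind` (one of `de_novo_hemi`,
#'   `de_novo_homo`, `inherited`). Each trio carries each locus independently
#'   with the frequency of its group.
#' @param cleft_type_mix Probability vector over proband cleft types
#'   (`CL`, `CP`, `CLP`) used for case trios; controls are always `none`.
#' @param seed Integer seed; all per-trio random streams are derived
#'   deterministically from it.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_case_trios = 100L,
                       n_control_trios = 100L,
                       markers_per_chrom = 100L,
                       mean_spacing_bp = 5000,
                       lrr_mean_by_cn = c("0" = -3.5, "1" = -0.45, "2" = 0),
                       lrr_sd_by_source = c(blood = 0.12, buccal = 0.22,
                                            mouthwash = 0.25, saliva = 0.20),
                       source_mix_case = c(blood = 1139, buccal = 125,
                                           mouthwash = 21, saliva = 90) / 1375,
                       source_mix_control = c(blood = 581, buccal = 64,
                                              mouthwash = 50, saliva = 207) / 902,
                       wave_amplitude_sd = 0.05,
                       baf_sd = 0.03,
                       planted_loci = NULL,
                       cleft_type_mix = c(CL = 0.3, CP = 0.28, CLP = 0.42),
                       seed = 1L) {
  if (markers_per_chrom < 1L || n_case_trios < 0L || n_control_trios < 0L)
    stop("configuration error: sizes must be non-negative and panel non-empty")
  if (mean_spacing_bp <= 0) stop("configuration error: mean_spacing_bp must be > 0")
  for (mix in list(source_mix_case, source_mix_control, cleft_type_mix)) {
    if (abs(sum(mix) - 1) > 1e-9)
      stop("configuration error: probability vector does not sum to 1")
  }
  if (is.null(planted_loci)) {
    planted_loci <- data.frame(chromosome = character(), start_marker = integer(),
                               width = integer(), case_freq = numeric(),
                               control_freq = numeric(), kind = character(),
                               stringsAsFactors = FALSE)
  } else {
    planted_loci <- as.data.frame(planted_loci, stringsAsFactors = FALSE)
    planted_loci$chromosome <- as.character(planted_loci$chromosome)
    stopifnot(all(planted_loci$width >= 1L),
              all(planted_loci$case_freq >= 0 & planted_loci$case_freq <= 1),
              all(planted_loci$control_freq >= 0 & planted_loci$control_freq <= 1),
              all(planted_loci$kind %in% c("de_novo_hemi", "de_novo_homo", "inherited")))
  }
  structure(list(n_case_trios = as.integer(n_case_trios),
                 n_control_trios = as.integer(n_control_trios),
                 markers_per_chrom = as.integer(markers_per_chrom),
                 mean_spacing_bp = mean_spacing_bp,
                 lrr_mean_by_cn = lrr_mean_by_cn,
                 lrr_sd_by_source = lrr_sd_by_source,
                 source_mix_case = source_mix_case,
                 source_mix_control = source_mix_control,
                 wave_amplitude_sd = wave_amplitude_sd,
                 baf_sd = baf_sd,
                 planted_loci = planted_loci,
                 cleft_type_mix = cleft_type_mix,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# deterministic sub-stream seed; kept inside 32-bit integer range
.derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 7919 + as.double(index) * 104729) %% 2147483647)
}

#' Build a synthetic autosomal marker panel
#'
#' Generates an ordered marker map for the 22 autosomes: positions accumulate
#' exponential gaps with mean `mean_spacing_bp`, and each marker gets a
#' population B-allele frequency drawn uniformly on \[0.01, 0.99\].
#' Deterministic given `config$seed`.
#'
#' @param config A [sim_config()] object.
#' @return A data.frame of class `marker_panel` with columns `name`,
#'   `chromosome`, `position`, `pop_baf`, ordered by chromosome then position.
#' @export
build_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$markers_per_chrom < 20L)
    stop("configuration error: markers_per_chrom must be at least 20")
  n <- config$markers_per_chrom
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(.derive_seed(config$seed, 0L))
  pieces <- lapply(1:22, function(chrom) {
    gaps <- stats::rexp(n, rate = 1 / config$mean_spacing_bp)
    pos <- as.integer(cumsum(pmax(1, round(gaps))))
    data.frame(name = sprintf("chr%d_m%05d", chrom, seq_len(n)),
               chromosome = as.character(chrom),
               position = pos,
               pop_baf = stats::runif(n, 0.01, 0.99),
               stringsAsFactors = FALSE)
  })
  panel <- do.call(rbind, pieces)
  rownames(panel) <- NULL
  class(panel) <- c("marker_panel", "data.frame")
  panel
}

# smooth panel-wide wave profile shared by all samples: three sinusoids with
# 0.5-5 Mb wavelengths, unit-normalized per chromosome block
.wave_profile <- function(panel, seed) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(.derive_seed(seed, 997L))
  wl <- stats::runif(3, 0.5e6, 5e6)
  ph <- stats::runif(3, 0, 2 * pi)
  w <- rowSums(sapply(1:3, function(k)
    sin(2 * pi * panel$position / wl[k] + ph[k])))
  w <- w - mean(w)
  s <- stats::sd(w)
  if (s > 0) w / s else w
}

.member_names <- c("father", "mother", "offspring")

# genotype codes: 0 = AA, 1 = AB, 2 = BB (count of B alleles)
.transmit <- function(parent_geno) {
  # returns one allele (0/1) transmitted from a diploid genotype
  if (parent_geno == 1L) stats::rbinom(1L, 1L, 0.5) else as.integer(parent_geno == 2L)
}

#' Simulate LRR/BAF intensities for one trio
#'
#' Parental genotypes are drawn per marker from Hardy-Weinberg proportions at
#' the panel's population B-allele frequency; the offspring genotype follows
#' Mendelian transmission. Copy-neutral LRR is Gaussian around
#' `lrr_mean_by_cn["2"]` with a DNA-source-specific SD plus a per-sample
#' amplitude times the shared genomic-wave profile. Planted loci override copy
#' number: de novo loci change the offspring only (CN 1 or 0, parents stay at
#' CN 2); inherited loci set one parent and the offspring to CN 1. BAF
#' clusters near 0/0.5/1 by genotype at CN 2, collapses to hemizygous A or B
#' (near 0/1) at CN 1, and is uniform on \[0,1\] at CN 0.
#'
#' Trio index `1..n_case_trios` yields a case trio; higher indices are
#' controls. Each planted locus is carried with its group-specific frequency,
#' drawn independently per trio; realized spans are recorded in `$truth` with
#' the three-digit trio state code (father, mother, offspring; copy number
#' + 1, capped at 3): `332` de novo hemizygous, `331` de novo homozygous,
#' `232`/`322` inherited.
#'
#' @param panel A `marker_panel` from [build_panel()].
#' @param config A [sim_config()] object.
#' @param trio_index Integer in `1..(n_case_trios + n_control_trios)`.
#' @return A list of class `trio_intensities`: `trio_id`, `label`
#'   (`case`/`control`), `cleft_type`, per-member lists with `lrr`, `baf`,
#'   `dna_source`, `wga_flag`, `external_qc_flag`, and a `truth` data.frame of
#'   realized planted spans (global 0-based half-open marker indices).
#' @export
simulate_trio <- function(panel, config, trio_index) {
  stopifnot(inherits(panel, "marker_panel"), inherits(config, "sim_config"))
  n_total <- config$n_case_trios + config$n_control_trios
  stopifnot(trio_index >= 1L, trio_index <= n_total)
  label <- if (trio_index <= config$n_case_trios) "case" else "control"
  n <- nrow(panel)
  wave <- .wave_profile(panel, config$seed)

  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(.derive_seed(config$seed, trio_index))

  cleft_type <- if (label == "case") {
    sample(names(config$cleft_type_mix), 1L, prob = config$cleft_type_mix)
  } else "none"
  mix <- if (label == "case") config$source_mix_case else config$source_mix_control
  source <- sample(names(mix), 1L, prob = mix)
  sd_lrr <- config$lrr_sd_by_source[[source]]

  # copy-number tracks, default 2 everywhere
  cn <- matrix(2L, nrow = n, ncol = 3L, dimnames = list(NULL, .member_names))
  truth <- data.frame(chromosome = character(), start_marker = integer(),
                      end_marker = integer(), state = character(),
                      kind = character(), stringsAsFactors = FALSE)
  loci <- config$planted_loci
  freq_col <- if (label == "case") "case_freq" else "control_freq"
  if (nrow(loci)) {
    chrom_offset <- match(loci$chromosome, unique(panel$chromosome))
    for (k in seq_len(nrow(loci))) {
      if (is.na(chrom_offset[k]))
        stop("configuration error: planted locus chromosome not in panel")
      g0 <- (chrom_offset[k] - 1L) * config$markers_per_chrom + loci$start_marker[k]
      g1 <- g0 + loci$width[k]
      if (loci$start_marker[k] < 0L || g1 > chrom_offset[k] * config$markers_per_chrom)
        stop("configuration error: planted locus outside panel")
      carried <- stats::runif(1) < loci[[freq_col]][k]
      if (!carried) next
      idx <- (g0 + 1L):g1
      kind <- loci$kind[k]
      if (kind == "de_novo_hemi") {
        cn[idx, "offspring"] <- 1L
        state <- "332"
      } else if (kind == "de_novo_homo") {
        cn[idx, "offspring"] <- 0L
        state <- "331"
      } else {
        parent <- sample(c("father", "mother"), 1L)
        cn[idx, parent] <- 1L
        cn[idx, "offspring"] <- 1L
        state <- if (parent == "father") "232" else "322"
      }
      truth <- rbind(truth, data.frame(chromosome = loci$chromosome[k],
                                       start_marker = g0, end_marker = g1,
                                       state = state, kind = kind,
                                       stringsAsFactors = FALSE))
    }
  }

  # HWE parental genotypes (B-allele counts), Mendelian offspring
  p <- panel$pop_baf
  gf <- stats::rbinom(n, 2L, p)
  gm <- stats::rbinom(n, 2L, p)
  allele_f <- ifelse(gf == 1L, stats::rbinom(n, 1L, 0.5), as.integer(gf == 2L))
  allele_m <- ifelse(gm == 1L, stats::rbinom(n, 1L, 0.5), as.integer(gm == 2L))
  go <- allele_f + allele_m
  geno <- cbind(father = gf, mother = gm, offspring = go)

  amp <- stats::rnorm(3L, 0, config$wave_amplitude_sd)
  names(amp) <- .member_names
  members <- lapply(.member_names, function(m) {
    cnm <- cn[, m]
    lrr <- config$lrr_mean_by_cn[as.character(cnm)] +
      stats::rnorm(n, 0, sd_lrr) + amp[[m]] * wave
    baf <- .baf_from_genotype(geno[, m], cnm, p, config$baf_sd)
    list(lrr = as.numeric(lrr), baf = baf, dna_source = source,
         wga_flag = FALSE, external_qc_flag = FALSE)
  })
  names(members) <- .member_names

  structure(c(list(trio_id = sprintf("trio%04d", trio_index),
                   label = label, cleft_type = cleft_type, truth = truth),
              members),
            class = "trio_intensities")
}

# BAF given genotype cluster and copy number; hemizygous spans collapse the
# genotype to A or B so heterozygous BAF values are suppressed
.baf_from_genotype <- function(geno, cn, pop_baf, baf_sd) {
  n <- length(geno)
  baf <- numeric(n)
  hemi <- cn == 1L
  null_cn <- cn == 0L
  neutral <- !hemi & !null_cn
  centers <- c(0, 0.5, 1)[geno + 1L]
  baf[neutral] <- stats::rnorm(sum(neutral), centers[neutral], baf_sd)
  if (any(hemi)) {
    # the single remaining allele: B with probability ~ pop_baf given genotype
    keep_b <- ifelse(geno[hemi] == 2L, 1L,
                     ifelse(geno[hemi] == 0L, 0L, stats::rbinom(sum(hemi), 1L, 0.5)))
    baf[hemi] <- stats::rnorm(sum(hemi), as.numeric(keep_b), baf_sd)
  }
  baf[null_cn] <- stats::runif(sum(null_cn))
  pmin(1, pmax(0, baf))
}

#' Simulate a full case-control trio cohort
#'
#' @param config A [sim_config()] object.
#' @return A list of class `trio_cohort` with elements `panel`, `trios`
#'   (list of [simulate_trio()] results, cases first) and `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  panel <- build_panel(config)
  n_total <- config$n_case_trios + config$n_control_trios
  trios <- lapply(seq_len(n_total), function(i) simulate_trio(panel, config, i))
  structure(list(panel = panel, trios = trios, config = config),
            class = "trio_cohort")
}

#' @export
print.trio_cohort <- function(x, ...) {
  labels <- vapply(x$trios, `[[`, "", "label")
  cat("Synthetic trio cohort\n")
  cat(sprintf("  markers: %d over %d chromosomes\n",
              nrow(x$panel), length(unique(x$panel$chromosome))))
  cat(sprintf("  trios: %d case, %d control\n",
              sum(labels == "case"), sum(labels == "control")))
  n_truth <- sum(vapply(x$trios, function(t) nrow(t$truth), 0L))
  cat(sprintf("  planted deletion spans realized: %d\n", n_truth))
  invisible(x)
}

#' Trio labels of a cohort
#'
#' @param cohort A `trio_cohort`.
#' @return Named character vector mapping trio id to `case`/`control`.
#' @export
cohort_labels <- function(cohort) {
  stats::setNames(vapply(cohort$trios, `[[`, "", "label"),
                  vapply(cohort$trios, `[[`, "", "trio_id"))
}

#' Proband cleft types of a cohort
#'
#' @param cohort A `trio_cohort`.
#' @return Named character vector mapping trio id to `CL`/`CP`/`CLP`/`none`.
#' @export
cohort_cleft_types <- function(cohort) {
  stats::setNames(vapply(cohort$trios, `[[`, "", "cleft_type"),
                  vapply(cohort$trios, `[[`, "", "trio_id"))
}

# save/restore the global RNG state so simulation helpers do not disturb the
# caller's random stream
.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
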