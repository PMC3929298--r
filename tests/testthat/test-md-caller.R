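test_that("minimum distance keeps the parent difference smaller in absolute value", {
  expect_equal(minimum_distance(0.3, 0.3, 0.3), 0)
  expect_equal(minimum_distance(0, 0.5, 0.8), -0.5)   # dF = -0.5, dM = -0.8
  expect_error(minimum_distance(1:3, 1:2, 1:3), "data error")

  # brute-force elementwise oracle on random tracks
  set.seed(4)
  o <- rnorm(1000); f <- rnorm(1000); m <- rnorm(1000)
  oracle <- vapply(seq_along(o), function(i) {
    cand <- c(o[i] - f[i], o[i] - m[i])
    cand[which.min(abs(cand))]
  }, 0)
  expect_equal(minimum_distance(o, f, m), oracle)
})

test_that("an identical wave added to all members leaves the track bit-identical", {
  # dyadic-grid values make the shared additions exact in floating point,
  # isolating the algebraic cancellation of the statistic
  set.seed(8)
  n <- 2000
  o <- dyadic(rnorm(n, 0, 0.15)); f <- dyadic(rnorm(n, 0, 0.15))
  m <- dyadic(rnorm(n, 0, 0.15))
  w <- dyadic(0.3 * sin(seq_len(n) / 100))
  expect_identical(minimum_distance(o + w, f + w, m + w),
                   minimum_distance(o, f, m))
})

test_that("segmentation recovers a planted step and partitions each chromosome", {
  # null case: constant signal stays one segment per chromosome
  set.seed(21)
  panel0 <- make_panel(200)
  d0 <- rnorm(200, 0, 0.01)
  seg0 <- cbs_segment(d0, panel0, alpha = 0.01, n_perm_cbs = 1000, seed = 2)
  expect_equal(nrow(seg0), 1)
  expect_equal(seg0$n_markers, 200)

  # step signal: 500 markers, drop of -0.5 over markers 200-249 (0-based)
  set.seed(33)
  panel <- make_panel(500)
  d <- rnorm(500, 0, 0.15)
  d[201:250] <- d[201:250] - 0.5
  seg <- cbs_segment(d, panel, alpha = 0.01, n_perm_cbs = 1000, seed = 3)
  # independent exhaustive single-arc scan oracle on the same data
  z_best <- -Inf; arc <- c(NA, NA)
  s <- c(0, cumsum(d)); tot <- s[501]
  for (i in 0:499) for (j in (i + 1):500) {
    mm <- j - i
    if (mm == 500) next
    z <- abs(s[j + 1] - s[i + 1] - mm / 500 * tot) / sqrt(mm * (500 - mm) / 500)
    if (z > z_best) { z_best <- z; arc <- c(i, j) }
  }
  expect_lte(abs(arc[1] - 200), 3)
  expect_lte(abs(arc[2] - 250), 3)
  bounds <- sort(unique(c(seg$start_marker, seg$end_marker)))
  expect_true(any(abs(bounds - 200) <= 3))
  expect_true(any(abs(bounds - 250) <= 3))

  # partition invariant: segments disjoint, ordered, covering all markers
  expect_equal(seg$start_marker[1], 0)
  expect_equal(seg$end_marker[nrow(seg)], 500)
  if (nrow(seg) > 1)
    expect_equal(seg$start_marker[-1], seg$end_marker[-nrow(seg)])

  # per-chromosome independence: a two-chromosome run equals separate runs
  panel2 <- make_panel(500, chrom = "2")
  panel2$name <- sub("chr1", "chr2", panel2$name)
  joint <- rbind(panel, panel2)
  class(joint) <- c("marker_panel", "data.frame")
  d2 <- rnorm(500, 0, 0.15); d2[101:160] <- d2[101:160] - 0.5
  seg_joint <- cbs_segment(c(d, d2), joint, alpha = 0.01, n_perm_cbs = 1000, seed = 3)
  seg_solo <- cbs_segment(d2, panel2, alpha = 0.01, n_perm_cbs = 1000, seed = 3)
  on2 <- seg_joint[seg_joint$chromosome == "2", ]
  expect_equal(on2$start_marker - 500L, seg_solo$start_marker)
  expect_equal(on2$end_marker - 500L, seg_solo$end_marker)
})

test_that("state classification follows the median/threshold decision rules", {
  n <- 40
  panel <- make_panel(n)
  seg <- data.frame(start_marker = 0L, end_marker = n, chromosome = "1")

  hemi <- make_flat_trio(n, father = -0.02, mother = 0.01, offspring = -0.45)
  hemi$offspring$baf <- rep(c(0.01, 0.99), n / 2)
  expect_equal(call_state(seg, hemi), "332")

  neutral <- make_flat_trio(n, father = 0.03, mother = -0.04, offspring = 0.02)
  neutral$offspring$baf <- c(rep(0.5, 13), rep(0.01, 14), rep(0.99, 13))
  expect_equal(call_state(seg, neutral), "333")

  homo <- make_flat_trio(n, father = 0.01, mother = -0.01, offspring = -3.2)
  homo$offspring$baf <- runif(n)
  homo$father$baf <- rep(c(0.02, 0.5, 0.98), length.out = n)
  homo$mother$baf <- rep(c(0.5, 0.97, 0.03), length.out = n)
  expect_equal(call_state(seg, homo), "331")

  inherited <- make_flat_trio(n, father = -0.45, mother = 0.01, offspring = -0.45)
  expect_equal(call_state(seg, inherited), "other")
})

test_that("the trio caller recovers planted deletions and applies the probe filter", {
  loci <- data.frame(chromosome = "1", start_marker = 30, width = 30,
                     case_freq = 1, control_freq = 0, kind = "de_novo_hemi")
  cfg <- sim_config(n_case_trios = 1, n_control_trios = 0,
                    markers_per_chrom = 100, planted_loci = loci, seed = 41)
  coh <- simulate_cohort(cfg)
  calls <- call_trio(coh$trios[[1]], coh$panel, seed = 6)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$state, "332")
  expect_lt(calls$start_marker, 60)   # overlaps the planted span [30, 60)
  expect_gt(calls$end_marker, 30)

  # a 9-marker planted deletion is below the 10-probe rule
  loci9 <- data.frame(chromosome = "1", start_marker = 30, width = 9,
                      case_freq = 1, control_freq = 0, kind = "de_novo_hemi")
  cfg9 <- sim_config(n_case_trios = 1, n_control_trios = 0,
                     markers_per_chrom = 100, planted_loci = loci9, seed = 43)
  coh9 <- simulate_cohort(cfg9)
  expect_equal(nrow(call_trio(coh9$trios[[1]], coh9$panel, seed = 6)), 0)

  # inherited deletions are never emitted as de novo
  loci_inh <- data.frame(chromosome = "1", start_marker = 30, width = 30,
                         case_freq = 1, control_freq = 0, kind = "inherited")
  cfg_inh <- sim_config(n_case_trios = 1, n_control_trios = 0,
                        markers_per_chrom = 100, planted_loci = loci_inh, seed = 47)
  coh_inh <- simulate_cohort(cfg_inh)
  expect_equal(nrow(call_trio(coh_inh$trios[[1]], coh_inh$panel, seed = 6)), 0)
})

test_that("Mendelian inconsistency counting follows biallelic transmission", {
  n <- 10
  trio <- make_flat_trio(n)
  trio$father$baf <- rep(0.02, n)      # AA
  trio$mother$baf <- rep(0.03, n)      # AA
  trio$offspring$baf <- c(0.5, rep(0.02, n - 1))   # one impossible AB
  expect_equal(mendelian_inconsistencies(trio, c(0, n)), 1)

  trio$offspring$baf <- rep(0.02, n)
  expect_equal(mendelian_inconsistencies(trio, c(0, n)), 0)

  # hemizygous offspring at low-frequency markers shows no inconsistencies:
  # rare B allele means parents are AA and the remaining single A allele
  # still reads as AA
  set.seed(55)
  n2 <- 44
  baf_noise <- function(center) pmin(1, pmax(0, rnorm(n2, center, 0.02)))
  trio2 <- make_trio(
    lrr = list(father = rep(0, n2), mother = rep(0, n2), offspring = rep(-0.45, n2)),
    baf = list(father = baf_noise(0), mother = baf_noise(0),
               offspring = baf_noise(0)))
  expect_equal(mendelian_inconsistencies(trio2, c(0, n2)), 0)
})

test_that("call files round-trip and malformed lines are rejected with line numbers", {
  panel <- make_panel(300)
  calls <- rbind(make_call(panel, "trioA", 10, 60),
                 make_call(panel, "trioB", 100, 140, state = "331"),
                 make_call(panel, "trioC", 200, 260))
  class(calls) <- c("denovo_calls", "data.frame")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_calls(calls, path)
  back <- read_calls(path, panel)
  expect_equal(nrow(back), 3)
  expect_equal(back[, c("trio_id", "chromosome", "start_bp", "end_bp",
                        "start_marker", "end_marker", "state", "n_markers")],
               calls[, c("trio_id", "chromosome", "start_bp", "end_bp",
                         "start_marker", "end_marker", "state", "n_markers")])
  # write -> read -> write is bit-exact
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_calls(back, path2)
  expect_identical(readLines(path), readLines(path2))

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("#header", "1\t500\t400\ttrioA\t332\t10\t-0.4\t10\t20"), bad)
  expect_error(read_calls(bad), "line 2.*end")
  writeLines(c("1\t100\t400\ttrioA\t322\t10\t-0.4\t10\t20"), bad)
  expect_error(read_calls(bad), "unknown state")
  writeLines("1\t100\t400", bad)
  expect_error(read_calls(bad), "line 1")
})

test_that("raising intensity noise never lowers the mean false-call rate", {
  count_false <- function(sd_level) {
    cfg <- sim_config(n_case_trios = 12, n_control_trios = 0,
                      markers_per_chrom = 50, seed = 5,
                      lrr_sd_by_source = c(blood = sd_level, buccal = sd_level,
                                           mouthwash = sd_level,
                                           saliva = sd_level))
    coh <- simulate_cohort(cfg)   # no planted loci: every call is false
    nrow(call_cohort(coh, seed = 3)) / length(coh$trios)
  }
  expect_gte(count_false(0.25), count_false(0.12))
})
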