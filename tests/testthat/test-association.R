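# exhaustive hypergeometric tail oracle: enumerate every table with the
# observed margins and sum the probabilities of tables at least as extreme
brute_fisher_upper <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  a_range <- max(0, k - n):min(k, m)
  probs <- choose(m, a_range) * choose(n, k - a_range) / choose(m + n, k)
  sum(probs[a_range >= a])
}

test_that("one-sided Fisher p equals exhaustive hypergeometric enumeration", {
  expect_equal(fisher_one_sided(0, 467, 0, 391), 1.0)
  # the 10/467 vs 0/391 carrier table
  expect_equal(fisher_one_sided(10, 457, 0, 391),
               brute_fisher_upper(10, 457, 0, 391), tolerance = 1e-12)
  expect_lt(abs(fisher_one_sided(10, 457, 0, 391) - 2.2e-3), 2e-4)

  # all tables with margins up to 40
  set.seed(71)
  for (rep in 1:200) {
    m <- sample(1:40, 1); n <- sample(1:40, 1)
    k <- sample(0:(m + n), 1)
    a_rng <- max(0, k - n):min(k, m)
    a <- a_rng[sample.int(length(a_rng), 1)]
    p <- fisher_one_sided(a, m - a, k - a, n - (k - a))
    expect_equal(p, brute_fisher_upper(a, m - a, k - a, n - (k - a)),
                 tolerance = 1e-12)
  }

  # agreement with the R reference implementation
  expect_equal(fisher_one_sided(10, 457, 0, 391),
               fisher.test(matrix(c(10, 457, 0, 391), 2, byrow = TRUE),
                           alternative = "greater")$p.value,
               tolerance = 1e-12)
  expect_error(fisher_one_sided(-1, 2, 3, 4), "validation error")
})

test_that("the minimum-event filter keeps components with five or more carriers", {
  labels <- make_labels(10, 10)
  ids <- names(labels)
  comp <- make_components(labels, list(ids[1:4], ids[c(1, 2, 11, 12, 13)],
                                       ids[1:7], character(0)))
  kept <- min_count_filter(comp)
  expect_equal(nrow(kept), 2)
  expect_equal(kept$n_case_carriers + kept$n_control_carriers, c(5, 7))
  expect_equal(nrow(min_count_filter(comp[0, ])), 0)
})

test_that("permutation FWER: adjusted p behaves as a max-statistic correction", {
  labels <- make_labels(100, 100)
  ids <- names(labels)

  # single component: no multiplicity, adjusted p close to the Fisher p
  set.seed(81)
  carriers <- c(sample(ids[1:100], 9), sample(ids[101:200], 1))
  comp1 <- make_components(labels, list(carriers))
  res1 <- permutation_fwer(comp1, labels, n_perm = 4000, seed = 5)
  p_fisher <- res1$results$fisher_p
  mc_se <- sqrt(p_fisher * (1 - p_fisher) / 4000)
  expect_lt(abs(res1$results$adjusted_p - p_fisher), 2 * mc_se + 1 / 4001)

  # equal carrier frequency in both groups: a null-centered statistic
  comp_null <- make_components(labels, list(c(sample(ids[1:100], 3),
                                              sample(ids[101:200], 3))))
  res_null <- permutation_fwer(comp_null, labels, n_perm = 2000, seed = 7)
  expect_gte(res_null$results$adjusted_p, 0.5)

  # reproducibility and ordering invariants
  res1b <- permutation_fwer(comp1, labels, n_perm = 4000, seed = 5)
  expect_identical(res1$null$max_neg_log10_p, res1b$null$max_neg_log10_p)
  expect_identical(res1$results$adjusted_p, res1b$results$adjusted_p)

  multi <- make_components(labels, list(
    c(sample(ids[1:100], 6), sample(ids[101:200], 1)),
    c(sample(ids[1:100], 3), sample(ids[101:200], 3)),
    c(sample(ids[1:100], 8), sample(ids[101:200], 2))))
  resm <- permutation_fwer(multi, labels, n_perm = 2000, seed = 11)
  ord <- order(resm$results$neg_log10_p, decreasing = TRUE)
  expect_true(all(diff(resm$results$adjusted_p[ord]) >= 0))
  expect_true(all(resm$results$adjusted_p >= resm$results$fisher_p - 2 *
                    sqrt(resm$results$fisher_p / 2000) - 1e-9))
  expect_true(all(resm$results$a + resm$results$b == 100))
  expect_true(all(resm$results$c + resm$results$d == 100))

  expect_error(permutation_fwer(comp1, stats::setNames(rep("case", 10),
                                                       sprintf("t%04d", 1:10)),
                                n_perm = 2000, seed = 1),
               "validation error")
  expect_error(permutation_fwer(comp1, labels, n_perm = 500, seed = 1),
               "validation error")
})

test_that("a case-enriched locus is detected as the significant arg-max component", {
  # power check over replicate cohorts: one locus at case frequency 0.15,
  # absent in controls, among null background components
  labels <- make_labels(100, 100)
  ids <- names(labels)
  hits <- 0
  n_rep <- 20
  for (r in seq_len(n_rep)) {
    set.seed(200 + r)
    signal <- ids[1:100][runif(100) < 0.15]
    bg <- lapply(1:5, function(k) {
      keep <- runif(200) < 0.035
      ids[keep]
    })
    comp <- min_count_filter(make_components(labels, c(list(signal), bg)))
    res <- permutation_fwer(comp, labels, n_perm = 2000, seed = 200 + r)
    top <- which.max(res$results$neg_log10_p)
    if (res$results$chromosome[top] == "1" && res$results$significant[top])
      hits <- hits + 1
  }
  expect_gte(hits / n_rep, 0.9)
})

test_that("inflating only control carriers never lowers a Fisher p", {
  set.seed(91)
  for (rep in 1:50) {
    a <- sample(0:20, 1); b <- sample(1:50, 1)
    c0 <- sample(0:10, 1); d0 <- sample(5:50, 1)
    p0 <- fisher_one_sided(a, b, c0, d0)
    # add control carriers (from the control non-carrier pool)
    add <- sample(0:min(5, d0), 1)
    p1 <- fisher_one_sided(a, b, c0 + add, d0 - add)
    expect_gte(p1 + 1e-12, p0)
  }
})

test_that("candidate-region overlap counts match a quadratic oracle", {
  panel <- make_panel(1000)
  set.seed(95)
  calls <- do.call(rbind, lapply(1:40, function(k) {
    s <- sample(0:950, 1)
    make_call(panel, sprintf("t%02d", k), s, s + sample(5:40, 1))
  }))
  class(calls) <- c("denovo_calls", "data.frame")
  regions <- data.frame(name = sprintf("gene%02d", 1:15),
                        chromosome = sample(c("1", "2"), 15, replace = TRUE),
                        start_bp = sample(1:4500000, 15),
                        stringsAsFactors = FALSE)
  regions$end_bp <- regions$start_bp + sample(10000:500000, 15)
  got <- candidate_gene_scan(calls, regions)
  oracle <- vapply(seq_len(nrow(regions)), function(i)
    sum(vapply(seq_len(nrow(calls)), function(j)
      calls$chromosome[j] == regions$chromosome[i] &&
        calls$start_bp[j] <= regions$end_bp[i] &&
        calls$end_bp[j] >= regions$start_bp[i], NA)), 0L)
  expect_equal(got$n_de_novo, oracle)
  # a region on an empty chromosome counts zero
  expect_equal(got$n_de_novo[got$chromosome == "2"],
               rep(0L, sum(got$chromosome == "2")))
})
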