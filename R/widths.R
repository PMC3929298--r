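#' Deletion widths in kilobases
#'
#' Width of each call under the 1-based inclusive genomic span convention:
#' `(end_bp - start_bp + 1) / 1000`.
#'
#' @param calls A `denovo_calls` data.frame.
#' @return Numeric vector of widths in kb.
#' @export
widths_kb <- function(calls) {
  if (!nrow(calls)) return(numeric())
  (calls$end_bp - calls$start_bp + 1) / 1000
}

#' Round half away from zero
#'
#' Decimal rounding with halves rounded up (0.005 -> 0.01), the convention
#' used for the reported rate and proportion tables.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 0L) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Percent increase of the cleft median width over the control median
#'
#' `100 * (cleft_median / control_median - 1)`, rounded half-up to the
#' nearest percent for reporting.
#'
#' @param control_median,cleft_median Group median widths (kb).
#' @return Integer percent.
#' @export
percent_increase <- function(control_median, cleft_median) {
  round_half_up(100 * (cleft_median / control_median - 1))
}

#' Median deletion width by group and cleft type
#'
#' Pools all de novo call widths per group (`control`, `cleft`, and the
#' cleft-type strata `CL`, `CP`, `CLP`) and reports each group's median width
#' in kb plus the percent increase of the cleft median over the control
#' median. Empty groups are reported as `NA`.
#'
#' @param calls A `denovo_calls` data.frame.
#' @param labels Named character vector trio id -> `case`/`control`.
#' @param cleft_types Named character vector trio id -> `CL`/`CP`/`CLP`/`none`.
#' @return A list of class `width_table`: `medians_kb` (named vector),
#'   `percent_increase`, `n_calls` (named vector).
#' @export
median_width_table <- function(calls, labels, cleft_types) {
  w <- widths_kb(calls)
  grp <- labels[calls$trio_id]
  ct <- cleft_types[calls$trio_id]
  sel <- list(control = grp == "control", cleft = grp == "case",
              CL = ct == "CL", CP = ct == "CP", CLP = ct == "CLP")
  med <- vapply(sel, function(s) if (any(s)) stats::median(w[s]) else NA_real_, 0)
  n <- vapply(sel, sum, 0L)
  pct <- if (is.finite(med[["control"]]) && is.finite(med[["cleft"]]))
    percent_increase(med[["control"]], med[["cleft"]]) else NA_real_
  structure(list(medians_kb = med, percent_increase = pct, n_calls = n),
            class = "width_table")
}

#' @export
print.width_table <- function(x, ...) {
  cat("Median de novo deletion width (kb) by group:\n")
  print(data.frame(group = names(x$medians_kb),
                   n_calls = as.integer(x$n_calls),
                   median_kb = unname(x$medians_kb), row.names = NULL))
  if (is.finite(x$percent_increase))
    cat(sprintf("Cleft vs control median width increase: %d%%\n",
                as.integer(x$percent_increase)))
  invisible(x)
}

#' One-sided two-sample Kolmogorov-Smirnov test for wider cleft deletions
#'
#' Statistic `D = max_t (F_control(t) - F_cleft(t))`, positive when the cleft
#' widths are stochastically larger; p-value from [stats::ks.test()] with the
#' matching one-sided alternative (exact for small tie-free samples,
#' asymptotic otherwise).
#'
#' @param x_cleft,x_control Width vectors (kb).
#' @return List with `statistic` (D) and `p`.
#' @export
ks_one_sided <- function(x_cleft, x_control) {
  if (!length(x_cleft) || !length(x_control))
    stop("validation error: both samples must be non-empty")
  res <- suppressWarnings(stats::ks.test(x_control, x_cleft,
                                         alternative = "greater"))
  list(statistic = unname(res$statistic), p = res$p.value)
}

#' One-sided Wilcoxon rank-sum test for wider cleft deletions
#'
#' Rank-sum test with midranks for ties, alternative "cleft widths
#' stochastically larger". Uses the exact null distribution when the smaller
#' sample has at most 10 observations and the data are tie-free, exact
#' enumeration of label assignments when ties are present and the assignment
#' space is small, and otherwise the normal approximation with continuity and
#' tie correction.
#'
#' @param x_cleft,x_control Width vectors (kb).
#' @return List with `statistic` (the Mann-Whitney U of the cleft sample)
#'   and `p`.
#' @export
wilcoxon_one_sided <- function(x_cleft, x_control) {
  n1 <- length(x_cleft); n2 <- length(x_control)
  if (!n1 || !n2) stop("validation error: both samples must be non-empty")
  pooled <- c(x_cleft, x_control)
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(pooled))
  if (min(n1, n2) <= 10L && !ties) {
    p <- stats::pwilcox(U - 1, n1, n2, lower.tail = FALSE)
  } else if (ties && choose(n1 + n2, n1) <= 2e5) {
    combos <- utils::combn(n1 + n2, n1)
    u_all <- colSums(matrix(r[combos], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(u_all >= U)
  } else {
    mu <- n1 * n2 / 2
    n <- n1 + n2
    tie_counts <- table(pooled)
    sigma2 <- n1 * n2 / 12 * (n + 1 - sum(tie_counts^3 - tie_counts) / (n * (n - 1)))
    p <- stats::pnorm((U - mu - 0.5) / sqrt(sigma2), lower.tail = FALSE)
  }
  list(statistic = unname(U), p = min(1, p))
}

#' Simulated quantile-quantile null envelope for width comparison
#'
#' Pools the two width samples and repeatedly resplits the pool at random
#' (without replacement) into groups of the original sizes, recording each
#' split's QQ curve (control quantiles vs cleft quantiles on a fixed
#' 99-point probability grid, 0.01-0.99). The envelope is the pointwise
#' 2.5th/97.5th percentile band of the cleft-minus-control quantile
#' difference; the observed curve "exits" where its difference leaves that
#' band.
#'
#' @param x_cleft,x_control Width vectors (kb).
#' @param n_sim Number of null resplits (default 10000).
#' @param seed Integer seed.
#' @return A list of class `qq_envelope`: `grid`, `observed_control`,
#'   `observed_cleft`, `lower`, `upper` (bands on the quantile difference),
#'   `outside` (logical per grid point), `n_sim`, `seed`.
#' @export
qq_null_envelope <- function(x_cleft, x_control, n_sim = 10000L, seed = 1L) {
  if (!length(x_cleft) || !length(x_control))
    stop("validation error: both samples must be non-empty")
  if (n_sim < 100L) warning("n_sim below 100: envelope will be unstable")
  grid <- seq(0.01, 0.99, by = 0.01)
  n1 <- length(x_cleft); n2 <- length(x_control)
  pool <- c(x_cleft, x_control)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(.derive_seed(seed, 71L))
  diffs <- matrix(0, nrow = n_sim, ncol = length(grid))
  for (b in seq_len(n_sim)) {
    take <- sample.int(n1 + n2, n1)
    diffs[b, ] <- stats::quantile(pool[take], grid, names = FALSE) -
      stats::quantile(pool[-take], grid, names = FALSE)
  }
  lower <- apply(diffs, 2L, stats::quantile, 0.025, names = FALSE)
  upper <- apply(diffs, 2L, stats::quantile, 0.975, names = FALSE)
  qc <- stats::quantile(x_cleft, grid, names = FALSE)
  qn <- stats::quantile(x_control, grid, names = FALSE)
  obs_diff <- qc - qn
  structure(list(grid = grid, observed_control = qn, observed_cleft = qc,
                 lower = lower, upper = upper,
                 outside = obs_diff < lower | obs_diff > upper,
                 n_sim = n_sim, seed = seed),
            class = "qq_envelope")
}

#' @export
print.qq_envelope <- function(x, ...) {
  cat(sprintf("QQ null envelope (%d resplits): observed curve outside the 95%% band at %d of %d grid points\n",
              x$n_sim, sum(x$outside), length(x$grid)))
  invisible(x)
}

#' Plot a width QQ curve against its null envelope
#'
#' @param x A `qq_envelope` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.qq_envelope <- function(x, ...) {
  graphics::plot(x$observed_control, x$observed_cleft, type = "l", lwd = 2,
                 xlab = "control width quantiles (kb)",
                 ylab = "cleft width quantiles (kb)", ...)
  graphics::lines(x$observed_control, x$observed_control + x$lower, lty = 2)
  graphics::lines(x$observed_control, x$observed_control + x$upper, lty = 2)
  graphics::abline(0, 1, col = "grey60")
  invisible(x)
}
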