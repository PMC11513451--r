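test_that("identical replicates are all retained by correlation QC", {
  set.seed(1)
  base <- tibble::tibble(sequence = paste0("P", 1:50), intensity = rlnorm(50, 10, 1))
  peptides <- tidyr::crossing(base, condition = "digest", replicate = 1:4, time_s = 60)
  qc <- replicate_qc(peptides)
  expect_true(all(qc$retained))
  expect_true(all(qc$mean_r == 1))
})

test_that("an independent-noise replicate alone is removed", {
  set.seed(2)
  truth <- rlnorm(200, 10, 2)
  rows <- lapply(1:4, function(r) {
    tibble::tibble(
      sequence = paste0("P", 1:200), condition = "digest", replicate = r,
      time_s = 60,
      intensity = if (r < 4) truth * rlnorm(200, 0, 0.2) else rlnorm(200, 10, 2)
    )
  })
  peptides <- dplyr::bind_rows(rows)
  qc <- replicate_qc(peptides, pearson_cutoff = 0.4)
  expect_equal(qc$replicate[!qc$retained], 4L)
  # verify against direct correlation computation for the outlier
  m <- tidyr::pivot_wider(peptides, names_from = replicate, values_from = intensity)
  r4 <- mean(sapply(1:3, function(j) cor(log2(m[[as.character(j)]]), log2(m[["4"]]))))
  expect_lt(r4, 0.4)
  expect_equal(qc$mean_r[qc$replicate == 4], r4, tolerance = 1e-12)
})

test_that("a two-sample group below the cutoff is kept with a warning", {
  set.seed(3)
  peptides <- dplyr::bind_rows(
    tibble::tibble(
      sequence = paste0("P", 1:100), condition = "digest", replicate = 1L,
      time_s = 0, intensity = rlnorm(100, 8, 1)
    ),
    tibble::tibble(
      sequence = paste0("P", 1:100), condition = "digest", replicate = 2L,
      time_s = 0, intensity = rlnorm(100, 8, 1)
    )
  )
  expect_warning(qc <- replicate_qc(peptides, pearson_cutoff = 0.4), "keeping best")
  expect_true(all(qc$retained))
})

test_that("score filtering uses greater-or-equal semantics", {
  tbl <- tibble::tibble(sequence = c("A", "B", "C"), score = c(49.9, 50, 51))
  expect_equal(score_filter(tbl, 50)$score, c(50, 51))
  expect_equal(nrow(score_filter(tbl[0, ], 50)), 0L)
  set.seed(4)
  rnd <- tibble::tibble(sequence = paste0("P", 1:500), score = runif(500, 0, 120))
  expect_equal(
    sort(score_filter(rnd, 50)$sequence),
    sort(rnd$sequence[rnd$score >= 50])
  )
})

test_that("slope test: identical digest and control series is not relevant", {
  tp <- rep(c(0, 30, 60, 120, 300, 600), each = 4)
  set.seed(5)
  y <- rlnorm(length(tp), 10, 0.5)
  fit <- slope_homogeneity_test(
    c(tp, tp), c(y, y), rep(c("digest", "control"), each = length(tp))
  )
  expect_equal(unname(diff(fit$slopes$slope)), 0, tolerance = 1e-12)
  expect_gt(fit$p_value, 0.99)
  expect_false(fit$relevant)
})

test_that("slope test matches a hand-computed ANCOVA on constructed data", {
  tp <- rep(c(0, 15, 30, 60, 120, 180, 300, 600), each = 4)
  set.seed(6)
  digest <- 50 * tp + rnorm(length(tp), 0, 100)
  control <- abs(rnorm(length(tp), 0, 1)) # flat at ~0 plus tiny jitter
  fit <- slope_homogeneity_test(
    c(tp, tp), c(digest, control),
    rep(c("digest", "control"), each = length(tp))
  )
  expect_true(fit$testable)
  expect_lt(fit$p_value, 0.05)
  expect_equal(fit$df1, 1L)
  expect_equal(fit$df2, fit$n_obs - 4L)
  # independent oracle: explicit design-matrix least squares + F ratio
  y <- log2(pmax(c(digest, control), 0) + 1)
  t2 <- c(tp, tp)
  g <- rep(c(1, 0), each = length(tp))
  X_full <- cbind(1, t2, g, t2 * g)
  X_red <- cbind(1, t2, g)
  rss <- function(X) sum(stats::lsfit(X, y, intercept = FALSE)$residuals^2)
  f <- (rss(X_red) - rss(X_full)) / (rss(X_full) / (length(y) - 4))
  expect_equal(fit$f_statistic, f, tolerance = 1e-8)
  expect_equal(fit$p_value, stats::pf(f, 1, length(y) - 4, lower.tail = FALSE),
    tolerance = 1e-10
  )
})

test_that("slope test is symmetric in group labels and flags rank deficiency", {
  tp <- rep(c(0, 60, 300), each = 3)
  set.seed(7)
  a <- rlnorm(9, 8, 0.4)
  b <- rlnorm(9, 8, 0.4)
  f1 <- slope_homogeneity_test(c(tp, tp), c(a, b), rep(c("g1", "g2"), each = 9))
  f2 <- slope_homogeneity_test(c(tp, tp), c(b, a), rep(c("g1", "g2"), each = 9))
  expect_equal(f1$p_value, f2$p_value, tolerance = 1e-12)
  # single usable time point in one group -> not testable
  f3 <- slope_homogeneity_test(
    c(tp, rep(0, 4)), c(a, rlnorm(4, 8, 1)),
    c(rep("digest", 9), rep("control", 4))
  )
  expect_false(f3$testable)
  expect_true(is.na(f3$p_value))
})

test_that("per-time-point significance behaves at the extremes", {
  expect_false(as.logical(timepoint_significance(c(0, 0, 0, 0), c(0, 0, 0, 0))))
  set.seed(8)
  hit <- timepoint_significance(
    c(1000, 1100, 900, 1050), abs(rnorm(4, 0, 0.5))
  )
  expect_true(as.logical(hit))
  # oracle: direct one-sided Welch on the transformed values
  ctl <- c(0.1, 0.2, 0.05, 0.15)
  p_direct <- stats::t.test(
    log2(c(1000, 1100, 900, 1050) + 1), log2(ctl + 1),
    alternative = "greater"
  )$p.value
  expect_equal(
    attr(timepoint_significance(c(1000, 1100, 900, 1050), ctl), "p_value"),
    p_direct
  )
  # alpha = 1 accepts anything with a positive digest measurement
  expect_true(as.logical(timepoint_significance(c(5, 6), c(4, 5), alpha = 1)))
})

test_that("both tests hold their type-I error under the null", {
  set.seed(9)
  n_rep <- 400
  tp <- rep(c(0, 30, 60, 120, 300, 600), each = 4)
  rej_slope <- rej_welch <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    digest <- rlnorm(length(tp), 10, 0.5)
    control <- rlnorm(length(tp), 10, 0.5)
    fit <- slope_homogeneity_test(
      c(tp, tp), c(digest, control),
      rep(c("digest", "control"), each = length(tp))
    )
    rej_slope[i] <- fit$p_value < 0.05
    rej_welch[i] <- as.logical(
      timepoint_significance(rlnorm(4, 10, 0.5), rlnorm(4, 10, 0.5))
    )
  }
  expect_lt(abs(mean(rej_slope) - 0.05), 0.03)
  # one-sided test against an equal-mean control rejects at most ~alpha
  expect_lt(mean(rej_welch), 0.08)
})

test_that("the filter stack is a pure function of table and config", {
  gt <- scenario_pseudo_anxa1(n_molecules = 300)
  tab <- simulate_peptide_table(gt, time_points = c(0, 60, 600), seed = 3)
  run <- function() {
    qc <- replicate_qc(tab$peptides)
    ps <- score_filter(apply_qc(tab$peptides, qc), 50)
    peptide_relevance(ps)
  }
  expect_identical(run(), run())
})
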