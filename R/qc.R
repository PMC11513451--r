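#' Filtering configuration
#'
#' Bundles the filter-stack settings: significance level 0.05, minimum
#' identification score 50, replicate Pearson-correlation cutoff 0.4 and a
#' log2 intensity transform — the defaults used for targeted-proteolysis
#' analysis.
#'
#' @param alpha Significance level in (0, 1).
#' @param min_score Minimum identification score retained.
#' @param pearson_cutoff Replicate mean-correlation cutoff in `[-1, 1]`.
#' @param transform `"log2"` or `"none"`.
#' @param adjust P-value adjustment for the slope test across peptides
#'   (`"none"` by default; `"BH"` for Benjamini-Hochberg).
#' @param both_bonds Should a peptide's ratio count toward both of its
#'   bounding scissile bonds (default) or only the C-terminal (P1 = end) bond?
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(alpha = 0.05, min_score = 50, pearson_cutoff = 0.4,
                          transform = c("log2", "none"), adjust = "none",
                          both_bonds = TRUE) {
  transform <- match.arg(transform)
  stopifnot(alpha > 0, alpha < 1, pearson_cutoff >= -1, pearson_cutoff <= 1)
  structure(
    list(
      alpha = alpha, min_score = min_score, pearson_cutoff = pearson_cutoff,
      transform = transform, adjust = adjust, both_bonds = both_bonds
    ),
    class = "filter_config"
  )
}

# log2 with zeros/negatives treated as missing (dropout = non-detection);
# used for replicate correlations, where only jointly detected values count.
transform_positive <- function(x, transform) {
  x[!is.na(x) & x <= 0] <- NA_real_
  if (transform == "log2") log2(x) else x
}

# log2(x + 1) keeping zeros as floor-level measurements; used by the tests,
# where protease-free controls are structurally zero. "none" is the identity.
transform_floor <- function(x, transform) {
  if (transform == "log2") log2(pmax(x, 0) + 1) else x
}

#' Replicate quality control by pairwise Pearson correlation
#'
#' Within each (condition, time point) group, each sample is correlated with
#' every other sample of the group on jointly detected, transformed peptide
#' intensities. Samples whose mean pairwise correlation falls below the
#' cutoff are flagged for exclusion. If exclusion would leave fewer than two
#' samples in a group, the best sample(s) are kept with a warning.
#'
#' @param peptides Long peptide table (`sequence`, `condition`, `replicate`,
#'   `time_s`, `intensity`).
#' @param pearson_cutoff Mean-correlation cutoff (default 0.4).
#' @param transform `"log2"` (default) or `"none"`.
#' @return A tibble with one row per sample: `condition`, `time_s`,
#'   `replicate`, `mean_r`, `n_pairs`, `retained`. Groups where too few
#'   peptides are jointly detected to compute a correlation are retained with
#'   `mean_r = NA`.
#' @export
replicate_qc <- function(peptides, pearson_cutoff = 0.4,
                         transform = c("log2", "none")) {
  transform <- match.arg(transform)
  groups <- peptides |>
    distinct(.data$condition, .data$time_s) |>
    arrange(.data$condition, .data$time_s)
  out <- pmap(groups, function(condition, time_s) {
    g <- peptides[peptides$condition == condition & peptides$time_s == time_s, ]
    mat <- g |>
      select("sequence", "replicate", "intensity") |>
      pivot_wider(names_from = "replicate", values_from = "intensity") |>
      select(-"sequence") |>
      as.matrix()
    mat <- transform_positive(mat, transform)
    reps <- as.integer(colnames(mat))
    k <- length(reps)
    mean_r <- rep(NA_real_, k)
    n_pairs <- rep(0L, k)
    if (k >= 2L) {
      rmat <- matrix(NA_real_, k, k)
      for (i in seq_len(k - 1L)) {
        for (j in (i + 1L):k) {
          ok <- complete.cases(mat[, c(i, j)])
          if (sum(ok) >= 3L && stats::sd(mat[ok, i]) > 0 && stats::sd(mat[ok, j]) > 0) {
            rmat[i, j] <- rmat[j, i] <- cor(mat[ok, i], mat[ok, j])
          }
        }
      }
      mean_r <- rowMeans(rmat, na.rm = TRUE)
      mean_r[is.nan(mean_r)] <- NA_real_
      n_pairs <- rowSums(!is.na(rmat))
    }
    retained <- is.na(mean_r) | mean_r >= pearson_cutoff
    if (sum(retained) < min(2L, k)) {
      keep_n <- min(2L, k)
      best <- order(mean_r, decreasing = TRUE)[seq_len(keep_n)]
      retained[best] <- TRUE
      warn(paste0(
        "replicate QC would leave <2 samples for ", condition, " t=", time_s,
        "; keeping best ", keep_n, " despite mean r below cutoff"
      ))
    }
    tibble(
      condition = condition, time_s = time_s, replicate = reps,
      mean_r = mean_r, n_pairs = n_pairs, retained = retained
    )
  })
  bind_rows(out)
}

#' Drop samples flagged by replicate QC
#'
#' @param peptides Long peptide table.
#' @param qc Output of [replicate_qc()].
#' @return The peptide table restricted to retained samples.
#' @export
apply_qc <- function(peptides, qc) {
  keep <- filter(qc, .data$retained) |>
    select("condition", "time_s", "replicate")
  inner_join(peptides, keep, by = c("condition", "time_s", "replicate"))
}

#' Filter peptides by identification score
#'
#' @param peptides Table with a `score` column.
#' @param min_score Minimum score; peptides with `score >= min_score` are kept.
#' @return Filtered tibble.
#' @export
score_filter <- function(peptides, min_score = 50) {
  as_tibble(filter(peptides, .data$score >= min_score))
}

#' Homogeneity-of-regression-slope test for one peptide
#'
#' Identifies relevant proteolytic products: a peptide whose (transformed)
#' intensity grows over digestion time while staying flat in protease-free
#' controls has a digest slope different from its control slope. Classical
#' ANCOVA is fitted by least squares, `y ~ time * group`, and the p-value of
#' the interaction (slope-difference) F-test with 1 and n - 4 degrees of
#' freedom is returned. With `transform = "log2"` intensities enter as
#' `log2(x + 1)`, so the structural zeros of protease-free control samples act
#' as floor-level measurements rather than being dropped; missing cells (`NA`)
#' are excluded.
#'
#' @param time Numeric vector of sampling times.
#' @param intensity Intensity measurements (same length).
#' @param group Factor/character distinguishing digest from control.
#' @param alpha Significance level used to call the peptide relevant.
#' @param transform `"log2"` (default) or `"none"`.
#' @return An object of class `slope_homogeneity` with the interaction
#'   F statistic, degrees of freedom, p-value, per-group slopes and the
#'   relevance call; `tidy()` and `glance()` methods are provided. If the
#'   design is rank-deficient (a single usable time point in a group) the
#'   peptide is flagged not testable and `p_value` is `NA`.
#' @examples
#' tp <- rep(c(0, 60, 120, 300), each = 2)
#' y <- c(0, 0, 4, 5, 8, 9, 20, 22) + 1
#' fit <- slope_homogeneity_test(
#'   rep(tp, 2), c(y, rep(1, 8)),
#'   rep(c("digest", "control"), each = 8)
#' )
#' glance(fit)
#' @export
slope_homogeneity_test <- function(time, intensity, group, alpha = 0.05,
                                   transform = c("log2", "none")) {
  transform <- match.arg(transform)
  y <- transform_floor(as.numeric(intensity), transform)
  d <- tibble(time = as.numeric(time), y = y, group = as.character(group)) |>
    filter(!is.na(.data$y))
  testable <- length(unique(d$group)) == 2L &&
    all(tapply(d$time, d$group, function(t) length(unique(t))) >= 2L) &&
    nrow(d) >= 5L
  out <- list(
    f_statistic = NA_real_, df1 = NA_integer_, df2 = NA_integer_,
    p_value = NA_real_, slopes = NULL, n_obs = nrow(d),
    alpha = alpha, relevant = FALSE, testable = testable
  )
  if (testable) {
    fit <- lm(y ~ time * group, data = d)
    an <- anova(fit)
    row <- grep(":", rownames(an))
    f <- an[row, "F value"]
    df1 <- an[row, "Df"]
    df2 <- an["Residuals", "Df"]
    coefs <- stats::coef(fit)
    g2 <- sort(unique(d$group))[2]
    out$f_statistic <- f
    out$df1 <- df1
    out$df2 <- df2
    out$p_value <- an[row, "Pr(>F)"]
    out$slopes <- tibble(
      group = sort(unique(d$group)),
      slope = c(coefs[["time"]], coefs[["time"]] + coefs[[paste0("time:group", g2)]])
    )
    out$relevant <- isTRUE(out$p_value < alpha)
  }
  structure(out, class = "slope_homogeneity")
}

#' @export
print.slope_homogeneity <- function(x, ...) {
  if (!x$testable) {
    cat("<slope_homogeneity> not testable (rank-deficient design)\n")
  } else {
    cat(sprintf(
      "<slope_homogeneity> F(%d, %d) = %.3f, p = %.4g, %s at alpha = %g\n",
      x$df1, x$df2, x$f_statistic, x$p_value,
      if (x$relevant) "relevant" else "not relevant", x$alpha
    ))
  }
  invisible(x)
}

#' @export
tidy.slope_homogeneity <- function(x, ...) {
  slopes <- x$slopes %||% tibble(group = character(), slope = numeric())
  bind_rows(
    tibble(
      term = paste0("slope_", slopes$group),
      estimate = slopes$slope, statistic = NA_real_, p.value = NA_real_
    ),
    tibble(
      term = "slope_difference",
      estimate = if (nrow(slopes) == 2L) diff(slopes$slope) else NA_real_,
      statistic = x$f_statistic, p.value = x$p_value
    )
  )
}

#' @export
glance.slope_homogeneity <- function(x, ...) {
  tibble(
    f_statistic = x$f_statistic, df1 = x$df1, df2 = x$df2,
    p_value = x$p_value, n_obs = x$n_obs, alpha = x$alpha,
    relevant = x$relevant, testable = x$testable
  )
}

#' Slope-homogeneity relevance call for every peptide in a table
#'
#' @param peptides Long peptide table with `sequence`, `time_s`, `intensity`,
#'   `is_control` columns.
#' @param alpha Significance level.
#' @param transform `"log2"` or `"none"`.
#' @param adjust P-value adjustment method passed to [stats::p.adjust()]
#'   (`"none"` by default).
#' @return A tibble with one row per peptide: `sequence`, `f_statistic`,
#'   `p_value`, `p_adjusted`, `testable`, `relevant`.
#' @export
peptide_relevance <- function(peptides, alpha = 0.05,
                              transform = c("log2", "none"), adjust = "none") {
  transform <- match.arg(transform)
  res <- peptides |>
    group_by(.data$sequence) |>
    group_modify(function(d, key) {
      fit <- slope_homogeneity_test(
        d$time_s, d$intensity,
        ifelse(d$is_control, "control", "digest"),
        alpha = alpha, transform = transform
      )
      tibble(
        f_statistic = fit$f_statistic, p_value = fit$p_value,
        testable = fit$testable
      )
    }) |>
    ungroup()
  res$p_adjusted <- stats::p.adjust(res$p_value, method = adjust)
  res$relevant <- !is.na(res$p_adjusted) & res$p_adjusted < alpha
  res
}

#' Per-time-point significance of a peptide against controls
#'
#' One-sided Welch two-sample t test of digest over control intensities
#' (products can only be enriched in the digest). Intensities enter on a
#' `log2(x + 1)` scale so that the structural zeros of protease-free controls
#' act as floor-level measurements. Used downstream to zero the average
#' intensity of a peptide at time points where it is not significantly above
#' control.
#'
#' @param digest Numeric digest replicate intensities at one time point.
#' @param control Numeric control intensities.
#' @param alpha Significance level.
#' @param transform `"log2"` (default, `log2(x + 1)`) or `"none"`.
#' @return `TRUE` iff the one-sided p-value is below `alpha`; the p-value is
#'   attached as attribute `p_value`. All-zero (or missing) digest values give
#'   `FALSE`.
#' @export
timepoint_significance <- function(digest, control, alpha = 0.05,
                                   transform = c("log2", "none")) {
  transform <- match.arg(transform)
  digest <- digest[!is.na(digest)]
  control <- control[!is.na(control)]
  if (length(digest) == 0L || all(digest <= 0)) {
    return(structure(FALSE, p_value = 1))
  }
  if (length(control) == 0L) {
    abort("control intensities are required for timepoint_significance")
  }
  d <- transform_floor(digest, transform)
  ctl <- transform_floor(control, transform)
  p <- tryCatch(
    stats::t.test(d, ctl, alternative = "greater", var.equal = FALSE)$p.value,
    error = function(e) {
      # both groups essentially constant: decide by the means
      if (mean(d) > mean(ctl)) 0 else 1
    }
  )
  structure(p < alpha, p_value = p)
}
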