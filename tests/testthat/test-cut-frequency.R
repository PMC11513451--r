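# Build a long table where per-time digest averages are exact by construction
# (identical replicates, controls zero).
series_table <- function(peptide_defs, time_points) {
  rows <- lapply(names(peptide_defs), function(sq) {
    def <- peptide_defs[[sq]]
    make_peptide_series(
      sq, time_points,
      digest = matrix(rep(def$avg, each = 4), nrow = 4),
      control = matrix(0, nrow = 4, ncol = length(time_points)),
      start = def$start, end = def$end
    )
  })
  dplyr::bind_rows(rows)
}

test_that("averages use zero-filled means and the significance gate", {
  tp <- c(0, 60, 120)
  tbl <- make_peptide_series("PEPA", tp,
    digest = rbind(
      c(0, 200, 100), c(0, 0, 100), c(0, 200, 100), c(0, 0, 100)
    ),
    control = matrix(0, 4, 3), start = 2, end = 5
  )
  avg <- average_intensities(tbl, alpha = 0.1)
  expect_equal(avg$avg, c(0, 100, 100)) # zero-fill mean: (200+0+200+0)/4
  # a non-significant time point is zeroed even with positive intensities
  tb2 <- make_peptide_series("PEPB", c(0, 60),
    digest = rbind(c(0, 100), c(0, 110), c(0, 90), c(0, 105)),
    control = rbind(c(0, 100), c(0, 110), c(0, 90), c(0, 105))
  )
  avg2 <- average_intensities(tb2)
  expect_equal(avg2$avg[avg2$time_s == 60], 0)
  expect_false(avg2$significant[avg2$time_s == 60])
})

test_that("intensity ratios reference the first positive average", {
  r1 <- intensity_ratios(tibble::tibble(
    sequence = "X", time_s = c(0, 1, 2, 3), avg = c(0, 100, 200, 100)
  ))
  expect_equal(r1$ratio, c(0, 1, 2, 1))
  r2 <- intensity_ratios(tibble::tibble(
    sequence = "X", time_s = 1:3, avg = c(50, 50, 0)
  ))
  expect_equal(r2$ratio, c(1, 1, 0))
  r3 <- intensity_ratios(tibble::tibble(
    sequence = "X", time_s = 1:3, avg = c(0, 0, 0)
  ))
  expect_equal(r3$ratio, c(0, 0, 0))
})

test_that("site frequencies sum supporting peptides' ratios per bond", {
  sub <- make_substrate(60, seed = 11)
  tp <- c(0, 60, 120)
  # two peptides ending at P1 = 41, ratio series [0,1,2] and [1,1,0]
  tbl <- series_table(list(
    PEP1 = list(avg = c(0, 100, 200), start = 30, end = 41),
    PEP2 = list(avg = c(50, 50, 0), start = 33, end = 41)
  ), tp)
  coords <- dplyr::distinct(tbl, sequence, start, end)
  prof <- relative_cut_frequency(tbl, sub)
  s41 <- dplyr::filter(tibble::as_tibble(prof), p1 == 41)
  expect_equal(s41$frequency, c(1, 2, 2))
  # the peptides also evidence their N-terminal bonds
  expect_equal(
    dplyr::filter(tibble::as_tibble(prof), p1 == 29)$frequency, c(0, 1, 2)
  )
  # c-terminal-only mode drops N-terminal support
  prof_c <- relative_cut_frequency(tbl, sub, both_bonds = FALSE)
  expect_false(29 %in% prof_c$p1)
})

test_that("frequencies equal a brute-force (peptide, bond, ratio) enumeration", {
  sub <- make_substrate(120, seed = 12)
  set.seed(13)
  tp <- c(0, 30, 60, 300, 600)
  defs <- list()
  for (i in 1:40) {
    s <- sample(1:110, 1)
    e <- min(s + sample(6:24, 1), 120)
    avg <- round(rlnorm(length(tp), 6, 1)) * rbinom(length(tp), 1, 0.7)
    defs[[sprintf("P%02d_%d_%d", i, s, e)]] <- list(avg = avg, start = s, end = e)
  }
  tbl <- series_table(defs, tp)
  prof <- relative_cut_frequency(tbl, sub)
  # oracle: explicit loop over peptides, bonds and time points
  oracle <- list()
  for (nm in names(defs)) {
    avg <- defs[[nm]]$avg
    ref <- which(avg > 0)[1]
    ratio <- if (is.na(ref)) rep(0, length(tp)) else avg / avg[ref]
    ratio[avg == 0] <- 0
    bonds <- c(
      if (defs[[nm]]$start > 1) defs[[nm]]$start - 1,
      if (defs[[nm]]$end < sub$length) defs[[nm]]$end
    )
    for (b in bonds) {
      key <- as.character(b)
      oracle[[key]] <- (oracle[[key]] %||% rep(0, length(tp))) + ratio
    }
  }
  for (key in names(oracle)) {
    got <- dplyr::filter(tibble::as_tibble(prof), p1 == as.integer(key))
    if (all(oracle[[key]] == 0)) {
      expect_equal(nrow(got), 0L)
    } else {
      expect_equal(got$frequency, oracle[[key]], tolerance = 1e-9)
    }
  }
})

test_that("frequencies are invariant to rescaling a peptide's intensities", {
  sub <- make_substrate(60, seed = 14)
  tp <- c(0, 60, 120)
  t1 <- series_table(list(A = list(avg = c(0, 40, 80), start = 10, end = 20)), tp)
  t2 <- series_table(list(A = list(avg = c(0, 40, 80) * 37, start = 10, end = 20)), tp)
  p1 <- tibble::as_tibble(relative_cut_frequency(t1, sub))
  p2 <- tibble::as_tibble(relative_cut_frequency(t2, sub))
  expect_equal(p1, p2)
})

test_that("frequencies are additive over disjoint peptide subsets", {
  sub <- make_substrate(100, seed = 15)
  tp <- c(0, 60, 300)
  defs <- list(
    A = list(avg = c(0, 10, 30), start = 5, end = 20),
    B = list(avg = c(5, 10, 20), start = 12, end = 20),
    C = list(avg = c(0, 0, 50), start = 21, end = 33)
  )
  all_prof <- tibble::as_tibble(relative_cut_frequency(series_table(defs, tp), sub))
  part1 <- tibble::as_tibble(relative_cut_frequency(series_table(defs["A"], tp), sub))
  part2 <- tibble::as_tibble(relative_cut_frequency(series_table(defs[c("B", "C")], tp), sub))
  merged <- dplyr::bind_rows(part1, part2) |>
    dplyr::group_by(p1, time_s) |>
    dplyr::summarise(frequency = sum(frequency), .groups = "drop")
  joined <- dplyr::inner_join(all_prof, merged, by = c("p1", "time_s"))
  expect_equal(nrow(joined), nrow(all_prof))
  expect_equal(joined$frequency.x, joined$frequency.y, tolerance = 1e-12)
})

test_that("site classification matches brute-force binning for both presets", {
  expect_equal(
    classify_sites(
      tibble::tibble(p1 = 1L, time_s = 1, frequency = 20),
      class_edges("anxa1")
    )$class_rank, 1L
  )
  zero <- classify_sites(
    tibble::tibble(p1 = 1L, time_s = 1, frequency = 0), class_edges("anxa1")
  )
  expect_equal(as.character(zero$class), "undetected")
  set.seed(16)
  prof <- tibble::tibble(
    p1 = rep(1:500, each = 2), time_s = rep(c(1, 2), 500),
    frequency = runif(1000, 0, 40)
  )
  for (preset in c("anxa1", "mdh")) {
    edges <- class_edges(preset)
    got <- classify_sites(prof, edges)
    mx <- tapply(prof$frequency, prof$p1, max)
    expected <- vapply(mx, function(m) {
      b <- findInterval(m, edges$lower)
      if (b == 0) "undetected" else edges$labels[b]
    }, character(1))
    expect_equal(as.character(got$class), unname(expected[as.character(got$p1)]))
  }
})

test_that("cut histograms bin frequencies and the Cls track is monotone", {
  prof <- tibble::tibble(
    p1 = c(10L, 20L, 30L), time_s = 1, frequency = c(5, 15, 25)
  )
  h <- cut_histogram(prof, 1, bin_width = 10)
  expect_equal(h$n_sites, c(1L, 1L, 1L))
  expect_equal(h$bin_start, c(0, 10, 20))
  zero <- cut_histogram(
    tibble::tibble(p1 = 1L, time_s = 1, frequency = 0), 1, 10
  )
  expect_equal(zero$n_sites, 1L)
  expect_equal(nrow(zero), 1L)
  # cumulative distinct-site count never decreases (noise-free simulation)
  gt <- scenario_pseudo_anxa1(n_molecules = 500)
  tab <- suppressWarnings(simulate_peptide_table(
    gt,
    time_points = c(0, 15, 60, 300, 1800),
    sigma_lognormal = 0, dropout_probability = 0,
    score_range = c(100, 100), seed = 17
  ))
  pm <- suppressWarnings(map_peptides(tab$peptides, gt$substrate))
  prof2 <- relative_cut_frequency(pm, gt$substrate)
  expect_true(all(diff(cls_track(prof2)$n_sites) >= 0))
})

test_that("the figure-style track prints frequencies under residues", {
  sub <- make_substrate(25, seed = 18)
  prof <- structure(
    tibble::tibble(p1 = 10L, time_s = c(15, 60), frequency = c(2.4, 7.6)),
    time_points = c(15, 60)
  )
  lines <- format_site_track(prof, sub, block = 25L)
  expect_length(lines, 4L) # sequence + 2 time rows + blank
  expect_match(lines[2], "2")
  expect_match(lines[3], "8") # rounded 7.6
})
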