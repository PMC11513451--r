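#' Per-time-point average intensities for each peptide
#'
#' For each peptide and time point the digest intensities are averaged over
#' retained replicates, counting non-detections as 0. The average is then set
#' to zero at any time point where the peptide's intensities are not
#' significantly above the protease-free controls (one-sided Welch test, see
#' [timepoint_significance()]). If the table carries no control samples the
#' significance gate is skipped with a warning and any positive average is
#' kept.
#'
#' @param peptides Long peptide table with `sequence`, `condition`,
#'   `replicate`, `time_s`, `intensity`, `is_control` (QC-filtered; see
#'   [apply_qc()]).
#' @param alpha Significance level for the per-time-point test.
#' @return A tibble with `sequence`, `time_s`, `avg`, `significant`,
#'   `n_replicates`.
#' @export
average_intensities <- function(peptides, alpha = 0.05) {
  has_controls <- any(peptides$is_control)
  if (!has_controls) {
    warn("no control samples found; per-time-point significance gate disabled")
  }
  digest <- filter(peptides, !.data$is_control)
  controls <- filter(peptides, .data$is_control)
  out <- digest |>
    group_by(.data$sequence, .data$time_s) |>
    summarise(
      avg = mean(replace_na(.data$intensity, 0)),
      n_replicates = dplyr::n(),
      .groups = "drop"
    )
  if (has_controls) {
    sig <- digest |>
      group_by(.data$sequence, .data$time_s) |>
      group_modify(function(d, key) {
        ctl <- controls$intensity[
          controls$sequence == key$sequence & controls$time_s == key$time_s
        ]
        tibble(significant = as.logical(
          timepoint_significance(d$intensity, ctl, alpha = alpha)
        ))
      }) |>
      ungroup()
    out <- left_join(out, sig, by = c("sequence", "time_s")) |>
      mutate(
        significant = replace_na(.data$significant, FALSE),
        avg = ifelse(.data$significant, .data$avg, 0)
      )
  } else {
    out$significant <- out$avg > 0
  }
  arrange(out, .data$sequence, .data$time_s)
}

#' Average-intensity ratios along the time course
#'
#' For each peptide, ratios are taken against the first average intensity
#' greater than zero along the (ascending) time points: the ratio is
#' `avg_t / avg_ref`, 0 before the reference time and wherever the average is
#' zero; an all-zero series yields all-zero ratios.
#'
#' @param averages Output of [average_intensities()] (columns `sequence`,
#'   `time_s`, `avg`).
#' @return The input with a `ratio` column added.
#' @examples
#' a <- tibble::tibble(sequence = "PEP", time_s = c(0, 60, 120, 300),
#'                     avg = c(0, 100, 200, 100))
#' intensity_ratios(a)$ratio # 0 1 2 1
#' @export
intensity_ratios <- function(averages) {
  averages |>
    group_by(.data$sequence) |>
    arrange(.data$time_s, .by_group = TRUE) |>
    mutate(
      ratio = {
        ref <- which(.data$avg > 0)[1]
        if (is.na(ref)) rep(0, dplyr::n()) else .data$avg / .data$avg[ref]
      }
    ) |>
    ungroup() |>
    arrange(.data$sequence, .data$time_s)
}

#' Relative frequency of cuts at each P1 site over time
#'
#' The central per-site statistic: peptides sharing the same P1-P1' scissile
#' bond are grouped, and the relative frequency of cuts at a P1 site at a time
#' point is the sum of the average-intensity ratios (see [intensity_ratios()])
#' of all peptides sharing that site. An internal peptide evidences two bonds
#' -- the cut ahead of its first residue (P1 = start - 1) and the cut at its
#' last residue (P1 = end) -- and by default contributes its ratio to both;
#' `both_bonds = FALSE` restricts support to the C-terminal bond.
#'
#' @param peptides Long mapped, filtered peptide table (columns `sequence`,
#'   `start`, `end`, `condition`, `replicate`, `time_s`, `intensity`,
#'   `is_control`).
#' @param substrate A [substrate_protein()].
#' @param alpha Significance level for the per-time-point gate.
#' @param both_bonds Count each peptide toward both bounding bonds (default)
#'   or only its C-terminal bond.
#' @param ratios Optional precomputed ratio table (as from
#'   [intensity_ratios()]); when supplied, `alpha` is ignored.
#' @return A tibble of class `site_profiles`: `p1`, `time_s`, `frequency`,
#'   `n_peptides` (supporting peptides with nonzero ratio at that time).
#'   Sites never reaching a positive frequency are omitted. Attributes:
#'   `substrate`, `time_points`, `onsets` (per-site first positive time).
#' @export
relative_cut_frequency <- function(peptides, substrate, alpha = 0.05,
                                   both_bonds = TRUE, ratios = NULL) {
  if (is.null(ratios)) {
    ratios <- peptides |>
      average_intensities(alpha = alpha) |>
      intensity_ratios()
  }
  coords <- distinct(peptides, .data$sequence, .data$start, .data$end)
  ratios <- inner_join(ratios, coords, by = "sequence")
  bonds <- peptide_bonds(ratios, substrate$length, both_bonds = both_bonds)
  profiles <- bonds |>
    group_by(.data$p1, .data$time_s) |>
    summarise(
      frequency = sum(.data$ratio),
      n_peptides = sum(.data$ratio > 0),
      .groups = "drop"
    ) |>
    group_by(.data$p1) |>
    filter(any(.data$frequency > 0)) |>
    ungroup() |>
    arrange(.data$p1, .data$time_s)
  onsets <- profiles |>
    filter(.data$frequency > 0) |>
    group_by(.data$p1) |>
    summarise(onset_time = min(.data$time_s), .groups = "drop")
  structure(
    profiles,
    substrate = substrate,
    time_points = sort(unique(ratios$time_s)),
    onsets = onsets,
    class = c("site_profiles", class(profiles))
  )
}

#' @export
glance.site_profiles <- function(x, ...) {
  tibble(
    n_sites = n_distinct(x$p1),
    n_time_points = length(attr(x, "time_points")),
    max_frequency = max(x$frequency),
    first_onset = min(attr(x, "onsets")$onset_time)
  )
}

#' Per-site onset times
#'
#' @param profiles A [relative_cut_frequency()] result.
#' @return Tibble `p1`, `onset_time` (first time point with positive frequency).
#' @export
site_onsets <- function(profiles) {
  attr(profiles, "onsets")
}

#' Class edges for binning sites by maximum cut frequency
#'
#' Presets follow the histogram-based classes used for the two model
#' substrates: a conformation-selective protease on a helical substrate
#' (`"anxa1"`: undetected, 1-10, 11-19, >= 20) and a sequence-selective
#' protease (`"mdh"`: undetected, 1-20, 21-30, >= 30).
#'
#' @param preset `"anxa1"` or `"mdh"`.
#' @return List with `lower` (ascending lower bin bounds above the undetected
#'   class) and `labels`.
#' @export
class_edges <- function(preset = c("anxa1", "mdh")) {
  preset <- match.arg(preset)
  if (preset == "anxa1") {
    list(lower = c(1, 11, 20), labels = c("1-10", "11-19", ">=20"))
  } else {
    list(lower = c(1, 21, 30), labels = c("1-20", "21-30", ">=30"))
  }
}

#' Classify P1 sites by their maximum relative cut frequency
#'
#' Sites are binned by the maximum of their frequency profile across time into
#' half-open classes defined by ascending lower bounds; anything below the
#' first bound is "undetected".
#'
#' @param profiles A [relative_cut_frequency()] result (or a tibble with
#'   `p1`, `time_s`, `frequency`).
#' @param edges A list as from [class_edges()], or a numeric vector of
#'   ascending lower bounds.
#' @return Tibble `p1`, `max_frequency`, `class` (factor, highest class
#'   first), `class_rank` (1 = highest class, matching the narrative "class 1").
#' @export
classify_sites <- function(profiles, edges = class_edges("anxa1")) {
  if (is.numeric(edges)) edges <- list(lower = edges, labels = paste0(">=", edges))
  lv <- c(rev(edges$labels), "undetected")
  profiles |>
    group_by(.data$p1) |>
    summarise(max_frequency = max(.data$frequency), .groups = "drop") |>
    mutate(
      bin = findInterval(.data$max_frequency, edges$lower),
      class = factor(
        ifelse(.data$bin == 0L, "undetected", edges$labels[.data$bin]),
        levels = rev(lv)
      ),
      class_rank = length(edges$lower) + 1L - .data$bin
    ) |>
    select("p1", "max_frequency", "class", "class_rank")
}

#' Histogram of cut frequencies at one time point
#'
#' @param profiles A [relative_cut_frequency()] result.
#' @param time_point Time point (seconds) at which to bin.
#' @param bin_width Frequency bin width.
#' @return Tibble `bin_start`, `bin_end` (half-open bins `[start, end)`),
#'   `n_sites`. Sites with frequency exactly 0 at this time point fall in the
#'   first bin.
#' @export
cut_histogram <- function(profiles, time_point, bin_width = 10) {
  f <- profiles$frequency[profiles$time_s == time_point]
  if (length(f) == 0L) f <- numeric()
  top <- if (length(f) > 0L) max(f) else 0
  breaks <- seq(0, (floor(top / bin_width) + 1) * bin_width, by = bin_width)
  idx <- findInterval(f, breaks, rightmost.closed = FALSE)
  tibble(
    bin_start = breaks[-length(breaks)],
    bin_end = breaks[-1],
    n_sites = as.integer(tabulate(idx, nbins = length(breaks) - 1L))
  )
}

#' Cumulative distinct cleavage-site count per time point
#'
#' The "Cls" coverage track: the number of distinct P1 sites with a positive
#' frequency at or before each time point; non-decreasing by construction.
#'
#' @param profiles A [relative_cut_frequency()] result.
#' @return Tibble `time_s`, `n_sites`.
#' @export
cls_track <- function(profiles) {
  times <- attr(profiles, "time_points") %||% sort(unique(profiles$time_s))
  onsets <- profiles |>
    filter(.data$frequency > 0) |>
    group_by(.data$p1) |>
    summarise(onset = min(.data$time_s), .groups = "drop")
  tibble(
    time_s = times,
    n_sites = map_int(times, ~ sum(onsets$onset <= .x))
  )
}

#' Figure-style per-residue frequency track
#'
#' Renders the substrate sequence in fixed-width blocks with, beneath each
#' residue, its (integer-rounded) relative cut frequency at each time point --
#' the text analogue of the per-residue figure tracks.
#'
#' @param profiles A [relative_cut_frequency()] result.
#' @param substrate A [substrate_protein()].
#' @param time_points Times to print (default: all).
#' @param block Residues per line block.
#' @return Character vector of lines (invisibly printable via `cat`).
#' @export
format_site_track <- function(profiles, substrate,
                              time_points = attr(profiles, "time_points"),
                              block = 20L) {
  L <- substrate$length
  res <- strsplit(substrate$sequence, "")[[1]]
  freq <- matrix(0, nrow = length(time_points), ncol = L,
                 dimnames = list(paste0("t", time_points), NULL))
  for (i in seq_along(time_points)) {
    sel <- profiles[profiles$time_s == time_points[i], ]
    freq[i, sel$p1] <- sel$frequency
  }
  lines <- character()
  width <- 4L
  for (s in seq(1L, L, by = block)) {
    e <- min(s + block - 1L, L)
    idx <- s:e
    lines <- c(lines, paste0(
      sprintf("%6s  ", s),
      paste(formatC(res[idx], width = width), collapse = "")
    ))
    for (i in seq_along(time_points)) {
      vals <- round(freq[i, idx])
      cells <- ifelse(vals > 0, formatC(vals, width = width), strrep(" ", width))
      lines <- c(lines, paste0(
        sprintf("%6s  ", paste0("t", time_points[i])),
        paste(cells, collapse = "")
      ))
    }
    lines <- c(lines, "")
  }
  lines
}
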