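specificity_positions <- function(width = 5L) {
  c(paste0("P", width:1), paste0("P", 1:width, "'"))
}

#' Extract the sequence window around a scissile bond
#'
#' Returns the residues occupying positions P<width>..P1 (N-terminal to the
#' bond, P1 nearest) and P1'..P<width>' (C-terminal). Positions beyond the
#' chain termini are padded with `"-"`.
#'
#' @param p1 P1 residue position (`1 <= p1 < length`).
#' @param substrate A [substrate_protein()].
#' @param width Residues on each side (default 5).
#' @return Named character vector of `2 * width` single-letter symbols.
#' @export
extract_window <- function(p1, substrate, width = 5L) {
  p1 <- as.integer(p1)
  if (p1 < 1L || p1 >= substrate$length) {
    abort("p1 must satisfy 1 <= p1 < substrate length")
  }
  pos <- c((p1 - width + 1L):p1, (p1 + 1L):(p1 + width))
  res <- ifelse(
    pos >= 1L & pos <= substrate$length,
    substring(substrate$sequence, pmax(pos, 1L), pmax(pos, 1L)),
    "-"
  )
  setNames(res, specificity_positions(width))
}

#' Amino-acid distribution around cleavage sites
#'
#' Tallies, at one time point, the residues occupying each window position
#' among the cleavage events observed so far (sites with positive frequency at
#' that time). By default each distinct site counts once
#' (`weighting = "site"`); `weighting = "frequency"` weights each site by its
#' relative cut frequency. The terminus padding symbol `"-"` participates as
#' its own category, so every position column sums to 100 percent.
#'
#' @param profiles A [relative_cut_frequency()] result.
#' @param substrate A [substrate_protein()].
#' @param time_point Time point (seconds).
#' @param weighting `"site"` (default) or `"frequency"`.
#' @param width Window half-width (default 5).
#' @return A tibble of class `specificity_matrix`: `position` (ordered factor
#'   P5..P1, P1'..P5'), `residue`, `percentage`, with attributes `time_s`,
#'   `weighting`, `n_events`.
#' @export
aa_distribution <- function(profiles, substrate, time_point,
                            weighting = c("site", "frequency"), width = 5L) {
  weighting <- match.arg(weighting)
  sel <- profiles |>
    filter(.data$time_s == time_point, .data$frequency > 0)
  positions <- specificity_positions(width)
  if (nrow(sel) == 0L) {
    out <- tibble(
      position = factor(character(), levels = positions),
      residue = character(), percentage = numeric()
    )
  } else {
    w <- if (weighting == "site") rep(1, nrow(sel)) else sel$frequency
    windows <- map(sel$p1, extract_window, substrate = substrate, width = width)
    long <- tibble(
      position = factor(rep(positions, times = nrow(sel)), levels = positions),
      residue = unlist(windows, use.names = FALSE),
      weight = rep(w, each = length(positions))
    )
    out <- long |>
      group_by(.data$position, .data$residue) |>
      summarise(weight = sum(.data$weight), .groups = "drop") |>
      group_by(.data$position) |>
      mutate(percentage = 100 * .data$weight / sum(.data$weight)) |>
      ungroup() |>
      select("position", "residue", "percentage") |>
      arrange(.data$position, desc(.data$percentage), .data$residue)
  }
  structure(
    out,
    time_s = time_point, weighting = weighting,
    n_events = nrow(sel), width = width,
    class = c("specificity_matrix", class(out))
  )
}

#' Consensus residues from a specificity matrix
#'
#' The consensus at each window position is the residue with the highest
#' percentage; ties are broken alphabetically and flagged. Positions whose
#' maximum falls below `floor` percent are reported in lower case (weak
#' consensus).
#'
#' @param matrix A [aa_distribution()] result.
#' @param floor Percentage below which a consensus is reported lowercase.
#' @return Tibble `position`, `residue` (consensus symbol), `percentage`,
#'   `tie`; attribute `consensus` holds the concatenated string.
#' @export
consensus <- function(matrix, floor = 10) {
  out <- matrix |>
    group_by(.data$position) |>
    summarise(
      top = max(.data$percentage),
      tie = sum(.data$percentage == max(.data$percentage)) > 1L,
      residue = sort(.data$residue[.data$percentage == max(.data$percentage)])[1],
      .groups = "drop"
    ) |>
    mutate(residue = ifelse(.data$top < floor,
                            tolower(.data$residue), .data$residue)) |>
    select("position", "residue", percentage = "top", "tie") |>
    arrange(.data$position)
  attr(out, "consensus") <- paste(out$residue, collapse = "")
  out
}

#' Compare two specificity matrices
#'
#' Per-position total variation distance between two amino-acid
#' distributions, `0.5 * sum(|p - q|)` in percentage points (0 = identical,
#' 100 = disjoint), plus the per-residue percentage differences.
#'
#' @param matrix_a,matrix_b [aa_distribution()] results over the same
#'   positions.
#' @return Tibble `position`, `tvd`; attribute `residue_differences` holds the
#'   per-residue table (`position`, `residue`, `delta` = a - b).
#' @export
compare_conditions <- function(matrix_a, matrix_b) {
  pos <- union(levels(matrix_a$position), levels(matrix_b$position))
  if (!setequal(levels(matrix_a$position), levels(matrix_b$position))) {
    abort("matrices must cover the same window positions")
  }
  joined <- full_join(
    as_tibble(matrix_a), as_tibble(matrix_b),
    by = c("position", "residue"), suffix = c("_a", "_b")
  ) |>
    mutate(
      percentage_a = replace_na(.data$percentage_a, 0),
      percentage_b = replace_na(.data$percentage_b, 0),
      delta = .data$percentage_a - .data$percentage_b
    )
  out <- joined |>
    group_by(.data$position) |>
    summarise(tvd = 0.5 * sum(abs(.data$delta)), .groups = "drop") |>
    arrange(.data$position)
  attr(out, "residue_differences") <-
    select(joined, "position", "residue", "delta")
  out
}

#' Convergence of two conditions' P1 specificity over time
#'
#' Computes the mean per-position total variation distance between the
#' specificity matrices of two site-profile sets at each shared time point --
#' e.g. a folded (gated) versus a denatured (ungated) digestion, whose P1
#' preferences differ early and converge as unfolding proceeds.
#'
#' @param profiles_a,profiles_b [relative_cut_frequency()] results.
#' @param substrate A [substrate_protein()].
#' @param positions Restrict the distance to these positions (default `"P1"`;
#'   `NULL` for all).
#' @param width Window half-width.
#' @return Tibble `time_s`, `tvd`.
#' @export
specificity_convergence <- function(profiles_a, profiles_b, substrate,
                                    positions = "P1", width = 5L) {
  times <- intersect(attr(profiles_a, "time_points"), attr(profiles_b, "time_points"))
  times <- sort(times[times > 0])
  rows <- map(times, function(tp) {
    ma <- aa_distribution(profiles_a, substrate, tp, width = width)
    mb <- aa_distribution(profiles_b, substrate, tp, width = width)
    if (nrow(ma) == 0L || nrow(mb) == 0L) {
      return(tibble(time_s = tp, tvd = NA_real_))
    }
    d <- compare_conditions(ma, mb)
    if (!is.null(positions)) d <- filter(d, .data$position %in% positions)
    tibble(time_s = tp, tvd = mean(d$tvd))
  })
  bind_rows(rows)
}
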