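#' Read a peptide-intensity table
#'
#' Reads a tab-separated peptide table (the MaxQuant `peptides.txt` dialect:
#' columns `Sequence`, `Score`, and one intensity column per sample) and
#' reshapes it to the long form used throughout the package. The sample map
#' assigns each intensity column a condition, replicate and time.
#'
#' @param path Path to a TSV file.
#' @param sample_map Data frame with columns `column`, `condition`,
#'   `replicate`, `time_s`; every intensity column must appear exactly once.
#' @param control_condition Name of the protease-free condition.
#' @return A long tibble: `sequence`, `score`, `condition`, `replicate`,
#'   `time_s`, `intensity` (missing cells stay `NA`, not 0), `is_control`.
#' @export
read_peptide_table <- function(path, sample_map, control_condition = "control") {
  sample_map <- as_tibble(sample_map)
  stopifnot(all(c("column", "condition", "replicate", "time_s") %in% names(sample_map)))
  if (anyDuplicated(sample_map$column) > 0L) {
    abort("sample_map assigns a column more than once")
  }
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("Sequence", "Score")
  missing_cols <- setdiff(c(required, sample_map$column), names(raw))
  if (length(missing_cols) > 0L) {
    abort(paste0("peptide table lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  bad <- raw$Sequence %in% c(NA, "") | is.na(raw$Score)
  if (any(bad)) {
    warn(paste0(sum(bad), " unparseable row(s) skipped"))
    raw <- raw[!bad, ]
  }
  raw |>
    select("Sequence", "Score", dplyr::all_of(sample_map$column)) |>
    pivot_longer(dplyr::all_of(sample_map$column),
      names_to = "column", values_to = "intensity"
    ) |>
    left_join(sample_map, by = "column") |>
    mutate(is_control = .data$condition == control_condition) |>
    select(
      sequence = "Sequence", score = "Score", "condition", "replicate",
      "time_s", "intensity", "is_control"
    ) |>
    arrange(.data$sequence, .data$condition, .data$replicate, .data$time_s)
}

#' Write a long peptide table in the wide TSV dialect
#'
#' Inverse of [read_peptide_table()]: one row per peptide, one intensity
#' column per sample, named `Intensity_<condition>_R<replicate>_t<time>`.
#'
#' @param peptides Long peptide table.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_peptide_table <- function(peptides, path) {
  wide <- peptides |>
    mutate(column = sprintf(
      "Intensity_%s_R%d_t%g", .data$condition, .data$replicate, .data$time_s
    )) |>
    select("sequence", "score", "column", "intensity") |>
    pivot_wider(names_from = "column", values_from = "intensity") |>
    rename(Sequence = "sequence", Score = "score") |>
    arrange(.data$Sequence)
  readr::write_tsv(wide, path, progress = FALSE)
  invisible(path)
}

#' Write the sample map of a long peptide table
#'
#' @param peptides Long peptide table (or a sample map tibble).
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_sample_map <- function(peptides, path) {
  sm <- if (all(c("column", "condition", "replicate", "time_s") %in% names(peptides))) {
    as_tibble(peptides)
  } else {
    peptides |>
      distinct(.data$condition, .data$replicate, .data$time_s) |>
      mutate(column = sprintf(
        "Intensity_%s_R%d_t%g", .data$condition, .data$replicate, .data$time_s
      )) |>
      select("column", "condition", "replicate", "time_s")
  }
  readr::write_tsv(sm, path, progress = FALSE)
  invisible(path)
}

#' Write simulator ground truth (rates, gates, event log) as JSON
#'
#' @param simulation A [simulate_digestion()] result.
#' @param path Output JSON path.
#' @param events Include the full per-molecule event log (default `TRUE`).
#' @return The path, invisibly.
#' @export
write_ground_truth <- function(simulation, path, events = TRUE) {
  gt <- simulation$ground_truth
  obj <- list(
    substrate = list(
      id = gt$substrate$id, length = gt$substrate$length,
      numbering_offset = gt$substrate$numbering_offset
    ),
    n_molecules = gt$n_molecules,
    detectable_length = gt$detectable_length,
    seed = simulation$seed,
    protease_multiplier = simulation$protease_multiplier,
    sites = map(seq_len(nrow(gt$sites)), function(i) {
      list(
        p1 = gt$sites$p1[i], rate = gt$sites$rate[i],
        gate = gt$sites$gate[[i]]
      )
    }),
    time_points = simulation$time_points
  )
  if (events) obj$events <- simulation$events
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
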