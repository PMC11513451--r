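#' Define a substrate protein
#'
#' A substrate is the single protein chain that the protease digests. All
#' peptide coordinates in the package are 1-based inclusive positions on this
#' sequence. A cleavage site is identified by its P1 residue: the residue
#' immediately N-terminal to the scissile bond (Schechter-Berger
#' nomenclature), so site `p1` denotes the bond between residues `p1` and
#' `p1 + 1`.
#'
#' Recombinant constructs are often truncated relative to the native protein;
#' `numbering_offset` maps recombinant coordinates to native ones
#' (`native = position + numbering_offset`). For example, a construct spanning
#' native residues 158-480 is described by `numbering_offset = 157`.
#'
#' @param sequence Amino-acid sequence, one-letter upper-case code
#'   (standard 20 residues plus `"X"`).
#' @param id Identifier for the substrate.
#' @param numbering_offset Integer added to a recombinant position to obtain
#'   the native position.
#' @return An object of class `substrate_protein` with fields `id`,
#'   `sequence`, `length` and `numbering_offset`.
#' @examples
#' sub <- substrate_protein("MKVLATTWYRAGELKK", id = "demo")
#' sub$length
#' @export
substrate_protein <- function(sequence, id = "substrate", numbering_offset = 0L) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0L) {
    abort("substrate sequence must be non-empty")
  }
  letters_seen <- unique(strsplit(sequence, "")[[1]])
  bad <- setdiff(letters_seen, c(AA_STANDARD, "X"))
  if (length(bad) > 0L) {
    abort(paste0(
      "substrate sequence contains non-standard residues: ",
      paste(bad, collapse = ", ")
    ))
  }
  structure(
    list(
      id = id,
      sequence = sequence,
      length = nchar(sequence),
      numbering_offset = as.integer(numbering_offset)
    ),
    class = "substrate_protein"
  )
}

#' @export
print.substrate_protein <- function(x, ...) {
  cat(
    "<substrate_protein> ", x$id, ": ", x$length, " residues",
    if (x$numbering_offset != 0L) {
      paste0(" (native numbering offset ", sprintf("%+d", x$numbering_offset), ")")
    },
    "\n",
    sep = ""
  )
  invisible(x)
}

#' Read a substrate protein from a FASTA file
#'
#' @param path Path to a FASTA file with a single record.
#' @param numbering_offset See [substrate_protein()].
#' @return A `substrate_protein`.
#' @export
read_substrate_fasta <- function(path, numbering_offset = 0L) {
  set <- Biostrings::readAAStringSet(path)
  if (length(set) != 1L) {
    abort(paste0("expected a single FASTA record, found ", length(set)))
  }
  substrate_protein(
    as.character(set[[1]]),
    id = sub("\\s.*$", "", names(set)[1]),
    numbering_offset = numbering_offset
  )
}

#' Convert a recombinant position to native numbering
#'
#' @param position Position(s) on the substrate, 1-based.
#' @param substrate A [substrate_protein()].
#' @return Integer native position(s).
#' @examples
#' htra1 <- substrate_protein(strrep("A", 323), numbering_offset = 157)
#' to_native_numbering(1, htra1) # construct residue 1 is native residue 158
#' @export
to_native_numbering <- function(position, substrate) {
  position <- as.integer(position)
  if (any(position < 1L | position > substrate$length)) {
    abort("position out of range for substrate")
  }
  position + substrate$numbering_offset
}

#' Locate every occurrence of a peptide in the substrate
#'
#' Exact substring search; overlapping occurrences are all reported.
#'
#' @param peptide_sequence Peptide amino-acid string.
#' @param substrate A [substrate_protein()].
#' @return A tibble with columns `start`, `end` (1-based inclusive), one row
#'   per occurrence; zero rows if the peptide does not occur.
#' @export
map_peptide <- function(peptide_sequence, substrate) {
  stopifnot(nchar(peptide_sequence) >= 1L)
  m <- nchar(peptide_sequence)
  L <- substrate$length
  if (m > L) {
    return(tibble(start = integer(), end = integer()))
  }
  starts <- which(
    substring(substrate$sequence, seq_len(L - m + 1L), seq_len(L - m + 1L) + m - 1L) ==
      peptide_sequence
  )
  tibble(start = as.integer(starts), end = as.integer(starts + m - 1L))
}

#' Map a peptide table onto the substrate
#'
#' Adds `start`/`end` coordinates to a peptide table by exact substring
#' search. Peptides that do not occur in the substrate are dropped with a
#' warning. Peptides occurring more than once are ambiguous: by default they
#' are discarded (a wrong coordinate corrupts every downstream per-site
#' statistic); `ambiguous = "first"` keeps the first occurrence instead.
#'
#' @param peptides A data frame with a `sequence` column (wide or long form).
#' @param substrate A [substrate_protein()].
#' @param ambiguous `"discard"` (default) or `"first"`.
#' @return The input tibble with `start` and `end` columns added.
#' @export
map_peptides <- function(peptides, substrate, ambiguous = c("discard", "first")) {
  ambiguous <- match.arg(ambiguous)
  stopifnot("sequence" %in% names(peptides))
  peptides <- select(peptides, -dplyr::any_of(c("start", "end")))
  seqs <- unique(peptides$sequence)
  hits <- map(seqs, map_peptide, substrate = substrate)
  n_hits <- map_int(hits, nrow)
  unmapped <- seqs[n_hits == 0L]
  multi <- seqs[n_hits > 1L]
  if (length(unmapped) > 0L) {
    warn(paste0(length(unmapped), " peptide(s) not found in substrate; dropped"))
  }
  if (length(multi) > 0L && ambiguous == "discard") {
    warn(paste0(
      length(multi), " peptide(s) map to multiple positions; discarded ",
      "(use ambiguous = \"first\" to keep the first occurrence)"
    ))
  }
  keep <- if (ambiguous == "discard") n_hits == 1L else n_hits >= 1L
  coords <- tibble(
    sequence = seqs[keep],
    start = map_int(hits[keep], ~ .x$start[1]),
    end = map_int(hits[keep], ~ .x$end[1])
  )
  peptides |>
    inner_join(coords, by = "sequence") |>
    as_tibble()
}

#' Cleavage sites implied by a peptide interval
#'
#' Except at the substrate termini, each proteolytic product is the result of
#' two cuts: one at its N terminus (the first residue of the peptide is the
#' P1' residue of that cut, so its P1 is `start - 1`) and one at its C
#' terminus (P1 is `end`). Peptides flush with a terminus carry one site; the
#' full-length chain carries none.
#'
#' @param start,end Peptide interval, 1-based inclusive.
#' @param substrate_length Length of the substrate chain.
#' @return Sorted integer vector of P1 positions (possibly empty).
#' @export
cleavage_sites_from_peptide <- function(start, end, substrate_length) {
  start <- as.integer(start)
  end <- as.integer(end)
  if (start < 1L || end < start || end > substrate_length) {
    abort("peptide interval out of bounds")
  }
  sites <- integer()
  if (start > 1L) sites <- c(sites, start - 1L)
  if (end < substrate_length) sites <- c(sites, end)
  sort(unique(sites))
}

# P1 sites for a whole interval table, one row per (peptide row, site).
peptide_bonds <- function(df, substrate_length, both_bonds = TRUE) {
  n_bond <- ifelse(df$start > 1L, df$start - 1L, NA_integer_)
  c_bond <- ifelse(df$end < substrate_length, df$end, NA_integer_)
  out <- bind_rows(
    if (both_bonds) mutate(df, p1 = n_bond) else NULL,
    mutate(df, p1 = c_bond)
  )
  filter(out, !is.na(.data$p1))
}

#' Group peptide intervals into gapless fragments
#'
#' Peptides whose intervals overlap or immediately abut (gap of zero
#' residues) are merged into a single fragment; fragments are separated by at
#' least one uncovered residue. This is the fragment overview used to chart
#' coverage per time point, together with the number of member peptides and
#' the number of distinct cleavage sites they imply.
#'
#' @param intervals A data frame with `start` and `end` columns (one row per
#'   peptide occurrence); may be empty.
#' @param substrate A [substrate_protein()] (or an integer chain length).
#' @param time_point Optional time in seconds, carried into the output.
#' @return A tibble of class `fragment_map` with columns `fragment`, `start`,
#'   `end`, `n_peptides`, `n_cleavage_sites` and (if given) `time_s`;
#'   attribute `peptide_members` holds the row indices of member peptides.
#' @export
group_fragments <- function(intervals, substrate, time_point = NULL) {
  substrate_length <- if (inherits(substrate, "substrate_protein")) {
    substrate$length
  } else {
    as.integer(substrate)
  }
  if (nrow(intervals) == 0L) {
    out <- tibble(
      fragment = integer(), start = integer(), end = integer(),
      n_peptides = integer(), n_cleavage_sites = integer()
    )
    if (!is.null(time_point)) out$time_s <- numeric()
    attr(out, "peptide_members") <- list()
    class(out) <- c("fragment_map", class(out))
    return(out)
  }
  stopifnot(
    all(intervals$start >= 1L),
    all(intervals$end >= intervals$start),
    all(intervals$end <= substrate_length)
  )
  ir <- IRanges::IRanges(start = intervals$start, end = intervals$end)
  merged <- IRanges::reduce(ir) # default: merges overlap and abutment
  ov <- IRanges::findOverlaps(ir, merged)
  members <- split(
    S4Vectors::queryHits(ov),
    factor(S4Vectors::subjectHits(ov), levels = seq_along(merged))
  )
  # each bond counted once per fragment covering the peptide it came from
  frag_of_row <- integer(nrow(intervals))
  frag_of_row[S4Vectors::queryHits(ov)] <- S4Vectors::subjectHits(ov)
  bond_p1 <- c(
    ifelse(intervals$start > 1L, intervals$start - 1L, NA_integer_),
    ifelse(intervals$end < substrate_length, intervals$end, NA_integer_)
  )
  bond_frag <- rep(frag_of_row, 2L)
  keep_bond <- !is.na(bond_p1)
  uniq <- !duplicated(cbind(bond_frag[keep_bond], bond_p1[keep_bond]))
  bonds_by_frag <- tabulate(bond_frag[keep_bond][uniq], nbins = length(merged))
  out <- tibble(
    fragment = seq_along(merged),
    start = IRanges::start(merged),
    end = IRanges::end(merged),
    n_peptides = tabulate(frag_of_row, nbins = length(merged)),
    n_cleavage_sites = bonds_by_frag
  )
  if (!is.null(time_point)) out$time_s <- time_point
  attr(out, "peptide_members") <- unname(map(members, as.integer))
  class(out) <- c("fragment_map", class(out))
  out
}

#' Fragment overview across all time points
#'
#' Runs [group_fragments()] once per time point on the peptides detected
#' (intensity greater than zero in at least one retained digest replicate) at
#' that time.
#'
#' @param peptides Long mapped peptide table (see [read_peptide_table()] and
#'   [map_peptides()]); control rows are ignored.
#' @param substrate A [substrate_protein()].
#' @return A tibble: one row per fragment per time point.
#' @export
fragment_maps <- function(peptides, substrate) {
  digest <- filter(peptides, !.data$is_control)
  times <- sort(unique(digest$time_s))
  maps <- map(times, function(tp) {
    present <- digest |>
      filter(.data$time_s == tp, !is.na(.data$intensity), .data$intensity > 0) |>
      distinct(.data$sequence, .data$start, .data$end)
    group_fragments(present, substrate, time_point = tp)
  })
  bind_rows(maps)
}
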