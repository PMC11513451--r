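# Shared fixtures, all generated in code.

make_substrate <- function(n = 60, seed = 1, offset = 0L) {
  set.seed(seed)
  substrate_protein(
    paste(sample(c(
      "A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
      "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"
    ), n, replace = TRUE), collapse = ""),
    id = "toy", numbering_offset = offset
  )
}

# Brute-force oracle: boolean coverage mask + run-length extraction.
coverage_mask_fragments <- function(intervals, len) {
  mask <- rep(FALSE, len)
  for (i in seq_len(nrow(intervals))) {
    mask[intervals$start[i]:intervals$end[i]] <- TRUE
  }
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  tibble::tibble(start = starts[r$values], end = ends[r$values])
}

# Long peptide table from explicit per-time digest/control replicate values.
make_peptide_series <- function(sequence, time_points, digest, control,
                                score = 100, start = NA, end = NA) {
  reps <- nrow(digest)
  stopifnot(ncol(digest) == length(time_points))
  rows <- list()
  for (cond in c("digest", "control")) {
    m <- if (cond == "digest") digest else control
    for (r in seq_len(nrow(m))) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        sequence = sequence, score = score, start = start, end = end,
        condition = cond, replicate = r, time_s = time_points,
        intensity = m[r, ], is_control = cond == "control"
      )
    }
  }
  dplyr::bind_rows(rows)
}

# Minimal PDB writer for synthetic toy structures.
write_toy_pdb <- function(path, atoms, helix = NULL, sheet = NULL) {
  lines <- character()
  fmt_range <- function(kind, start, end, i) {
    if (kind == "HELIX") {
      sprintf(
        "HELIX  %3d %3s ALA A %4d  ALA A %4d  1%36d", i, sprintf("%3d", i),
        start, end, end - start + 1
      )
    } else {
      sprintf(
        "SHEET  %3d %3s 1 ALA A%4d  ALA A%4d  0", i, sprintf("%3d", i),
        start, end
      )
    }
  }
  if (!is.null(helix)) {
    for (i in seq_len(nrow(helix))) {
      lines <- c(lines, fmt_range("HELIX", helix$start[i], helix$end[i], i))
    }
  }
  if (!is.null(sheet)) {
    for (i in seq_len(nrow(sheet))) {
      lines <- c(lines, fmt_range("SHEET", sheet$start[i], sheet$end[i], i))
    }
  }
  for (i in seq_len(nrow(atoms))) {
    a <- atoms[i, ]
    lines <- c(lines, sprintf(
      "ATOM  %5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      i, a$elety, ifelse(is.null(a$alt) || is.na(a$alt), " ", a$alt),
      a$resid, a$chain, a$resno, a$x, a$y, a$z, a$occ, a$b, a$element
    ))
  }
  writeLines(c(lines, "END"), path)
  path
}

# A 3-residue Ala-Gly-Ala backbone-only toy chain along x.
toy_atoms <- function(chain = "A") {
  tibble::tibble(
    elety = rep(c("N", "CA", "C", "O"), 3),
    alt = NA_character_,
    resid = rep(c("ALA", "GLY", "ALA"), each = 4),
    chain = chain,
    resno = rep(1:3, each = 4),
    x = rep(c(0, 1.5, 3.0, 4.0), 3) + rep(c(0, 6, 12), each = 4),
    y = rep(c(0, 1, 0, -1), 3),
    z = 0,
    occ = 1, b = rep(c(10, 20, 30), each = 4),
    element = rep(c("N", "C", "C", "O"), 3)
  )
}

# Free glycine: the four backbone heavy atoms at ideal-ish geometry.
glycine_atoms <- function() {
  tibble::tibble(
    elety = c("N", "CA", "C", "O"),
    alt = NA_character_, resid = "GLY", chain = "A", resno = 1,
    x = c(0, 1.45, 2.0, 3.2), y = c(0, 0.3, 1.6, 1.8), z = c(0, 0, 0, 0),
    occ = 1, b = 15, element = c("N", "C", "C", "O")
  )
}
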