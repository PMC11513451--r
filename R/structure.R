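# Theoretical maximum ASA per residue (Tien et al. 2013, theoretical scale), A^2.
MAX_ASA_TIEN <- c(
  A = 129.0, R = 274.0, N = 195.0, D = 193.0, C = 167.0, Q = 225.0, E = 223.0,
  G = 104.0, H = 224.0, I = 197.0, L = 201.0, K = 236.0, M = 224.0, F = 240.0,
  P = 159.0, S = 155.0, T = 172.0, W = 285.0, Y = 263.0, V = 174.0
)

# van der Waals radii by element, A.
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80, SE = 1.90)

# Expected heavy-atom counts per residue, to flag partially modelled residues.
HEAVY_ATOMS <- c(
  G = 4, A = 5, S = 6, C = 6, T = 7, V = 7, P = 7, L = 8, I = 8, N = 8,
  D = 8, M = 8, Q = 9, E = 9, K = 9, H = 10, F = 11, R = 11, Y = 12, W = 14
)

#' Parse a protein structure from a PDB file
#'
#' Reads one chain's ATOM records: heavy-atom coordinates, B-factors and
#' author residue numbering. Altloc duplicates are resolved by keeping the
#' highest-occupancy atom. HELIX/SHEET header records for the chain are
#' retained for [secondary_structure()].
#'
#' @param path Path to a PDB file.
#' @param chain Chain identifier (default `"A"`).
#' @param keep_hydrogens Keep hydrogen atoms (default `FALSE`).
#' @return An object of class `protein_structure` with `atoms` (tibble:
#'   `resno`, `resid`, `elety`, `element`, `x`, `y`, `z`, `b`, `occupancy`),
#'   `residues` (tibble: `resno`, `aa`, `b_mean`, `n_atoms`), `helix`/`sheet`
#'   interval tibbles, `sequence` and `chain`.
#' @export
read_structure <- function(path, chain = "A", keep_hydrogens = FALSE) {
  pdb <- suppressWarnings(bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE))
  atoms <- as_tibble(pdb$atom) |>
    filter(.data$type == "ATOM")
  available <- sort(unique(atoms$chain))
  atoms <- filter(atoms, .data$chain == !!chain)
  if (nrow(atoms) == 0L) {
    abort(paste0(
      "chain '", chain, "' not found; available chains: ",
      paste(available, collapse = ", ")
    ))
  }
  element <- toupper(ifelse(
    !is.na(atoms$elesy) & atoms$elesy != "",
    atoms$elesy,
    substring(gsub("[0-9]", "", atoms$elety), 1, 1)
  ))
  atoms$element <- element
  if (!keep_hydrogens) atoms <- filter(atoms, .data$element != "H")
  # altloc: keep the highest-occupancy copy of each (residue, atom name)
  atoms <- atoms |>
    group_by(.data$resno, .data$elety) |>
    arrange(desc(.data$o), .data$alt, .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    arrange(.data$resno, .data$eleno)
  residues <- atoms |>
    group_by(.data$resno, .data$resid) |>
    summarise(b_mean = mean(.data$b), n_atoms = dplyr::n(), .groups = "drop") |>
    mutate(aa = bio3d::aa321(.data$resid)) |>
    arrange(.data$resno) |>
    select("resno", "aa", "resid", "b_mean", "n_atoms")
  pick_chain <- function(rec) {
    if (is.null(rec) || length(rec$start) == 0L) {
      return(tibble(start = integer(), end = integer()))
    }
    tibble(
      start = as.integer(rec$start), end = as.integer(rec$end),
      chain = rec$chain
    ) |>
      filter(.data$chain == !!chain) |>
      select("start", "end")
  }
  structure(
    list(
      atoms = select(
        atoms, "resno", "resid", "elety", "element", "x", "y", "z",
        b = "b", occupancy = "o"
      ),
      residues = residues,
      helix = pick_chain(pdb$helix),
      sheet = pick_chain(pdb$sheet),
      sequence = paste(residues$aa, collapse = ""),
      chain = chain,
      path = path
    ),
    class = "protein_structure"
  )
}

#' @export
print.protein_structure <- function(x, ...) {
  cat(
    "<protein_structure> chain ", x$chain, ": ", nrow(x$residues),
    " residues, ", nrow(x$atoms), " atoms\n",
    sep = ""
  )
  invisible(x)
}

#' Reconcile structure numbering with the substrate sequence
#'
#' Finds the constant offset such that every modelled residue matches the
#' substrate sequence at `resno + offset`. Fails, with a mismatch report, if
#' no offset reconciles the two sequences.
#'
#' @param structure A [read_structure()] result.
#' @param substrate A [substrate_protein()].
#' @return Integer offset (substrate position = `resno + offset`).
#' @export
reconcile_numbering <- function(structure, substrate) {
  res <- structure$residues
  sub_res <- strsplit(substrate$sequence, "")[[1]]
  offsets <- (1L - min(res$resno)):(substrate$length - max(res$resno))
  if (length(offsets) == 0L) {
    abort("structure residue range exceeds substrate length")
  }
  mismatches <- map_int(offsets, function(o) {
    sum(sub_res[res$resno + o] != res$aa)
  })
  hits <- offsets[mismatches == 0L]
  if (length(hits) == 0L) {
    best <- offsets[which.min(mismatches)]
    bad <- which(sub_res[res$resno + best] != res$aa)
    report <- paste(sprintf(
      "resno %d: structure %s vs substrate %s",
      res$resno[bad], res$aa[bad], sub_res[res$resno + best][bad]
    ), collapse = "; ")
    abort(paste0(
      "structure sequence does not match substrate at any offset; best offset ",
      best, " leaves ", min(mismatches), " mismatch(es): ",
      substr(report, 1, 300)
    ))
  }
  if (length(hits) > 1L) {
    warn("multiple offsets reconcile structure and substrate; using the first")
  }
  as.integer(hits[1])
}

#' Per-residue secondary structure from HELIX/SHEET records
#'
#' Classes are read from the coordinate file's HELIX and SHEET header records
#' (the assignment deposited with the crystal structure); residues covered by
#' neither are loops. Where records overlap, helix takes precedence.
#'
#' @param structure A [read_structure()] result.
#' @return Tibble `resno`, `ss` (`"helix"`, `"strand"` or `"loop"`).
#' @export
secondary_structure <- function(structure) {
  res <- structure$residues
  ss <- rep("loop", nrow(res))
  if (nrow(structure$helix) == 0L && nrow(structure$sheet) == 0L) {
    warn("no HELIX/SHEET records found; all residues classified as loop")
  }
  in_any <- function(resno, iv) {
    if (nrow(iv) == 0L) return(rep(FALSE, length(resno)))
    Reduce(`|`, map2(iv$start, iv$end, ~ resno >= .x & resno <= .y))
  }
  ss[in_any(res$resno, structure$sheet)] <- "strand"
  ss[in_any(res$resno, structure$helix)] <- "helix" # helix precedence
  tibble(resno = res$resno, ss = ss)
}

# Deterministic quasi-uniform points on the unit sphere (golden-section spiral).
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley solvent-accessible surface area per atom
#'
#' Numerical SASA: each atom is covered with `n_points` quasi-uniform test
#' points on its solvent-expanded sphere (van der Waals radius + probe
#' radius); the accessible area is the sphere area times the fraction of
#' points not buried inside any neighbouring atom's expanded sphere.
#'
#' @param xyz Numeric matrix (atoms x 3) of coordinates.
#' @param radii van der Waals radii (one per atom), A.
#' @param probe_radius Solvent probe radius (default 1.4 A, water).
#' @param n_points Test points per atom (default 960).
#' @return Numeric vector of per-atom ASA values (A^2).
#' @export
shrake_rupley <- function(xyz, radii, probe_radius = 1.4, n_points = 960L) {
  xyz <- as.matrix(xyz)
  stopifnot(ncol(xyz) == 3L, length(radii) == nrow(xyz))
  n <- nrow(xyz)
  pts <- sphere_points(n_points)
  expanded <- radii + probe_radius
  asa <- numeric(n)
  for (i in seq_len(n)) {
    ri <- expanded[i]
    d2 <- rowSums(sweep(xyz, 2, xyz[i, ])^2)
    nb <- which(d2 < (ri + expanded)^2 & seq_len(n) != i)
    p <- pts * ri
    p <- sweep(p, 2, xyz[i, ], `+`)
    accessible <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(accessible)) break
      keep <- accessible
      dd <- (p[keep, 1] - xyz[j, 1])^2 + (p[keep, 2] - xyz[j, 2])^2 +
        (p[keep, 3] - xyz[j, 3])^2
      accessible[keep] <- dd >= expanded[j]^2
    }
    asa[i] <- 4 * pi * ri^2 * mean(accessible)
  }
  asa
}

#' Per-residue solvent accessibility of a structure
#'
#' Sums Shrake-Rupley atomic ASA per residue and normalises by the residue's
#' theoretical maximum ASA (Tien et al. 2013 scale) to a relative solvent
#' accessibility (RSA, clamped to `[0, 1]`). A residue is classified as
#' surface if its RSA reaches `surface_cutoff`. Residues with fewer heavy
#' atoms than expected for their type are flagged `partial` (ASA computed on
#' the atoms present).
#'
#' @param structure A [read_structure()] result.
#' @param probe_radius Probe radius, A.
#' @param n_points Sphere test points per atom.
#' @param surface_cutoff RSA threshold for the surface flag (default 0.2).
#' @return Tibble `resno`, `aa`, `asa`, `rsa`, `surface`, `partial`.
#' @export
solvent_accessibility <- function(structure, probe_radius = 1.4,
                                  n_points = 960L, surface_cutoff = 0.2) {
  atoms <- structure$atoms
  radii <- unname(VDW_RADII[atoms$element])
  radii[is.na(radii)] <- 1.70
  asa_atom <- shrake_rupley(
    as.matrix(atoms[, c("x", "y", "z")]), radii,
    probe_radius = probe_radius, n_points = n_points
  )
  per_res <- tibble(resno = atoms$resno, asa = asa_atom) |>
    group_by(.data$resno) |>
    summarise(asa = sum(.data$asa), n_atoms = dplyr::n(), .groups = "drop")
  structure$residues |>
    select("resno", "aa") |>
    left_join(per_res, by = "resno") |>
    mutate(
      max_asa = unname(MAX_ASA_TIEN[.data$aa]),
      rsa = pmin(1, .data$asa / .data$max_asa),
      surface = .data$rsa >= surface_cutoff,
      partial = .data$n_atoms < unname(HEAVY_ATOMS[.data$aa])
    ) |>
    select("resno", "aa", "asa", "rsa", "surface", "partial")
}

# Clustal conservation groups.
CLUSTAL_STRONG <- c("STA", "NEQK", "NHQK", "NDEQ", "QHRK", "MILV", "MILF", "HY", "FYW")
CLUSTAL_WEAK <- c(
  "CSA", "ATV", "SAG", "STNK", "STPA", "SGND", "SNDEQK",
  "NDEQHK", "NEQHRK", "FVLIM", "HFY"
)

conservation_symbol <- function(residues) {
  residues <- toupper(residues)
  if (any(residues == "-" | residues == "." | residues == "X")) return(" ")
  if (length(unique(residues)) == 1L) return("*")
  in_group <- function(groups) {
    any(map_lgl(groups, function(g) {
      all(residues %in% strsplit(g, "")[[1]])
    }))
  }
  if (in_group(CLUSTAL_STRONG)) return(":")
  if (in_group(CLUSTAL_WEAK)) return(".")
  " "
}

read_alignment <- function(alignment) {
  if (is.character(alignment) && length(alignment) == 1L && file.exists(alignment)) {
    fmt <- if (grepl("\\.(aln|clu|clustal)$", alignment, ignore.case = TRUE)) {
      "clustal"
    } else {
      "fasta"
    }
    aln <- Biostrings::readAAMultipleAlignment(alignment, format = fmt)
    setNames(
      as.character(Biostrings::unmasked(aln)),
      rownames(aln)
    )
  } else {
    unlist(alignment)
  }
}

#' Per-column conservation symbols from a multiple sequence alignment
#'
#' Clustal-style annotation: `"*"` for identical columns, `":"` when all
#' residues fall in one strong conservation group, `"."` for a weak group,
#' `" "` otherwise (including any column containing a gap). Columns are
#' mapped to substrate numbering through the (gapped) reference row.
#'
#' @param alignment Path to a FASTA or Clustal alignment, or a named character
#'   vector of equal-length gapped sequences.
#' @param reference Index or name of the reference row (the substrate);
#'   default 1.
#' @return Tibble `column` (alignment column), `position` (reference/substrate
#'   position; `NA` where the reference has a gap), `symbol`.
#' @export
msa_conservation <- function(alignment, reference = 1L) {
  seqs <- read_alignment(alignment)
  if (length(seqs) < 2L) abort("alignment must contain at least two sequences")
  if (length(unique(nchar(seqs))) != 1L) {
    abort("alignment rows must have equal length")
  }
  mat <- do.call(rbind, strsplit(toupper(seqs), ""))
  ref <- if (is.character(reference)) match(reference, names(seqs)) else reference
  if (is.na(ref) || ref < 1L || ref > nrow(mat)) abort("reference row not found")
  symbols <- apply(mat, 2, conservation_symbol)
  ref_row <- mat[ref, ]
  position <- ifelse(ref_row == "-", NA_integer_, cumsum(ref_row != "-"))
  tibble(
    column = seq_len(ncol(mat)),
    position = as.integer(position),
    symbol = symbols
  )
}

#' Combined per-residue annotation and frequency track table
#'
#' Joins, per substrate residue: sequence, native numbering, secondary
#' structure, mean B-factor, solvent accessibility (surface/buried) and MSA
#' conservation with the relative cut-frequency profile at every time point
#' (wide columns `freq_<t>`). This is the tabular form of the per-residue
#' figure tracks.
#'
#' @param profiles A [relative_cut_frequency()] result (may have zero rows).
#' @param substrate A [substrate_protein()].
#' @param structure Optional [read_structure()] result (numbering reconciled
#'   via [reconcile_numbering()]).
#' @param msa Optional alignment (see [msa_conservation()]) whose reference
#'   row is the substrate.
#' @param accessibility Optional precomputed [solvent_accessibility()] table
#'   (recomputed from `structure` when omitted).
#' @return A tibble with one row per substrate residue.
#' @export
annotate_profiles <- function(profiles, substrate, structure = NULL,
                              msa = NULL, accessibility = NULL) {
  out <- tibble(
    position = seq_len(substrate$length),
    native_position = to_native_numbering(seq_len(substrate$length), substrate),
    aa = strsplit(substrate$sequence, "")[[1]]
  )
  if (!is.null(structure)) {
    offset <- reconcile_numbering(structure, substrate)
    ss <- secondary_structure(structure) |>
      mutate(position = .data$resno + offset) |>
      select("position", "ss")
    bfac <- structure$residues |>
      mutate(position = .data$resno + offset) |>
      select("position", b_factor = "b_mean")
    if (is.null(accessibility)) {
      accessibility <- solvent_accessibility(structure)
    }
    acc <- accessibility |>
      mutate(position = .data$resno + offset) |>
      select("position", "asa", "rsa", "surface")
    out <- out |>
      left_join(ss, by = "position") |>
      left_join(bfac, by = "position") |>
      left_join(acc, by = "position") |>
      mutate(ss = ifelse(is.na(.data$ss), "unknown", .data$ss))
  }
  if (!is.null(msa)) {
    cons <- msa_conservation(msa) |>
      filter(!is.na(.data$position)) |>
      select("position", conservation = "symbol")
    out <- left_join(out, cons, by = "position")
  }
  if (nrow(profiles) > 0L) {
    wide <- profiles |>
      as_tibble() |>
      select("p1", "time_s", "frequency") |>
      pivot_wider(
        names_from = "time_s", values_from = "frequency",
        names_prefix = "freq_", values_fill = 0
      ) |>
      rename(position = "p1")
    out <- left_join(out, wide, by = "position") |>
      mutate(across(starts_with("freq_"), ~ replace_na(.x, 0)))
  }
  out
}
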