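test_that("a toy PDB round-trips atoms, B-factors and chains", {
  path <- withr::local_tempfile(fileext = ".pdb")
  write_toy_pdb(path, toy_atoms())
  st <- read_structure(path, "A")
  expect_equal(nrow(st$atoms), 12L)
  expect_equal(st$residues$b_mean, c(10, 20, 30))
  expect_equal(st$sequence, "AGA")
  expect_error(read_structure(path, "Z"), "available chains: A")
})

test_that("altloc duplicates keep the highest-occupancy atom", {
  path <- withr::local_tempfile(fileext = ".pdb")
  atoms <- toy_atoms()
  dup <- atoms[2, ]
  dup$alt <- "B"
  dup$occ <- 0.7
  dup$x <- dup$x + 0.5
  atoms$alt[2] <- "A"
  atoms$occ[2] <- 0.3
  write_toy_pdb(path, dplyr::bind_rows(atoms[1:2, ], dup, atoms[3:12, ]))
  st <- read_structure(path, "A")
  expect_equal(nrow(st$atoms), 12L) # record count unchanged
  ca1 <- dplyr::filter(st$atoms, resno == 1, elety == "CA")
  expect_equal(ca1$occupancy, 0.7) # the higher-occupancy B copy wins
  expect_equal(ca1$x, atoms$x[2] + 0.5)
})

test_that("secondary structure comes from HELIX/SHEET records, helix wins", {
  path <- withr::local_tempfile(fileext = ".pdb")
  write_toy_pdb(path, toy_atoms(),
    helix = tibble::tibble(start = 1, end = 2),
    sheet = tibble::tibble(start = 2, end = 3)
  )
  st <- read_structure(path, "A")
  ss <- secondary_structure(st)
  expect_equal(ss$ss, c("helix", "helix", "strand"))
  # no records -> all loop, with a warning
  path2 <- withr::local_tempfile(fileext = ".pdb")
  write_toy_pdb(path2, toy_atoms())
  expect_warning(ss2 <- secondary_structure(read_structure(path2, "A")), "loop")
  expect_true(all(ss2$ss == "loop"))
})

test_that("numbering reconciliation finds the construct offset or reports a diff", {
  sub <- substrate_protein(paste0("KKKK", "AGA", "KK")) # AGA at positions 5-7
  path <- withr::local_tempfile(fileext = ".pdb")
  write_toy_pdb(path, toy_atoms())
  st <- read_structure(path, "A")
  expect_equal(reconcile_numbering(st, sub), 4L)
  expect_error(
    reconcile_numbering(st, substrate_protein("KKKKKKKKK")),
    "mismatch"
  )
})

test_that("a free glycine is fully exposed and an enclosed atom is buried", {
  path <- withr::local_tempfile(fileext = ".pdb")
  write_toy_pdb(path, glycine_atoms())
  st <- read_structure(path, "A")
  acc <- solvent_accessibility(st)
  expect_gte(acc$rsa, 0.9)
  expect_true(acc$surface)
  # an atom inside a dense synthetic shell of neighbours has ASA ~ 0
  theta <- seq(0, pi, length.out = 12)[-c(1, 12)]
  phi <- seq(0, 2 * pi, length.out = 24)[-24]
  shell <- expand.grid(t = theta, p = phi)
  xyz <- rbind(
    c(0, 0, 0),
    cbind(
      3 * sin(shell$t) * cos(shell$p),
      3 * sin(shell$t) * sin(shell$p),
      3 * cos(shell$t)
    ),
    c(0, 0, 3), c(0, 0, -3)
  )
  asa <- shrake_rupley(xyz, rep(1.7, nrow(xyz)), n_points = 480)
  expect_equal(asa[1], 0)
})

test_that("960-point ASA is within 2% of a 10,000-point reference", {
  set.seed(41)
  n <- 50
  xyz <- matrix(rnorm(n * 3, sd = 4), ncol = 3)
  radii <- sample(c(1.52, 1.55, 1.7, 1.8), n, replace = TRUE)
  coarse <- shrake_rupley(xyz, radii, n_points = 960)
  fine <- shrake_rupley(xyz, radii, n_points = 10000)
  expect_lt(abs(sum(coarse) - sum(fine)) / sum(fine), 0.02)
})

test_that("occlusion can only reduce ASA and the RSA cutoff only moves flags", {
  path <- withr::local_tempfile(fileext = ".pdb")
  write_toy_pdb(path, toy_atoms())
  st <- read_structure(path, "A")
  inside <- solvent_accessibility(st)
  # isolated middle residue
  path_iso <- withr::local_tempfile(fileext = ".pdb")
  write_toy_pdb(path_iso, toy_atoms()[5:8, ])
  iso <- solvent_accessibility(read_structure(path_iso, "A"))
  expect_gte(iso$asa, inside$asa[2])
  strict <- solvent_accessibility(st, surface_cutoff = 2)
  loose <- solvent_accessibility(st, surface_cutoff = 0)
  expect_equal(strict$asa, inside$asa) # cutoff never changes ASA values
  expect_equal(loose$asa, inside$asa)
  expect_true(all(!strict$surface))
  expect_true(all(loose$surface))
})

test_that("conservation symbols follow the Clustal group rules", {
  aln <- c(ref = "AIGW-", s2 = "ALGWC", s3 = "AVGWC")
  cons <- msa_conservation(aln, reference = "ref")
  expect_equal(cons$symbol, c("*", ":", "*", "*", " "))
  expect_equal(cons$position, c(1L, 2L, 3L, 4L, NA))
  # weak group and no-group columns
  aln2 <- c(a = "CG", b = "SW", c = "AG")
  cons2 <- msa_conservation(aln2)
  expect_equal(cons2$symbol[1], ".") # {C,S,A} is a weak group
  expect_equal(cons2$symbol[2], " ") # {G,W} matches no group
  # row order does not matter
  expect_equal(
    msa_conservation(aln)$symbol,
    msa_conservation(aln[c(1, 3, 2)])$symbol
  )
})

test_that("annotation joins every track onto one row per residue", {
  sub <- substrate_protein(paste0("KKKK", "AGA", "KK"), numbering_offset = 10L)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_toy_pdb(path, toy_atoms(), helix = tibble::tibble(start = 1, end = 3))
  st <- read_structure(path, "A")
  prof <- tibble::tibble(p1 = rep(c(2L, 5L), each = 2),
                         time_s = rep(c(15, 60), 2),
                         frequency = c(1, 3, 0, 2))
  msa <- c(ref = sub$sequence, other = sub$sequence)
  ann <- annotate_profiles(prof, sub, structure = st, msa = msa)
  expect_equal(nrow(ann), sub$length)
  expect_equal(ann$native_position, 11:19)
  expect_equal(ann$ss[5:7], rep("helix", 3))
  expect_true(all(ann$conservation == "*"))
  expect_equal(ann$freq_15[ann$position == 2], 1)
  expect_equal(ann$freq_60[ann$position == 5], 2)
  # annotation-only table when no profiles exist
  empty <- annotate_profiles(prof[0, ], sub)
  expect_equal(nrow(empty), sub$length)
  # oracle: join equals a dictionary merge on position for the B-factor track
  expect_equal(ann$b_factor[5:7], st$residues$b_mean)
})
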