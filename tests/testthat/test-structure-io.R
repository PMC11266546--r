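test_that("PDB parse/write round-trip preserves coordinates and sequence", {
  s <- make_helix_structure("ACDEFGHIKL", id = "rt", seed = 1)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(s, f)
  s2 <- parse_structure(f)
  expect_equal(nrow(s2$atoms), nrow(s$atoms))
  expect_lt(max(abs(as.matrix(s2$atoms[, c("x", "y", "z")]) -
                      as.matrix(s$atoms[, c("x", "y", "z")]))), 1e-3)
  expect_equal(unname(structure_sequences(s2)), "ACDEFGHIKL")
})

test_that("altloc records resolve to the highest-occupancy conformer", {
  lines <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA AALA A   1       1.458   0.000   0.000  0.60  0.00           C",
    "ATOM      3  CA BALA A   1       1.400   0.200   0.000  0.40  0.00           C",
    "ATOM      4  C   ALA A   1       2.009   1.420   0.000  1.00  0.00           C",
    "END")
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, f)
  s <- parse_structure(f)
  ca <- s$atoms[trimws(s$atoms$atom_name) == "CA", ]
  expect_equal(nrow(ca), 1L)
  expect_equal(ca$occupancy, 0.6)
  expect_equal(ca$x, 1.458)
})

test_that("waters are excluded by default and hetero atoms retained", {
  lines <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "HETATM    3 ZN    ZN A  90       5.000   5.000   5.000  1.00  0.00          ZN",
    "HETATM    4  O   HOH A  99       8.000   8.000   8.000  1.00  0.00           O",
    "END")
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, f)
  s <- parse_structure(f)
  expect_equal(nrow(s$atoms), 3L)
  expect_true("other" %in% s$atoms$element)  # Zn maps to the catch-all class
  expect_equal(nrow(parse_structure(f, keep_hetero = FALSE)$atoms), 2L)
})

test_that("unparseable and empty files raise parse errors", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(character(0), f)
  expect_error(parse_structure(f))
  expect_error(parse_structure("/nonexistent/file.pdb"), "not found")
  g <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("ATOM      1  N   ALA A   1       0.0", "END"), g)
  expect_error(suppressWarnings(parse_structure(g)))
})

test_that("requesting a missing model names the model index", {
  s <- make_helix_structure("AAA", seed = 1)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(s, f)
  expect_error(parse_structure(f, model_index = 3), "model 3")
})

test_that("partial charges follow the bundled table with 0.0 fallback", {
  s <- make_helix_structure("GAG", id = "chg", seed = 1)
  tab <- default_charge_table()
  s2 <- assign_partial_charges(s, tab)
  gly_n <- s2$atoms$partial_charge[s2$atoms$residue_name == "GLY" &
                                     s2$atoms$atom_name == "N"]
  expect_identical(unique(gly_n),
                   tab$charge[tab$residue_name == "GLY" & tab$atom_name == "N"])

  # per-residue sums match a brute-force summation over the table itself
  for (rn in unique(s2$atoms$residue_name)) {
    for (resno in unique(s2$atoms$residue_number[s2$atoms$residue_name == rn])) {
      sel <- s2$atoms$residue_name == rn & s2$atoms$residue_number == resno
      oracle <- sum(vapply(s2$atoms$atom_name[sel], function(an) {
        hit <- tab$charge[tab$residue_name == rn & tab$atom_name == an]
        if (length(hit) == 0) 0 else hit
      }, numeric(1)))
      expect_equal(sum(s2$atoms$partial_charge[sel]), oracle)
    }
  }

  # atom not in the table: 0.0 with a counted warning
  s$atoms$atom_name[1] <- "XX9"
  expect_warning(s3 <- assign_partial_charges(s, tab), "1 atom")
  expect_identical(s3$atoms$partial_charge[1], 0)
  expect_identical(attr(s3, "n_uncharged"), 1L)
})

test_that("SASA matches the closed form for isolated and distant atoms", {
  iso <- compute_sasa(atom_structure(c(0, 0, 0)))
  expect_equal(iso$atoms$sasa, 4 * pi * (1.7 + 1.4)^2, tolerance = 1e-8)

  far <- compute_sasa(atom_structure(rbind(c(0, 0, 0), c(100, 0, 0))))
  expect_equal(far$atoms$sasa, rep(4 * pi * 3.1^2, 2), tolerance = 1e-8)
})

test_that("a fully enclosed atom has zero SASA (point-rejection oracle)", {
  shell <- mutstab:::golden_spiral_points(80) * 2.4
  s <- compute_sasa(atom_structure(rbind(c(0, 0, 0), shell)),
                    n_sphere_points = 1920L)
  expect_equal(s$atoms$sasa[1], 0)
  # oracle: every test point of the central atom is inside a shell sphere
  pts <- mutstab:::golden_spiral_points(1920) * 3.1
  covered <- vapply(seq_len(nrow(pts)), function(i) {
    any(sqrt(colSums((t(shell) - pts[i, ])^2)) < 3.1)
  }, TRUE)
  expect_true(all(covered))
})

test_that("SASA is rigid-motion invariant and monotone under atom addition", {
  s <- make_helix_structure("ACDEF", id = "inv", seed = 1)
  a <- compute_sasa(s, n_sphere_points = 240L)
  withr::local_seed(5)
  R <- random_rotation()
  b <- compute_sasa(rotate_structure(s, R, shift = c(3, -2, 7)),
                    n_sphere_points = 240L, rotation = R)
  expect_lt(max(abs(a$atoms$sasa - b$atoms$sasa)), 1e-6)
  # independently rotated point set: agreement within 1% of total area
  c_ <- compute_sasa(rotate_structure(s, R), n_sphere_points = 960L)
  a2 <- compute_sasa(s, n_sphere_points = 960L)
  expect_lt(abs(sum(c_$atoms$sasa) - sum(a2$atoms$sasa)) / sum(a2$atoms$sasa),
            0.01)

  # adding atoms can only occlude: per-atom SASA non-increasing
  bigger <- make_helix_structure("ACDEFGH", id = "inv2", seed = 1)
  big <- compute_sasa(bigger, n_sphere_points = 240L)
  shared <- seq_len(nrow(a$atoms))
  expect_true(all(big$atoms$sasa[shared] <= a$atoms$sasa[shared] + 1e-9))
})

test_that("residue RSA is capped at 1 and near 1 for a free residue", {
  free <- featurize_structure(make_helix_structure("A", id = "free", seed = 1))
  r <- residue_rsa(free)
  expect_true(r$rsa >= 0.9 && r$rsa <= 1)
})

test_that("chain FASTA export round-trips through Biostrings", {
  s <- fx_helix()
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(s, f)
  seqs <- Biostrings::readAAStringSet(f)
  expect_equal(as.character(seqs[[1]]), "ACDEFGHIKL")
})
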