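test_that("toy complexes are deterministic, two-chained and meet the gap", {
  s1 <- make_toy_complex(5, 4.0, 42)
  s2 <- make_toy_complex(5, 4.0, 42)
  expect_identical(s1$atoms, s2$atoms)
  expect_setequal(unique(s1$atoms$chain), c("A", "B"))

  # brute-force minimal inter-chain distance
  a <- s1$atoms[s1$atoms$chain == "A", c("x", "y", "z")]
  b <- s1$atoms[s1$atoms$chain == "B", c("x", "y", "z")]
  dmin <- min(as.matrix(stats::dist(rbind(a, b)))[seq_len(nrow(a)),
                                                  nrow(a) + seq_len(nrow(b))])
  expect_gt(dmin, 3.9)
  expect_lt(dmin, 4.1)

  tiny <- make_toy_complex(1, 10.0, 1)
  expect_equal(length(unique(tiny$atoms$chain)), 2)
  expect_equal(nrow(unique(tiny$atoms[, c("chain", "resno")])), 2)
})

test_that("PDB write/read round-trips and mmCIF agrees with PDB", {
  s <- make_toy_complex(4, 4.5, 7)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(s, f)
  s2 <- read_structure(f)
  expect_equal(nrow(s2$atoms), nrow(s$atoms))
  expect_lt(max(abs(as.matrix(s2$atoms[, c("x", "y", "z")]) -
                      as.matrix(s$atoms[, c("x", "y", "z")]))), 1e-3)

  pdb <- read_structure(system.file("extdata", "toy_complex.pdb",
                                    package = "ppiddg"))
  cif <- read_structure(system.file("extdata", "toy_complex.cif",
                                    package = "ppiddg"))
  expect_equal(nrow(pdb$atoms), nrow(cif$atoms))
  expect_lt(max(abs(as.matrix(pdb$atoms[, c("x", "y", "z")]) -
                      as.matrix(cif$atoms[, c("x", "y", "z")]))), 1e-3)
  expect_identical(pdb$atoms$elety, cif$atoms$elety)
})

test_that("altloc handling keeps the highest-occupancy conformer, ties -> A", {
  lines <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA AALA A   1       1.458   0.000   0.000  0.60  0.00           C",
    "ATOM      3  CA BALA A   1       9.000   9.000   9.000  0.40  0.00           C",
    "ATOM      4  C   ALA A   1       2.009   1.423   0.000  1.00  0.00           C",
    "ATOM      5  O   ALA A   1       1.251   2.390   0.000  1.00  0.00           O",
    "ATOM      6  CB AALA A   1       2.000   0.000   1.000  0.50  0.00           C",
    "ATOM      7  CB BALA A   1       8.000   8.000   8.000  0.50  0.00           C",
    "END")
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, f)
  s <- read_structure(f)
  ca <- s$atoms[s$atoms$elety == "CA", ]
  expect_equal(nrow(ca), 1)
  expect_equal(ca$x, 1.458)         # higher occupancy wins
  cb <- s$atoms[s$atoms$elety == "CB", ]
  expect_equal(nrow(cb), 1)
  expect_equal(cb$x, 2.0)           # occupancy tie resolved towards altloc A

  # when altloc B has the higher occupancy, B must win
  lines2 <- sub("0.60", "0.30", lines)
  f2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines2, f2)
  s2 <- read_structure(f2)
  expect_equal(s2$atoms[s2$atoms$elety == "CA", "x"], 9.0)
})

test_that("unreadable or empty inputs raise format errors", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("REMARK nothing here", "END"), f)
  expect_error(read_structure(f), "empty structure|cannot parse")
  expect_error(read_structure("no_such_file_anywhere"), "no local structure")
})

test_that("relative solvent accessibility behaves at both exposure extremes", {
  iso <- mk_isolated_gly()
  expect_gt(relative_solvent_accessibility(iso, residue_ref("A", 1)), 0.7)

  buried <- mk_buried_gly()
  expect_lt(relative_solvent_accessibility(buried, residue_ref("A", 1)), 0.05)

  expect_error(
    relative_solvent_accessibility(
      mk_structure("A", 1L, "XXX", "CA", "C", rbind(c(0, 0, 0))),
      residue_ref("A", 1)),
    "unknown residue")
})

test_that("per-residue SASA adds up to the whole-structure SASA", {
  s <- make_toy_complex(4, 4.0, 3)
  sa <- atom_sasa(s)
  per_res <- tapply(sa, paste(s$atoms$chain, s$atoms$resno), sum)
  expect_equal(sum(per_res), sum(sa), tolerance = 0.01)
})

test_that("phi torsion matches geometry and flags undefined cases", {
  h <- make_helix(10)
  expect_true(is.na(phi_torsion(h, residue_ref("A", 1))))
  for (i in 3:8)
    expect_equal(phi_torsion(h, residue_ref("A", i)), -57, tolerance = 3)

  # exactly planar-trans four atoms -> +/-180
  expect_equal(abs(dihedral_angle(c(0, 1, 0), c(0, 0, 0), c(1.5, 0, 0),
                                  c(1.5, -1, 0))), 180)

  # missing backbone atom -> NA with warning, not an error
  h2 <- h
  h2$atoms <- h2$atoms[!(h2$atoms$resno == 4 & h2$atoms$elety == "N"), ]
  expect_warning(v <- phi_torsion(h2, residue_ref("A", 4)), "missing backbone")
  expect_true(is.na(v))
})

test_that("residue depth separates surface from deeply buried residues", {
  s <- make_toy_complex(4, 4.0, 3)
  sa <- atom_sasa(s)
  expect_lt(residue_depth(s, residue_ref("A", 1), sa), 3)

  ball <- mk_atom_ball(radius = 15, spacing = 2.5)
  sa_ball <- atom_sasa(ball, n_points = 120)
  d <- residue_depth(ball, residue_ref("A", 1), sa_ball)
  expect_gte(d, 10)
  # brute-force oracle: mean over residue heavy atoms of min distance to
  # solvent-exposed atom centers
  surf <- which(sa_ball > 0)
  res_idx <- which(ball$atoms$chain == "A" & ball$atoms$resno == 1)
  oracle <- mean(vapply(res_idx, function(i) {
    min(sqrt((ball$atoms$x[surf] - ball$atoms$x[i])^2 +
               (ball$atoms$y[surf] - ball$atoms$y[i])^2 +
               (ball$atoms$z[surf] - ball$atoms$z[i])^2))
  }, numeric(1)))
  expect_equal(d, oracle, tolerance = 1e-9)
})

test_that("geometry descriptors are invariant under rigid-body transforms", {
  s <- make_toy_complex(4, 4.0, 5)
  sa <- atom_sasa(s)
  r <- residue_ref("A", 2)
  rsa0 <- relative_solvent_accessibility(s, r, sa)
  dep0 <- residue_depth(s, r, sa)
  phi0 <- phi_torsion(s, r)
  for (seed in 1:3) {
    tr <- random_rigid(seed)
    st <- transform_structure(s, tr$rot, tr$tr)
    sat <- atom_sasa(st)
    expect_equal(relative_solvent_accessibility(st, r, sat), rsa0,
                 tolerance = 1e-6)
    expect_equal(residue_depth(st, r, sat), dep0, tolerance = 1e-6)
    expect_equal(phi_torsion(st, r), phi0, tolerance = 1e-6)
  }
})

test_that("chain sequences and FASTA input agree", {
  s <- make_toy_complex(3, 4.0, 2, substitutions = c(A2 = "W"))
  expect_equal(chain_sequence(s, "A"), "AWA")
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">chainA", "AWA", ">chainB", "AAA"), f)
  fa <- read_fasta(f)
  expect_equal(unname(fa["chainA"]), chain_sequence(s, "A"))
  expect_equal(unname(fa["chainB"]), chain_sequence(s, "B"))
})

test_that("amino-acid composition counts letters with the X exclusion", {
  v <- aa_composition("AAAA")
  expect_equal(unname(v["A"]), 1)
  expect_equal(sum(v), 1)
  expect_equal(unname(aa_composition("ACDEFGHIKLMNPQRSTVWY")),
               rep(0.05, 20))
  vx <- aa_composition("AAX")
  expect_equal(unname(vx["A"]), 1)
  expect_error(aa_composition(""), "non-empty")
  expect_error(aa_composition("AAZ"), "invalid residue")
  # property: sums to 1 for random valid sequences
  set.seed(4)
  for (k in 1:20) {
    seq <- paste(sample(ppiddg:::AA_ALPHABET, sample(3:40, 1),
                        replace = TRUE), collapse = "")
    expect_equal(sum(aa_composition(seq)), 1, tolerance = 1e-9)
  }
})
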