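test_that("glycine/proline flags enumerate the four cases", {
  expect_equal(unname(gly_pro_flags("G", "A")), c(1L, 0L, 0L, 0L))
  expect_equal(unname(gly_pro_flags("A", "P")), c(0L, 0L, 0L, 1L))
  expect_equal(unname(gly_pro_flags("L", "K")), c(0L, 0L, 0L, 0L))
  expect_equal(unname(gly_pro_flags("P", "G")), c(0L, 1L, 1L, 0L))
  expect_error(gly_pro_flags("B", "A"), "invalid amino acid")
})

test_that("the PSI-BLAST PSSM parser round-trips the shipped fixture", {
  p <- read_pssm(system.file("extdata", "example_10res.pssm",
                             package = "ppiddg"))
  expect_equal(dim(p$scores), c(10L, 20L))
  expect_equal(p$query, "MKVLAYGFTT")
  # frozen values printed in the fixture file: position 3 is V
  expect_equal(unname(p$scores[3, "V"]), 8L)
  expect_equal(unname(p$scores[3, "A"]), -3L)
  expect_equal(unname(p$scores[1, "M"]), 6L)

  # a row with 19 score columns must fail with a line number
  lines <- readLines(system.file("extdata", "example_10res.pssm",
                                 package = "ppiddg"))
  broken <- lines
  row3 <- strsplit(trimws(broken[6]), "\\s+")[[1]]
  broken[6] <- paste(row3[-length(row3)], collapse = " ")
  f <- withr::local_tempfile(fileext = ".pssm")
  writeLines(broken, f)
  expect_error(read_pssm(f), "line 6")
})

test_that("evolutionary scores check alignment and subtract correctly", {
  p <- read_pssm(system.file("extdata", "example_10res.pssm",
                             package = "ppiddg"))
  sc <- evolutionary_scores(p, 3, "V", "A")
  expect_equal(unname(sc), c(8, -3, 11))
  expect_equal(unname(evolutionary_scores(p, 3, "V", "V")["diff"]), 0)
  expect_error(evolutionary_scores(p, 99, "V", "A"), "outside")
  expect_error(evolutionary_scores(p, 3, "L", "A"), "misalignment")
})

test_that("a PSSM can be built from an alignment as a fallback", {
  aln <- c("ACDE", "ACDE", "ACDF", "ACDE", "GCDE")
  p <- pssm_from_alignment(aln)
  expect_equal(dim(p$scores), c(4L, 20L))
  expect_equal(p$query, "ACDE")
  # conserved cysteine column scores C above a residue never observed
  expect_gt(p$scores[2, "C"], p$scores[2, "W"])
})

test_that("contact potential lookups are symmetric and fixture-exact", {
  tabs <- default_contact_potentials()
  expect_length(tabs, 3)
  for (tb in tabs) expect_equal(tb, t(tb))
  expect_equal(contact_potential_scores("A", "L"),
               contact_potential_scores("L", "A"))
  # frozen printed cell: first table, A/A is the first lower-triangle value
  first_line <- readLines(system.file(
    "extdata", "contact_potential_synthetic1.aaindex",
    package = "ppiddg"))[5]
  expect_equal(contact_potential_scores("A", "A")[1],
               as.numeric(trimws(first_line)))
  expect_error(contact_potential_scores("A", "Z"), "not present")
})

test_that("FoldX-style adapters parse terms or mark the block absent", {
  expect_true(ppiddg:::is_absent(energetic_terms()))
  e <- energetic_terms(
    system.file("extdata", "example_interaction.fxout", package = "ppiddg"),
    system.file("extdata", "example_dif.fxout", package = "ppiddg"))
  expect_equal(unname(e), c(-12.34, 1.87))
  f <- withr::local_tempfile(fileext = ".fxout")
  writeLines(c("garbage", "no header here"), f)
  expect_error(energetic_terms(f, NULL), "malformed FoldX")
})

test_that("elastic-network fluctuations have 6 rigid modes and match the
          pseudo-inverse oracle", {
  h <- make_helix(10)
  for (ff in c("calpha", "pfanm")) {
    prof <- enm_fluctuations(h, ff)
    expect_length(prof$fluctuations, 10)
    expect_true(all(prof$fluctuations > 0))
    # independent oracle: build the Hessian from the published spring
    # definitions and invert with MASS::ginv
    ca <- h$atoms[h$atoms$elety == "CA", ]
    xyz <- as.matrix(ca[, c("x", "y", "z")])
    n <- nrow(xyz)
    hess <- matrix(0, 3 * n, 3 * n)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      dv <- xyz[j, ] - xyz[i, ]
      d <- sqrt(sum(dv^2))
      k <- if (ff == "pfanm") d^-2 else {
        if (d > 15) 0 else {
          dd <- max(d, 2.9)
          if (dd < 4) 8.6e2 * dd - 2.39e3 else 128e4 * dd^-6
        }
      }
      if (k == 0) next
      u <- dv / d
      blk <- k * (u %o% u)
      ii <- (3 * i - 2):(3 * i); jj <- (3 * j - 2):(3 * j)
      hess[ii, jj] <- hess[ii, jj] - blk
      hess[jj, ii] <- hess[jj, ii] - blk
      hess[ii, ii] <- hess[ii, ii] + blk
      hess[jj, jj] <- hess[jj, jj] + blk
    }
    pinv <- MASS::ginv(hess)
    oracle <- vapply(seq_len(n), function(i)
      sum(diag(pinv)[(3 * i - 2):(3 * i)]), numeric(1))
    expect_equal(prof$fluctuations, oracle, tolerance = 1e-8)
  }
})

test_that("fluctuations are isometry-invariant and mirror-symmetric", {
  h <- make_helix(8)
  base <- enm_fluctuations(h, "calpha")$fluctuations
  tr <- random_rigid(2)
  ht <- transform_structure(h, tr$rot, tr$tr)
  expect_equal(enm_fluctuations(ht, "calpha")$fluctuations, base,
               tolerance = 1e-6)

  # palindromic 3D chain: mirror-image residues fluctuate identically
  xs <- c(-3.5, -2.5, -1.5, -0.5, 0.5, 1.5, 2.5, 3.5)
  xyz <- cbind(xs, cos(abs(xs)) * 2, sin(2 * abs(xs)))
  s <- mk_structure("A", seq_along(xs), rep("ALA", length(xs)),
                    rep("CA", length(xs)), rep("C", length(xs)), xyz)
  fl <- enm_fluctuations(s, "pfanm")$fluctuations
  expect_equal(fl, rev(fl), tolerance = 1e-6)

  # degenerate geometry is rejected
  line <- cbind(seq(0, 10, length.out = 6), 0, 0)
  sl <- mk_structure("A", 1:6, rep("ALA", 6), rep("CA", 6), rep("C", 6),
                     line)
  expect_error(enm_fluctuations(sl, "pfanm"), "degenerate|collinear")
  expect_error(enm_fluctuations(make_helix(3), "pfanm"), ">= 4 CA")
})

test_that("calpha and pfanm profiles agree in rank on a helix", {
  h <- make_helix(20)
  a <- enm_fluctuations(h, "calpha")$fluctuations
  b <- enm_fluctuations(h, "pfanm")$fluctuations
  expect_gt(cor(a, b, method = "spearman"), 0.5)
})

test_that("feature assembly is deterministic, named and CSV-stable", {
  s <- make_toy_complex(4, 4.0, 5)
  ctx <- feature_context(s)
  r <- residue_ref("A", 2)
  f1 <- compute_mutation_features(ctx, r, "G")
  f2 <- compute_mutation_features(ctx, r, "G")
  expect_identical(f1, f2)

  # length is the sum of the block lengths
  expect_length(f1, 36 * 19 + 24 + 4 + 4 + 5 + 3 + 3 + 2 + 4)
  expect_equal(attr(f1, "absent_blocks"), c("evolution", "energy"))

  # absent blocks are explicit NA, never silent zeros
  expect_true(all(is.na(f1[c("pssm.diff", "energy.folding_ddg")])))

  # CSV round-trip to 1e-9
  f <- withr::local_tempfile(fileext = ".csv")
  write_feature_csv(list(f1, f2), f)
  back <- read_feature_csv(f)
  expect_equal(names(back), names(f1))
  expect_equal(as.numeric(back[1, ]), as.numeric(f1), tolerance = 1e-9)

  # missing mandatory block errors by name
  expect_error(assemble_features(NULL, environment = 1:24,
                                 flags = gly_pro_flags("A", "G"),
                                 contact_delta = c(0, 0, 0, 0),
                                 network = list(mean_closeness = 0,
                                                central_point_dominance = 0,
                                                graph_center_size = 1,
                                                n_nodes = 1, n_edges = 0)),
               "mandatory feature block missing: signature")
})
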