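test_that("free-energy conversion follows RT ln(KD) with the fixed constants", {
  expect_identical(dg_from_kd(1.0, 298.15), 0)
  # independent evaluation of the formula with the printed constant
  expect_equal(dg_from_kd(1e-9, 298.15), 1.985e-3 * 298.15 * log(1e-9))
  expect_equal(dg_from_kd(1e-9, 298.15), -12.27, tolerance = 0.01)
  expect_equal(dg_from_kd(1e-6, 298.15), -8.18, tolerance = 0.01)
  # strictly increasing in kd
  kds <- 10^seq(-12, 0, by = 1)
  expect_true(all(diff(dg_from_kd(kds, 298.15)) > 0))
  expect_error(dg_from_kd(0), "KD")
  expect_error(dg_from_kd(-1), "KD")
})

test_that("ddg subtracts wild-type minus mutant and is antisymmetric", {
  expect_identical(ddg(-10, -10), 0)
  expect_equal(ddg(-12.27, -8.18), -4.09)
  set.seed(8)
  a <- rnorm(50); b <- rnorm(50)
  expect_identical(ddg(a, b), -ddg(b, a))
})

test_that("replicate aggregation means under 2.0 kcal/mol spread, else drops", {
  expect_equal(aggregate_replicates(1.2), 1.2)
  expect_equal(aggregate_replicates(c(1.0, 2.5)), 1.75)
  expect_true(is.na(aggregate_replicates(c(0.0, 2.5))))   # spread >= 2.0
  expect_true(is.na(aggregate_replicates(c(0.0, 2.0))))   # strict <
  expect_equal(aggregate_replicates(c(0.0, 1.999999)), mean(c(0, 1.999999)))
  expect_error(aggregate_replicates(numeric(0)), "no replicate")
})

test_that("SKEMPI curation retains exactly the hand-curated fixture rows", {
  path <- system.file("extdata", "skempi_fixture.csv", package = "ppiddg")
  recs <- parse_skempi(path)
  counts <- attr(recs, "curation_counts")
  expect_equal(counts$n_input, 12)
  expect_equal(counts$n_multi_dropped, 1)
  expect_equal(counts$n_discarded_replicate_spread, 1)
  expect_equal(counts$n_retained, 8)
  expect_equal(nrow(recs), 8)

  # the aggregated replicate pair: mean of the two per-experiment ddGs,
  # recomputed independently from the printed KD values
  rt <- 1.985e-3 * 298
  d1 <- rt * log(1e-9) - rt * log(1e-7)
  d2 <- rt * log(1e-9) - rt * log(1.2e-7)
  agg <- recs[recs$pdb_id == "1ABC" & recs$res_number == 38, ]
  expect_equal(agg$ddg, mean(c(d1, d2)))
  expect_equal(agg$n_replicates, 2)

  # the discarded pair (spread > 2) and the multi-point row are absent
  expect_false(any(recs$res_number == 40 & recs$pdb_id == "1ABC"))

  # the missing-temperature row fell back to 298.15 K
  expect_equal(recs$temperature[recs$res_number == 31], 298.15)
  # the "(assumed)" annotation parses to its numeric part
  expect_equal(recs$temperature[recs$res_number == 30], 298)

  # stabilising mutation has positive ddg under the wt - mut convention
  expect_gt(recs$ddg[recs$mut_aa == "W"], 0)

  # order independence: shuffling input rows leaves the retained set alone
  lines <- readLines(path)
  set.seed(3)
  shuffled <- c(lines[1], sample(lines[-1]))
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(shuffled, f)
  recs2 <- parse_skempi(f)
  o1 <- recs[order(recs$complex_id, recs$chain, recs$res_number), ]
  o2 <- recs2[order(recs2$complex_id, recs2$chain, recs2$res_number), ]
  rownames(o1) <- rownames(o2) <- NULL
  attr(o1, "curation_counts") <- attr(o2, "curation_counts") <- NULL
  expect_equal(o1, o2)
})

test_that("unparseable affinities are skipped, missing columns fatal", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("#Pdb;Mutation(s)_PDB;Affinity_mut_parsed;Affinity_wt_parsed;Temperature",
               "1AAA_A_B;LA1G;n.b.;1.0E-09;298",
               "1AAA_A_B;KA2M;1.0E-08;1.0E-09;298"), f)
  expect_message(recs <- parse_skempi(f), "unparseable affinity")
  expect_equal(nrow(recs), 1)
  expect_equal(recs$mut_aa, "M")

  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("#Pdb;Affinity_mut_parsed", "1AAA_A_B;1e-9"), f2)
  expect_error(parse_skempi(f2), "missing mandatory SKEMPI columns")
})

test_that("reverse augmentation doubles, negates exactly and refuses twice", {
  recs <- parse_skempi(system.file("extdata", "skempi_fixture.csv",
                                   package = "ppiddg"))
  aug <- augment_reverse(recs)
  expect_equal(nrow(aug), 2 * nrow(recs))
  fwd <- aug[!aug$is_reverse, ]
  rev <- aug[aug$is_reverse, ]
  expect_identical(fwd$ddg + rev$ddg[match(fwd$pair_id, rev$pair_id)],
                   rep(0, nrow(fwd)))
  expect_identical(rev$wt_aa, fwd$mut_aa)
  expect_identical(rev$mut_aa, fwd$wt_aa)
  expect_error(augment_reverse(aug), "refusing to re-augment")
})

test_that("paired stratified k-fold keeps twins together with even folds", {
  recs <- parse_skempi(system.file("extdata", "skempi_fixture.csv",
                                   package = "ppiddg"))
  aug <- augment_reverse(recs)
  plan <- split_stratified_paired(aug, k = 4, repeats = 10, seed = 17)
  asg <- plan$assignments
  for (r in unique(asg$rep)) {
    sub <- asg[asg$rep == r, ]
    # full partition
    expect_setequal(sub$row, seq_len(nrow(aug)))
    # twins never straddle folds
    per_pair <- tapply(sub$fold, aug$pair_id[sub$row],
                       function(x) length(unique(x)))
    expect_true(all(per_pair == 1))
    # fold sizes differ by at most 2 records (one pair)
    sizes <- table(sub$fold)
    expect_lte(max(sizes) - min(sizes), 2)
  }
  # deterministic per seed
  plan2 <- split_stratified_paired(aug, k = 4, repeats = 10, seed = 17)
  expect_identical(plan$assignments, plan2$assignments)
  plan3 <- split_stratified_paired(aug, k = 4, repeats = 10, seed = 18)
  expect_false(identical(plan$assignments, plan3$assignments))

  expect_error(split_stratified_paired(aug, k = 99), "exceeds")
  expect_error(split_stratified_paired(recs), "augmented")
})

test_that("leave-one-complex-out and leave-one-binding-site-out never leak", {
  recs <- parse_skempi(system.file("extdata", "skempi_fixture.csv",
                                   package = "ppiddg"))
  loco <- split_leave_one_complex_out(recs)
  expect_equal(length(unique(loco$assignments$group)),
               length(unique(recs$complex_id)))
  for (g in unique(loco$assignments$group)) {
    test_rows <- loco$assignments$row[loco$assignments$group == g]
    train_rows <- setdiff(seq_len(nrow(recs)), test_rows)
    expect_length(intersect(recs$complex_id[test_rows],
                            recs$complex_id[train_rows]), 0)
  }

  lobso <- split_leave_one_binding_site_out(recs)
  expect_equal(length(unique(lobso$assignments$group)),
               length(unique(recs$binding_site_id)))
  for (g in unique(lobso$assignments$group)) {
    test_rows <- lobso$assignments$row[lobso$assignments$group == g]
    train_rows <- setdiff(seq_len(nrow(recs)), test_rows)
    expect_length(intersect(recs$binding_site_id[test_rows],
                            recs$binding_site_id[train_rows]), 0)
  }

  one <- recs[recs$complex_id == recs$complex_id[1], ]
  expect_error(split_leave_one_complex_out(one), ">= 2 complexes")
})

test_that("mutations at one site share a binding-site group", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("#Pdb;Mutation(s)_PDB;Affinity_mut_parsed;Affinity_wt_parsed;Temperature",
               "1AAA_A_B;LA1G;1.0E-08;1.0E-09;298",
               "1AAA_A_B;LA1W;2.0E-08;1.0E-09;298",
               "1AAA_A_B;KA2M;1.0E-08;1.0E-09;298",
               "2BBB_A_B;KA2M;1.0E-08;1.0E-09;298"), f)
  recs <- parse_skempi(f)
  expect_equal(recs$binding_site_id[1], recs$binding_site_id[2])
  expect_equal(length(unique(recs$binding_site_id)), 3)
})
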