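# Shared fixtures and independent oracles for the test suite.  Everything
# is generated in code; nothing is downloaded.

# bare atom-table structure builder for synthetic geometries
mk_structure <- function(chain, resno, resid, elety, element, xyz,
                         icode = "") {
  ppiddg:::new_structure(data.frame(
    chain = chain, resno = resno, icode = icode, resid = resid,
    aa = unname(ifelse(resid %in% names(ppiddg:::AA_THREE_TO_ONE),
                       ppiddg:::AA_THREE_TO_ONE[resid], "X")),
    elety = elety, element = element,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], occ = 1,
    stringsAsFactors = FALSE), id = "synthetic")
}

# a single isolated glycine residue (backbone only, ideal-ish geometry)
mk_isolated_gly <- function() {
  xyz <- rbind(c(0, 0, 0), c(1.458, 0, 0), c(2.009, 1.423, 0),
               c(1.251, 2.39, 0))
  mk_structure("A", 1L, "GLY", c("N", "CA", "C", "O"),
               c("N", "C", "C", "O"), xyz)
}

# glycine at the origin surrounded by a dense occluding shell of carbons
mk_buried_gly <- function(r_shell = 6, n_shell = 400) {
  core <- mk_isolated_gly()
  pts <- ppiddg:::sphere_points(n_shell) * r_shell
  shell <- mk_structure("S", seq_len(n_shell) + 10L, "ALA",
                        rep("CA", n_shell), rep("C", n_shell), pts)
  core$atoms <- rbind(core$atoms, shell$atoms)
  core
}

# solid ball of pseudo-atoms on a grid, with a central glycine; used for
# the deep-burial depth fixture
mk_atom_ball <- function(radius = 15, spacing = 2.5) {
  g <- seq(-radius, radius, by = spacing)
  grid <- as.matrix(expand.grid(x = g, y = g, z = g))
  grid <- grid[sqrt(rowSums(grid^2)) <= radius &
                 sqrt(rowSums(grid^2)) > 2.5, , drop = FALSE]
  core <- mk_isolated_gly()
  n <- nrow(grid)
  shell <- mk_structure("S", seq_len(n) + 10L, "ALA", rep("CA", n),
                        rep("C", n), grid)
  core$atoms <- rbind(core$atoms, shell$atoms)
  core
}

# seeded random proper rotation + translation
random_rigid <- function(seed) {
  set.seed(seed)
  rot <- ppiddg:::random_rotation()
  list(rot = rot, tr = stats::runif(3, -20, 20))
}

# construct a ppi_environment directly from coordinates and a label matrix
mk_environment <- function(xyz, labels, radius = 1e6) {
  n <- nrow(xyz)
  atoms <- data.frame(
    chain = "A", resno = seq_len(n), icode = "", resid = "ALA", aa = "A",
    elety = "CA", element = "C", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    occ = 1, stringsAsFactors = FALSE)
  structure(list(center = colMeans(xyz), atoms = atoms, labels = labels,
                 radius = radius, focus = NULL),
            class = "ppi_environment")
}

# independent brute-force cutoff-scan oracle: explicit per-pair loop over
# distinct unordered label pairs, then cumulative sum
oracle_signature <- function(xyz, labels, cutoffs) {
  classes <- colnames(labels)
  pp <- ppiddg:::pharmacophore_pairs()
  key <- paste(pp$p, pp$q, sep = ":")
  counts <- matrix(0L, nrow(pp), length(cutoffs),
                   dimnames = list(key, as.character(cutoffs)))
  n <- nrow(xyz)
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
        bin <- which(cutoffs >= d)[1]
        if (is.na(bin)) next
        li <- classes[labels[i, ]]
        lj <- classes[labels[j, ]]
        seen <- character(0)
        for (a in li) for (b in lj) {
          # canonical order follows the class table, not the alphabet
          pr <- c(a, b)[order(match(c(a, b), classes))]
          k <- paste(pr[1], pr[2], sep = ":")
          if (!k %in% seen) {
            seen <- c(seen, k)
            counts[k, bin] <- counts[k, bin] + 1L
          }
        }
      }
    }
  }
  t(apply(counts, 1, cumsum))
}

# brute-force interfacial residue oracle (all-pairs, inclusive boundary)
oracle_interface <- function(s, cutoff = 5.0) {
  a <- s$atoms[s$atoms$element != "H", , drop = FALSE]
  out <- character(0)
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(a))) {
      if (a$chain[i] == a$chain[j]) next
      d <- sqrt(sum((c(a$x[i], a$y[i], a$z[i]) -
                       c(a$x[j], a$y[j], a$z[j]))^2))
      if (d <= cutoff + 1e-6)
        out <- c(out, paste0(a$chain[i], a$resno[i], a$icode[i]))
    }
  }
  sort(unique(out))
}

# shared toy complex + trained model for scan/CLI tests (built once)
.toy_env <- new.env()
toy_model_fixture <- function() {
  if (!is.null(.toy_env$fix)) return(.toy_env$fix)
  s <- make_toy_complex(5, 4.0, 42, substitutions = c(A2 = "F", B1 = "K"))
  ctx <- feature_context(s)
  rt <- ppiddg:::residue_table(s)
  set.seed(11)
  feats <- list(); targs <- numeric(0)
  picks <- expand.grid(i = seq_len(nrow(rt)), m = c("G", "L"))
  for (k in seq_len(nrow(picks))) {
    i <- picks$i[k]
    mu <- as.character(picks$m[k])
    if (rt$aa[i] == mu) next
    feats[[length(feats) + 1]] <- compute_mutation_features(
      ctx, residue_ref(rt$chain[i], rt$resno[i]), mu)
    targs <- c(targs, stats::rnorm(1))
  }
  m <- train_model(feats, targs, model_config(num_trees = 60), seed = 5)
  .toy_env$fix <- list(s = s, model = m, ctx = ctx, features = feats,
                       targets = targs)
  .toy_env$fix
}
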