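# Synthetic fixture structures: internally consistent poly-alanine chains
# built from ideal backbone internal coordinates, and two-chain complexes
# with a controllable inter-chain gap.  These are the test-bed the package
# uses in place of downloaded PDB entries.

# Build one poly-alanine chain (heavy atoms N, CA, C, O, CB) from phi/psi.
# Returns an atom data.frame in the structure-table layout.
build_polyala_chain <- function(n_res, phi = -57, psi = -47, chain = "A",
                                omega = 180) {
  stopifnot(n_res >= 1)
  phi <- rep_len(phi, n_res)
  psi <- rep_len(psi, n_res)
  coords <- vector("list", n_res)
  # residue 1 in a canonical frame
  n1 <- c(0, 0, 0)
  ca1 <- c(1.458, 0, 0)
  ang <- 111.2 * pi / 180
  c1 <- ca1 + 1.525 * c(cos(pi - ang), sin(pi - ang), 0)
  prev <- list(N = n1, CA = ca1, C = c1)
  for (i in seq_len(n_res)) {
    if (i > 1) {
      nn <- place_atom(prev$N, prev$CA, prev$C, 1.329, 116.6, psi[i - 1])
      ca <- place_atom(prev$CA, prev$C, nn, 1.458, 121.9, omega)
      cc <- place_atom(prev$C, nn, ca, 1.525, 111.2, phi[i])
      prev <- list(N = nn, CA = ca, C = cc)
    }
    o <- place_atom(prev$N, prev$CA, prev$C, 1.231, 120.8, psi[i] + 180)
    cb <- place_atom(prev$C, prev$N, prev$CA, 1.53, 109.5, 120)
    coords[[i]] <- rbind(prev$N, prev$CA, prev$C, o, cb)
  }
  xyz <- do.call(rbind, coords)
  elety <- rep(c("N", "CA", "C", "O", "CB"), n_res)
  data.frame(
    chain = chain, resno = rep(seq_len(n_res), each = 5), icode = "",
    resid = "ALA", aa = "A", elety = elety,
    element = substr(elety, 1, 1),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], occ = 1,
    stringsAsFactors = FALSE)
}

#' Ideal alpha-helix fixture
#'
#' A poly-alanine chain built on ideal helical backbone torsions
#' (phi = -57, psi = -47 degrees).
#'
#' @param n_res number of residues.
#' @param chain chain identifier.
#' @return a \code{ppi_structure}.
#' @export
make_helix <- function(n_res = 12, chain = "A") {
  new_structure(build_polyala_chain(n_res, phi = -57, psi = -47,
                                    chain = chain),
                id = sprintf("helix%d", n_res), source_format = "pdb")
}

# run code with a locally seeded RNG, restoring the caller's RNG state
with_local_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Deterministic two-chain toy complex
#'
#' Builds a two-chain poly-alanine complex whose minimal inter-chain
#' heavy-atom distance equals \code{gap} (to numerical tolerance).  Both
#' chains are ideal alpha-helices (a well-conditioned 3D geometry for the
#' downstream elastic-network features); chain B faces chain A and is
#' translated perpendicular to the helix axis, with the translation solved
#' so the requested gap is met.  The same seed always yields bit-identical
#' coordinates.  Optional residue substitutions turn selected alanines into
#' other amino acids via \code{\link{mutate_residue}}.
#'
#' @param n_res_per_chain residues per chain (>= 1).
#' @param gap target minimal inter-chain heavy-atom distance, Angstrom (> 0).
#' @param seed integer seed controlling the small coordinate jitter.
#' @param substitutions optional named character vector, e.g.
#'   \code{c(A3 = "F", B2 = "W")}: chain id + residue number to mutant
#'   one-letter code.
#' @return a \code{ppi_structure} with chains \code{"A"} and \code{"B"}.
#' @export
make_toy_complex <- function(n_res_per_chain, gap, seed = 1,
                             substitutions = NULL) {
  stopifnot(n_res_per_chain >= 1, gap > 0)
  a <- build_polyala_chain(n_res_per_chain, chain = "A")
  b <- build_polyala_chain(n_res_per_chain, chain = "B")
  with_local_seed(seed, {
    jit_a <- matrix(stats::runif(nrow(a) * 3, -0.05, 0.05), ncol = 3)
    jit_b <- matrix(stats::runif(nrow(b) * 3, -0.05, 0.05), ncol = 3)
  })
  a[, c("x", "y", "z")] <- a[, c("x", "y", "z")] + jit_a
  b[, c("x", "y", "z")] <- b[, c("x", "y", "z")] + jit_b
  # face chain B towards A (rotate 180 degrees about the x axis) and slide it
  # along +z until the minimal heavy-atom separation equals `gap`
  b$y <- -b$y
  b$z <- -b$z
  axyz <- as.matrix(a[, c("x", "y", "z")])
  bxyz <- as.matrix(b[, c("x", "y", "z")])
  mindist <- function(t) {
    bb <- bxyz; bb[, 3] <- bb[, 3] + t
    min(sqrt(pmax(outer(rowSums(axyz^2), rowSums(bb^2), `+`) -
                    2 * axyz %*% t(bb), 0)))
  }
  lo <- 0
  while (mindist(lo) > gap) lo <- lo - 5
  hi <- lo + 5
  while (mindist(hi) < gap) hi <- hi + 5
  t_star <- stats::uniroot(function(t) mindist(t) - gap, c(lo, hi),
                           tol = 1e-9)$root
  b$z <- b$z + t_star
  s <- new_structure(rbind(a, b),
                     id = sprintf("toy%d_g%.1f_s%d", n_res_per_chain, gap,
                                  seed))
  if (!is.null(substitutions)) {
    for (key in names(substitutions)) {
      ch <- substr(key, 1, 1)
      no <- as.integer(substr(key, 2, nchar(key)))
      s <- mutate_residue(s, residue_ref(ch, no), substitutions[[key]])
    }
  }
  s
}
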