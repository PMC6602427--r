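# Elastic network model fluctuations of a monomer, from the C-alpha
# Hessian: Hinsen distance-dependent springs ("calpha") or parameter-free
# inverse-square springs ("pfanm").

# Hinsen (2000) calpha force-field spring constant, r in Angstrom
hinsen_spring <- function(r, rmin = 2.9) {
  r <- pmax(r, rmin)
  ifelse(r < 4, 8.6e2 * r - 2.39e3, 128e4 * r^(-6))
}

# 3N x 3N elastic network Hessian from CA coordinates
enm_hessian <- function(xyz, forcefield = c("calpha", "pfanm"),
                        calpha_cutoff = 15) {
  forcefield <- match.arg(forcefield)
  n <- nrow(xyz)
  h <- matrix(0, 3 * n, 3 * n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dv <- xyz[j, ] - xyz[i, ]
      d <- vnorm(dv)
      k <- switch(forcefield,
                  calpha = if (d <= calpha_cutoff) hinsen_spring(d) else 0,
                  pfanm = d^(-2))
      if (k == 0) next
      u <- dv / d
      blk <- k * (u %o% u)
      ii <- (3 * i - 2):(3 * i); jj <- (3 * j - 2):(3 * j)
      h[ii, jj] <- h[ii, jj] - blk
      h[jj, ii] <- h[jj, ii] - blk
      h[ii, ii] <- h[ii, ii] + blk
      h[jj, jj] <- h[jj, jj] + blk
    }
  }
  h
}

#' Elastic-network atomic fluctuations of a monomer
#'
#' Builds the C-alpha Hessian of the chain under the chosen force field
#' (\code{calpha}: Hinsen distance-dependent spring constants, pair
#' enumeration within 15 A; \code{pfanm}: springs between all pairs with
#' stiffness proportional to 1/d^2), eigen-decomposes it, discards the six
#' near-zero rigid-body modes (tolerance \code{1e-8} of the largest
#' eigenvalue) and accumulates per-residue fluctuations as the sum over
#' internal modes of squared eigenvector components divided by the
#' eigenvalue (the diagonal of the Hessian pseudo-inverse), in arbitrary
#' units.
#'
#' @param monomer a \code{ppi_structure}; if it has several chains, supply
#'   \code{chain}.
#' @param forcefield \code{"calpha"} or \code{"pfanm"}.
#' @param chain chain to analyse (default: the only chain).
#' @return a \code{ppi_fluctuations}: list with \code{fluctuations}
#'   (per-CA, non-negative), \code{forcefield}, \code{residues}.
#' @export
enm_fluctuations <- function(monomer, forcefield = c("calpha", "pfanm"),
                             chain = NULL) {
  forcefield <- match.arg(forcefield)
  a <- monomer$atoms
  if (is.null(chain)) {
    ch <- chain_ids(monomer)
    if (length(ch) > 1)
      stop("structure has several chains; supply `chain`")
    chain <- ch[1]
  }
  ca <- a[a$chain == chain & a$elety == "CA", , drop = FALSE]
  if (nrow(ca) < 4) stop("ENM needs >= 4 CA atoms")
  xyz <- xyz_matrix(ca)
  # collinearity guard: rank of centred coordinates must be 3
  sv <- svd(sweep(xyz, 2, colMeans(xyz)))$d
  if (sv[3] < 1e-6 * sv[1])
    stop("degenerate geometry: CA atoms are (near-)collinear or planar")
  h <- enm_hessian(xyz, forcefield)
  eig <- eigen(h, symmetric = TRUE)
  lam <- eig$values
  tol <- 1e-8 * max(abs(lam))
  zero <- abs(lam) < tol
  if (sum(zero) > 6)
    stop("degenerate elastic network: ", sum(zero), " near-zero modes")
  if (sum(zero) < 6)
    stop("rigid-body modes not resolved: only ", sum(zero),
         " near-zero modes")
  keep <- which(!zero)
  v2 <- eig$vectors[, keep, drop = FALSE]^2
  contrib <- sweep(v2, 2, lam[keep], `/`)
  per_coord <- rowSums(contrib)
  n <- nrow(ca)
  fl <- vapply(seq_len(n), function(i) sum(per_coord[(3 * i - 2):(3 * i)]),
               numeric(1))
  structure(list(fluctuations = fl, forcefield = forcefield,
                 residues = ca[, c("chain", "resno", "icode", "aa")]),
            class = "ppi_fluctuations")
}

#' Fluctuation feature block for a mutation site
#'
#' The mutated residue's own fluctuation and the monomer mean, for both
#' force fields (4 slots).
#'
#' @param s a \code{ppi_structure}.
#' @param r a \code{ppi_residue_ref} (the mutation site; its chain defines
#'   the monomer).
#' @return named numeric vector (calpha_site, calpha_mean, pfanm_site,
#'   pfanm_mean).
#' @export
fluctuation_features <- function(s, r) {
  out <- numeric(0)
  for (ff in c("calpha", "pfanm")) {
    prof <- enm_fluctuations(s, ff, chain = r$chain)
    hit <- prof$residues$resno == r$resno & prof$residues$icode == r$icode
    if (!any(hit)) stop("mutation site has no CA atom in chain ", r$chain)
    out <- c(out, prof$fluctuations[which(hit)[1]],
             mean(prof$fluctuations))
  }
  stats::setNames(out, c("calpha_site", "calpha_mean", "pfanm_site",
                         "pfanm_mean"))
}
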