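# Solvent accessibility (Shrake-Rupley), RSA normalisation and residue
# depth.  SASA is computed on the full complex with a 1.4 A water probe.

# theoretical maximum accessible surface areas (Tien et al. 2013), A^2
MAX_ASA <- c(
  A = 129.0, R = 274.0, N = 195.0, D = 193.0, C = 167.0,
  Q = 225.0, E = 223.0, G = 104.0, H = 224.0, I = 197.0,
  L = 201.0, K = 236.0, M = 224.0, F = 240.0, P = 159.0,
  S = 155.0, T = 172.0, W = 285.0, Y = 263.0, V = 174.0)

VDW_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
               P = 1.80, SE = 1.90)

vdw_radius <- function(element) {
  r <- VDW_RADII[element]
  if (anyNA(r))
    stop("unknown element(s): ",
         paste(unique(element[is.na(r)]), collapse = ", "))
  unname(r)
}

# deterministic quasi-uniform sphere points (golden-section spiral)
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# quasi-uniform sphere points symmetric under all coordinate-sign flips:
# one octant of a dense spiral mirrored into the eight octants.  The flip
# symmetry makes the SASA integration insensitive to the sign ambiguity of
# the structure-derived frame below.
sphere_points_symmetric <- function(n) {
  base <- sphere_points(8 * n)
  oct <- base[base[, 1] > 1e-6 & base[, 2] > 1e-6 & base[, 3] > 1e-6, ,
              drop = FALSE]
  signs <- as.matrix(expand.grid(c(1, -1), c(1, -1), c(1, -1)))
  do.call(rbind, lapply(seq_len(8), function(k)
    sweep(oct, 2, signs[k, ], `*`)))
}

# deterministic principal-axes frame of a coordinate set.  The test-point
# sphere is expressed in this frame, so rigid-body motion of the structure
# carries the integration points along and the SASA is exactly invariant.
principal_frame <- function(xyz) {
  if (nrow(xyz) < 3) return(diag(3))
  v <- eigen(stats::cov(xyz), symmetric = TRUE)$vectors
  for (k in 1:3) {
    i <- which.max(abs(v[, k]))
    if (v[i, k] < 0) v[, k] <- -v[, k]
  }
  if (det(v) < 0) v[, 3] <- -v[, 3]
  v
}

#' Per-atom solvent-accessible surface area (Shrake-Rupley)
#'
#' @param s a \code{ppi_structure}.
#' @param probe probe radius in Angstrom (water: 1.4).
#' @param n_points test points per atom sphere.
#' @return numeric vector, one SASA value (A^2) per atom row of \code{s}.
#' @export
atom_sasa <- function(s, probe = 1.4, n_points = 500) {
  a <- s$atoms
  xyz <- xyz_matrix(a)
  rad <- vdw_radius(a$element) + probe
  n <- nrow(a)
  pts <- sphere_points_symmetric(ceiling(n_points / 8)) %*%
    t(principal_frame(xyz))
  n_points <- nrow(pts)
  out <- numeric(n)
  # neighbour lists via a coarse distance prefilter
  maxr <- max(rad)
  for (i in seq_len(n)) {
    d2 <- (xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2 +
      (xyz[, 3] - xyz[i, 3])^2
    nb <- which(d2 < (rad[i] + maxr)^2 & d2 > 1e-12)
    nb <- nb[sqrt(d2[nb]) < rad[i] + rad[nb]]
    surf <- sweep(pts * rad[i], 2, xyz[i, ], `+`)
    if (length(nb) == 0) {
      acc <- n_points
    } else {
      nbxyz <- xyz[nb, , drop = FALSE]
      dd <- outer(rowSums(surf^2), rowSums(nbxyz^2), `+`) -
        2 * surf %*% t(nbxyz)
      covered <- rowSums(sweep(dd, 2, rad[nb]^2, `<`) ) > 0
      acc <- sum(!covered)
    }
    out[i] <- 4 * pi * rad[i]^2 * acc / n_points
  }
  out
}

#' Relative solvent accessibility of a residue
#'
#' Shrake-Rupley SASA of the residue, computed in the context of the full
#' complex, divided by the theoretical maximum ASA of its amino acid
#' (Tien et al. 2013).  Values above 1 are possible for chain termini and
#' very exposed residues.
#'
#' @param s a \code{ppi_structure}.
#' @param r a \code{ppi_residue_ref}.
#' @param sasa optional precomputed per-atom SASA vector (from
#'   \code{\link{atom_sasa}}) to avoid recomputation in batch workflows.
#' @return numeric scalar (fraction, >= 0).
#' @export
relative_solvent_accessibility <- function(s, r, sasa = NULL) {
  at <- resolve_residue(s, r)
  aa <- at$aa[1]
  if (!aa %in% names(MAX_ASA))
    stop(sprintf("unknown residue type '%s' at %s%d%s", at$resid[1],
                 r$chain, r$resno, r$icode))
  if (is.null(sasa)) sasa <- atom_sasa(s)
  hit <- s$atoms$chain == r$chain & s$atoms$resno == r$resno &
    s$atoms$icode == r$icode & s$atoms$element != "H"
  sum(sasa[hit]) / MAX_ASA[[aa]]
}

#' Backbone phi torsion of a residue
#'
#' Dihedral C(i-1)-N(i)-CA(i)-C(i) in degrees.  The first residue of a
#' chain, or any residue with missing backbone atoms, yields \code{NA} with
#' a warning (not an error).
#'
#' @param s a \code{ppi_structure}.
#' @param r a \code{ppi_residue_ref}.
#' @return numeric scalar in [-180, 180], or \code{NA}.
#' @export
phi_torsion <- function(s, r) {
  rt <- residue_table(s)
  idx <- which(rt$chain == r$chain & rt$resno == r$resno & rt$icode == r$icode)
  if (length(idx) != 1)
    stop(sprintf("residue %s%d%s not found", r$chain, r$resno, r$icode))
  if (idx == 1 || rt$chain[idx - 1] != r$chain) return(NA_real_)
  prev <- rt[idx - 1, ]
  get_atom <- function(row, name) {
    a <- s$atoms
    hit <- a$chain == row$chain & a$resno == row$resno &
      a$icode == row$icode & a$elety == name
    if (!any(hit)) return(NULL)
    unlist(a[which(hit)[1], c("x", "y", "z")], use.names = FALSE)
  }
  cprev <- get_atom(prev, "C")
  nn <- get_atom(rt[idx, ], "N")
  ca <- get_atom(rt[idx, ], "CA")
  cc <- get_atom(rt[idx, ], "C")
  if (is.null(cprev) || is.null(nn) || is.null(ca) || is.null(cc)) {
    warning(sprintf("missing backbone atom around %s%d%s; phi undefined",
                    r$chain, r$resno, r$icode))
    return(NA_real_)
  }
  dihedral_angle(cprev, nn, ca, cc)
}

#' Residue depth
#'
#' Mean distance from the residue's heavy atoms to the nearest surface
#' point, where the surface is the set of atom centers with non-zero
#' solvent-accessible surface area.
#'
#' @inheritParams relative_solvent_accessibility
#' @return depth in Angstrom (>= 0).
#' @export
residue_depth <- function(s, r, sasa = NULL) {
  if (nrow(residue_table(s)) < 2)
    stop("residue depth needs a structure with >= 2 residues")
  if (is.null(sasa)) sasa <- atom_sasa(s)
  surf <- which(sasa > 0 & s$atoms$element != "H")
  if (length(surf) == 0)
    stop("degenerate structure: no solvent-exposed atoms to define a surface")
  at <- resolve_residue(s, r)
  at <- at[at$element != "H", , drop = FALSE]
  sxyz <- xyz_matrix(s$atoms[surf, , drop = FALSE])
  rxyz <- xyz_matrix(at)
  d2 <- outer(rowSums(rxyz^2), rowSums(sxyz^2), `+`) - 2 * rxyz %*% t(sxyz)
  mean(sqrt(pmax(apply(d2, 1, min), 0)))
}

#' Amino-acid composition of a sequence
#'
#' Frequency of each of the 20 amino acids, ordered alphabetically by
#' one-letter code.  \code{"X"} is tolerated and excluded from the
#' denominator.
#'
#' @param sequence one-letter amino-acid string.
#' @return named numeric vector of length 20 summing to 1.
#' @export
aa_composition <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1 || nchar(sequence) == 0)
    stop("sequence must be a non-empty one-letter string")
  letters1 <- strsplit(toupper(sequence), "")[[1]]
  bad <- setdiff(letters1, c(AA_ALPHABET, "X"))
  if (length(bad) > 0)
    stop("invalid residue letters: ", paste(unique(bad), collapse = ", "))
  letters1 <- letters1[letters1 != "X"]
  if (length(letters1) == 0)
    stop("sequence contains no standard residues")
  counts <- table(factor(letters1, levels = AA_ALPHABET))
  out <- as.numeric(counts) / length(letters1)
  names(out) <- AA_ALPHABET
  out
}
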