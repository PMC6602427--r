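# Non-covalent contact typing (covalent / van der Waals / hydrogen bond /
# aromatic), in the spirit of Arpeggio but reduced to the four classes the
# downstream features consume.  All thresholds live in one rule table.

COVALENT_RADII <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66, S = 1.05,
                    P = 1.07, SE = 1.20)

AROMATIC_RINGS <- list(
  PHE = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  TYR = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  HIS = list(c("CG", "ND1", "CD2", "CE1", "NE2")),
  TRP = list(c("CG", "CD1", "CD2", "NE1", "CE2"),
             c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2")))

#' Contact rule table
#'
#' Distance thresholds for the four contact classes.  \code{cov_tol} and
#' \code{vdw_tol} are added to the sums of covalent and van der Waals radii
#' respectively; \code{hbond_max} is the donor-acceptor heavy-atom limit
#' (no angle term is applied because hydrogens are not required);
#' \code{aromatic_max} is the ring centroid-centroid limit.
#'
#' @param cov_tol,vdw_tol,hbond_max,aromatic_max numeric thresholds (A).
#' @return named list of thresholds.
#' @export
contact_params <- function(cov_tol = 0.4, vdw_tol = 0.5, hbond_max = 3.9,
                           aromatic_max = 5.0) {
  list(cov_tol = cov_tol, vdw_tol = vdw_tol, hbond_max = hbond_max,
       aromatic_max = aromatic_max)
}

covalent_radius <- function(element) {
  r <- COVALENT_RADII[element]
  if (anyNA(r))
    stop("unknown element(s): ",
         paste(unique(element[is.na(r)]), collapse = ", "))
  unname(r)
}

# rings present in an atom table: list of integer index vectors
find_rings <- function(atoms) {
  out <- list()
  key <- paste(atoms$chain, atoms$resno, atoms$icode, sep = "|")
  for (res in unique(key[atoms$resid %in% names(AROMATIC_RINGS)])) {
    rows <- which(key == res)
    defs <- AROMATIC_RINGS[[atoms$resid[rows[1]]]]
    for (def in defs) {
      idx <- rows[match(def, atoms$elety[rows])]
      if (!anyNA(idx)) out[[length(out) + 1]] <- idx
    }
  }
  out
}

#' Detect and type inter-atomic contacts
#'
#' Classifies heavy-atom pairs of the structure:
#' \itemize{
#'   \item \emph{covalent}: d <= r_cov(a) + r_cov(b) + cov_tol;
#'   \item \emph{hbond}: one donor-capable and one acceptor-capable atom
#'     (pharmacophore table) with d <= hbond_max;
#'   \item \emph{vdw}: d <= r_vdw(a) + r_vdw(b) + vdw_tol and not covalent;
#'   \item \emph{aromatic}: one contact per pair of distinct rings whose
#'     centroids are <= aromatic_max apart (reported through the closest
#'     atom pair of the two rings).
#' }
#' A pair may yield several kinds.
#'
#' @param s a \code{ppi_structure}.
#' @param params rule table from \code{\link{contact_params}}.
#' @return data.frame with one row per (atom pair, kind): indices
#'   \code{i}, \code{j} into the heavy-atom table, residue identifiers,
#'   \code{kind} and \code{distance}.
#' @export
detect_contacts <- function(s, params = contact_params()) {
  a <- heavy_atoms(s)
  if (nrow(a) == 0) stop("empty structure")
  xyz <- xyz_matrix(a)
  rvdw <- vdw_radius(a$element)
  rcov <- covalent_radius(a$element)
  lab <- assign_pharmacophores(a)
  enum_max <- max(2 * max(rvdw) + params$vdw_tol, params$hbond_max)
  n <- nrow(a)
  res <- list()
  if (n >= 2) {
    pr <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    i <- pr[, 1]; j <- pr[, 2]
    d <- sqrt(rowSums((xyz[i, , drop = FALSE] - xyz[j, , drop = FALSE])^2))
    keep <- d <= enum_max
    i <- i[keep]; j <- j[keep]; d <- d[keep]
    cov <- d <= rcov[i] + rcov[j] + params$cov_tol
    hb <- d <= params$hbond_max &
      ((lab[i, "donor"] & lab[j, "acceptor"]) |
         (lab[j, "donor"] & lab[i, "acceptor"]))
    vdw <- d <= rvdw[i] + rvdw[j] + params$vdw_tol & !cov
    add <- function(sel, kind) {
      if (any(sel))
        data.frame(i = i[sel], j = j[sel], kind = kind,
                   distance = d[sel], stringsAsFactors = FALSE)
    }
    res <- Filter(Negate(is.null),
                  list(add(cov, "covalent"), add(vdw, "vdw"),
                       add(hb, "hbond")))
  }
  rings <- find_rings(a)
  if (length(rings) >= 2) {
    cents <- t(vapply(rings, function(ix) colMeans(xyz[ix, , drop = FALSE]),
                      numeric(3)))
    for (p in seq_len(length(rings) - 1)) {
      for (q in (p + 1):length(rings)) {
        dc <- vnorm(cents[p, ] - cents[q, ])
        if (dc <= params$aromatic_max) {
          ri <- rings[[p]]; rj <- rings[[q]]
          dd <- outer(rowSums(xyz[ri, , drop = FALSE]^2),
                      rowSums(xyz[rj, , drop = FALSE]^2), `+`) -
            2 * xyz[ri, , drop = FALSE] %*% t(xyz[rj, , drop = FALSE])
          best <- which(dd == min(dd), arr.ind = TRUE)[1, ]
          res[[length(res) + 1]] <- data.frame(
            i = ri[best[1]], j = rj[best[2]], kind = "aromatic",
            distance = dc, stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- if (length(res) > 0) do.call(rbind, res) else
    data.frame(i = integer(), j = integer(), kind = character(),
               distance = numeric(), stringsAsFactors = FALSE)
  swap <- out$i > out$j
  tmp <- out$i[swap]; out$i[swap] <- out$j[swap]; out$j[swap] <- tmp
  out$chain_a <- a$chain[out$i]; out$resno_a <- a$resno[out$i]
  out$icode_a <- a$icode[out$i]; out$atom_a <- a$elety[out$i]
  out$chain_b <- a$chain[out$j]; out$resno_b <- a$resno[out$j]
  out$icode_b <- a$icode[out$j]; out$atom_b <- a$elety[out$j]
  rownames(out) <- NULL
  out
}

#' Export a contact set as CSV
#'
#' @param contacts data.frame from \code{\link{detect_contacts}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_contacts_csv <- function(contacts, path) {
  utils::write.csv(
    contacts[, c("chain_a", "resno_a", "atom_a", "chain_b", "resno_b",
                 "atom_b", "kind", "distance")],
    path, row.names = FALSE)
  invisible(path)
}
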