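# Graph-based structural signatures: the wild-type residue environment is
# represented as pharmacophore-typed atoms, and pairwise distance patterns
# are summarised as cumulative counts over an ascending cutoff ladder.

PHARMACOPHORE_CLASSES <- c("hydrophobic", "aromatic", "donor", "acceptor",
                           "positive", "negative", "sulfur", "neutral")

.ppi_cache <- new.env(parent = emptyenv())

pkg_extdata <- function(file) {
  p <- system.file("extdata", file, package = "ppiddg")
  if (p == "") p <- file.path("inst", "extdata", file)  # pre-install use
  if (!file.exists(p)) stop("packaged data file not found: ", file)
  p
}

#' Pharmacophore lookup table
#'
#' The shipped residue/atom to atom-class assignment table.  Classes are
#' \code{hydrophobic, aromatic, donor, acceptor, positive, negative,
#' sulfur, neutral}; an atom may carry several.
#'
#' @return data.frame with columns \code{resid}, \code{atom},
#'   \code{element}, \code{labels} (semicolon-separated).
#' @export
pharmacophore_table <- function() {
  if (is.null(.ppi_cache$pharm)) {
    .ppi_cache$pharm <- utils::read.csv(pkg_extdata("pharmacophores.csv"),
                                        stringsAsFactors = FALSE)
  }
  .ppi_cache$pharm
}

#' Assign pharmacophore labels to atoms
#'
#' Each atom receives the classes recorded for its (residue, atom name)
#' pair in the shipped lookup table.  Atoms absent from the table are
#' labelled \code{neutral} with a warning.
#'
#' @param atoms atom data.frame (structure-table layout).
#' @return logical matrix [atoms x 8 classes].
#' @export
assign_pharmacophores <- function(atoms) {
  tab <- pharmacophore_table()
  key <- paste(atoms$resid, atoms$elety, sep = "|")
  tkey <- paste(tab$resid, tab$atom, sep = "|")
  hit <- match(key, tkey)
  lab <- matrix(FALSE, nrow = nrow(atoms), ncol = length(PHARMACOPHORE_CLASSES),
                dimnames = list(NULL, PHARMACOPHORE_CLASSES))
  miss <- is.na(hit)
  if (any(miss))
    warning(sum(miss), " atom(s) missing from the pharmacophore table; ",
            "labelled neutral (e.g. ", atoms$resid[which(miss)[1]], "/",
            atoms$elety[which(miss)[1]], ")")
  lab[miss, "neutral"] <- TRUE
  if (any(!miss)) {
    lists <- strsplit(tab$labels[hit[!miss]], ";", fixed = TRUE)
    rows <- which(!miss)
    for (k in seq_along(rows)) lab[rows[k], lists[[k]]] <- TRUE
  }
  lab
}

#' Extract the atom environment of a residue
#'
#' All heavy atoms of the complex (any chain, the mutated residue included)
#' whose distance from the geometric center of the residue's heavy atoms is
#' at most \code{radius}, carrying pharmacophore labels.
#'
#' @param s a \code{ppi_structure}.
#' @param r a \code{ppi_residue_ref}.
#' @param radius sphere radius in Angstrom (> 0).
#' @return a \code{ppi_environment}: list with \code{center}, \code{atoms},
#'   \code{labels}, \code{radius}, \code{focus}.
#' @export
extract_environment <- function(s, r, radius = 10) {
  stopifnot(radius > 0)
  center <- residue_center(s, r)
  ha <- heavy_atoms(s)
  xyz <- xyz_matrix(ha)
  d <- sqrt((xyz[, 1] - center[1])^2 + (xyz[, 2] - center[2])^2 +
              (xyz[, 3] - center[3])^2)
  keep <- d <= radius
  atoms <- ha[keep, , drop = FALSE]
  labels <- if (nrow(atoms) > 0) assign_pharmacophores(atoms) else
    matrix(FALSE, 0, length(PHARMACOPHORE_CLASSES),
           dimnames = list(NULL, PHARMACOPHORE_CLASSES))
  structure(list(center = center, atoms = atoms, labels = labels,
                 radius = radius, focus = r),
            class = "ppi_environment")
}

# unordered pairs of the 8 classes, in a fixed order (36 rows)
pharmacophore_pairs <- function() {
  k <- length(PHARMACOPHORE_CLASSES)
  idx <- which(upper.tri(matrix(0, k, k), diag = TRUE), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  data.frame(p = PHARMACOPHORE_CLASSES[idx[, 1]],
             q = PHARMACOPHORE_CLASSES[idx[, 2]],
             stringsAsFactors = FALSE)
}

#' Cutoff-scanning structural signature
#'
#' For every unordered atom pair of the environment, and every distinct
#' unordered pharmacophore class pair carried by the two atoms, the count
#' at the smallest cutoff >= the pair distance is incremented; counts are
#' then accumulated along the ladder (cumulative distribution).  Pairs
#' farther apart than the largest cutoff are dropped.
#'
#' @param env a \code{ppi_environment}.
#' @param cutoffs strictly ascending distance ladder in Angstrom.
#' @param include_self_pairs keep pairs where both atoms belong to the
#'   focal residue itself (default \code{TRUE}).
#' @return a \code{ppi_signature}: integer matrix [36 class pairs x
#'   cutoffs] with a \code{cutoffs} attribute.
#' @export
cutoff_scan_signature <- function(env, cutoffs = seq(1, 10, by = 0.5),
                                  include_self_pairs = TRUE) {
  stopifnot(inherits(env, "ppi_environment"))
  if (length(cutoffs) < 1 || is.unsorted(cutoffs, strictly = TRUE))
    stop("cutoffs must be a strictly ascending ladder with >= 1 entry")
  pp <- pharmacophore_pairs()
  counts <- matrix(0L, nrow = nrow(pp), ncol = length(cutoffs),
                   dimnames = list(paste(pp$p, pp$q, sep = ":"),
                                   as.character(cutoffs)))
  n <- nrow(env$atoms)
  if (n >= 2) {
    xyz <- xyz_matrix(env$atoms)
    pr <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    i <- pr[, 1]; j <- pr[, 2]
    if (!include_self_pairs && !is.null(env$focus)) {
      f <- env$focus
      self <- env$atoms$chain == f$chain & env$atoms$resno == f$resno &
        env$atoms$icode == f$icode
      keep <- !(self[i] & self[j])
      i <- i[keep]; j <- j[keep]
    }
    if (length(i) > 0) {
      d <- sqrt(rowSums((xyz[i, , drop = FALSE] - xyz[j, , drop = FALSE])^2))
      bin <- findInterval(d, cutoffs, left.open = TRUE) + 1L
      ok <- bin <= length(cutoffs)
      i <- i[ok]; j <- j[ok]; bin <- bin[ok]
      lab <- env$labels
      for (rw in seq_len(nrow(pp))) {
        p <- pp$p[rw]; q <- pp$q[rw]
        hit <- (lab[i, p] & lab[j, q]) | (lab[i, q] & lab[j, p])
        if (any(hit))
          counts[rw, ] <- counts[rw, ] +
            tabulate(bin[hit], nbins = length(cutoffs))
      }
    }
  }
  counts <- t(apply(counts, 1, cumsum))
  if (length(cutoffs) == 1) counts <- matrix(counts, ncol = 1,
    dimnames = list(paste(pp$p, pp$q, sep = ":"), as.character(cutoffs)))
  storage.mode(counts) <- "integer"
  structure(counts, cutoffs = cutoffs, class = c("ppi_signature", "matrix"))
}

#' Flatten a signature into a named feature row
#'
#' Row-major [class pair x cutoff] flattening with stable names of the
#' form \code{sig.<p>.<q>@<cutoff>}.
#'
#' @param sig a \code{ppi_signature}.
#' @return named numeric vector.
#' @export
signature_vector <- function(sig) {
  cutoffs <- attr(sig, "cutoffs")
  m <- unclass(sig)
  out <- as.numeric(t(m))
  names(out) <- as.vector(t(outer(rownames(m), cutoffs, function(r, c)
    sprintf("sig.%s@%s", gsub(":", ".", r), c))))
  out
}

#' Export signatures as a CSV table
#'
#' @param sigs named list of \code{ppi_signature} objects (one per mutation).
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_signature_csv <- function(sigs, path) {
  rows <- lapply(sigs, signature_vector)
  df <- as.data.frame(do.call(rbind, rows), check.names = FALSE)
  df <- cbind(id = names(sigs), df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
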