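# Remaining feature families and the feature-vector assembler.

PSSM_COLS <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]

#' Glycine/proline mutation flags
#'
#' Four binary indicators: mutation from glycine, to glycine, from proline,
#' to proline.
#'
#' @param wt_aa,mut_aa one-letter amino-acid codes.
#' @return named integer vector (from_gly, to_gly, from_pro, to_pro).
#' @export
gly_pro_flags <- function(wt_aa, mut_aa) {
  wt_aa <- toupper(wt_aa); mut_aa <- toupper(mut_aa)
  if (!wt_aa %in% AA_ALPHABET || !mut_aa %in% AA_ALPHABET)
    stop("invalid amino acid code: ", wt_aa, "/", mut_aa)
  c(from_gly = as.integer(wt_aa == "G"), to_gly = as.integer(mut_aa == "G"),
    from_pro = as.integer(wt_aa == "P"), to_pro = as.integer(mut_aa == "P"))
}

#' Read a PSI-BLAST ASCII PSSM
#'
#' Parses the ASCII position-specific scoring matrix dialect produced by
#' PSI-BLAST: a header row of the 20 amino-acid column letters followed by
#' one row per query position (\code{pos letter score_1 ... score_20}).
#' When 40 score columns are present (log-odds plus weighted percentages),
#' the first 20 (log-odds) are used.
#'
#' @param path PSSM file path.
#' @return a \code{ppi_pssm}: list with \code{scores} (positions x 20
#'   integer matrix, columns in PSI-BLAST order ARNDCQEGHILKMFPSTWYV) and
#'   \code{query} (one-letter string).
#' @export
read_pssm <- function(path) {
  lines <- readLines(path, warn = FALSE)
  header_at <- NA
  for (k in seq_along(lines)) {
    f <- strsplit(trimws(lines[k]), "\\s+")[[1]]
    if (length(f) >= 20 && all(f[1:20] == PSSM_COLS)) { header_at <- k; break }
  }
  if (is.na(header_at))
    stop("not a PSI-BLAST ASCII PSSM: no amino-acid header row in ", path)
  rows <- list(); query <- character()
  for (k in seq(header_at + 1, length(lines))) {
    ln <- trimws(lines[k])
    if (ln == "") break
    f <- strsplit(ln, "\\s+")[[1]]
    if (!grepl("^[0-9]+$", f[1])) break
    if (length(f) < 22)
      stop("malformed PSSM row at line ", k, ": expected >= 20 score columns")
    scores <- suppressWarnings(as.integer(f[3:22]))
    if (anyNA(scores))
      stop("malformed PSSM row at line ", k, ": non-numeric score")
    pos <- as.integer(f[1])
    if (pos != length(rows) + 1)
      stop("malformed PSSM at line ", k, ": positions not consecutive")
    rows[[pos]] <- scores
    query[pos] <- f[2]
  }
  if (length(rows) == 0) stop("PSSM in ", path, " contains no data rows")
  m <- do.call(rbind, rows)
  colnames(m) <- PSSM_COLS
  structure(list(scores = m, query = paste(query, collapse = "")),
            class = "ppi_pssm")
}

#' Build a PSSM from a multiple sequence alignment
#'
#' A testing/fallback builder when PSI-BLAST output is not available:
#' rounded log2-odds of per-column residue frequencies (with +1
#' pseudocounts) against the background composition of the alignment.
#'
#' @param sequences character vector of aligned sequences (equal length);
#'   the first is the query.
#' @return a \code{ppi_pssm}.
#' @export
pssm_from_alignment <- function(sequences) {
  stopifnot(length(sequences) >= 2)
  mat <- do.call(rbind, strsplit(toupper(sequences), ""))
  if (length(unique(nchar(sequences))) != 1)
    stop("aligned sequences must have equal length")
  query <- mat[1, ]
  keep <- query %in% AA_ALPHABET
  bg <- table(factor(mat[mat %in% PSSM_COLS], levels = PSSM_COLS)) + 20
  bg <- as.numeric(bg) / sum(bg)
  scores <- t(vapply(which(keep), function(jc) {
    cnt <- table(factor(mat[, jc][mat[, jc] %in% PSSM_COLS],
                        levels = PSSM_COLS)) + 1
    p <- as.numeric(cnt) / sum(cnt)
    as.integer(round(log2(p / bg) * 2))
  }, integer(20)))
  colnames(scores) <- PSSM_COLS
  structure(list(scores = scores, query = paste(query[keep], collapse = "")),
            class = "ppi_pssm")
}

#' Evolutionary conservation scores for a mutation
#'
#' PSSM log-odds of the wild-type and mutant residues at the mutated
#' position, plus their difference (wild-type minus mutant).
#'
#' @param p a \code{ppi_pssm}.
#' @param pos 1-based position in the PSSM query.
#' @param wt,mut one-letter codes; \code{wt} must match the query letter.
#' @return named numeric vector (wt_score, mut_score, diff).
#' @export
evolutionary_scores <- function(p, pos, wt, mut) {
  stopifnot(inherits(p, "ppi_pssm"))
  if (pos < 1 || pos > nrow(p$scores))
    stop("position ", pos, " outside PSSM range 1..", nrow(p$scores))
  qletter <- substr(p$query, pos, pos)
  if (qletter != toupper(wt))
    stop(sprintf(paste0("PSSM misalignment at position %d: query has '%s', ",
                        "mutation says '%s'"), pos, qletter, wt))
  w <- p$scores[pos, toupper(wt)]
  m <- p$scores[pos, toupper(mut)]
  c(wt_score = as.numeric(w), mut_score = as.numeric(m),
    diff = as.numeric(w - m))
}

#' Read an AAindex-format 20x20 matrix
#'
#' Parses the AAindex MATRIX entry format (\code{H}/\code{D} header lines,
#' an \code{M rows = ..., cols = ...} line, then a lower-triangular or full
#' numeric block) into a symmetric matrix keyed by one-letter codes.
#'
#' @param path file path.
#' @return 20x20 symmetric numeric matrix.
#' @export
read_aaindex_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  mline <- grep("^M ", lines)
  if (length(mline) == 0) stop("no 'M rows = ...' line in ", path)
  spec <- lines[mline[1]]
  rows_order <- strsplit(sub(".*rows = ([A-Z]+).*", "\\1", spec), "")[[1]]
  if (length(rows_order) != 20) stop("expected 20 row letters in ", path)
  vals <- list()
  for (k in seq(mline[1] + 1, length(lines))) {
    ln <- trimws(lines[k])
    if (ln == "" || ln == "//") break
    vals[[length(vals) + 1]] <- as.numeric(strsplit(ln, "\\s+")[[1]])
  }
  if (length(vals) != 20) stop("expected 20 matrix rows in ", path)
  m <- matrix(NA_real_, 20, 20, dimnames = list(rows_order, rows_order))
  for (i in seq_len(20)) {
    v <- vals[[i]]
    if (length(v) == i) m[i, seq_len(i)] <- v
    else if (length(v) == 20) m[i, ] <- v
    else stop("row ", i, " of ", path, " has ", length(v), " values")
  }
  m[upper.tri(m)] <- t(m)[upper.tri(m)]
  if (anyNA(m)) stop("incomplete matrix in ", path)
  m
}

#' Contact-potential scores for a substitution
#'
#' Symmetric lookup of the (wild-type, mutant) cell in each of three
#' AAindex-format residue contact-potential matrices.  The shipped default
#' tables are deterministic synthetic substitutes (see the package
#' vignette); real AAindex entries can be supplied as files.
#'
#' @param wt,mut one-letter codes.
#' @param tables list of three 20x20 matrices (from
#'   \code{\link{read_aaindex_matrix}}); default: the shipped substitutes.
#' @return numeric vector of length 3 (one score per table).
#' @export
contact_potential_scores <- function(wt, mut,
                                     tables = default_contact_potentials()) {
  wt <- toupper(wt); mut <- toupper(mut)
  vapply(seq_along(tables), function(k) {
    tb <- tables[[k]]
    if (!wt %in% rownames(tb) || !mut %in% rownames(tb))
      stop("residue code not present in potential table ", k, ": ",
           wt, "/", mut)
    v <- tb[wt, mut]
    if (is.na(v)) stop("missing cell (", wt, ",", mut, ") in table ", k)
    v
  }, numeric(1))
}

#' @rdname contact_potential_scores
#' @export
default_contact_potentials <- function() {
  if (is.null(.ppi_cache$potentials)) {
    .ppi_cache$potentials <- lapply(1:3, function(k)
      read_aaindex_matrix(pkg_extdata(
        sprintf("contact_potential_synthetic%d.aaindex", k))))
  }
  .ppi_cache$potentials
}

ABSENT_BLOCK <- structure(list(absent = TRUE), class = "ppi_absent")

is_absent <- function(x) inherits(x, "ppi_absent") || is.null(x)

#' FoldX-style energetic terms adapter
#'
#' Reads the inter-chain interaction energy from a FoldX
#' \code{AnalyseComplex}-style table (column \code{Interaction Energy}) and
#' the predicted folding free-energy change from a difference-style table
#' (column \code{total energy}).  With no files supplied the block is
#' explicitly absent (never silently zero); model training works either
#' way.
#'
#' @param interaction_path,dif_path paths to the two tab-separated FoldX
#'   output tables, or \code{NULL}.
#' @return named numeric vector (interaction_energy, folding_ddg) in
#'   kcal/mol, or the absent-marker.
#' @export
energetic_terms <- function(interaction_path = NULL, dif_path = NULL) {
  if (is.null(interaction_path) && is.null(dif_path)) return(ABSENT_BLOCK)
  grab <- function(path, column) {
    if (is.null(path)) return(NA_real_)
    lines <- readLines(path, warn = FALSE)
    hdr <- grep(column, lines, fixed = TRUE)
    if (length(hdr) == 0)
      stop("malformed FoldX table ", path, ": no '", column, "' column")
    cols <- strsplit(lines[hdr[1]], "\t", fixed = TRUE)[[1]]
    vals <- strsplit(lines[hdr[1] + 1], "\t", fixed = TRUE)[[1]]
    v <- suppressWarnings(as.numeric(vals[match(column, cols)]))
    if (is.na(v)) stop("malformed FoldX table ", path,
                       ": non-numeric '", column, "' value")
    v
  }
  c(interaction_energy = grab(interaction_path, "Interaction Energy"),
    folding_ddg = grab(dif_path, "total energy"))
}

#' Assemble the feature vector
#'
#' Concatenates the feature blocks into one named numeric row with a
#' deterministic slot order.  Mandatory blocks: \code{signature} (a
#' \code{ppi_signature}), \code{environment} (rsa, phi, depth, 20-slot
#' composition), \code{flags}, \code{contact_delta}, \code{network}.
#' Optional blocks (\code{evolution}, \code{potentials}, \code{energy},
#' \code{fluctuation}) may be given as \code{NULL} or the absent-marker:
#' their slots are filled with \code{NA} and the block is recorded in the
#' \code{absent_blocks} attribute, which the model layer uses to keep the
#' training and prediction schemas aligned.
#'
#' @param signature a \code{ppi_signature}.
#' @param environment named list/vector: \code{rsa}, \code{phi} (0 when
#'   undefined), \code{phi_defined} (1/0 indicator; chain starts have no
#'   phi), \code{depth} and the amino-acid composition vector.
#' @param flags output of \code{\link{gly_pro_flags}}.
#' @param contact_delta output of \code{\link{contact_delta}}.
#' @param network output of \code{\link{network_metrics}}.
#' @param evolution output of \code{\link{evolutionary_scores}} or absent.
#' @param potentials output of \code{\link{contact_potential_scores}} or
#'   absent.
#' @param energy output of \code{\link{energetic_terms}} or absent.
#' @param fluctuation named vector (site and mean fluctuation per force
#'   field, 4 slots) or absent.
#' @return a \code{ppi_features}: named numeric vector with attribute
#'   \code{absent_blocks}.
#' @export
assemble_features <- function(signature, environment, flags, contact_delta,
                              network, evolution = NULL, potentials = NULL,
                              energy = NULL, fluctuation = NULL) {
  mandatory <- list(signature = signature, environment = environment,
                    flags = flags, contact_delta = contact_delta,
                    network = network)
  for (nm in names(mandatory))
    if (is_absent(mandatory[[nm]]))
      stop("mandatory feature block missing: ", nm)
  env <- unlist(environment)
  envnames <- c("rsa", "phi", "phi_defined", "depth",
                paste0("aac.", AA_ALPHABET))
  if (length(env) != 24)
    stop(paste0("environment block must have 24 slots (rsa, phi, ",
                "phi_defined, depth, 20 AAC)"))
  names(env) <- envnames
  net <- unlist(network[c("mean_closeness", "central_point_dominance",
                          "graph_center_size", "n_nodes", "n_edges")])
  names(net) <- paste0("net.", c("mean_closeness", "cpd", "center_size",
                                 "n_nodes", "n_edges"))
  cd <- as.numeric(contact_delta)
  names(cd) <- paste0("delta.", CONTACT_KINDS)
  opt <- function(x, slots, prefix) {
    if (is_absent(x)) {
      v <- rep(NA_real_, length(slots))
    } else {
      v <- as.numeric(x)
      if (length(v) != length(slots))
        stop("block '", prefix, "' has length ", length(v), ", expected ",
             length(slots))
    }
    stats::setNames(v, paste0(prefix, ".", slots))
  }
  evo <- opt(evolution, c("wt_score", "mut_score", "diff"), "pssm")
  pot <- opt(potentials, c("t1", "t2", "t3"), "potential")
  ene <- opt(energy, c("interaction_energy", "folding_ddg"), "energy")
  flu <- opt(fluctuation, c("calpha_site", "calpha_mean", "pfanm_site",
                            "pfanm_mean"), "fluct")
  out <- c(signature_vector(signature), env,
           stats::setNames(as.numeric(flags), paste0("flag.", names(flags))),
           cd, net, evo, pot, ene, flu)
  absent <- c("evolution", "potentials", "energy", "fluctuation")[
    c(is_absent(evolution), is_absent(potentials), is_absent(energy),
      is_absent(fluctuation))]
  structure(out, absent_blocks = absent, class = "ppi_features")
}

#' Write/read feature rows as CSV
#'
#' @param features list of \code{ppi_features} rows (identical slots).
#' @param path CSV path.
#' @return \code{write_feature_csv}: \code{path}; \code{read_feature_csv}:
#'   data.frame with one column per slot.
#' @export
write_feature_csv <- function(features, path) {
  df <- as.data.frame(do.call(rbind, lapply(features, as.numeric)))
  names(df) <- names(features[[1]])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  utils::read.csv(path, check.names = FALSE)
}
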