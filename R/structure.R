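# Structure model: a light atom-table representation of a (multi-chain)
# protein complex, read through bio3d's PDB/mmCIF parsers.

AA_THREE_TO_ONE <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

AA_ONE_TO_THREE <- structure(names(AA_THREE_TO_ONE), names = AA_THREE_TO_ONE)

# one-letter codes in alphabetical order (the composition vector layout)
AA_ALPHABET <- sort(unname(AA_THREE_TO_ONE))

BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

new_structure <- function(atoms, id = "structure", source_format = "pdb") {
  needed <- c("chain", "resno", "icode", "resid", "aa", "elety", "element",
              "x", "y", "z", "occ")
  missing <- setdiff(needed, names(atoms))
  if (length(missing) > 0)
    stop("atom table lacks columns: ", paste(missing, collapse = ", "))
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  rownames(atoms) <- NULL
  structure(list(id = id, atoms = atoms, source_format = source_format),
            class = "ppi_structure")
}

#' @export
print.ppi_structure <- function(x, ...) {
  cat(sprintf("<ppi_structure '%s': %d atoms, %d residues, chains %s [%s]>\n",
              x$id, nrow(x$atoms), nrow(residue_table(x)),
              paste(chain_ids(x), collapse = ","), x$source_format))
  invisible(x)
}

# Minimal mmCIF _atom_site loop parser, returning a bio3d-style atom
# data.frame.  Only the columns the package consumes are mapped; author
# (auth_*) identifiers are preferred over label_* ones, matching PDB files.
parse_mmcif_atoms <- function(path) {
  lines <- readLines(path, warn = FALSE)
  loop_at <- which(trimws(lines) == "loop_")
  atoms <- NULL
  for (lp in loop_at) {
    tags <- character(0)
    k <- lp + 1
    while (k <= length(lines) && startsWith(trimws(lines[k]), "_")) {
      tags <- c(tags, trimws(lines[k])); k <- k + 1
    }
    if (!any(startsWith(tags, "_atom_site."))) next
    rows <- list()
    while (k <= length(lines)) {
      ln <- trimws(lines[k])
      if (ln == "" || startsWith(ln, "_") || ln == "loop_" ||
          startsWith(ln, "#") || startsWith(ln, "data_")) break
      rows[[length(rows) + 1]] <- scan(text = ln, what = character(),
                                       quiet = TRUE)
      k <- k + 1
    }
    m <- do.call(rbind, rows)
    colnames(m) <- sub("^_atom_site\\.", "", tags)
    atoms <- m
    break
  }
  if (is.null(atoms)) stop("no _atom_site loop found")
  col <- function(names, default = NA) {
    for (nm in names) if (nm %in% colnames(atoms)) {
      v <- atoms[, nm]
      v[v %in% c(".", "?")] <- NA
      return(v)
    }
    rep(default, nrow(atoms))
  }
  data.frame(
    type = col("group_PDB", "ATOM"),
    elety = col(c("auth_atom_id", "label_atom_id")),
    alt = col("label_alt_id"),
    resid = col(c("auth_comp_id", "label_comp_id")),
    chain = col(c("auth_asym_id", "label_asym_id")),
    resno = as.integer(col(c("auth_seq_id", "label_seq_id"))),
    insert = col("pdbx_PDB_ins_code"),
    x = as.numeric(col("Cartn_x")), y = as.numeric(col("Cartn_y")),
    z = as.numeric(col("Cartn_z")),
    o = suppressWarnings(as.numeric(col("occupancy", "1"))),
    b = suppressWarnings(as.numeric(col("B_iso_or_equiv", "0"))),
    elesy = col("type_symbol"),
    stringsAsFactors = FALSE)
}

guess_element <- function(elety) {
  e <- gsub("[0-9'\\*]", "", elety)
  ifelse(substr(elety, 1, 1) %in% as.character(0:9), "H",
         ifelse(toupper(e) %in% c("SE", "FE", "ZN", "MG", "MN", "CL", "BR", "NA"),
                toupper(substr(e, 1, 2)), toupper(substr(e, 1, 1))))
}

#' Read a protein complex structure
#'
#' Reads a PDB or mmCIF file into the package's atom-table representation.
#' Water and hetero records are dropped, hydrogens are retained when present,
#' and at most one alternate-location conformer per atom is kept (highest
#' occupancy; ties resolved in favour of altloc \code{"A"}).  A bare
#' accession code is resolved against a local file \code{<code>.pdb} or
#' \code{<code>.cif} in the working directory; no network access is made.
#'
#' @param path_or_id path to a \code{.pdb}/\code{.ent}/\code{.cif} file, or
#'   an accession code with such a file present locally.
#' @return a \code{ppi_structure}.
#' @export
read_structure <- function(path_or_id) {
  path <- path_or_id
  if (!file.exists(path)) {
    for (ext in c(".pdb", ".ent", ".cif")) {
      cand <- paste0(path_or_id, ext)
      if (file.exists(cand)) { path <- cand; break }
    }
  }
  if (!file.exists(path))
    stop("no local structure file found for '", path_or_id, "'")
  ext <- tolower(tools::file_ext(path))
  fmt <- if (ext %in% c("cif", "mmcif")) "mmcif" else "pdb"
  at <- tryCatch(
    if (fmt == "mmcif") parse_mmcif_atoms(path)
    else bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE)$atom,
    error = function(e) stop("cannot parse '", path, "' as ", fmt, ": ",
                             conditionMessage(e)))
  at <- at[at$type == "ATOM" & !(at$resid %in% c("HOH", "WAT", "DOD")), ,
           drop = FALSE]
  if (nrow(at) == 0) stop("empty structure: no protein atoms in '", path, "'")
  icode <- ifelse(is.na(at$insert), "", at$insert)
  alt <- ifelse(is.na(at$alt), "", at$alt)
  occ <- ifelse(is.na(at$o), 1, at$o)
  elem <- at$elesy
  bad <- is.na(elem) | elem == ""
  elem[bad] <- guess_element(at$elety[bad])
  atoms <- data.frame(
    chain = ifelse(is.na(at$chain), "A", at$chain),
    resno = at$resno, icode = icode, resid = at$resid,
    aa = unname(ifelse(at$resid %in% names(AA_THREE_TO_ONE),
                       AA_THREE_TO_ONE[at$resid], "X")),
    elety = at$elety, element = toupper(elem),
    x = at$x, y = at$y, z = at$z, occ = occ, alt = alt,
    stringsAsFactors = FALSE)
  # altloc: keep the highest-occupancy conformer, ties -> 'A' (then first);
  # the surviving atoms keep their file order
  atoms$.ord <- seq_len(nrow(atoms))
  key <- paste(atoms$chain, atoms$resno, atoms$icode, atoms$elety, sep = "|")
  ord <- order(key, -atoms$occ, atoms$alt != "A", atoms$alt, atoms$.ord)
  atoms <- atoms[ord, , drop = FALSE]
  atoms <- atoms[!duplicated(key[ord]), , drop = FALSE]
  chain_order <- unique(atoms$chain[order(atoms$.ord)])
  atoms <- atoms[order(match(atoms$chain, chain_order), atoms$resno,
                       atoms$icode, atoms$.ord), , drop = FALSE]
  atoms$alt <- NULL
  atoms$.ord <- NULL
  new_structure(atoms, id = sub("\\.[^.]*$", "", basename(path)),
                source_format = fmt)
}

#' Write a structure as a minimal PDB file
#'
#' Fixed-width ATOM records only; sufficient to round-trip the package's
#' fixtures through any standard PDB reader.
#'
#' @param s a \code{ppi_structure}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_pdb <- function(s, path) {
  a <- s$atoms
  name <- ifelse(nchar(a$elety) <= 3, sprintf(" %-3s", a$elety),
                 sprintf("%-4s", a$elety))
  lines <- sprintf(
    "ATOM  %5d %s %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(a)), name, a$resid, a$chain, a$resno,
    ifelse(a$icode == "", " ", a$icode), a$x, a$y, a$z, a$occ, 0, a$element)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' @rdname residue_ref
#' @export
residue_ref <- function(chain, resno, icode = "") {
  structure(list(chain = as.character(chain), resno = as.integer(resno),
                 icode = as.character(icode)), class = "ppi_residue_ref")
}

#' Resolve a residue reference
#'
#' A residue reference (\code{residue_ref}) is a chain id plus author residue
#' number and optional insertion code.  \code{resolve_residue} returns the
#' atom rows of exactly one residue or raises an error.
#'
#' @param s a \code{ppi_structure}.
#' @param r a \code{ppi_residue_ref}.
#' @return data.frame of the residue's atom rows.
#' @name residue_ref
#' @export
resolve_residue <- function(s, r) {
  stopifnot(inherits(s, "ppi_structure"), inherits(r, "ppi_residue_ref"))
  hit <- s$atoms$chain == r$chain & s$atoms$resno == r$resno &
    s$atoms$icode == r$icode
  if (!any(hit))
    stop(sprintf("residue %s%d%s not found in chain %s",
                 r$chain, r$resno, r$icode, r$chain))
  s$atoms[hit, , drop = FALSE]
}

chain_ids <- function(s) unique(s$atoms$chain)

# one row per residue, in file order
residue_table <- function(s) {
  a <- s$atoms
  key <- paste(a$chain, a$resno, a$icode, sep = "|")
  first <- !duplicated(key)
  data.frame(chain = a$chain[first], resno = a$resno[first],
             icode = a$icode[first], resid = a$resid[first], aa = a$aa[first],
             stringsAsFactors = FALSE)
}

#' Chain sequence as a one-letter string
#'
#' @param s a \code{ppi_structure}.
#' @param chain chain identifier.
#' @return character scalar; non-standard residues appear as \code{"X"}.
#' @export
chain_sequence <- function(s, chain) {
  rt <- residue_table(s)
  rt <- rt[rt$chain == chain, , drop = FALSE]
  if (nrow(rt) == 0) stop("no chain '", chain, "' in structure")
  paste(rt$aa, collapse = "")
}

#' Read sequences from a FASTA file
#'
#' @param path FASTA file path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  fa <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE)
  vapply(fa, function(x) toupper(as.character(x)[1]), character(1))
}

xyz_matrix <- function(atoms) as.matrix(atoms[, c("x", "y", "z")])

#' Apply a rigid-body transform to a structure
#'
#' @param s a \code{ppi_structure}.
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 numeric vector (Angstrom).
#' @return transformed \code{ppi_structure}.
#' @export
transform_structure <- function(s, rotation = diag(3), translation = c(0, 0, 0)) {
  xyz <- xyz_matrix(s$atoms) %*% t(rotation)
  xyz <- sweep(xyz, 2, translation, `+`)
  s$atoms$x <- xyz[, 1]; s$atoms$y <- xyz[, 2]; s$atoms$z <- xyz[, 3]
  s
}

heavy_atoms <- function(s) s$atoms[s$atoms$element != "H", , drop = FALSE]

residue_center <- function(s, r) {
  at <- resolve_residue(s, r)
  at <- at[at$element != "H", , drop = FALSE]
  colMeans(xyz_matrix(at))
}
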