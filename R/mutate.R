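# In-silico point mutation by deterministic side-chain template grafting:
# the mutant side chain is taken from an ideal-geometry residue template
# and placed by superposing the template backbone (N, CA, C) onto the
# target backbone.  The backbone itself is never moved.

aa_template_table <- function() {
  if (is.null(.ppi_cache$templates)) {
    .ppi_cache$templates <- utils::read.csv(pkg_extdata("aa_ideal_coords.csv"),
                                            stringsAsFactors = FALSE)
  }
  .ppi_cache$templates
}

#' Replace a residue's side chain with another amino acid
#'
#' The side chain (all heavy atoms beyond N, CA, C, O, OXT) is replaced by
#' the ideal-geometry template of \code{mut_aa}, aligned on the backbone
#' N-CA-C frame.  Identity mutations return the structure unchanged.
#' Glycine targets need no CB: the backbone frame fully determines the
#' placement.
#'
#' @param s a \code{ppi_structure}.
#' @param r a \code{ppi_residue_ref}.
#' @param mut_aa mutant amino acid, one-letter code.
#' @return mutated \code{ppi_structure}.
#' @export
mutate_residue <- function(s, r, mut_aa) {
  mut_aa <- toupper(mut_aa)
  if (!mut_aa %in% AA_ALPHABET) stop("invalid amino acid code: ", mut_aa)
  at <- resolve_residue(s, r)
  if (at$aa[1] == mut_aa) return(s)
  need <- c("N", "CA", "C")
  tgt <- at[match(need, at$elety), , drop = FALSE]
  if (anyNA(tgt$elety))
    stop(sprintf("residue %s%d%s lacks backbone atoms needed for mutation",
                 r$chain, r$resno, r$icode))
  tmpl <- aa_template_table()
  tmpl <- tmpl[tmpl$resid == AA_ONE_TO_THREE[[mut_aa]], , drop = FALSE]
  tb <- tmpl[match(need, tmpl$atom), c("x", "y", "z")]
  fit <- kabsch_transform(as.matrix(tb), xyz_matrix(tgt))
  side <- tmpl[!tmpl$atom %in% BACKBONE_ATOMS, , drop = FALSE]
  hit <- s$atoms$chain == r$chain & s$atoms$resno == r$resno &
    s$atoms$icode == r$icode
  keep_bb <- s$atoms[hit & s$atoms$elety %in% BACKBONE_ATOMS, , drop = FALSE]
  keep_bb$resid <- AA_ONE_TO_THREE[[mut_aa]]
  keep_bb$aa <- mut_aa
  new_rows <- NULL
  if (nrow(side) > 0) {
    sxyz <- fit(as.matrix(side[, c("x", "y", "z")]))
    new_rows <- data.frame(
      chain = r$chain, resno = r$resno, icode = r$icode,
      resid = AA_ONE_TO_THREE[[mut_aa]], aa = mut_aa,
      elety = side$atom, element = side$element,
      x = sxyz[, 1], y = sxyz[, 2], z = sxyz[, 3], occ = 1,
      stringsAsFactors = FALSE)
  }
  first <- which(hit)[1]
  before <- s$atoms[seq_len(nrow(s$atoms)) < first, , drop = FALSE]
  after <- s$atoms[seq_len(nrow(s$atoms)) > max(which(hit)), , drop = FALSE]
  # drop any hydrogens of the replaced residue along with the side chain
  s$atoms <- rbind(before, keep_bb, new_rows, after)
  rownames(s$atoms) <- NULL
  s
}

CONTACT_KINDS <- c("covalent", "vdw", "aromatic", "hbond")

# contact-kind counts for one residue (pairs with >= 1 atom in the residue,
# intra-residue pairs included).  The structure is trimmed to residues
# within `window` of the focal residue before contact detection.
residue_contact_counts <- function(s, r, params = contact_params(),
                                   window = 15) {
  center <- residue_center(s, r)
  ha <- heavy_atoms(s)
  xyz <- xyz_matrix(ha)
  d <- sqrt((xyz[, 1] - center[1])^2 + (xyz[, 2] - center[2])^2 +
              (xyz[, 3] - center[3])^2)
  key <- paste(ha$chain, ha$resno, ha$icode, sep = "|")
  keep_res <- unique(key[d <= window])
  sub <- s
  subkey <- paste(s$atoms$chain, s$atoms$resno, s$atoms$icode, sep = "|")
  sub$atoms <- s$atoms[subkey %in% keep_res, , drop = FALSE]
  contacts <- detect_contacts(sub, params)
  in_r <- function(ch, no, ic) ch == r$chain & no == r$resno & ic == r$icode
  hit <- in_r(contacts$chain_a, contacts$resno_a, contacts$icode_a) |
    in_r(contacts$chain_b, contacts$resno_b, contacts$icode_b)
  counts <- table(factor(contacts$kind[hit], levels = CONTACT_KINDS))
  stats::setNames(as.integer(counts), CONTACT_KINDS)
}

#' Wild-type minus mutant contact counts
#'
#' Counts the typed contacts involving the mutated residue in the wild-type
#' structure and in the template-grafted mutant model, and reports the
#' per-kind difference (wild-type minus mutant) for covalent, van der
#' Waals, aromatic and hydrogen-bond contacts.
#'
#' @param wt wild-type \code{ppi_structure}.
#' @param r a \code{ppi_residue_ref}.
#' @param mut_aa mutant one-letter code.
#' @param params contact rule table.
#' @param mutant optional externally modelled mutant structure (e.g. from a
#'   dedicated side-chain modelling tool); defaults to
#'   \code{\link{mutate_residue}} grafting.
#' @return named integer vector (covalent, vdw, aromatic, hbond).
#' @export
contact_delta <- function(wt, r, mut_aa, params = contact_params(),
                          mutant = NULL) {
  if (is.null(mutant)) mutant <- mutate_residue(wt, r, mut_aa)
  wt_counts <- residue_contact_counts(wt, r, params)
  mut_counts <- residue_contact_counts(mutant, r, params)
  wt_counts - mut_counts
}
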