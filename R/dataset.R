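# SKEMPI-style dataset construction: KD -> binding free energy, replicate
# aggregation, single-point filtering, antisymmetric reverse-mutation
# augmentation and the validation split generators.

#' Thermodynamic constants
#'
#' The ideal gas constant in kcal K^-1 mol^-1 and the default temperature
#' in Kelvin used when an experiment does not record one.
#'
#' @export
thermo_constants <- function() {
  list(R = 1.985e-3, T_default = 298.15)
}

#' Binding free energy from a dissociation constant
#'
#' \eqn{\Delta G = R T \ln(K_D)} with R = 1.985e-3 kcal K^-1 mol^-1.
#'
#' @param kd equilibrium dissociation constant (molar, > 0).
#' @param temperature temperature in Kelvin (> 0).
#' @return free energy in kcal/mol.
#' @export
dg_from_kd <- function(kd, temperature = thermo_constants()$T_default) {
  if (any(!is.finite(kd)) || any(kd <= 0))
    stop("KD must be finite and > 0 (molar)")
  if (any(temperature <= 0)) stop("temperature must be > 0 K")
  thermo_constants()$R * temperature * log(kd)
}

#' Change in binding free energy upon mutation
#'
#' \eqn{\Delta\Delta G = \Delta G_{wild-type} - \Delta G_{mutant}}.  Under
#' this sign convention destabilising mutations (weaker binding) are
#' negative.
#'
#' @param dg_wt,dg_mut free energies in kcal/mol.
#' @return kcal/mol.
#' @export
ddg <- function(dg_wt, dg_mut) {
  stopifnot(all(is.finite(dg_wt)), all(is.finite(dg_mut)))
  dg_wt - dg_mut
}

#' Aggregate replicate measurements
#'
#' Replicated measurements of the same variant are averaged when their
#' spread (max - min) is strictly below \code{tol} kcal/mol and discarded
#' otherwise (returned as \code{NA}).
#'
#' @param values numeric vector of replicate ddG values (>= 1).
#' @param tol spread tolerance in kcal/mol (default 2.0).
#' @return mean value, or \code{NA_real_} as the discard marker.
#' @export
aggregate_replicates <- function(values, tol = 2.0) {
  if (length(values) == 0) stop("no replicate values supplied")
  if (any(!is.finite(values))) stop("replicate values must be finite")
  if (max(values) - min(values) < tol) mean(values) else NA_real_
}

# "LI38G" / "LA38aG" -> list(wt, chain, resno, icode, mut)
parse_skempi_mutation <- function(code) {
  m <- regmatches(code, regexec(
    "^([ACDEFGHIKLMNPQRSTVWY])([A-Za-z0-9])([0-9]+)([A-Za-z]?)([ACDEFGHIKLMNPQRSTVWY])$",
    code))[[1]]
  if (length(m) == 0) return(NULL)
  list(wt = m[2], chain = m[3], resno = as.integer(m[4]), icode = m[5],
       mut = m[6])
}

parse_temperature <- function(x) {
  v <- suppressWarnings(as.numeric(gsub("[^0-9.]", "", x)))
  ifelse(is.na(v) | v <= 0, thermo_constants()$T_default, v)
}

#' Parse a SKEMPI 2.0-dialect affinity table
#'
#' Reads a semicolon-separated table with columns \code{#Pdb},
#' \code{Mutation(s)_PDB}, \code{Affinity_wt_parsed},
#' \code{Affinity_mut_parsed} (molar) and optional \code{Temperature}.
#' Multi-point mutation rows are dropped; rows with unparseable affinities
#' are skipped (counted); per-variant ddG is computed at the row's
#' temperature (default 298.15 K when absent) and replicates are
#' aggregated under the 2.0 kcal/mol spread rule.
#'
#' @param path CSV path.
#' @param tol replicate spread tolerance (kcal/mol).
#' @return data.frame of curated forward mutation records with attribute
#'   \code{curation_counts}; columns include \code{pdb_id}, \code{chain},
#'   \code{res_number}, \code{icode}, \code{wt_aa}, \code{mut_aa},
#'   \code{kd_wt}, \code{kd_mut}, \code{temperature}, \code{ddg},
#'   \code{complex_id}, \code{binding_site_id}, \code{is_reverse},
#'   \code{n_replicates}.
#' @export
parse_skempi <- function(path, tol = 2.0) {
  raw <- utils::read.table(path, sep = ";", header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character", comment.char = "",
                           quote = "\"")
  need <- c("#Pdb", "Mutation(s)_PDB", "Affinity_wt_parsed",
            "Affinity_mut_parsed")
  missing <- setdiff(need, names(raw))
  if (length(missing) > 0)
    stop("missing mandatory SKEMPI columns: ",
         paste(missing, collapse = ", "))
  n_input <- nrow(raw)
  multi <- grepl(",", raw$`Mutation(s)_PDB`, fixed = TRUE)
  n_multi <- sum(multi)
  raw <- raw[!multi, , drop = FALSE]
  kd_wt <- suppressWarnings(as.numeric(raw$Affinity_wt_parsed))
  kd_mut <- suppressWarnings(as.numeric(raw$Affinity_mut_parsed))
  bad <- is.na(kd_wt) | is.na(kd_mut) | kd_wt <= 0 | kd_mut <= 0
  n_bad <- sum(bad)
  if (n_bad > 0)
    message(n_bad, " row(s) with unparseable affinity skipped")
  raw <- raw[!bad, , drop = FALSE]
  kd_wt <- kd_wt[!bad]; kd_mut <- kd_mut[!bad]
  temp <- if ("Temperature" %in% names(raw))
    parse_temperature(raw$Temperature) else
      rep(thermo_constants()$T_default, nrow(raw))
  specs <- lapply(raw$`Mutation(s)_PDB`, parse_skempi_mutation)
  unparsed <- vapply(specs, is.null, logical(1))
  if (any(unparsed))
    message(sum(unparsed), " row(s) with unparseable mutation code skipped")
  n_bad <- n_bad + sum(unparsed)
  raw <- raw[!unparsed, , drop = FALSE]
  kd_wt <- kd_wt[!unparsed]; kd_mut <- kd_mut[!unparsed]
  temp <- temp[!unparsed]; specs <- specs[!unparsed]
  row_ddg <- ddg(dg_from_kd(kd_wt, temp), dg_from_kd(kd_mut, temp))
  key <- paste(raw$`#Pdb`, raw$`Mutation(s)_PDB`, sep = "|")
  # aggregate replicates per (complex, mutation), keeping input order of
  # first occurrence; order-independent because the key decides grouping
  groups <- split(seq_along(key), factor(key, levels = unique(key)))
  recs <- lapply(groups, function(ix) {
    val <- aggregate_replicates(row_ddg[ix], tol)
    if (is.na(val)) return(NULL)
    i1 <- ix[1]
    sp <- specs[[i1]]
    pdb_id <- strsplit(raw$`#Pdb`[i1], "_", fixed = TRUE)[[1]][1]
    data.frame(
      pdb_id = pdb_id, chain = sp$chain, res_number = sp$resno,
      icode = sp$icode, wt_aa = sp$wt, mut_aa = sp$mut,
      kd_wt = mean(kd_wt[ix]), kd_mut = mean(kd_mut[ix]),
      temperature = temp[i1], ddg = val,
      complex_id = raw$`#Pdb`[i1],
      binding_site_id = paste0(pdb_id, "_", sp$chain, sp$resno, sp$icode),
      is_reverse = FALSE, n_replicates = length(ix),
      stringsAsFactors = FALSE)
  })
  n_groups <- length(groups)
  out <- do.call(rbind, Filter(Negate(is.null), recs))
  if (is.null(out)) out <- data.frame()
  rownames(out) <- NULL
  attr(out, "curation_counts") <- list(
    n_input = n_input, n_multi_dropped = n_multi, n_unparseable = n_bad,
    n_variants = n_groups, n_discarded_replicate_spread =
      n_groups - nrow(out), n_retained = nrow(out))
  out
}

#' Add hypothetical reverse mutations
#'
#' Doubles the record set: every forward mutation gains a reverse twin with
#' wild-type and mutant swapped and ddG negated (thermodynamic
#' antisymmetry).  Augmenting an already augmented set is rejected.
#'
#' @param records forward record data.frame from \code{\link{parse_skempi}}.
#' @return data.frame of 2x the rows with \code{pair_id} linking twins.
#' @export
augment_reverse <- function(records) {
  if (nrow(records) == 0) stop("no records to augment")
  if (any(records$is_reverse))
    stop("records already contain reverse mutations; refusing to re-augment")
  fwd <- records
  fwd$pair_id <- seq_len(nrow(fwd))
  rev <- fwd
  rev$wt_aa <- fwd$mut_aa
  rev$mut_aa <- fwd$wt_aa
  rev$ddg <- -fwd$ddg
  rev$kd_wt <- fwd$kd_mut
  rev$kd_mut <- fwd$kd_wt
  rev$is_reverse <- TRUE
  out <- rbind(fwd, rev)
  rownames(out) <- NULL
  out
}

new_split_plan <- function(scheme, assignments, seed = NA_integer_) {
  structure(list(scheme = scheme, assignments = assignments, seed = seed),
            class = "ppi_split_plan")
}

#' Stratified paired k-fold cross-validation plan
#'
#' Folds partition the forward/reverse pairs, so twins are always
#' co-assigned; stratification is on the sign of the forward ddG (>= 0
#' counted as increased binding).  Repeated \code{repeats} times with
#' different seeded shuffles.
#'
#' @param records augmented record set (from \code{\link{augment_reverse}}).
#' @param k folds (default 10).
#' @param repeats repetitions (default 10).
#' @param seed integer seed.
#' @return a \code{ppi_split_plan}; \code{assignments} is a data.frame with
#'   \code{row} (record row), \code{rep}, \code{fold}.
#' @export
split_stratified_paired <- function(records, k = 10, repeats = 10, seed = 1) {
  if (!any(records$is_reverse) || is.null(records$pair_id))
    stop("records must be reverse-augmented (paired) before splitting")
  pairs <- unique(records$pair_id)
  if (k > length(pairs))
    stop("k = ", k, " exceeds the number of forward/reverse pairs")
  fwd <- records[!records$is_reverse, , drop = FALSE]
  strata <- ifelse(fwd$ddg >= 0, "increase", "decrease")[
    match(pairs, fwd$pair_id)]
  out <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    fold_of <- integer(length(pairs))
    dealt <- 0L
    for (st in unique(strata)) {
      ix <- which(strata == st)
      perm <- with_local_seed(seed * 1000L + r, ix[sample.int(length(ix))])
      # global round-robin across strata keeps fold sizes within one pair
      fold_of[perm] <- (dealt + seq_along(perm) - 1L) %% k + 1L
      dealt <- dealt + length(perm)
    }
    out[[r]] <- data.frame(
      row = seq_len(nrow(records)), rep = r,
      fold = fold_of[match(records$pair_id, pairs)])
  }
  new_split_plan("stratified_kfold_paired", do.call(rbind, out), seed)
}

#' Leave-one-complex-out split plan
#'
#' One test group per complex; training data never shares a complex with
#' the test group.
#'
#' @param records record data.frame with \code{complex_id}.
#' @return a \code{ppi_split_plan}; \code{assignments} has \code{row} and
#'   \code{group} (the held-out complex).
#' @export
split_leave_one_complex_out <- function(records) {
  cx <- unique(records$complex_id)
  if (length(cx) < 2) stop("need >= 2 complexes for leave-one-complex-out")
  new_split_plan("loco", data.frame(row = seq_len(nrow(records)),
                                    group = records$complex_id,
                                    stringsAsFactors = FALSE))
}

#' Leave-one-binding-site-out split plan
#'
#' One test group per binding site id (SKEMPI hold-out columns when
#' available; the fallback id is pdb + chain + position).
#'
#' @param records record data.frame with \code{binding_site_id}.
#' @return a \code{ppi_split_plan}.
#' @export
split_leave_one_binding_site_out <- function(records) {
  sites <- unique(records$binding_site_id)
  if (length(sites) < 2)
    stop("need >= 2 binding sites for leave-one-binding-site-out")
  new_split_plan("lobso", data.frame(row = seq_len(nrow(records)),
                                     group = records$binding_site_id,
                                     stringsAsFactors = FALSE))
}

#' Write a split plan as JSON
#'
#' @param plan a \code{ppi_split_plan}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_split_json <- function(plan, path) {
  jsonlite::write_json(list(scheme = plan$scheme, seed = plan$seed,
                            assignments = plan$assignments),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
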