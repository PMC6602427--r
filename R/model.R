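# Feature-pipeline orchestration, the tree-ensemble regressor and the two
# interface scanning modes.

#' Feature pipeline configuration
#'
#' @param radius environment sphere radius (A).
#' @param cutoffs signature cutoff ladder (A).
#' @param interface_cutoff interface residue cutoff (A).
#' @param params contact rule table.
#' @param include_fluctuation compute the ENM fluctuation block.
#' @param include_potentials compute the contact-potential block.
#' @param potentials list of three 20x20 contact-potential matrices.
#' @return named list of settings.
#' @export
feature_config <- function(radius = 10, cutoffs = seq(1, 10, by = 0.5),
                           interface_cutoff = 5.0,
                           params = contact_params(),
                           include_fluctuation = TRUE,
                           include_potentials = TRUE,
                           potentials = default_contact_potentials()) {
  list(radius = radius, cutoffs = cutoffs,
       interface_cutoff = interface_cutoff, params = params,
       include_fluctuation = include_fluctuation,
       include_potentials = include_potentials, potentials = potentials)
}

#' Reusable per-structure feature context
#'
#' Precomputes the per-structure quantities (atom SASA, interface network
#' metrics, per-chain fluctuation profiles) shared by every mutation of the
#' same complex.  Purely a cache: results are identical with or without it.
#'
#' @param s a \code{ppi_structure}.
#' @param config from \code{\link{feature_config}}.
#' @return a \code{ppi_feature_context}.
#' @export
feature_context <- function(s, config = feature_config()) {
  structure(list(s = s, config = config, sasa = atom_sasa(s),
                 cache = new.env(parent = emptyenv())),
            class = "ppi_feature_context")
}

ctx_network <- function(ctx, r) {
  id <- closest_interface(ctx$s, r, ctx$config$interface_cutoff)
  key <- paste0("net:", id)
  if (is.null(ctx$cache[[key]])) {
    net <- build_contact_network(ctx$s, id, ctx$config$interface_cutoff,
                                 ctx$config$params)
    ctx$cache[[key]] <- network_metrics(net)
  }
  ctx$cache[[key]]
}

ctx_fluctuation <- function(ctx, r) {
  key <- paste0("fluct:", r$chain)
  if (is.null(ctx$cache[[key]])) {
    site <- numeric(0)
    for (ff in c("calpha", "pfanm")) {
      prof <- enm_fluctuations(ctx$s, ff, chain = r$chain)
      ctx$cache[[paste0(key, ":", ff)]] <- prof
    }
    ctx$cache[[key]] <- TRUE
  }
  out <- numeric(0)
  for (ff in c("calpha", "pfanm")) {
    prof <- ctx$cache[[paste0(key, ":", ff)]]
    hit <- prof$residues$resno == r$resno & prof$residues$icode == r$icode
    if (!any(hit)) stop("mutation site has no CA atom in chain ", r$chain)
    out <- c(out, prof$fluctuations[which(hit)[1]], mean(prof$fluctuations))
  }
  stats::setNames(out, c("calpha_site", "calpha_mean", "pfanm_site",
                         "pfanm_mean"))
}

#' Compute the full feature vector for one mutation
#'
#' Runs the whole wild-type-structure feature pipeline for a single
#' mutation: graph-based signature, residue environment, Gly/Pro flags,
#' contact deltas against the template-grafted mutant, interface network
#' metrics, and the optional evolutionary, contact-potential, energetic
#' and fluctuation blocks.
#'
#' @param ctx a \code{ppi_feature_context} (or a \code{ppi_structure}, in
#'   which case a throwaway context is built).
#' @param r a \code{ppi_residue_ref}.
#' @param mut_aa mutant one-letter code.
#' @param pssm optional \code{ppi_pssm} for the mutated chain (positions
#'   must follow the chain's residue order).
#' @param energy optional output of \code{\link{energetic_terms}}.
#' @return a \code{ppi_features} row.
#' @export
compute_mutation_features <- function(ctx, r, mut_aa, pssm = NULL,
                                      energy = NULL) {
  if (inherits(ctx, "ppi_structure")) ctx <- feature_context(ctx)
  s <- ctx$s; config <- ctx$config
  at <- resolve_residue(s, r)
  wt_aa <- at$aa[1]
  phi <- suppressWarnings(phi_torsion(s, r))
  environment <- c(
    rsa = relative_solvent_accessibility(s, r, sasa = ctx$sasa),
    phi = if (is.na(phi)) 0 else phi,
    phi_defined = as.numeric(!is.na(phi)),
    depth = residue_depth(s, r, sasa = ctx$sasa),
    aa_composition(chain_sequence(s, r$chain)))
  sig <- cutoff_scan_signature(extract_environment(s, r, config$radius),
                               config$cutoffs)
  evolution <- NULL
  if (!is.null(pssm)) {
    rt <- residue_table(s)
    rt <- rt[rt$chain == r$chain, , drop = FALSE]
    pos <- which(rt$resno == r$resno & rt$icode == r$icode)
    evolution <- evolutionary_scores(pssm, pos, wt_aa, mut_aa)
  }
  potentials <- if (config$include_potentials)
    contact_potential_scores(wt_aa, mut_aa, config$potentials) else NULL
  fluctuation <- if (config$include_fluctuation) ctx_fluctuation(ctx, r)
    else NULL
  assemble_features(
    signature = sig, environment = environment,
    flags = gly_pro_flags(wt_aa, mut_aa),
    contact_delta = contact_delta(s, r, mut_aa, config$params),
    network = ctx_network(ctx, r),
    evolution = evolution, potentials = potentials, energy = energy,
    fluctuation = fluctuation)
}

#' Model hyperparameters
#'
#' Defaults follow the extremely-randomised-trees configuration: 500
#' trees, random single-threshold splits, regression targets in kcal/mol.
#'
#' @param num_trees number of trees.
#' @param min_node_size minimal node size.
#' @param mtry predictors sampled per split; \code{NULL} uses all
#'   predictors, the classical extremely-randomised-trees choice for
#'   regression (Geurts et al. 2006).
#' @param splitrule \code{"extratrees"} or \code{"variance"}.
#' @param num_random_splits random candidate thresholds per draw
#'   (extratrees only).
#' @return named list.
#' @export
model_config <- function(num_trees = 500, min_node_size = 5, mtry = NULL,
                         splitrule = "extratrees", num_random_splits = 1) {
  list(num_trees = num_trees, min_node_size = min_node_size, mtry = mtry,
       splitrule = splitrule, num_random_splits = num_random_splits)
}

features_as_df <- function(features) {
  if (is.data.frame(features)) return(features)
  if (inherits(features, "ppi_features"))
    features <- list(features)
  df <- as.data.frame(do.call(rbind, lapply(features, as.numeric)))
  names(df) <- names(features[[1]])
  df
}

#' Train the ddG regressor
#'
#' Fits an extremely-randomised-trees regression forest (via
#' \pkg{ranger}) on assembled feature rows.  Columns belonging to absent
#' optional blocks (all-\code{NA}) are excluded and recorded in the model
#' schema; prediction refuses feature rows whose slot schema differs.
#'
#' @param features list of \code{ppi_features} rows or a data.frame.
#' @param targets numeric ddG targets (kcal/mol), one per row.
#' @param config from \code{\link{model_config}}.
#' @param seed integer seed (training is deterministic given it).
#' @return a \code{ppi_model}.
#' @export
train_model <- function(features, targets, config = model_config(),
                        seed = 1) {
  df <- features_as_df(features)
  if (nrow(df) < 10) stop("need >= 10 training rows, got ", nrow(df))
  if (length(targets) != nrow(df))
    stop("targets length does not match feature rows")
  if (any(!is.finite(targets))) stop("targets contain non-finite values")
  all_na <- vapply(df, function(x) all(is.na(x)), logical(1))
  part_na <- vapply(df, function(x) any(is.na(x)) && !all(is.na(x)),
                    logical(1))
  if (any(part_na))
    stop("feature column(s) with partial missingness: ",
         paste(utils::head(names(df)[part_na], 3), collapse = ", "))
  active <- names(df)[!all_na]
  x <- df[, active, drop = FALSE]
  fit <- ranger::ranger(
    x = x, y = targets,
    num.trees = config$num_trees,
    mtry = if (is.null(config$mtry)) ncol(x) else config$mtry,
    min.node.size = config$min_node_size,
    splitrule = config$splitrule,
    num.random.splits = config$num_random_splits,
    seed = seed, num.threads = 1, verbose = FALSE)
  structure(list(fit = fit, config = config, seed = seed,
                 schema = list(slots = names(df), active = active),
                 fingerprint = digest_rows(x, targets),
                 version = 1L),
            class = "ppi_model")
}

# cheap deterministic fingerprint of the training set
digest_rows <- function(x, y) {
  v <- c(dim(x), sum(x[!is.na(x)]), sum(y), stats::sd(y))
  sprintf("%dx%d:%.8g:%.8g:%.8g", v[1], v[2], v[3], v[4], v[5])
}

#' Predict ddG for feature rows
#'
#' @param m a \code{ppi_model}.
#' @param features list of \code{ppi_features} or data.frame with the
#'   training slot schema.
#' @param sign_convention \code{"native"} (the default: destabilising < 0) or
#'   \code{"skempi"} (destabilising > 0, i.e. the negated scale).
#' @return numeric vector of predictions (kcal/mol).
#' @export
predict_ddg <- function(m, features, sign_convention = c("native", "skempi")) {
  sign_convention <- match.arg(sign_convention)
  stopifnot(inherits(m, "ppi_model"))
  df <- features_as_df(features)
  bad <- which(!(m$schema$slots %in% names(df)))
  if (length(bad) > 0)
    stop("feature schema mismatch: slot '", m$schema$slots[bad[1]],
         "' missing")
  extra <- setdiff(names(df), m$schema$slots)
  if (length(extra) > 0)
    stop("feature schema mismatch: unexpected slot '", extra[1], "'")
  x <- df[, m$schema$active, drop = FALSE]
  if (anyNA(x)) {
    col <- m$schema$active[which(vapply(x, anyNA, logical(1)))[1]]
    stop("feature schema mismatch: active slot '", col,
         "' is NA (block absent at prediction time)")
  }
  p <- stats::predict(m$fit, data = x, num.threads = 1)$predictions
  if (sign_convention == "skempi") {
    warning("reporting predictions on the negated (SKEMPI) ddG scale")
    p <- -p
  }
  p
}

#' Persist / restore a trained model
#'
#' The on-disk file embeds the schema and configuration; reloading yields
#' bit-identical predictions.
#'
#' @param m a \code{ppi_model}.
#' @param path file path.
#' @return \code{save_model}: \code{path}; \code{load_model}: the model.
#' @export
save_model <- function(m, path) {
  stopifnot(inherits(m, "ppi_model"))
  saveRDS(m, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "ppi_model")) stop("not a ppi_model file: ", path)
  m
}

scan_targets <- function(s, interface_cutoff) {
  faces <- interface_residues(s, interface_cutoff)
  if (length(faces) == 0)
    stop("no interface within ", interface_cutoff, " A")
  res <- do.call(rbind, lapply(names(faces), function(id)
    cbind(interface = id, faces[[id]], stringsAsFactors = FALSE)))
  res[!duplicated(paste(res$interface, res$chain, res$resno, res$icode)), ,
      drop = FALSE]
}

run_scan <- function(m, s, mutants_for, config, pssms = NULL) {
  ctx <- feature_context(s, config)
  targets <- scan_targets(s, config$interface_cutoff)
  rows <- list()
  for (k in seq_len(nrow(targets))) {
    t <- targets[k, ]
    muts <- mutants_for(t$aa)
    if (length(muts) == 0) next
    r <- residue_ref(t$chain, t$resno, t$icode)
    pssm <- if (!is.null(pssms)) pssms[[t$chain]] else NULL
    feats <- lapply(muts, function(mm)
      compute_mutation_features(ctx, r, mm, pssm = pssm))
    pred <- predict_ddg(m, feats)
    rows[[length(rows) + 1]] <- data.frame(
      interface = t$interface, chain = t$chain, resno = t$resno,
      icode = t$icode, wt_aa = t$aa, mut_aa = muts, pred_ddg = pred,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0)
    return(structure(list(
      results = data.frame(interface = character(), chain = character(),
                           resno = integer(), icode = character(),
                           wt_aa = character(), mut_aa = character(),
                           pred_ddg = numeric(), stringsAsFactors = FALSE),
      summary = data.frame()), class = "ppi_scan_result"))
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  key <- paste(results$interface, results$chain, results$resno,
               results$icode)
  summary <- do.call(rbind, lapply(split(results, factor(key, unique(key))),
    function(g) data.frame(
      interface = g$interface[1], chain = g$chain[1], resno = g$resno[1],
      icode = g$icode[1], wt_aa = g$wt_aa[1], n_mutations = nrow(g),
      mean_pred_ddg = mean(g$pred_ddg), min_pred_ddg = min(g$pred_ddg),
      max_pred_ddg = max(g$pred_ddg), stringsAsFactors = FALSE)))
  rownames(summary) <- NULL
  structure(list(results = results, summary = summary),
            class = "ppi_scan_result")
}

#' Alanine scanning of all interfaces
#'
#' Every interface residue (5 A rule) that is not already an alanine is
#' mutated to alanine and scored with the trained model.
#'
#' @param m a \code{ppi_model}.
#' @param s a \code{ppi_structure} with >= 2 chains.
#' @param config feature pipeline configuration (must match the model's
#'   training features).
#' @param pssms optional named list of \code{ppi_pssm} per chain.
#' @return a \code{ppi_scan_result}: \code{results} rows (one per
#'   mutation) and per-residue \code{summary}.
#' @export
alanine_scan <- function(m, s, config = feature_config(), pssms = NULL) {
  run_scan(m, s, function(wt) if (wt == "A") character(0) else "A",
           config, pssms)
}

#' Saturation mutagenesis of all interfaces
#'
#' Every interface residue is mutated to each of the 19 other amino acids;
#' the per-residue mean prediction is reported in the summary (the
#' quantity used for residue-level colouring/heatmaps).
#'
#' @inheritParams alanine_scan
#' @return a \code{ppi_scan_result}.
#' @export
saturation_scan <- function(m, s, config = feature_config(), pssms = NULL) {
  run_scan(m, s, function(wt) setdiff(AA_ALPHABET, wt), config, pssms)
}

#' Write scan outputs
#'
#' One CSV per interface plus a JSON summary (per-residue means and, for
#' saturation scans, the residue x mutation heatmap matrix).
#'
#' @param scan a \code{ppi_scan_result}.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return character vector of written paths, invisibly.
#' @export
write_scan_output <- function(scan, dir, prefix = "scan") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  res <- scan$results
  for (id in unique(res$interface)) {
    sub <- res[res$interface == id, , drop = FALSE]
    p <- file.path(dir, sprintf("%s_interface_%s.csv", prefix,
                                gsub(":", "-", id)))
    sub$pred_ddg <- sprintf("%.6f", sub$pred_ddg)
    utils::write.csv(sub, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  js <- list(interfaces = unique(res$interface), summary = scan$summary)
  if (nrow(res) > 0) {
    muts <- sort(unique(res$mut_aa))
    if (length(muts) > 1) {
      rk <- paste0(res$chain, res$resno, res$icode)
      hm <- tapply(res$pred_ddg, list(factor(rk, unique(rk)),
                                      factor(res$mut_aa, muts)),
                   identity)
      js$heatmap <- list(residues = rownames(hm), mutations = colnames(hm),
                         pred_ddg = unname(apply(hm, 1, as.numeric,
                                                 simplify = FALSE)))
    }
  }
  pj <- file.path(dir, paste0(prefix, "_summary.json"))
  jsonlite::write_json(js, pj, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(c(paths, pj))
}
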