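# Interface detection (5 A heavy-atom rule) and interface contact-network
# metrics.

# squared-distance matrix between two coordinate matrices
cross_dist2 <- function(a, b) {
  pmax(outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * a %*% t(b), 0)
}

#' Interface residues per chain pair
#'
#' A residue is interfacial if any of its heavy atoms lies at most
#' \code{cutoff} Angstrom (inclusive) from any heavy atom of another chain.
#'
#' @param s a \code{ppi_structure} with >= 2 chains.
#' @param cutoff interface distance cutoff in Angstrom (default 5.0).
#' @return named list (\code{"A:B"} keys, lexicographic) of data.frames of
#'   interfacial residues; chain pairs with no interfacial residue are
#'   omitted, so a gap wider than the cutoff yields an empty list.
#' @export
interface_residues <- function(s, cutoff = 5.0) {
  chains <- sort(chain_ids(s))
  if (length(chains) < 2) stop("no interface: structure has a single chain")
  ha <- heavy_atoms(s)
  out <- list()
  for (p in seq_len(length(chains) - 1)) {
    for (q in (p + 1):length(chains)) {
      ca <- ha[ha$chain == chains[p], , drop = FALSE]
      cb <- ha[ha$chain == chains[q], , drop = FALSE]
      d2 <- cross_dist2(xyz_matrix(ca), xyz_matrix(cb))
      hit <- d2 <= cutoff^2 + 1e-6
      if (!any(hit)) next
      pick <- function(at, sel) {
        r <- at[sel, c("chain", "resno", "icode", "aa"), drop = FALSE]
        r[!duplicated(paste(r$chain, r$resno, r$icode)), , drop = FALSE]
      }
      res <- rbind(pick(ca, apply(hit, 1, any)), pick(cb, apply(hit, 2, any)))
      rownames(res) <- NULL
      out[[paste(chains[p], chains[q], sep = ":")]] <- res
    }
  }
  out
}

#' Closest interface to a residue
#'
#' Among the detected interfaces, returns the chain pair minimising the
#' distance from the residue's geometric center to the midpoints of the
#' cross-chain atom pairs defining the interface.  Ties are broken by
#' lexicographic chain-pair order.
#'
#' @param s a \code{ppi_structure}.
#' @param r a \code{ppi_residue_ref}.
#' @param cutoff interface cutoff (A).
#' @return interface id, e.g. \code{"A:B"}.
#' @export
closest_interface <- function(s, r, cutoff = 5.0) {
  faces <- interface_residues(s, cutoff)
  if (length(faces) == 0) stop("no interface within ", cutoff, " A")
  center <- residue_center(s, r)
  ha <- heavy_atoms(s)
  best <- NULL; best_d <- Inf
  for (id in names(faces)) {  # names are already lexicographic
    ch <- strsplit(id, ":", fixed = TRUE)[[1]]
    ca <- ha[ha$chain == ch[1], , drop = FALSE]
    cb <- ha[ha$chain == ch[2], , drop = FALSE]
    axyz <- xyz_matrix(ca); bxyz <- xyz_matrix(cb)
    d2 <- cross_dist2(axyz, bxyz)
    prs <- which(d2 <= cutoff^2 + 1e-6, arr.ind = TRUE)
    mids <- (axyz[prs[, 1], , drop = FALSE] + bxyz[prs[, 2], , drop = FALSE]) / 2
    dmin <- min(sqrt(rowSums(sweep(mids, 2, center)^2)))
    if (dmin < best_d - 1e-9) { best <- id; best_d <- dmin }
  }
  best
}

#' Contact network of an interface
#'
#' Nodes are the interfacial residues of the chosen chain pair; edges
#' aggregate atom-level contacts (any of the four kinds) between distinct
#' interfacial residues.
#'
#' @param s a \code{ppi_structure}.
#' @param interface_id chain-pair id such as \code{"A:B"}; default is the
#'   first detected interface.
#' @param cutoff interface cutoff (A).
#' @param params contact rule table.
#' @return a \code{ppi_contact_network}: list with \code{graph} (igraph),
#'   \code{residues}, \code{interface_id}.
#' @export
build_contact_network <- function(s, interface_id = NULL, cutoff = 5.0,
                                  params = contact_params()) {
  faces <- interface_residues(s, cutoff)
  if (length(faces) == 0) stop("no interface within ", cutoff, " A")
  if (is.null(interface_id)) interface_id <- names(faces)[1]
  if (!interface_id %in% names(faces))
    stop("no such interface: ", interface_id)
  res <- faces[[interface_id]]
  rid <- paste0(res$chain, res$resno, res$icode)
  contacts <- detect_contacts(s, params)
  ca <- paste0(contacts$chain_a, contacts$resno_a, contacts$icode_a)
  cb <- paste0(contacts$chain_b, contacts$resno_b, contacts$icode_b)
  keep <- ca %in% rid & cb %in% rid & ca != cb
  edges <- contacts[keep, , drop = FALSE]
  ekey <- paste(pmin(ca[keep], cb[keep]), pmax(ca[keep], cb[keep]), sep = "~")
  agg <- tapply(edges$kind, ekey, function(k) paste(sort(k), collapse = ","))
  epairs <- do.call(rbind, strsplit(names(agg), "~", fixed = TRUE))
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, nrow(res), name = rid)
  if (!is.null(epairs) && nrow(epairs) > 0)
    g <- igraph::add_edges(g, t(matrix(match(epairs, rid), ncol = 2)),
                           kinds = unname(agg))
  structure(list(graph = g, residues = res, interface_id = interface_id),
            class = "ppi_contact_network")
}

#' Complex-network metrics of a contact network
#'
#' Computed on the largest connected component: mean normalised closeness
#' centrality, Freeman central-point dominance (from normalised
#' betweenness) and the cardinality of the graph center (minimum
#' eccentricity set).
#'
#' @param net a \code{ppi_contact_network} or an igraph graph.
#' @return named list: \code{mean_closeness}, \code{central_point_dominance},
#'   \code{graph_center_size}, \code{n_nodes}, \code{n_edges}.
#' @export
network_metrics <- function(net) {
  g <- if (inherits(net, "ppi_contact_network")) net$graph else net
  if (igraph::vcount(g) == 0) stop("network has no nodes")
  comp <- igraph::components(g)
  big <- which.max(comp$csize)
  sub <- igraph::induced_subgraph(g, which(comp$membership == big))
  n <- igraph::vcount(sub)
  if (n == 1) {
    return(list(mean_closeness = 0, central_point_dominance = 0,
                graph_center_size = 1L,
                n_nodes = igraph::vcount(g), n_edges = igraph::ecount(g)))
  }
  clo <- igraph::closeness(sub, normalized = TRUE)
  bet <- igraph::betweenness(sub, directed = FALSE)
  bmax_possible <- (n - 1) * (n - 2) / 2
  bnorm <- if (bmax_possible > 0) bet / bmax_possible else rep(0, n)
  cpd <- if (n > 2) sum(max(bnorm) - bnorm) / (n - 1) else 0
  ecc <- igraph::eccentricity(sub)
  list(mean_closeness = mean(clo),
       central_point_dominance = cpd,
       graph_center_size = sum(ecc == min(ecc)),
       n_nodes = igraph::vcount(g), n_edges = igraph::ecount(g))
}

#' Export network metrics as JSON
#'
#' @param metrics list from \code{\link{network_metrics}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_metrics_json <- function(metrics, path) {
  jsonlite::write_json(metrics, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
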