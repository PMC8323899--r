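# Build D-PRN / PIE-PRN graphs and split supramolecular systems.
#
# PrnGraphs are igraph objects: vertex attribute `name` is the canonical
# residue label "chain:number[:icode]:name", optional `monomer`; edge
# attributes weight, importance, energy components, r_ij; graph attribute
# `kind` in {dprn, pieprn_fmo, pieprn_ff}.

#' Edge acceptance criteria for network construction
#'
#' For a D-PRN the mandatory criterion is the centre-of-mass distance
#' cutoff `r_lim` (edge iff \eqn{R_{ij} \le R_{lim}}).  For a PIE-PRN the
#' mandatory criterion is the energy cutoff `e_lim` on the chosen energy
#' term (edge iff \eqn{E_{ij} \le E_{lim}}, a signed comparison — PIEDA
#' terms may be positive); `r_lim` is then an optional secondary criterion.
#' Edge weights follow the scheme \eqn{w_{ij} = |E_{ij}|^{-1}} (energy
#' networks) or \eqn{w_{ij} = R_{ij}} (distance networks); the edge
#' importance is always the inverse of the weight, so strong interactions
#' are short, highly conductive links.
#'
#' @param e_lim PIE cutoff, kcal/mol (typically negative, e.g. -1).
#' @param r_lim Distance cutoff, angstroms.
#' @param energy_term Which energy component drives acceptance/weights:
#'   one of `"e_tot"`, `"es"`, `"ex"`, `"ct"`, `"di"`, `"solv"`,
#'   `"elec_ff"`, `"vdw_ff"`.
#' @param include_covalent Treat sequence-adjacent (peptide-bonded) residue
#'   pairs as ordinary edge candidates (`TRUE`, default) or skip them.
#' @param weight_scheme `"inverse_abs_energy"` or `"distance"`.
#' @return A `build_criteria` list.
#' @export
build_criteria <- function(e_lim = NULL, r_lim = NULL, energy_term = "e_tot",
                           include_covalent = TRUE,
                           weight_scheme = c("inverse_abs_energy", "distance")) {
  weight_scheme <- match.arg(weight_scheme)
  energy_term <- match.arg(energy_term, .pie_component_names)
  structure(list(e_lim = e_lim, r_lim = r_lim, energy_term = energy_term,
                 include_covalent = include_covalent,
                 weight_scheme = weight_scheme),
            class = "build_criteria")
}

# residues i,j are sequence-adjacent (candidate peptide neighbours)?
.covalent_pairs <- function(chain, resno) {
  function(i, j) chain[i] == chain[j] & abs(resno[i] - resno[j]) == 1L
}

#' Build a distance-based residue network (D-PRN)
#'
#' Nodes are the residues of the structure; an edge joins residues whose
#' centre-of-mass distance is at most `r_lim`.  Edge weight is the distance
#' itself, importance its inverse.
#'
#' @param structure A `prn_structure`.
#' @param criteria A [build_criteria()] with a positive `r_lim`.
#' @return An igraph `PrnGraph` (graph attribute `kind = "dprn"`).
#' @export
build_dprn <- function(structure, criteria) {
  stopifnot(inherits(structure, "prn_structure"),
            inherits(criteria, "build_criteria"))
  if (is.null(criteria$r_lim) || criteria$r_lim <= 0)
    prn_stop("D-PRN requires a positive r_lim", "prn_criteria_error")
  com <- center_of_mass(structure)
  n <- nrow(com)
  labels <- rownames(com)
  d <- as.matrix(stats::dist(com))
  sel <- which(upper.tri(d) & d <= criteria$r_lim, arr.ind = TRUE)
  if (nrow(sel) && !criteria$include_covalent) {
    cov <- .covalent_pairs(structure$residues$chain, structure$residues$resno)
    sel <- sel[!cov(sel[, 1], sel[, 2]), , drop = FALSE]
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  igraph::V(g)$name <- labels
  if (nrow(sel)) {
    g <- igraph::add_edges(g, rbind(sel[, 1], sel[, 2]))
    w <- d[sel]
    igraph::E(g)$weight <- w
    igraph::E(g)$importance <- 1 / w
    igraph::E(g)$r_ij <- w
  }
  g <- igraph::set_graph_attr(g, "kind", "dprn")
  g
}

# electrostatic vs dispersion character from attractive magnitudes
.edge_character <- function(es, di) {
  a_es <- pmax(-es, 0)
  a_di <- pmax(-di, 0)
  ifelse(a_es + a_di > 0, a_es / (a_es + a_di), NA_real_)
}

#' Build a pair-interaction-energy residue network (PIE-PRN)
#'
#' Nodes are the labels of the pair table; an edge joins nodes whose chosen
#' energy term satisfies \eqn{E \le E_{lim}} and, when both `r_lim` and a
#' structure are supplied, whose centre-of-mass distance satisfies
#' \eqn{R_{ij} \le R_{lim}}.  Edge weight is \eqn{1/|E|}, importance
#' \eqn{|E|}; all available components are copied onto the edge, and when
#' PIEDA electrostatic/dispersion terms are present an electrostatic
#' `character` fraction es/(es+di) over attractive magnitudes is added.
#'
#' @param pie A [pie_table()].
#' @param criteria A [build_criteria()] with `e_lim` set.
#' @param structure Optional `prn_structure` whose residue labels match the
#'   pie labels; provides distances `r_ij` and enables the secondary
#'   distance criterion.
#' @return An igraph `PrnGraph` (`kind = "pieprn_fmo"` or `"pieprn_ff"`).
#' @export
build_pieprn <- function(pie, criteria, structure = NULL) {
  stopifnot(inherits(pie, "pie_table"), inherits(criteria, "build_criteria"))
  if (is.null(criteria$e_lim))
    prn_stop("PIE-PRN requires e_lim", "prn_criteria_error")
  term <- criteria$energy_term
  if (!term %in% names(pie$pairs))
    prn_stop(paste0("energy term not present in pair table: ", term),
             "prn_criteria_error")
  df <- pie$pairs
  keep <- !is.na(df[[term]]) & df[[term]] <= criteria$e_lim

  com <- NULL
  if (!is.null(structure)) {
    com_all <- center_of_mass(structure)
    idx <- match(pie$labels, rownames(com_all))
    if (!anyNA(idx)) com <- com_all[idx, , drop = FALSE]
  }
  r_ij <- rep(NA_real_, nrow(df))
  if (!is.null(com) && nrow(df))
    r_ij <- sqrt(rowSums((com[df$i, , drop = FALSE] -
                            com[df$j, , drop = FALSE])^2))
  if (!is.null(criteria$r_lim)) {
    if (is.null(com))
      prn_stop("secondary r_lim criterion needs a structure with matching labels",
               "prn_criteria_error")
    keep <- keep & r_ij <= criteria$r_lim
  }
  if (!criteria$include_covalent && nrow(df)) {
    parts <- .parse_labels(pie$labels)
    if (!is.null(parts)) {
      cov <- parts$chain[df$i] == parts$chain[df$j] &
        abs(parts$resno[df$i] - parts$resno[df$j]) == 1L
      keep <- keep & !cov
    }
  }
  zero <- keep & df[[term]] == 0
  if (any(zero)) {
    warning("pairs with zero-valued accepted energy rejected (weight undefined)")
    keep <- keep & !zero
  }

  g <- igraph::make_empty_graph(n = length(pie$labels), directed = FALSE)
  igraph::V(g)$name <- pie$labels
  sel <- which(keep)
  if (length(sel)) {
    g <- igraph::add_edges(g, rbind(df$i[sel], df$j[sel]))
    e <- df[[term]][sel]
    igraph::E(g)$weight <- 1 / abs(e)
    igraph::E(g)$importance <- abs(e)
    for (cn in intersect(.pie_component_names, names(df)))
      g <- igraph::set_edge_attr(g, cn, value = df[[cn]][sel])
    igraph::E(g)$r_ij <- r_ij[sel]
    if (all(c("es", "di") %in% names(df)))
      igraph::E(g)$character <- .edge_character(df$es[sel], df$di[sel])
  }
  kind <- if (pie$source == "fmo") "pieprn_fmo" else "pieprn_ff"
  g <- igraph::set_graph_attr(g, "kind", kind)
  g
}

# parse canonical labels "chain:number[:icode]:name"; NULL if not canonical
.parse_labels <- function(labels) {
  parts <- strsplit(labels, ":", fixed = TRUE)
  len <- lengths(parts)
  if (!all(len %in% c(3L, 4L))) return(NULL)
  chain <- vapply(parts, `[`, "", 1L)
  resno <- suppressWarnings(as.integer(vapply(parts, `[`, "", 2L)))
  if (anyNA(resno)) return(NULL)
  list(chain = chain, resno = resno)
}

#' Split a supersystem graph into monomer and interface subgraphs
#'
#' Decomposes the graph G of a complex into \eqn{G = G_A \cup G_B \cup
#' G_{PPI}}: the monomer subgraphs carry all nodes and the edges within
#' each monomer; the bipartite interface graph \eqn{G_{PPI}} carries only
#' nodes with at least one cross-monomer edge and only cross-monomer
#' edges.  \eqn{G_{A\cup B}} keeps all nodes of G with the interface edges
#' removed — the baseline graph of network differential analysis.
#'
#' @param g A `PrnGraph`.
#' @param membership Named character vector over all node names of `g`
#'   with values `"A"` or `"B"`.
#' @return A `prn_split`: list with `g`, `g_a`, `g_b`, `g_ppi`, `g_aub`,
#'   and counts `n_a`, `n_b`, `n_ppi`.
#' @export
split_supersystem <- function(g, membership) {
  nm <- igraph::V(g)$name
  miss <- setdiff(nm, names(membership))
  if (length(miss))
    prn_stop(paste0("nodes without monomer membership: ",
                    paste(head(miss, 5), collapse = ", ")),
             "prn_membership_error")
  memb <- membership[nm]
  if (!all(memb %in% c("A", "B")))
    prn_stop("membership values must be 'A' or 'B'", "prn_membership_error")
  igraph::V(g)$monomer <- unname(memb)

  ends <- igraph::ends(g, igraph::E(g), names = FALSE)
  cross <- if (nrow(ends)) memb[ends[, 1]] != memb[ends[, 2]] else logical(0)
  if (igraph::ecount(g)) igraph::E(g)$cross_monomer <- cross

  g_aub <- igraph::delete_edges(g, which(cross))
  g_ppi <- igraph::subgraph_from_edges(g, which(cross), delete.vertices = TRUE)
  g_a <- igraph::induced_subgraph(g, which(memb == "A"))
  g_b <- igraph::induced_subgraph(g, which(memb == "B"))
  structure(list(g = g, g_a = g_a, g_b = g_b, g_ppi = g_ppi, g_aub = g_aub,
                 n_a = sum(memb == "A"), n_b = sum(memb == "B"),
                 n_ppi = igraph::vcount(g_ppi)),
            class = "prn_split")
}

#' @export
print.prn_split <- function(x, ...) {
  cat(sprintf(
    "prn_split: |V(G)|=%d |E(G)|=%d; N_A=%d N_B=%d; interface: %d nodes, %d edges\n",
    igraph::vcount(x$g), igraph::ecount(x$g), x$n_a, x$n_b,
    x$n_ppi, igraph::ecount(x$g_ppi)))
  invisible(x)
}

#' Tabulate the edges of a network
#'
#' One row per edge with both node labels and all numeric edge attributes
#' (weight, importance, energy components, distance, interface flag,
#' electrostatic character), deterministically ordered by node labels.
#'
#' @param g A `PrnGraph`.
#' @return A data frame (zero rows, with header, for an edgeless graph).
#' @export
edge_table <- function(g) {
  nm <- igraph::V(g)$name
  base_cols <- c("weight", "importance", "e_tot", "es", "ex", "ct", "di",
                 "solv", "elec_ff", "vdw_ff", "r_ij", "cross_monomer",
                 "character")
  have <- intersect(base_cols, igraph::edge_attr_names(g))
  if (!igraph::ecount(g)) {
    out <- data.frame(node_a = character(), node_b = character())
    for (cn in have) out[[cn]] <- numeric()
    return(out)
  }
  ends <- igraph::ends(g, igraph::E(g), names = FALSE)
  a <- nm[ends[, 1]]; b <- nm[ends[, 2]]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  out <- data.frame(node_a = a, node_b = b, stringsAsFactors = FALSE)
  for (cn in have) out[[cn]] <- igraph::edge_attr(g, cn)
  out <- out[order(out$node_a, out$node_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}
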