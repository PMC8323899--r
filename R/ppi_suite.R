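# Supramolecular analyses on a prn_split: network differential analysis,
# SVD interface motifs, SPIE tables, per-fragment binding energies.

.nda_kinds <- c(.centrality_kinds, "etot", "efficiency")

.centrality_of <- function(g, kind) {
  switch(kind,
         etot = total_energy_centrality(g),
         efficiency = efficiency_centrality(g),
         node_centrality(g, kind))$values
}

#' Network differential analysis (NDA)
#'
#' Quantifies how the interface edges change each node's centrality:
#' \eqn{\Delta C_k = C_k(G) - C_k(G_{A\cup B})}, where \eqn{G_{A\cup B}}
#' has all nodes of G but none of the interface edges.  Because both
#' graphs share the node set, the scores are directly comparable — the
#' pitfall of comparing centralities across graphs of different size is
#' avoided.  A monomer baseline (centralities evaluated on \eqn{G_A} /
#' \eqn{G_B} separately) is retained behind `baseline = "monomer"` but its
#' ranking is flagged as size-inconsistent.
#'
#' @param split A `prn_split` from [split_supersystem()].
#' @param kind Centrality kind: `"degree"`, `"closeness"`,
#'   `"betweenness"`, `"current_flow_betweenness"`, `"etot"`,
#'   `"efficiency"`.
#' @param baseline `"g_aub"` (default) or `"monomer"`.
#' @return A `prn_nda`: list with `kind`, `baseline` and `delta`, a named
#'   numeric vector over all nodes of G.
#' @export
nda <- function(split, kind = .nda_kinds, baseline = c("g_aub", "monomer")) {
  stopifnot(inherits(split, "prn_split"))
  kind <- match.arg(kind)
  baseline <- match.arg(baseline)
  g <- split$g
  if (kind == "etot" &&
      (igraph::ecount(g) > 0L) && !"e_tot" %in% igraph::edge_attr_names(g))
    prn_stop("etot NDA needs a PIE-PRN (edges with e_tot)",
             "prn_unsupported_graph_error")
  c_full <- .centrality_of(g, kind)
  if (baseline == "g_aub") {
    c_base <- .centrality_of(split$g_aub, kind)[names(c_full)]
  } else {
    c_base <- setNames(rep(NA_real_, length(c_full)), names(c_full))
    for (sub in list(split$g_a, split$g_b)) {
      if (igraph::vcount(sub) == 0L) next
      cb <- tryCatch(.centrality_of(sub, kind), prn_error = function(e) NULL)
      if (!is.null(cb)) c_base[names(cb)] <- cb
    }
    warning("monomer baseline compares centralities across graphs of ",
            "different size; ranking may be unreliable")
  }
  structure(list(kind = kind, baseline = baseline,
                 delta = c_full - c_base),
            class = "prn_nda")
}

#' @export
print.prn_nda <- function(x, ...) {
  top <- head(sort(abs(x$delta), decreasing = TRUE), 3)
  cat(sprintf("prn_nda (%s, baseline %s): %d nodes; top |delta|: %s\n",
              x$kind, x$baseline, length(x$delta),
              paste(sprintf("%s=%.4g", names(top), x$delta[names(top)]),
                    collapse = ", ")))
  invisible(x)
}

#' Interface energy matrix
#'
#' The matrix subjected to SVD motif analysis.  In `block` mode rows are
#' the interface nodes of monomer A and columns those of monomer B (the
#' off-diagonal block of the adjacency matrix); in `full` mode the square
#' symmetric adjacency matrix of the bipartite interface graph over all
#' N_PPI interface nodes is returned.  Entries hold the chosen energy term
#' of the cross-monomer edges, zero elsewhere; a sign filter can restrict
#' to attractive (negative) or repulsive (positive) interactions.
#'
#' @param split A `prn_split` with a non-empty interface.
#' @param term Energy term carried by the interface edges (default
#'   `"e_tot"`).
#' @param mode `"block"` or `"full"`.
#' @param sign_filter `"both"`, `"attractive"` or `"repulsive"`.
#' @return A `prn_ppi_matrix`: list with `entries`, `row_index`,
#'   `col_index`, `mode`, `term`, `sign_filter`.
#' @export
ppi_matrix <- function(split, term = "e_tot", mode = c("block", "full"),
                       sign_filter = c("both", "attractive", "repulsive")) {
  stopifnot(inherits(split, "prn_split"))
  mode <- match.arg(mode)
  sign_filter <- match.arg(sign_filter)
  gp <- split$g_ppi
  if (igraph::ecount(gp) == 0L)
    prn_stop("empty interface: no cross-monomer edges", "prn_empty_interface_error")
  if (!term %in% igraph::edge_attr_names(gp))
    prn_stop(paste0("interface edges carry no term ", term), "prn_criteria_error")
  ends <- igraph::ends(gp, igraph::E(gp), names = TRUE)
  val <- igraph::edge_attr(gp, term)
  if (sign_filter == "attractive") val[val > 0] <- 0
  if (sign_filter == "repulsive") val[val < 0] <- 0
  memb <- setNames(igraph::V(gp)$monomer, igraph::V(gp)$name)
  a_side <- ifelse(memb[ends[, 1]] == "A", ends[, 1], ends[, 2])
  b_side <- ifelse(memb[ends[, 1]] == "A", ends[, 2], ends[, 1])
  a_nodes <- names(memb)[memb == "A"]
  b_nodes <- names(memb)[memb == "B"]
  if (mode == "block") {
    M <- matrix(0, length(a_nodes), length(b_nodes),
                dimnames = list(a_nodes, b_nodes))
    M[cbind(match(a_side, a_nodes), match(b_side, b_nodes))] <- val
    row_index <- a_nodes; col_index <- b_nodes
  } else {
    all_nodes <- names(memb)
    M <- matrix(0, length(all_nodes), length(all_nodes),
                dimnames = list(all_nodes, all_nodes))
    ia <- match(a_side, all_nodes); ib <- match(b_side, all_nodes)
    M[cbind(ia, ib)] <- val
    M[cbind(ib, ia)] <- val
    row_index <- all_nodes; col_index <- all_nodes
  }
  structure(list(entries = M, row_index = row_index, col_index = col_index,
                 mode = mode, term = term, sign_filter = sign_filter),
            class = "prn_ppi_matrix")
}

#' SVD motif decomposition of the interface matrix
#'
#' Decomposes the interface energy matrix as \eqn{M = U \Sigma V^*}.  Each
#' rank-1 term \eqn{\sigma_i u_i \otimes v_i^*} is an interaction motif
#' (principal coordinate) of the interface; the convergence factor
#' \eqn{f^{(r)} = \sum_{i \le r} \sigma_i / \sum_{i \le k} \sigma_i}
#' measures how much of the interaction pattern the leading r motifs
#' capture (\eqn{f^{(k)} = 1}).  The sign ambiguity of each singular pair
#' is resolved by making the largest-magnitude entry of \eqn{u_i}
#' positive, so motif reports are reproducible.
#'
#' @param m A `prn_ppi_matrix` (must not be all zero).
#' @return A `prn_svd`: list with `sigma` (descending), `u`, `v`
#'   (orthonormal columns), `f_series`, `k`, `row_index`, `col_index`.
#' @export
svd_motifs <- function(m) {
  stopifnot(inherits(m, "prn_ppi_matrix"))
  M <- m$entries
  if (all(M == 0))
    prn_stop("all-zero interface matrix (sign filter removed everything?)",
             "prn_empty_interface_error")
  s <- svd(M)
  k <- length(s$d)
  for (i in seq_len(k)) {
    jm <- which.max(abs(s$u[, i]))
    if (s$u[jm, i] < 0) { s$u[, i] <- -s$u[, i]; s$v[, i] <- -s$v[, i] }
  }
  structure(list(sigma = s$d, u = s$u, v = s$v,
                 f_series = cumsum(s$d) / sum(s$d), k = k,
                 row_index = m$row_index, col_index = m$col_index,
                 mode = m$mode, term = m$term),
            class = "prn_svd")
}

#' @export
print.prn_svd <- function(x, ...) {
  r <- min(4L, x$k)
  cat(sprintf("prn_svd (%s, %s): k=%d; sigma_1..%d = %s; f^(%d) = %.3f\n",
              x$mode, x$term, x$k, r,
              paste(sprintf("%.3f", x$sigma[seq_len(r)]), collapse = ", "),
              r, x$f_series[r]))
  invisible(x)
}

#' Rank-r reconstruction of the interface matrix
#'
#' \eqn{\tilde M^{(r)} = \sum_{i=1}^r \sigma_i u_i \otimes v_i^*}; for
#' r = k the original matrix is recovered.
#'
#' @param res A `prn_svd`.
#' @param r Rank, `1 <= r <= k`.
#' @return Numeric matrix with the original dimnames.
#' @export
reconstruct_rank_r <- function(res, r) {
  stopifnot(inherits(res, "prn_svd"))
  if (r < 1L || r > res$k)
    prn_stop("rank r out of range", "prn_criteria_error")
  M <- res$u[, seq_len(r), drop = FALSE] %*%
    (res$sigma[seq_len(r)] * t(res$v[, seq_len(r), drop = FALSE]))
  dimnames(M) <- list(res$row_index, res$col_index)
  M
}

#' Dominant nodes of an interface motif
#'
#' Within motif i, nodes whose singular-vector component magnitude reaches
#' `alpha` times the maximum are reported, together with their strongest
#' interacting partners on the other side (ordered by the magnitude of the
#' shared interface entry).
#'
#' @param res A `prn_svd`.
#' @param m The `prn_ppi_matrix` the decomposition came from (provides the
#'   partner energies).
#' @param i Motif index, `1 <= i <= k`.
#' @param side `"A"` (left vectors / rows) or `"B"` (right vectors /
#'   columns).
#' @param alpha Dominance threshold in (0, 1]; default 0.5.
#' @return Data frame: `node`, `component`, `partners` (semicolon-joined
#'   `partner(energy)` strings), ordered by decreasing |component|.
#' @export
dominant_motif_nodes <- function(res, m, i, side = c("A", "B"), alpha = 0.5) {
  stopifnot(inherits(res, "prn_svd"), inherits(m, "prn_ppi_matrix"))
  side <- match.arg(side)
  if (alpha <= 0 || alpha > 1)
    prn_stop("alpha must lie in (0, 1]", "prn_criteria_error")
  if (i < 1L || i > res$k) prn_stop("motif index out of range", "prn_criteria_error")
  vec <- if (side == "A") res$u[, i] else res$v[, i]
  nodes <- if (side == "A") res$row_index else res$col_index
  thr <- alpha * max(abs(vec))
  sel <- which(abs(vec) >= thr)
  sel <- sel[order(-abs(vec[sel]))]
  partners <- vapply(sel, function(jj) {
    row <- if (side == "A") m$entries[nodes[jj] == m$row_index, , drop = TRUE]
           else m$entries[, nodes[jj] == m$col_index, drop = TRUE]
    pn <- if (side == "A") m$col_index else m$row_index
    nz <- which(row != 0)
    nz <- nz[order(-abs(row[nz]))]
    paste(sprintf("%s(%.3f)", pn[nz], row[nz]), collapse = ";")
  }, "")
  data.frame(node = nodes[sel], component = vec[sel], partners = partners,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Scattered pair interaction energy (SPIE) table
#'
#' Long-format data behind a 3D-SPIE plot: every cross-monomer pair of the
#' raw pair table (not only pairs accepted as edges, so repulsive
#' interactions appear too) with the chosen energy term and an
#' attractive/repulsive label; pairs below `min_abs` in magnitude are
#' dropped.
#'
#' @param split A `prn_split` (supplies monomer membership).
#' @param pie The `pie_table` the network came from.
#' @param term Energy component column of the pair table.
#' @param min_abs Minimum |energy| to report, kcal/mol.
#' @return Data frame: `node_a`, `node_b`, `energy`, `sign`
#'   (`"attractive"` if negative, else `"repulsive"`).
#' @export
spie_data <- function(split, pie, term = "e_tot", min_abs = 0) {
  stopifnot(inherits(split, "prn_split"), inherits(pie, "pie_table"))
  if (!term %in% names(pie$pairs))
    prn_stop(paste0("term absent from pair table: ", term), "prn_criteria_error")
  memb <- setNames(igraph::V(split$g)$monomer, igraph::V(split$g)$name)
  mi <- memb[pie$labels[pie$pairs$i]]
  mj <- memb[pie$labels[pie$pairs$j]]
  val <- pie$pairs[[term]]
  keep <- !is.na(mi) & !is.na(mj) & mi != mj & !is.na(val) & abs(val) >= min_abs
  df <- pie$pairs[keep, , drop = FALSE]
  val <- val[keep]; mi <- mi[keep]
  node_a <- ifelse(mi == "A", pie$labels[df$i], pie$labels[df$j])
  node_b <- ifelse(mi == "A", pie$labels[df$j], pie$labels[df$i])
  out <- data.frame(node_a = node_a, node_b = node_b, energy = val,
                    sign = ifelse(val < 0, "attractive", "repulsive"),
                    stringsAsFactors = FALSE)
  out <- out[order(out$node_a, out$node_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-fragment binding energies
#'
#' Divides the total inter-monomer interaction energy (the sum of all
#' cross-monomer pair energies, regardless of edge criteria) into
#' per-fragment contributions: asymmetric assignment gives fragment
#' \eqn{i \in A} the sum \eqn{\sum_{j \in B} E_{tot}(i,j)} (and B
#' fragments zero; mirrored for `asymmetric_B`), symmetric assignment
#' gives each endpoint half of every cross pair.  In every mode the
#' contributions sum to the total cross energy.
#'
#' @param pie A `pie_table`.
#' @param membership Named `"A"`/`"B"` vector over the pie labels.
#' @param mode `"symmetric"`, `"asymmetric_A"` or `"asymmetric_B"`.
#' @return A `prn_binding`: list with `mode`, `contributions` (named,
#'   kcal/mol) and `total`.
#' @export
binding_energies <- function(pie, membership,
                             mode = c("symmetric", "asymmetric_A",
                                      "asymmetric_B")) {
  stopifnot(inherits(pie, "pie_table"))
  mode <- match.arg(mode)
  miss <- setdiff(pie$labels, names(membership))
  if (length(miss))
    prn_stop(paste0("fragments without membership: ",
                    paste(head(miss, 5), collapse = ", ")),
             "prn_membership_error")
  memb <- membership[pie$labels]
  contrib <- setNames(rep(0, length(pie$labels)), pie$labels)
  df <- pie$pairs
  mi <- memb[df$i]; mj <- memb[df$j]
  cross <- which(mi != mj)
  if (!length(cross)) {
    warning("no cross-monomer pairs in the table; binding energies are zero")
    return(structure(list(mode = mode, contributions = contrib, total = 0),
                     class = "prn_binding"))
  }
  for (r in cross) {
    e <- df$e_tot[r]
    li <- pie$labels[df$i[r]]; lj <- pie$labels[df$j[r]]
    if (mode == "symmetric") {
      contrib[li] <- contrib[li] + e / 2
      contrib[lj] <- contrib[lj] + e / 2
    } else {
      tgt <- if (mode == "asymmetric_A") {
        if (memb[df$i[r]] == "A") li else lj
      } else {
        if (memb[df$i[r]] == "B") li else lj
      }
      contrib[tgt] <- contrib[tgt] + e
    }
  }
  structure(list(mode = mode, contributions = contrib,
                 total = sum(df$e_tot[cross])),
            class = "prn_binding")
}

#' @export
print.prn_binding <- function(x, ...) {
  cat(sprintf("prn_binding (%s): total cross energy %.3f kcal/mol over %d fragments\n",
              x$mode, x$total, length(x$contributions)))
  invisible(x)
}
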