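# Node/edge analytics on PrnGraphs. Edge `weight` acts as a distance-like
# cost (shortest paths, closeness, betweenness, efficiency); `importance`
# = 1/weight acts as connection strength/conductance (Louvain, spectral,
# current-flow betweenness).

.centrality_kinds <- c("degree", "closeness", "betweenness",
                       "current_flow_betweenness")

#' Node centralities
#'
#' Weighted centralities with the package's weight semantics: degree
#' centrality is the neighbour count normalised by \eqn{n-1}; closeness and
#' betweenness treat the edge weight as a distance; current-flow
#' betweenness uses the edge importance as electrical conductance, so
#' strong interactions conduct more.  On disconnected graphs closeness
#' follows the within-component convention scaled by
#' \eqn{(s-1)/(n-1)} for component size s, and current-flow betweenness is
#' computed per connected component.
#'
#' @param g A `PrnGraph` with at least one node.
#' @param kind One of `"degree"`, `"closeness"`, `"betweenness"`,
#'   `"current_flow_betweenness"`.
#' @return A `prn_centrality`: list with `kind` and `values`, a named
#'   numeric vector over all nodes.
#' @export
node_centrality <- function(g, kind = .centrality_kinds) {
  kind <- match.arg(kind)
  n <- igraph::vcount(g)
  if (n == 0L) prn_stop("empty graph", "prn_empty_graph_error")
  w <- if (igraph::ecount(g)) igraph::E(g)$weight else numeric(0)
  vals <- switch(
    kind,
    degree = igraph::degree(g) / max(1L, n - 1L),
    closeness = .closeness_wf(g, w),
    betweenness = if (n < 3L) setNames(rep(0, n), igraph::V(g)$name) else
      igraph::betweenness(g, weights = w, normalized = TRUE),
    current_flow_betweenness = .current_flow_betweenness(g)
  )
  vals <- setNames(as.numeric(vals), igraph::V(g)$name)
  structure(list(kind = kind, values = vals,
                 graph_id = igraph::graph_attr(g, "kind")),
            class = "prn_centrality")
}

# closeness with the Wasserman-Faust component correction:
# C(v) = ((s-1)/(n-1)) * (s-1)/sum(d(v,u), u in component of v)
.closeness_wf <- function(g, w) {
  n <- igraph::vcount(g)
  d <- igraph::distances(g, weights = w)
  vapply(seq_len(n), function(v) {
    dv <- d[v, -v]
    reach <- is.finite(dv)
    s <- sum(reach) + 1L
    if (s < 2L || n < 2L) return(0)
    ((s - 1) / (n - 1)) * ((s - 1) / sum(dv[reach]))
  }, numeric(1))
}

# Current-flow (random-walk) betweenness via the Laplacian pseudoinverse,
# per connected component; conductance = edge importance. Throughput of an
# interior node v for a unit s->t current is half the sum of absolute
# currents on its incident edges; scores are averaged over the pairs of the
# component not containing v.
.current_flow_betweenness <- function(g) {
  n <- igraph::vcount(g)
  out <- setNames(rep(0, n), igraph::V(g)$name)
  comps <- igraph::components(g)
  for (ci in seq_len(comps$no)) {
    vs <- which(comps$membership == ci)
    nc <- length(vs)
    if (nc < 3L) next
    sub <- igraph::induced_subgraph(g, vs)
    m <- igraph::ecount(sub)
    if (!m) next
    ends <- igraph::ends(sub, igraph::E(sub), names = FALSE)
    cond <- igraph::E(sub)$importance
    L <- matrix(0, nc, nc)
    for (e in seq_len(m)) {
      i <- ends[e, 1]; j <- ends[e, 2]
      L[i, i] <- L[i, i] + cond[e]; L[j, j] <- L[j, j] + cond[e]
      L[i, j] <- L[i, j] - cond[e]; L[j, i] <- L[j, i] - cond[e]
    }
    Tm <- .pinv_sym(L)
    tau <- rep(0, nc)
    inc <- lapply(seq_len(nc), function(v) which(ends[, 1] == v | ends[, 2] == v))
    for (s in 1:(nc - 1)) {
      for (t in (s + 1):nc) {
        p <- Tm[, s] - Tm[, t]
        cur <- cond * (p[ends[, 1]] - p[ends[, 2]])
        absflow <- abs(cur)
        for (v in seq_len(nc)) {
          if (v == s || v == t) next
          tau[v] <- tau[v] + 0.5 * sum(absflow[inc[[v]]])
        }
      }
    }
    npairs <- (nc - 1) * (nc - 2) / 2
    out[vs] <- tau / npairs
  }
  out
}

.pinv_sym <- function(L, tol = 1e-10) {
  e <- eigen(L, symmetric = TRUE)
  keep <- e$values > tol * max(abs(e$values))
  if (!any(keep)) return(matrix(0, nrow(L), ncol(L)))
  e$vectors[, keep, drop = FALSE] %*%
    (t(e$vectors[, keep, drop = FALSE]) / e$values[keep])
}

#' Total energy centrality
#'
#' \eqn{C_k^{Etot} = \sum_{(k,j) \in E} E_{tot}(k,j)}: the sum of total
#' pair energies over a node's incident edges.  A node with a low (more
#' negative) score is strongly bound in the network, the interpretation
#' common in FMO-based studies.  Isolated nodes score 0.
#'
#' @param g A PIE-PRN (edges must carry `e_tot`).
#' @return A `prn_centrality` with kind `"etot"` (kcal/mol).
#' @export
total_energy_centrality <- function(g) {
  if (igraph::vcount(g) == 0L) prn_stop("empty graph", "prn_empty_graph_error")
  if (igraph::ecount(g) && !"e_tot" %in% igraph::edge_attr_names(g))
    prn_stop("graph edges carry no e_tot (distance network?)",
             "prn_unsupported_graph_error")
  vals <- setNames(rep(0, igraph::vcount(g)), igraph::V(g)$name)
  if (igraph::ecount(g)) {
    ends <- igraph::ends(g, igraph::E(g), names = FALSE)
    et <- igraph::E(g)$e_tot
    for (e in seq_along(et)) {
      vals[ends[e, 1]] <- vals[ends[e, 1]] + et[e]
      vals[ends[e, 2]] <- vals[ends[e, 2]] + et[e]
    }
  }
  structure(list(kind = "etot", values = vals,
                 graph_id = igraph::graph_attr(g, "kind")),
            class = "prn_centrality")
}

#' Weighted global efficiency
#'
#' \eqn{E_{glob} = \frac{1}{N(N-1)} \sum_{i \ne j} 1/d(i,j)} with d the
#' weighted shortest-path length and \eqn{1/d = 0} for disconnected pairs.
#'
#' @param g A `PrnGraph` with at least 2 nodes.
#' @return A number in `[0, Inf)`; 1 for a complete unit-weight graph.
#' @export
global_efficiency <- function(g) {
  n <- igraph::vcount(g)
  if (n < 2L) prn_stop("global efficiency undefined for N < 2",
                       "prn_undefined_error")
  w <- if (igraph::ecount(g)) igraph::E(g)$weight else numeric(0)
  d <- igraph::distances(g, weights = w)
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' Weighted local efficiency of a node
#'
#' Global efficiency of the subgraph induced by the neighbours of `k`
#' (edge weights retained); 0 when `k` has fewer than two neighbours.
#'
#' @param g A `PrnGraph`.
#' @param k Node name or index.
#' @return A number.
#' @export
local_efficiency <- function(g, k) {
  nb <- igraph::neighbors(g, k)
  if (length(nb) < 2L) return(0)
  global_efficiency(igraph::induced_subgraph(g, nb))
}

#' Efficiency centrality
#'
#' The relative drop in weighted global efficiency when a node is removed:
#' \eqn{C_k^{eff} = (E_{glob}(G) - E_{glob}(G \setminus k)) / E_{glob}(G)}.
#' May be negative: removing a peripheral node can raise the mean
#' efficiency of the remainder.
#'
#' @param g A `PrnGraph` with at least 3 nodes and nonzero global
#'   efficiency.
#' @return A `prn_centrality` with kind `"efficiency"`.
#' @export
efficiency_centrality <- function(g) {
  n <- igraph::vcount(g)
  if (n < 3L) prn_stop("efficiency centrality needs N >= 3",
                       "prn_undefined_error")
  e0 <- global_efficiency(g)
  if (e0 == 0) prn_stop("zero global efficiency", "prn_undefined_error")
  vals <- vapply(seq_len(n), function(v) {
    (e0 - global_efficiency(igraph::delete_vertices(g, v))) / e0
  }, numeric(1))
  structure(list(kind = "efficiency",
                 values = setNames(vals, igraph::V(g)$name),
                 graph_id = igraph::graph_attr(g, "kind")),
            class = "prn_centrality")
}

#' Residue folding degree
#'
#' A per-residue backbone-curvature index in the spirit of spectral folding
#' measures.  For each chain the backbone atoms (N, CA, C in residue order)
#' define M consecutive dihedral angles \eqn{\theta_i}; the symmetric
#' tridiagonal matrix with diagonal \eqn{\cos\theta_i} and unit
#' off-diagonal couples neighbouring dihedrals along the chain.  Its
#' principal eigenpair \eqn{(\lambda_1, v)} yields per-angle contributions
#' \eqn{\lambda_1 v_i^2}, which are summed onto the residue owning the
#' central bond of each dihedral; per-chain scores therefore sum to
#' \eqn{\lambda_1}, the chain folding index.  Folded (curled) backbones
#' with small dihedrals score higher than extended (trans) backbones.  The
#' score depends only on dihedral angles, hence is invariant under
#' rigid-body motion.
#'
#' @param structure A `prn_structure` with chains of at least 4 backbone
#'   atoms.
#' @return Named numeric vector over residue labels (residues of chains
#'   too short to define a dihedral get `NA`).
#' @export
folding_degree <- function(structure) {
  stopifnot(inherits(structure, "prn_structure"))
  at <- structure$atoms
  res <- structure$residues
  out <- setNames(rep(NA_real_, nrow(res)), res$label)
  any_chain <- FALSE
  for (ch in structure$chain_ids) {
    bb <- at[at$chain == ch & at$name %in% c("N", "CA", "C"), , drop = FALSE]
    ord <- order(bb$res_index, match(bb$name, c("N", "CA", "C")))
    bb <- bb[ord, , drop = FALSE]
    nb <- nrow(bb)
    if (nb < 4L) next
    any_chain <- TRUE
    xyz <- as.matrix(bb[, c("x", "y", "z")])
    M <- nb - 3L
    theta <- vapply(seq_len(M), function(i) {
      .dihedral(xyz[i, ], xyz[i + 1, ], xyz[i + 2, ], xyz[i + 3, ])
    }, numeric(1))
    Tm <- diag(cos(theta), M, M)
    if (M > 1L) for (i in 1:(M - 1)) { Tm[i, i + 1] <- 1; Tm[i + 1, i] <- 1 }
    e <- eigen(Tm, symmetric = TRUE)
    lam <- e$values[1]
    v <- e$vectors[, 1]
    contrib <- lam * v^2
    owner <- bb$res_index[seq_len(M) + 1L]  # residue of first central-bond atom
    for (i in seq_len(M)) {
      lab <- res$label[owner[i]]
      out[lab] <- if (is.na(out[lab])) contrib[i] else out[lab] + contrib[i]
    }
  }
  if (!any_chain)
    prn_stop("no chain with >= 4 consecutive backbone atoms",
             "prn_undefined_error")
  out
}

# signed dihedral angle (radians) of points a-b-c-d
.dihedral <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- .cross3(b1, b2); n2 <- .cross3(b2, b3)
  m1 <- .cross3(n1, b2 / sqrt(sum(b2^2)))
  atan2(sum(m1 * n2), sum(n1 * n2))
}

.cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' Minimum-weight path between two nodes
#'
#' Dijkstra shortest path on the edge weights with a deterministic
#' tie-break: among equally short paths the lexicographically smallest
#' node-label sequence is returned.
#'
#' @param g A `PrnGraph`.
#' @param s,t Node names (or indices).
#' @return List with `path` (character vector of node labels) and
#'   `length` (total weight).
#' @export
shortest_path <- function(g, s, t) {
  w <- if (igraph::ecount(g)) igraph::E(g)$weight else numeric(0)
  d <- igraph::distances(g, v = s, to = t, weights = w)[1, 1]
  if (!is.finite(d))
    prn_stop("no path between the requested nodes", "prn_no_path_error")
  ap <- igraph::all_shortest_paths(g, from = s, to = t, weights = w)
  seqs <- lapply(ap$vpaths, function(p) igraph::V(g)$name[as.integer(p)])
  keys <- vapply(seqs, paste, "", collapse = "\r")
  best <- seqs[[order(keys)[1L]]]
  list(path = best, length = unname(d))
}

#' Louvain community detection
#'
#' Modularity-based communities with edge importance as connection
#' strength.  Seeded: the same seed yields the same partition.
#'
#' @param g A `PrnGraph`.
#' @param resolution Louvain resolution parameter (default 1).
#' @param seed Integer RNG seed.
#' @return A `prn_partition`: list with `method`, `membership` (named,
#'   communities indexed 1..m, all non-empty) and `modularity`.
#' @export
louvain_communities <- function(g, resolution = 1.0, seed = 1L) {
  n <- igraph::vcount(g)
  if (igraph::ecount(g) == 0L) {
    memb <- setNames(seq_len(n), igraph::V(g)$name)
    return(structure(list(method = "louvain", membership = memb,
                          modularity = 0, resolution = resolution),
                     class = "prn_partition"))
  }
  cl <- with_prn_seed(seed, igraph::cluster_louvain(
    g, weights = igraph::E(g)$importance, resolution = resolution))
  memb <- igraph::membership(cl)
  structure(list(method = "louvain",
                 membership = setNames(as.integer(memb), igraph::V(g)$name),
                 modularity = igraph::modularity(
                   g, memb, weights = igraph::E(g)$importance,
                   resolution = resolution),
                 resolution = resolution),
            class = "prn_partition")
}

#' Spectral graph partition
#'
#' Normalised-Laplacian spectral clustering on the importance-weighted
#' adjacency: the k eigenvectors of smallest eigenvalue are row-normalised
#' and grouped with seeded k-means, making the partition reproducible.
#'
#' @param g A `PrnGraph`.
#' @param k Number of clusters, `1 <= k <= N`.
#' @param seed Integer RNG seed for the k-means grouping.
#' @return A `prn_partition` (method `"spectral"`).
#' @export
spectral_partition <- function(g, k, seed = 1L) {
  n <- igraph::vcount(g)
  if (k < 1L || k > n)
    prn_stop("k must satisfy 1 <= k <= N", "prn_criteria_error")
  nm <- igraph::V(g)$name
  if (k == 1L)
    return(structure(list(method = "spectral",
                          membership = setNames(rep(1L, n), nm), k = 1L),
                     class = "prn_partition"))
  if (k == n)
    return(structure(list(method = "spectral",
                          membership = setNames(seq_len(n), nm), k = k),
                     class = "prn_partition"))
  W <- matrix(0, n, n)
  if (igraph::ecount(g)) {
    ends <- igraph::ends(g, igraph::E(g), names = FALSE)
    imp <- igraph::E(g)$importance
    for (e in seq_along(imp)) {
      W[ends[e, 1], ends[e, 2]] <- W[ends[e, 1], ends[e, 2]] + imp[e]
      W[ends[e, 2], ends[e, 1]] <- W[ends[e, 2], ends[e, 1]] + imp[e]
    }
  }
  dg <- rowSums(W)
  dinv <- ifelse(dg > 0, 1 / sqrt(dg), 0)
  Lsym <- diag(n) - (dinv %o% dinv) * W
  e <- eigen(Lsym, symmetric = TRUE)
  U <- e$vectors[, n:(n - k + 1L), drop = FALSE]  # k smallest eigenvalues
  rn <- sqrt(rowSums(U^2))
  U <- U / ifelse(rn > 0, rn, 1)
  memb <- with_prn_seed(seed, {
    keys <- apply(round(U, 10), 1, paste, collapse = ",")
    if (length(unique(keys)) <= k) {
      match(keys, unique(keys))  # fewer distinct spectral rows than clusters
    } else {
      as.integer(kmeans(U, centers = k, nstart = 25, iter.max = 100)$cluster)
    }
  })
  memb <- match(memb, unique(memb))  # renumber 1..m in order of appearance
  structure(list(method = "spectral",
                 membership = setNames(memb, nm), k = k),
            class = "prn_partition")
}

#' @export
print.prn_centrality <- function(x, ...) {
  cat(sprintf("prn_centrality (%s), %d nodes; range [%.4g, %.4g]\n",
              x$kind, length(x$values), min(x$values), max(x$values)))
  invisible(x)
}

#' @export
print.prn_partition <- function(x, ...) {
  cat(sprintf("prn_partition (%s): %d communities over %d nodes%s\n",
              x$method, length(unique(x$membership)), length(x$membership),
              if (!is.null(x$modularity))
                sprintf(", modularity %.4f", x$modularity) else ""))
  invisible(x)
}
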