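unit_graph <- function(edges, n = max(edges), names = NULL) {
  g <- igraph::make_empty_graph(n, directed = FALSE)
  igraph::V(g)$name <- if (is.null(names)) sprintf("n%d", seq_len(n)) else names
  g <- igraph::add_edges(g, t(edges))
  igraph::E(g)$weight <- 1
  igraph::E(g)$importance <- 1
  igraph::set_graph_attr(g, "kind", "dprn")
}

test_that("degree and betweenness match their textbook values", {
  star <- unit_graph(cbind(1, 2:4))
  expect_equal(unname(node_centrality(star, "degree")$values[1]), 1.0)
  path3 <- unit_graph(cbind(1:2, 2:3))
  expect_equal(unname(node_centrality(path3, "betweenness")$values),
               c(0, 1, 0))
  expect_error(node_centrality(igraph::make_empty_graph(0, directed = FALSE)),
               class = "prn_empty_graph_error")
})

test_that("closeness uses the component-scaled convention when disconnected", {
  # path a-b plus isolated c: C(a) = (1/2) * (1/1) = 0.5
  g <- unit_graph(cbind(1, 2), n = 3)
  cl <- node_centrality(g, "closeness")$values
  expect_equal(unname(cl), c(0.5, 0.5, 0))
})

test_that("betweenness matches exhaustive path enumeration on small graphs", {
  for (seed in 1:12) {
    g <- random_prn(sample(4:6, 1), seed = seed)
    expect_equal(node_centrality(g, "betweenness")$values,
                 bf_betweenness(g), tolerance = 1e-10)
  }
})

test_that("current-flow betweenness is sane on a path and a cycle", {
  # on a path every unit s-t current passes through the interior node
  path3 <- unit_graph(cbind(1:2, 2:3))
  cfb <- node_centrality(path3, "current_flow_betweenness")$values
  expect_equal(unname(cfb), c(0, 1, 0))
  # symmetric ring: all nodes equivalent
  ring <- unit_graph(cbind(1:4, c(2, 3, 4, 1)))
  cfb_r <- node_centrality(ring, "current_flow_betweenness")$values
  expect_equal(max(cfb_r) - min(cfb_r), 0, tolerance = 1e-10)
  # stronger conductance draws more flow: duplicate path with importance 3
  g <- unit_graph(rbind(c(1, 2), c(2, 4), c(1, 3), c(3, 4)))
  igraph::E(g)$importance <- c(3, 3, 1, 1)
  igraph::E(g)$weight <- 1 / igraph::E(g)$importance
  cfb_g <- node_centrality(g, "current_flow_betweenness")$values
  expect_gt(cfb_g["n2"], cfb_g["n3"])
})

test_that("total energy centrality sums incident edge energies", {
  g <- igraph::make_empty_graph(3, directed = FALSE)
  igraph::V(g)$name <- c("a", "b", "c")
  g <- igraph::add_edges(g, c(1, 2, 1, 3))
  igraph::E(g)$weight <- 1; igraph::E(g)$importance <- 1
  igraph::E(g)$e_tot <- c(-3.0, -2.5)
  vals <- total_energy_centrality(g)$values
  expect_equal(unname(vals), c(-5.5, -3.0, -2.5))
  # isolated node scores zero
  g4 <- igraph::add_vertices(g, 1, name = "d")
  expect_equal(unname(total_energy_centrality(g4)$values["d"]), 0)
  # handshake identity on random graphs
  for (seed in 1:5) {
    gr <- random_prn(7, seed = seed)
    expect_equal(sum(total_energy_centrality(gr)$values),
                 2 * sum(igraph::E(gr)$e_tot), tolerance = 1e-12)
  }
  # distance networks carry no energies
  gd <- unit_graph(cbind(1, 2))
  expect_error(total_energy_centrality(gd),
               class = "prn_unsupported_graph_error")
})

test_that("global and local efficiency follow the inverse-distance sums", {
  path3 <- unit_graph(cbind(1:2, 2:3))
  expect_equal(global_efficiency(path3), 5 / 6)
  k4 <- unit_graph(t(combn(4, 2)))
  expect_equal(global_efficiency(k4), 1)
  iso2 <- igraph::make_empty_graph(2, directed = FALSE)
  igraph::V(iso2)$name <- c("a", "b")
  expect_equal(global_efficiency(iso2), 0)
  expect_error(global_efficiency(igraph::make_empty_graph(1, directed = FALSE)),
               class = "prn_undefined_error")
  # local efficiency of the k4 hub: induced neighbour triangle
  expect_equal(local_efficiency(k4, "n1"), 1)
  expect_equal(local_efficiency(path3, "n1"), 0)
})

test_that("efficiency centrality equals the relative efficiency drop", {
  star <- unit_graph(cbind(1, 2:4))
  eff <- efficiency_centrality(star)$values
  expect_equal(unname(eff[1]), 1.0)          # removing the hub kills E_glob
  expect_equal(unname(eff[2]), -1 / 9, tolerance = 1e-12)
  for (seed in 1:8) {
    g <- random_prn(sample(5:8, 1), seed = seed + 40)
    e0 <- tryCatch(global_efficiency(g), prn_error = function(e) 0)
    if (e0 == 0) next
    expect_equal(efficiency_centrality(g)$values, bf_efficiency_centrality(g),
                 tolerance = 1e-10)
  }
  # every node of a complete unit-weight graph scores equally
  k5 <- unit_graph(t(combn(5, 2)))
  effs <- efficiency_centrality(k5)$values
  expect_equal(max(effs) - min(effs), 0, tolerance = 1e-12)
})

test_that("folding degree is rigid-motion invariant and ranks helix above strand", {
  s_h <- parse_pdb_text(backbone_pdb("helix"))
  s_s <- parse_pdb_text(backbone_pdb("strand"))
  fd_h <- folding_degree(s_h)
  fd_s <- folding_degree(s_s)
  expect_gt(mean(fd_h, na.rm = TRUE), mean(fd_s, na.rm = TRUE))

  # rotate + translate the helix rigidly: identical scores
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  s_r <- s_h
  xyz <- as.matrix(s_h$atoms[, c("x", "y", "z")]) %*% t(R)
  s_r$atoms$x <- xyz[, 1] + 11; s_r$atoms$y <- xyz[, 2] - 4
  s_r$atoms$z <- xyz[, 3] + 2.5
  expect_equal(folding_degree(s_r), fd_h, tolerance = 1e-9)

  # a chain of fewer than 4 backbone atoms cannot define a dihedral
  short <- parse_pdb_text(backbone_pdb("helix", n_res = 1))
  expect_error(folding_degree(short), class = "prn_undefined_error")
})

test_that("shortest paths prefer low total weight with lexicographic ties", {
  g <- igraph::make_empty_graph(3, directed = FALSE)
  igraph::V(g)$name <- c("a", "b", "c")
  g <- igraph::add_edges(g, c(1, 3, 1, 2, 2, 3))
  igraph::E(g)$weight <- c(1, 0.4, 0.4)
  igraph::E(g)$importance <- 1 / igraph::E(g)$weight
  sp <- shortest_path(g, "a", "c")
  expect_equal(sp$path, c("a", "b", "c"))
  expect_equal(sp$length, 0.8)

  disc <- igraph::make_empty_graph(2, directed = FALSE)
  igraph::V(disc)$name <- c("a", "b")
  expect_error(shortest_path(disc, "a", "b"), class = "prn_no_path_error")

  for (seed in 1:10) {
    gr <- random_prn(5, seed = seed + 7)
    nm <- igraph::V(gr)$name
    ref <- bf_all_min_paths(gr, 1, 5)
    if (!is.finite(ref$length)) {
      expect_error(shortest_path(gr, nm[1], nm[5]), class = "prn_no_path_error")
    } else {
      got <- shortest_path(gr, nm[1], nm[5])
      expect_equal(got$length, ref$length, tolerance = 1e-12)
      keys <- vapply(ref$paths, function(p) paste(nm[p], collapse = "\r"), "")
      expect_equal(paste(got$path, collapse = "\r"), sort(keys)[1])
    }
  }
})

test_that("Louvain recovers planted cliques and beats the trivial partition", {
  edge_less <- igraph::make_empty_graph(4, directed = FALSE)
  igraph::V(edge_less)$name <- letters[1:4]
  p0 <- louvain_communities(edge_less)
  expect_equal(length(unique(p0$membership)), 4L)

  # two 3-cliques joined by one bridge
  ed <- rbind(c(1, 2), c(1, 3), c(2, 3), c(4, 5), c(4, 6), c(5, 6), c(3, 4))
  g <- unit_graph(ed)
  part <- louvain_communities(g, seed = 42)
  expect_equal(length(unique(part$membership)), 2L)
  expect_equal(length(unique(part$membership[1:3])), 1L)
  expect_equal(length(unique(part$membership[4:6])), 1L)

  # brute-force modularity maximisation over all partitions of 6 nodes
  best <- -Inf
  for (pp in all_partitions(6))
    best <- max(best, igraph::modularity(g, pp, weights = igraph::E(g)$importance))
  expect_equal(part$modularity, best, tolerance = 1e-12)

  singleton_mod <- igraph::modularity(g, 1:6, weights = igraph::E(g)$importance)
  expect_gte(part$modularity, singleton_mod)
  # determinism
  expect_identical(louvain_communities(g, seed = 7)$membership,
                   louvain_communities(g, seed = 7)$membership)
})

test_that("spectral partitions split planted cliques and handle edge cases", {
  ed <- rbind(c(1, 2), c(1, 3), c(2, 3), c(4, 5), c(4, 6), c(5, 6), c(3, 4))
  g <- unit_graph(ed)
  expect_equal(unname(spectral_partition(g, 1)$membership), rep(1L, 6))
  expect_equal(unname(spectral_partition(g, 6)$membership), 1:6)
  expect_error(spectral_partition(g, 7), class = "prn_criteria_error")
  part <- spectral_partition(g, 2, seed = 3)
  expect_equal(length(unique(part$membership)), 2L)
  expect_equal(length(unique(part$membership[1:3])), 1L)
  expect_equal(length(unique(part$membership[4:6])), 1L)
})

test_that("centralities are permutation-equivariant", {
  g <- random_prn(7, seed = 99)
  perm <- sample(7)
  gp <- igraph::permute(g, perm)
  for (kind in c("degree", "closeness", "betweenness",
                 "current_flow_betweenness")) {
    v1 <- node_centrality(g, kind)$values
    v2 <- node_centrality(gp, kind)$values
    expect_equal(v2[names(v1)], v1, tolerance = 1e-10)
  }
  v1 <- total_energy_centrality(g)$values
  v2 <- total_energy_centrality(gp)$values
  expect_equal(v2[names(v1)], v1, tolerance = 1e-12)
})
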