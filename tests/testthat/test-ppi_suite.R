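three_node_split <- function() {
  g <- igraph::make_empty_graph(3, directed = FALSE)
  igraph::V(g)$name <- c("A1", "A2", "B1")
  g <- igraph::add_edges(g, c(1, 2, 2, 3))
  igraph::E(g)$weight <- 1; igraph::E(g)$importance <- 1
  igraph::E(g)$e_tot <- c(-2, -3)
  split_supersystem(g, c(A1 = "A", A2 = "A", B1 = "B"))
}

test_that("NDA is identically zero when the interface is empty", {
  g <- igraph::make_empty_graph(4, directed = FALSE)
  igraph::V(g)$name <- c("A1", "A2", "B1", "B2")
  g <- igraph::add_edges(g, c(1, 2, 3, 4))
  igraph::E(g)$weight <- c(0.5, 2); igraph::E(g)$importance <- c(2, 0.5)
  igraph::E(g)$e_tot <- c(-2, -0.5)
  sp <- split_supersystem(g, c(A1 = "A", A2 = "A", B1 = "B", B2 = "B"))
  for (kind in c("degree", "closeness", "betweenness", "etot"))
    expect_equal(unname(nda(sp, kind)$delta), rep(0, 4))
})

test_that("degree NDA matches the hand-computed three-node example", {
  sp <- three_node_split()
  d <- nda(sp, "degree")$delta
  expect_equal(unname(d[c("A1", "A2", "B1")]), c(0, 0.5, 0.5))
})

test_that("etot NDA equals each node's summed cross-monomer energies", {
  for (seed in 1:10) {
    pl <- toy_pipeline(sample(3:5, 1), sample(4:7, 1), seed = seed,
                       noise_sd = 0.5)
    delta <- nda(pl$split, "etot")$delta
    tab <- edge_table(pl$split$g)
    memb <- setNames(igraph::V(pl$split$g)$monomer,
                     igraph::V(pl$split$g)$name)
    expected <- setNames(rep(0, length(delta)), names(delta))
    cross <- tab[memb[tab$node_a] != memb[tab$node_b], ]
    for (r in seq_len(nrow(cross))) {
      expected[cross$node_a[r]] <- expected[cross$node_a[r]] + cross$e_tot[r]
      expected[cross$node_b[r]] <- expected[cross$node_b[r]] + cross$e_tot[r]
    }
    expect_equal(delta, expected, tolerance = 1e-12)
  }
})

test_that("the monomer baseline is flagged as size-inconsistent", {
  sp <- three_node_split()
  expect_warning(res <- nda(sp, "degree", baseline = "monomer"),
                 "different size")
  expect_equal(res$baseline, "monomer")
})

test_that("interface matrices have block shape and obey the sign filter", {
  sp <- three_node_split()
  m <- ppi_matrix(sp, mode = "block")
  expect_equal(dim(m$entries), c(1L, 1L))  # one A-side, one B-side interface node
  expect_equal(unname(m$entries[1, 1]), -3)

  # mixed-sign interface
  g <- igraph::make_empty_graph(3, directed = FALSE)
  igraph::V(g)$name <- c("A1", "A2", "B1")
  g <- igraph::add_edges(g, c(1, 3, 2, 3))
  igraph::E(g)$weight <- 1; igraph::E(g)$importance <- 1
  igraph::E(g)$e_tot <- c(-2, 1)
  sp2 <- split_supersystem(g, c(A1 = "A", A2 = "A", B1 = "B"))
  ma <- ppi_matrix(sp2, mode = "block", sign_filter = "attractive")
  expect_equal(sort(as.numeric(ma$entries)), c(-2, 0))
  mr <- ppi_matrix(sp2, mode = "block", sign_filter = "repulsive")
  expect_equal(sort(as.numeric(mr$entries)), c(0, 1))

  mf <- ppi_matrix(sp2, mode = "full")
  expect_equal(dim(mf$entries), c(3L, 3L))
  expect_equal(mf$entries, t(mf$entries))
  expect_equal(unname(diag(mf$entries)), rep(0, 3))
  expect_equal(unname(mf$entries["A1", "A2"]), 0)  # no within-monomer entries
  mb <- ppi_matrix(sp2, mode = "block")
  expect_equal(unname(mf$entries[mb$row_index, mb$col_index, drop = FALSE]),
               unname(mb$entries))

  g0 <- igraph::make_empty_graph(2, directed = FALSE)
  igraph::V(g0)$name <- c("A1", "B1")
  sp0 <- split_supersystem(g0, c(A1 = "A", B1 = "B"))
  expect_error(ppi_matrix(sp0), class = "prn_empty_interface_error")
})

test_that("the SVD worked example and the f-series closure hold", {
  m <- make_matrix_fixture(rbind(c(3, 0), c(0, 4)))
  sv <- svd_motifs(m)
  expect_equal(sv$sigma, c(4, 3))
  expect_equal(sv$f_series[1], 4 / 7, tolerance = 1e-12)
  expect_equal(sv$f_series[2], 1, tolerance = 1e-12)

  set.seed(5)
  for (rep in 1:5) {
    M <- matrix(rnorm(35), 5, 7)
    sv <- svd_motifs(make_matrix_fixture(M))
    expect_equal(sv$f_series[sv$k], 1, tolerance = 1e-12)
    expect_true(all(diff(sv$f_series) >= -1e-15))
    expect_true(all(diff(sv$sigma) <= 1e-12))
    # orthonormality of singular vector families
    expect_equal(crossprod(sv$u), diag(sv$k), tolerance = 1e-10)
    expect_equal(crossprod(sv$v), diag(sv$k), tolerance = 1e-10)
  }
  expect_error(svd_motifs(make_matrix_fixture(matrix(0, 2, 2))),
               class = "prn_empty_interface_error")
})

test_that("rank-r reconstructions satisfy the Eckart-Young identity", {
  set.seed(17)
  for (rep in 1:5) {
    M <- matrix(rnorm(35), 5, 7)
    sv <- svd_motifs(make_matrix_fixture(M))
    expect_equal(unname(reconstruct_rank_r(sv, sv$k)), M, tolerance = 1e-10)
    for (r in 1:(sv$k - 1)) {
      err <- norm(M - reconstruct_rank_r(sv, r), "F")
      expect_equal(err, sqrt(sum(sv$sigma[(r + 1):sv$k]^2)), tolerance = 1e-10)
    }
  }
  # rank-1 matrices are recovered exactly at r = 1
  M1 <- outer(c(1, 2, 3), c(2, -1))
  sv1 <- svd_motifs(make_matrix_fixture(M1))
  expect_equal(unname(reconstruct_rank_r(sv1, 1)), M1, tolerance = 1e-12)
  # independent oracle: eigen-decomposition of M^T M gives the same rank-2
  M <- matrix(rnorm(16), 4, 4)
  sv <- svd_motifs(make_matrix_fixture(M))
  ev <- eigen(crossprod(M), symmetric = TRUE)
  V2 <- ev$vectors[, 1:2]
  oracle <- M %*% V2 %*% t(V2)  # projection onto the top-2 right space
  expect_equal(unname(reconstruct_rank_r(sv, 2)), oracle, tolerance = 1e-9)
  expect_error(reconstruct_rank_r(sv, 9), class = "prn_criteria_error")
})

test_that("dominant motif nodes respect the alpha threshold", {
  M <- diag(c(5, 1, 0.5))
  sv <- svd_motifs(make_matrix_fixture(M))
  m <- make_matrix_fixture(M)
  d1 <- dominant_motif_nodes(sv, m, 1, side = "A", alpha = 0.5)
  expect_equal(d1$node, "a1")

  # components (1, .6, .4): threshold 0.5 keeps the first two
  M2 <- outer(c(1, 0.6, 0.4), c(1, 0.2))
  sv2 <- svd_motifs(make_matrix_fixture(M2))
  m2 <- make_matrix_fixture(M2)
  d2 <- dominant_motif_nodes(sv2, m2, 1, side = "A", alpha = 0.5)
  expect_equal(d2$node, c("a1", "a2"))
  expect_error(dominant_motif_nodes(sv2, m2, 1, alpha = 0),
               class = "prn_criteria_error")
})

test_that("the strongest interface pair dominates the first motif", {
  pl <- toy_pipeline(4, 6, seed = 13)
  # make one planted pair overwhelmingly strong
  pie <- pl$tp$pie
  cross <- which(pie$labels[pie$pairs$i] %in%
                   igraph::V(pl$split$g_ppi)$name &
                 pie$labels[pie$pairs$j] %in%
                   igraph::V(pl$split$g_ppi)$name &
                 pie$pairs$e_tot <= -1)
  boost <- cross[1]
  pie$pairs$e_tot[boost] <- -40
  g <- build_pieprn(pie, build_criteria(e_lim = -1), structure = pl$s)
  sp <- split_supersystem(g, pl$tc$membership)
  m <- ppi_matrix(sp, sign_filter = "attractive")
  sv <- svd_motifs(m)
  d <- dominant_motif_nodes(sv, m, 1, side = "A")
  expect_equal(d$node[1], pie$labels[pie$pairs$i[boost]])
})

test_that("SPIE tables list raw cross pairs with sign labels", {
  pl <- toy_pipeline(4, 6, seed = 23)
  tab <- spie_data(pl$split, pl$tp$pie)
  # all cross pairs of the raw table appear, including the repulsive one
  memb <- pl$tc$membership
  raw_cross <- sum(memb[pl$tp$pie$labels[pl$tp$pie$pairs$i]] !=
                     memb[pl$tp$pie$labels[pl$tp$pie$pairs$j]])
  expect_equal(nrow(tab), raw_cross)
  expect_true(any(tab$sign == "repulsive"))
  expect_true(all(tab$sign[tab$energy < 0] == "attractive"))
  expect_true(all(substr(tab$node_a, 1, 1) == "A"))
  # magnitude filter
  tab2 <- spie_data(pl$split, pl$tp$pie, min_abs = 1)
  expect_equal(nrow(tab2), sum(abs(tab$energy) >= 1))
  expect_error(spie_data(pl$split, pl$tp$pie, term = "solv"),
               class = "prn_criteria_error")
})

test_that("binding energies assign and conserve the total cross energy", {
  pie <- pie_table(c("a1", "a2", "b1"),
                   data.frame(i = c(1L, 2L, 1L), j = c(3L, 3L, 2L),
                              e_tot = c(-4, -1, -9)))
  memb <- c(a1 = "A", a2 = "A", b1 = "B")
  asym <- binding_energies(pie, memb, mode = "asymmetric_A")
  expect_equal(unname(asym$contributions["a1"]), -4)
  expect_equal(unname(asym$contributions["b1"]), 0)
  expect_equal(sum(asym$contributions), -5)

  sym <- binding_energies(pie, memb, mode = "symmetric")
  expect_equal(unname(sym$contributions["b1"]), -2.5)
  expect_equal(sum(sym$contributions), -5)

  asym_b <- binding_energies(pie, memb, mode = "asymmetric_B")
  expect_equal(unname(asym_b$contributions["b1"]), -5)

  # conservation on random tables (intra-chain pairs never contribute)
  for (seed in 1:6) {
    pl <- toy_pipeline(3, 5, seed = seed, noise_sd = 1)
    m2 <- pl$tc$membership
    cross_tot <- sum(pl$tp$pie$pairs$e_tot[
      m2[pl$tp$pie$labels[pl$tp$pie$pairs$i]] !=
        m2[pl$tp$pie$labels[pl$tp$pie$pairs$j]]])
    for (mode in c("symmetric", "asymmetric_A", "asymmetric_B"))
      expect_equal(sum(binding_energies(pl$tp$pie, m2, mode)$contributions),
                   cross_tot, tolerance = 1e-12)
  }

  # no cross pairs: zero result with a warning
  pie0 <- pie_table(c("a1", "a2"), data.frame(i = 1L, j = 2L, e_tot = -2))
  expect_warning(b0 <- binding_energies(pie0, c(a1 = "A", a2 = "A")))
  expect_equal(sum(b0$contributions), 0)
})
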