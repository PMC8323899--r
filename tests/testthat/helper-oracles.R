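# Independent brute-force oracles and small fixture builders used across
# the suite. Oracles deliberately avoid the package's own code paths.

# mass-weighted mean coordinate by direct summation
bf_com <- function(masses, coords) {
  colSums(coords * masses) / sum(masses)
}

# write a prn fixture's PDB text to a temp file and parse it
parse_toy <- function(tc, ...) {
  f <- tempfile(fileext = ".pdb")
  writeLines(tc$pdb_text, f)
  parse_pdb(f, ...)
}

# small random weighted graph; weights on a 0.25 grid so path-length ties
# are exact in floating point
random_prn <- function(n, seed, p = 0.5, energies = TRUE) {
  set.seed(seed)
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- sprintf("n%02d", seq_len(n))
  m <- igraph::ecount(g)
  if (m) {
    w <- sample(seq(0.25, 2, by = 0.25), m, replace = TRUE)
    igraph::E(g)$weight <- w
    igraph::E(g)$importance <- 1 / w
    if (energies) igraph::E(g)$e_tot <- -sample(seq(0.5, 4, by = 0.5), m,
                                                replace = TRUE)
  }
  igraph::set_graph_attr(g, "kind", "pieprn_fmo")
}

# enumerate all simple paths s -> t; return min total weight and the
# minimising node-index sequences
bf_all_min_paths <- function(g, s, t) {
  n <- igraph::vcount(g)
  adj <- lapply(seq_len(n), function(v) {
    nb <- as.integer(igraph::neighbors(g, v))
    w <- vapply(nb, function(u)
      igraph::E(g)$weight[igraph::get_edge_ids(g, c(v, u))], numeric(1))
    list(nb = nb, w = w)
  })
  best <- Inf
  paths <- list()
  rec <- function(v, visited, len, trail) {
    if (v == t) {
      if (len < best) { best <<- len; paths <<- list(trail) }
      else if (len == best) paths[[length(paths) + 1L]] <<- trail
      return()
    }
    a <- adj[[v]]
    for (k in seq_along(a$nb)) {
      u <- a$nb[k]
      if (!visited[u]) {
        visited[u] <- TRUE
        rec(u, visited, len + a$w[k], c(trail, u))
        visited[u] <- FALSE
      }
    }
  }
  visited <- rep(FALSE, n)
  visited[s] <- TRUE
  rec(s, visited, 0, s)
  list(length = best, paths = paths)
}

# normalized weighted betweenness by exhaustive shortest-path enumeration
bf_betweenness <- function(g) {
  n <- igraph::vcount(g)
  score <- rep(0, n)
  if (n >= 3) {
    for (s in 1:(n - 1)) for (t in (s + 1):n) {
      r <- bf_all_min_paths(g, s, t)
      if (!is.finite(r$length)) next
      npaths <- length(r$paths)
      for (p in r$paths) {
        inner <- setdiff(p, c(s, t))
        score[inner] <- score[inner] + 1 / npaths
      }
    }
    score <- score / ((n - 1) * (n - 2) / 2)
  }
  stats::setNames(score, igraph::V(g)$name)
}

bf_global_efficiency <- function(g) {
  n <- igraph::vcount(g)
  tot <- 0
  for (s in 1:(n - 1)) for (t in (s + 1):n) {
    r <- bf_all_min_paths(g, s, t)
    if (is.finite(r$length)) tot <- tot + 2 / r$length
  }
  tot / (n * (n - 1))
}

bf_efficiency_centrality <- function(g) {
  e0 <- bf_global_efficiency(g)
  n <- igraph::vcount(g)
  vals <- vapply(seq_len(n), function(v) {
    (e0 - bf_global_efficiency(igraph::delete_vertices(g, v))) / e0
  }, numeric(1))
  stats::setNames(vals, igraph::V(g)$name)
}

# Independent force-field energy from a make_toy_topology manifest:
# double loop over atom pairs, exclusions from adjacency-matrix powers.
bf_ff_energies <- function(manifest, scee = 1.2, scnb = 2.0) {
  at <- manifest$atoms
  natom <- nrow(at)
  A1 <- matrix(0, natom, natom)
  A1[manifest$bonds] <- 1
  A1 <- A1 + t(A1)
  A2 <- (A1 %*% A1 > 0) & !diag(natom) & !(A1 > 0)
  A3 <- (A1 %*% A1 %*% A1 > 0) & !diag(natom) & !(A1 > 0) & !A2
  nres <- manifest$n_res
  elec <- matrix(0, nres, nres)
  vdw <- matrix(0, nres, nres)
  for (a in 1:(natom - 1)) for (b in (a + 1):natom) {
    if (at$res[a] == at$res[b]) next
    if (A1[a, b] > 0 || A2[a, b]) next
    r <- sqrt((at$x[a] - at$x[b])^2 + (at$y[a] - at$y[b])^2 +
                (at$z[a] - at$z[b])^2)
    ee <- 332.0636 * at$q[a] * at$q[b] / r
    e_ab <- sqrt(manifest$eps[at$type[a]] * manifest$eps[at$type[b]])
    rs <- manifest$rstar[at$type[a]] + manifest$rstar[at$type[b]]
    vv <- e_ab * (rs / r)^12 - 2 * e_ab * (rs / r)^6
    if (A3[a, b]) { ee <- ee / scee; vv <- vv / scnb }
    i <- min(at$res[a], at$res[b]); j <- max(at$res[a], at$res[b])
    elec[i, j] <- elec[i, j] + ee
    vdw[i, j] <- vdw[i, j] + vv
  }
  list(elec = elec, vdw = vdw)
}

# minimal hand-built prmtop + pdb for point-charge / single-LJ scenarios
two_atom_system <- function(q1, q2, r, eps = 0, rstar = 1) {
  fmtE <- function(v) paste(sprintf("%16.8E", v), collapse = "")
  fmtI <- function(v) paste(sprintf("%8d", v), collapse = "")
  pointers <- integer(31); pointers[1] <- 2L; pointers[2] <- 1L
  pointers[12] <- 2L
  A <- eps * (2 * rstar)^12
  B <- 2 * eps * (2 * rstar)^6
  prmtop <- c(
    "%VERSION  VERSION_STAMP = V0001.000",
    "%FLAG POINTERS", "%FORMAT(10I8)",
    fmtI(pointers[1:10]), fmtI(pointers[11:20]), fmtI(pointers[21:31]),
    "%FLAG CHARGE", "%FORMAT(5E16.8)", fmtE(c(q1, q2) * 18.2223),
    "%FLAG ATOM_TYPE_INDEX", "%FORMAT(10I8)", fmtI(c(1L, 1L)),
    "%FLAG NONBONDED_PARM_INDEX", "%FORMAT(10I8)", fmtI(1L),
    "%FLAG RESIDUE_LABEL", "%FORMAT(20a4)", "X1  X2",
    "%FLAG RESIDUE_POINTER", "%FORMAT(10I8)", fmtI(c(1L, 2L)),
    "%FLAG LENNARD_JONES_ACOEF", "%FORMAT(5E16.8)", fmtE(A),
    "%FLAG LENNARD_JONES_BCOEF", "%FORMAT(5E16.8)", fmtE(B),
    "%FLAG BONDS_INC_HYDROGEN", "%FORMAT(10I8)",
    "%FLAG BONDS_WITHOUT_HYDROGEN", "%FORMAT(10I8)"
  )
  pdb <- c(
    sprintf("ATOM  %5d  %-3s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            1L, "C1", "X1", "A", 1L, 0, 0, 0, 1, 0, "C"),
    sprintf("ATOM  %5d  %-3s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            2L, "C1", "X2", "A", 2L, r, 0, 0, 1, 0, "C"),
    "END")
  ft <- tempfile(fileext = ".prmtop"); fp <- tempfile(fileext = ".pdb")
  writeLines(prmtop, ft); writeLines(pdb, fp)
  list(prmtop = ft, pdb = fp)
}

# backbone fixtures for the folding degree: a smooth helical curve and a
# planar zigzag (all-trans) strand, as raw PDB text
backbone_pdb <- function(kind = c("helix", "strand"), n_res = 8) {
  kind <- match.arg(kind)
  lines <- character(0)
  serial <- 0L
  nm <- c("N", "CA", "C"); el <- c("N", "C", "C")
  for (r in seq_len(n_res)) {
    for (a in 1:3) {
      t <- (3 * (r - 1) + a - 1)
      if (kind == "helix") {
        ang <- 0.6 * t
        xyz <- c(2.3 * cos(ang), 2.3 * sin(ang), 0.5 * t)
      } else {
        xyz <- c(1.2 * t, 0.5 * (t %% 2), 0)
      }
      serial <- serial + 1L
      lines <- c(lines, sprintf(
        "ATOM  %5d  %-3s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial, nm[a], "GLY", "A", r, xyz[1], xyz[2], xyz[3], 1, 0, el[a]))
    }
  }
  c(lines, "END")
}

parse_pdb_text <- function(lines, ...) {
  f <- tempfile(fileext = ".pdb")
  writeLines(lines, f)
  parse_pdb(f, ...)
}

# all set partitions of 1..n (restricted growth strings), for brute-force
# modularity maximisation on tiny graphs
all_partitions <- function(n) {
  out <- list()
  rec <- function(assign, kmax) {
    i <- length(assign) + 1L
    if (i > n) { out[[length(out) + 1L]] <<- assign; return() }
    for (c in seq_len(kmax + 1L)) rec(c(assign, c), max(kmax, c))
  }
  rec(integer(0), 0L)
  out
}

# wrap a bare matrix as an interface-matrix object for SVD tests
make_matrix_fixture <- function(M) {
  structure(list(entries = M,
                 row_index = sprintf("a%d", seq_len(nrow(M))),
                 col_index = sprintf("b%d", seq_len(ncol(M))),
                 mode = "block", term = "e_tot", sign_filter = "both"),
            class = "prn_ppi_matrix")
}

# complete toy pipeline: complex + pie + graph + split (shared by several
# files); returns list(s, tc, tp, g, split)
toy_pipeline <- function(n_a = 4, n_b = 6, seed = 1, e_lim = -1,
                         noise_sd = 0) {
  tc <- make_toy_complex(n_a, n_b, seed = seed)
  s <- parse_toy(tc)
  tp <- make_toy_pie_table(tc$manifest, noise_sd = noise_sd, seed = seed + 100)
  g <- build_pieprn(tp$pie, build_criteria(e_lim = e_lim), structure = s)
  split <- split_supersystem(g, tc$membership)
  list(s = s, tc = tc, tp = tp, g = g, split = split)
}
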