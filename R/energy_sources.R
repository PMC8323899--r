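# Pair interaction energy (PIE) tables: from Gamess FMO output or from
# force-field parameters in an Amber topology. All energies in kcal/mol.

HARTREE_TO_KCAL <- 627.5095
COULOMB_K <- 332.0636       # kcal A mol^-1 e^-2
AMBER_CHARGE_SCALE <- 18.2223  # prmtop charges are q[e] * 18.2223
SCEE_DEFAULT <- 1.2         # 1-4 electrostatic divisor
SCNB_DEFAULT <- 2.0         # 1-4 van der Waals divisor

.pie_component_names <- c("e_tot", "es", "ex", "ct", "di", "solv",
                          "elec_ff", "vdw_ff")

#' Construct a pair interaction energy table
#'
#' A `pie_table` stores symmetric residue/fragment pair energies, one row
#' per unordered pair (i < j), in kcal/mol.  `e_tot` is always present;
#' PIEDA components (es, ex, ct, di, solv) or force-field components
#' (elec_ff, vdw_ff) are present when the source provides them.
#'
#' @param labels Character vector of node (fragment/residue) labels.
#' @param pairs Data frame with integer columns `i`, `j` (1-based indices
#'   into `labels`, i < j), a numeric `e_tot`, and optionally the other
#'   component columns.
#' @param source `"fmo"` or `"forcefield"`.
#' @return A `pie_table`.
#' @export
pie_table <- function(labels, pairs, source = c("fmo", "forcefield")) {
  source <- match.arg(source)
  stopifnot(is.character(labels), is.data.frame(pairs),
            all(c("i", "j", "e_tot") %in% names(pairs)))
  if (nrow(pairs)) {
    stopifnot(all(pairs$i >= 1), all(pairs$j <= length(labels)))
    if (any(pairs$i == pairs$j)) stop("self-pairs are not allowed")
    swap <- pairs$i > pairs$j
    if (any(swap)) { tmp <- pairs$i[swap]; pairs$i[swap] <- pairs$j[swap]; pairs$j[swap] <- tmp }
    key <- paste(pairs$i, pairs$j)
    if (anyDuplicated(key)) {
      first <- pairs[!duplicated(key), , drop = FALSE]
      same <- TRUE
      for (k in which(duplicated(key))) {
        ref <- first[match(key[k], paste(first$i, first$j)), ]
        if (!isTRUE(all.equal(unlist(ref[-(1:2)]), unlist(pairs[k, -(1:2)]),
                              tolerance = 1e-9, check.attributes = FALSE)))
          same <- FALSE
      }
      if (!same)
        prn_stop("duplicate conflicting pair entries", "prn_ambiguity_error")
      pairs <- first
    }
    pairs <- pairs[order(pairs$i, pairs$j), , drop = FALSE]
    rownames(pairs) <- NULL
  }
  structure(list(labels = labels, pairs = pairs, source = source,
                 units = "kcal/mol"),
            class = "pie_table")
}

#' @export
print.pie_table <- function(x, ...) {
  comp <- intersect(.pie_component_names, names(x$pairs))
  cat(sprintf("pie_table (%s): %d nodes, %d pairs, components: %s\n",
              x$source, length(x$labels), nrow(x$pairs),
              paste(comp, collapse = ", ")))
  invisible(x)
}

#' Look up the components of one pair
#'
#' Symmetric access: `pie_components(p, a, b)` and `pie_components(p, b, a)`
#' return the same row.  Nodes may be given as labels or indices.
#'
#' @param pie A `pie_table`.
#' @param a,b Node labels or 1-based indices.
#' @return One-row data frame of components, or `NULL` when the pair is not
#'   listed.
#' @export
pie_components <- function(pie, a, b) {
  stopifnot(inherits(pie, "pie_table"))
  ia <- if (is.character(a)) match(a, pie$labels) else as.integer(a)
  ib <- if (is.character(b)) match(b, pie$labels) else as.integer(b)
  if (is.na(ia) || is.na(ib)) prn_stop("unknown node label", "prn_io_error")
  i <- min(ia, ib); j <- max(ia, ib)
  row <- pie$pairs[pie$pairs$i == i & pie$pairs$j == j, , drop = FALSE]
  if (!nrow(row)) return(NULL)
  row
}

# ---------------------------------------------------------------------------
# Gamess FMO output

#' Parse pair interaction energies from a Gamess FMO output
#'
#' Locates the two-body pair-interaction (IFIE/PIEDA) table with a tolerant
#' match on the section header, so minor version drift in the log format
#' does not break parsing.  Energies are converted from Hartree to kcal/mol
#' (factor 627.5095) when the section is tagged as atomic units; tables
#' already printed in kcal/mol are taken verbatim.  PIEDA columns
#' (electrostatic, exchange repulsion, charge transfer + mix, dispersion,
#' optional solvation screening) are captured when present.  Outputs of
#' other FMO codes (Abinit-MP, PAICS) are not supported.
#'
#' Fragment names are read from optional `FRAGMENT <index> <name>` lines;
#' otherwise fragments are labelled `frag<index>`.  For amino-acid
#' fragments the FMO fragmentation shifts the backbone C,O atoms to the
#' neighbouring residue, so fragments are not exactly PDB residues; the
#' returned fragment map carries an `offset_note` flag recording this.
#'
#' @param path Path to the FMO log text.
#' @return List with elements `pie` (a [pie_table()]) and `fragment_map`
#'   (data frame: fragment `index`, `label`; attribute `offset_note`).
#' @export
parse_gamess_fmo <- function(path) {
  if (!file.exists(path)) prn_stop(paste0("file not found: ", path), "prn_io_error")
  lines <- readLines(path, warn = FALSE)

  hdr_rx <- "(?i)(two-?body)|(pair[- ]interaction energ)|(PIEDA)|(IFIE)"
  hdr <- grep(hdr_rx, lines, perl = TRUE)
  if (!length(hdr))
    prn_stop("no two-body pair-interaction section found: not an FMO output",
             "prn_not_fmo_error")

  # unit tag: look at the header line and its close neighbourhood
  start <- hdr[1L]
  ctx <- lines[start:min(length(lines), start + 3L)]
  in_au <- any(grepl("(?i)hartree|atomic units|a\\.u\\.", ctx, perl = TRUE)) &&
    !any(grepl("(?i)kcal", ctx, perl = TRUE))

  # data rows: first two tokens integers, remaining tokens numeric
  rows <- list()
  for (ln in lines[(start + 1L):length(lines)]) {
    if (grepl("^\\s*$", ln)) { if (length(rows)) break else next }
    toks <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(toks) < 3) { if (length(rows)) break else next }
    vals <- suppressWarnings(as.numeric(toks))
    ints <- suppressWarnings(as.integer(toks[1:2]))
    if (anyNA(ints) || anyNA(vals)) { if (length(rows)) break else next }
    rows[[length(rows) + 1L]] <- vals
  }
  if (!length(rows))
    prn_stop("pair-interaction section contains no data rows: not an FMO output",
             "prn_not_fmo_error")

  ncols <- vapply(rows, length, 1L)
  if (length(unique(ncols)) != 1L)
    prn_stop("ragged pair-interaction table", "prn_not_fmo_error")
  tab <- do.call(rbind, rows)
  nc <- ncol(tab)
  # canonical layouts:
  #   I J DL Z R Q(I->J) dE dD*V total                      -> 9 columns
  #   ... + Ees Eex Ect+mix Edisp                           -> 13
  #   ... + Gsol                                            -> 14
  # minimal pseudo-tables "I J E" (3 columns) also accepted
  if (!nc %in% c(3L, 9L, 13L, 14L))
    prn_stop(sprintf("unrecognised pair table width (%d columns)", nc),
             "prn_not_fmo_error")
  i <- as.integer(tab[, 1]); j <- as.integer(tab[, 2])
  conv <- if (in_au) HARTREE_TO_KCAL else 1
  pairs <- data.frame(i = i, j = j)
  if (nc == 3L) {
    pairs$e_tot <- tab[, 3] * conv
  } else {
    pairs$e_tot <- tab[, 9] * conv
    pairs$r_frag <- tab[, 5]
    if (nc >= 13L) {
      pairs$es <- tab[, 10] * conv
      pairs$ex <- tab[, 11] * conv
      pairs$ct <- tab[, 12] * conv
      pairs$di <- tab[, 13] * conv
      if (nc == 14L) pairs$solv <- tab[, 14] * conv
    }
  }

  nfrag <- max(pairs$i, pairs$j)
  labels <- paste0("frag", seq_len(nfrag))
  frag_lines <- regmatches(lines,
    regexec("^\\s*FRAGMENT\\s+(\\d+)\\s+(\\S+)", lines, perl = TRUE))
  for (m in frag_lines) {
    if (length(m) == 3) {
      k <- as.integer(m[2])
      if (k >= 1 && k <= nfrag) labels[k] <- m[3]
    }
  }
  pie <- pie_table(labels, pairs, source = "fmo")
  fmap <- data.frame(index = seq_len(nfrag), label = labels,
                     stringsAsFactors = FALSE)
  attr(fmap, "offset_note") <- TRUE  # backbone C,O shifted to neighbour
  list(pie = pie, fragment_map = fmap)
}

#' Map FMO fragments onto structure residues
#'
#' FMO fragments of a polypeptide are not exactly PDB residues (backbone
#' C,O atoms are assigned to the neighbouring fragment), but a one-to-one
#' correspondence by position or by residue number is usually available;
#' covalently unbound fragments (ligands) map one-to-one naturally.
#'
#' @param fragment_map Fragment map from [parse_gamess_fmo()].
#' @param structure A `prn_structure`.
#' @param mode `"by_index"` (fragment k is the k-th residue) or
#'   `"by_number"` (a trailing integer in the fragment name, e.g. `ALA12`,
#'   is matched against residue numbers).
#' @return Data frame (fragment `index`, `label`, `residue` node label);
#'   attribute `offset_note` is carried over.
#' @export
map_fragments_to_residues <- function(fragment_map, structure,
                                      mode = c("by_index", "by_number")) {
  mode <- match.arg(mode)
  stopifnot(inherits(structure, "prn_structure"))
  res <- structure$residues
  nfrag <- nrow(fragment_map)
  if (mode == "by_index") {
    if (nfrag > nrow(res))
      prn_stop(sprintf("cannot map %d fragments onto %d residues",
                       nfrag, nrow(res)), "prn_mapping_error")
    residue <- res$label[fragment_map$index]
  } else {
    nums <- suppressWarnings(as.integer(sub("^.*?(\\d+)$", "\\1",
                                            fragment_map$label)))
    residue <- character(nfrag)
    for (k in seq_len(nfrag)) {
      if (is.na(nums[k]))
        prn_stop(paste0("fragment not mappable by number: ",
                        fragment_map$label[k]), "prn_mapping_error")
      hit <- which(res$resno == nums[k])
      if (length(hit) != 1L)
        prn_stop(sprintf("fragment %s: residue number %d matches %d residues",
                         fragment_map$label[k], nums[k], length(hit)),
                 "prn_mapping_error")
      residue[k] <- res$label[hit]
    }
  }
  if (anyDuplicated(residue))
    prn_stop("fragment-to-residue mapping is not injective", "prn_mapping_error")
  out <- data.frame(index = fragment_map$index, label = fragment_map$label,
                    residue = residue, stringsAsFactors = FALSE)
  attr(out, "offset_note") <- isTRUE(attr(fragment_map, "offset_note"))
  out
}

# ---------------------------------------------------------------------------
# Force-field pair energies from an Amber topology

# Parse the %FLAG sections of an Amber prmtop into a named list.
read_prmtop <- function(path) {
  lines <- readLines(path, warn = FALSE)
  flag_idx <- grep("^%FLAG", lines)
  if (!length(flag_idx)) prn_stop("not an Amber prmtop (no %FLAG sections)",
                                  "prn_topology_error")
  flag_idx <- c(flag_idx, length(lines) + 1L)
  out <- list()
  for (k in seq_len(length(flag_idx) - 1L)) {
    i0 <- flag_idx[k]
    name <- trimws(sub("^%FLAG\\s+", "", lines[i0]))
    body <- lines[(i0 + 1L):(flag_idx[k + 1L] - 1L)]
    fmt <- body[grepl("^%FORMAT", body)]
    body <- body[!grepl("^%", body)]
    spec <- if (length(fmt))
      regmatches(fmt[1], regexec("\\((\\d+)([aAiIeEfF])(\\d+)", fmt[1]))[[1]]
    else character(0)
    if (length(spec) == 4 && tolower(spec[3]) == "a") {
      w <- as.integer(spec[4])
      vals <- unlist(lapply(body, function(ln) {
        n <- nchar(ln)
        if (!n) return(character(0))
        starts <- seq(1, n, by = w)
        trimws(substring(ln, starts, pmin(starts + w - 1L, n)))
      }))
      out[[name]] <- vals[vals != ""]
    } else {
      toks <- unlist(strsplit(trimws(body[body != ""]), "\\s+"))
      out[[name]] <- suppressWarnings(as.numeric(toks[toks != ""]))
    }
  }
  out
}

#' Force-field pair interaction energies from an Amber topology
#'
#' Evaluates, for every residue pair of the static structure, the
#' electrostatic energy \eqn{\sum k_e q_a q_b / r_{ab}} (with
#' \eqn{k_e = 332.0636} kcal A/mol/e^2, charges in electron units) and the
#' Lennard-Jones 12-6 energy from the topology's A/B coefficients, summed
#' over inter-residue atom pairs.  Bonded 1-2 and 1-3 atom pairs are
#' excluded and 1-4 pairs are scaled by 1/`scee` (electrostatic) and
#' 1/`scnb` (van der Waals), the Amber defaults being 1.2 and 2.0; the
#' bonded distance of an atom pair is its distance in the bond graph.  No
#' cutoff and no periodicity are applied: the sums are taken over the
#' structure exactly as given.
#'
#' @param structure A `prn_structure`; atom count and order must match the
#'   topology.
#' @param topology Path to an Amber prmtop file.
#' @param scee,scnb 1-4 scaling divisors.
#' @return A [pie_table()] with components `elec_ff`, `vdw_ff` and
#'   `e_tot = elec_ff + vdw_ff`, one row per residue pair with nonzero
#'   interaction.
#' @export
compute_ff_pies <- function(structure, topology,
                            scee = SCEE_DEFAULT, scnb = SCNB_DEFAULT) {
  stopifnot(inherits(structure, "prn_structure"))
  top <- read_prmtop(topology)
  need <- c("POINTERS", "CHARGE", "ATOM_TYPE_INDEX", "NONBONDED_PARM_INDEX",
            "LENNARD_JONES_ACOEF", "LENNARD_JONES_BCOEF", "RESIDUE_POINTER")
  miss <- setdiff(need, names(top))
  if (length(miss))
    prn_stop(paste0("prmtop missing sections: ", paste(miss, collapse = ", ")),
             "prn_topology_error")
  natom <- as.integer(top$POINTERS[1])
  ntypes <- as.integer(top$POINTERS[2])
  if (natom != nrow(structure$atoms))
    prn_stop(sprintf("topology has %d atoms but structure has %d",
                     natom, nrow(structure$atoms)), "prn_topology_error")

  q <- top$CHARGE / AMBER_CHARGE_SCALE
  tind <- as.integer(top$ATOM_TYPE_INDEX)
  nbidx <- as.integer(top$NONBONDED_PARM_INDEX)
  acoef <- top$LENNARD_JONES_ACOEF
  bcoef <- top$LENNARD_JONES_BCOEF

  # residue partition comes from the topology; map onto structure residues
  rptr <- as.integer(top$RESIDUE_POINTER)
  nres <- length(rptr)
  if (nres != nrow(structure$residues))
    prn_stop(sprintf("topology has %d residues but structure has %d",
                     nres, nrow(structure$residues)), "prn_topology_error")
  res_of <- rep(seq_len(nres), diff(c(rptr, natom + 1L)))

  # bond graph distances 1..3 classify excluded (1-2, 1-3) and 1-4 pairs
  bonds <- c(top$BONDS_INC_HYDROGEN, top$BONDS_WITHOUT_HYDROGEN)
  nb <- length(bonds) %/% 3L
  bdist <- .bond_distances(natom, bonds, nb)

  xyz <- as.matrix(structure$atoms[, c("x", "y", "z")])
  elec <- matrix(0, nres, nres)
  vdw <- matrix(0, nres, nres)
  for (a in seq_len(natom - 1L)) {
    b <- (a + 1L):natom
    keep <- res_of[b] != res_of[a]
    if (!any(keep)) next
    b <- b[keep]
    bd <- bdist[[a]]
    d12 <- !is.na(bd[b]) & bd[b] <= 2L
    b <- b[!d12]
    if (!length(b)) next
    scale14 <- !is.na(bdist[[a]][b]) & bdist[[a]][b] == 3L
    dr <- sqrt((xyz[b, 1] - xyz[a, 1])^2 + (xyz[b, 2] - xyz[a, 2])^2 +
                 (xyz[b, 3] - xyz[a, 3])^2)
    ee <- COULOMB_K * q[a] * q[b] / dr
    ico <- nbidx[ntypes * (tind[a] - 1L) + tind[b]]
    Aab <- ifelse(ico > 0, acoef[pmax(ico, 1L)], 0)
    Bab <- ifelse(ico > 0, bcoef[pmax(ico, 1L)], 0)
    vv <- Aab / dr^12 - Bab / dr^6
    ee[scale14] <- ee[scale14] / scee
    vv[scale14] <- vv[scale14] / scnb
    ra <- res_of[a]; rb <- res_of[b]
    for (t in seq_along(b)) {
      elec[ra, rb[t]] <- elec[ra, rb[t]] + ee[t]
      vdw[ra, rb[t]] <- vdw[ra, rb[t]] + vv[t]
    }
  }
  elec <- elec + t(elec); vdw <- vdw + t(vdw)

  ij <- which(upper.tri(elec) & (elec != 0 | vdw != 0), arr.ind = TRUE)
  pairs <- data.frame(i = ij[, 1], j = ij[, 2],
                      e_tot = elec[ij] + vdw[ij],
                      elec_ff = elec[ij], vdw_ff = vdw[ij])
  pie_table(structure$residues$label, pairs, source = "forcefield")
}

# per-atom named distances (1,2,3) to bonded neighbours within 3 bonds
.bond_distances <- function(natom, bonds, nb) {
  adj <- vector("list", natom)
  if (nb) {
    ai <- as.integer(bonds[seq(1, 3 * nb, by = 3)] / 3L) + 1L
    aj <- as.integer(bonds[seq(2, 3 * nb, by = 3)] / 3L) + 1L
    for (k in seq_len(nb)) {
      adj[[ai[k]]] <- c(adj[[ai[k]]], aj[k])
      adj[[aj[k]]] <- c(adj[[aj[k]]], ai[k])
    }
  }
  lapply(seq_len(natom), function(a) {
    d <- rep(NA_integer_, natom)
    frontier <- a; d[a] <- 0L
    for (depth in 1:3) {
      nxt <- unique(unlist(adj[frontier]))
      nxt <- nxt[is.na(d[nxt])]
      if (!length(nxt)) break
      d[nxt] <- depth
      frontier <- nxt
    }
    d[a] <- NA_integer_
    d
  })
}

#' Write a pair table as TSV
#'
#' One row per unordered pair with node labels and all available energy
#' components, `%.6f`-formatted for stable text diffs.
#'
#' @param pie A `pie_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pie_tsv <- function(pie, path) {
  stopifnot(inherits(pie, "pie_table"))
  df <- pie$pairs
  out <- data.frame(node_i = pie$labels[df$i], node_j = pie$labels[df$j])
  for (cn in intersect(.pie_component_names, names(df)))
    out[[cn]] <- sprintf("%.6f", df[[cn]])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
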