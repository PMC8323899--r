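# Synthetic toy complexes with known ground truth: a PDB text, a monomer
# membership, a pseudo-FMO pair-energy file and a toy Amber topology, all
# fully determined by (parameters, seed), so every analysis is testable
# offline. Geometry is schematic (3-atom pseudo-residues), not chemistry.

#' Generate a toy two-chain complex with planted interface contacts
#'
#' Chain A holds `n_a` pseudo-residues on a line (6 angstrom spacing);
#' chain B runs parallel.  A seeded subset of aligned cross-chain residue
#' pairs is placed ~7 angstroms apart (the planted contacts); all other
#' cross-chain pairs are at least ~9.2 angstroms apart, so a
#' centre-of-mass cutoff of 8 angstroms recovers exactly the planted
#' pairs as cross edges.  Each residue has three backbone-like atoms
#' (N, CA, C) with small out-of-plane offsets so backbone dihedrals are
#' defined.  Chain B numbering skips one residue number (a planted gap)
#' when it has at least three residues.
#'
#' @param n_a,n_b Residue counts of the two chains (>= 1).
#' @param seed Integer seed; the same seed reproduces the fixture
#'   byte-for-byte.
#' @param contact_fraction Fraction of aligned cross pairs made contacts.
#' @return List with
#'   \describe{
#'     \item{pdb_text}{character vector of PDB lines.}
#'     \item{membership}{named `"A"`/`"B"` vector over residue labels.}
#'     \item{manifest}{ground truth: residue table with centres, planted
#'       contact pairs, the distance cutoff `r_contact` that separates
#'       them, expected numbering gaps, and the seed.}
#'   }
#' @export
make_toy_complex <- function(n_a, n_b, seed = 1L, contact_fraction = 0.5) {
  stopifnot(n_a >= 1, n_b >= 1)
  with_prn_seed(seed, {
    n_align <- min(n_a, n_b)
    n_contact <- max(1L, round(contact_fraction * n_align))
    contact_pos <- sort(sample(seq_len(n_align), n_contact))

    resno_a <- seq_len(n_a)
    resno_b <- seq_len(n_b)
    gap <- NULL
    if (n_b >= 3L) {  # planted numbering gap after the 2nd residue of B
      resno_b[resno_b >= 3L] <- resno_b[resno_b >= 3L] + 1L
      gap <- data.frame(chain = "B", after = 2L, stringsAsFactors = FALSE)
    }

    centers <- list()
    for (i in seq_len(n_a))
      centers[[length(centers) + 1L]] <-
        data.frame(chain = "A", resno = resno_a[i],
                   cx = 6 * i, cy = 0, cz = 0)
    for (j in seq_len(n_b)) {
      y <- if (j <= n_align && j %in% contact_pos) 7 else 18
      centers[[length(centers) + 1L]] <-
        data.frame(chain = "B", resno = resno_b[j],
                   cx = 6 * j, cy = y, cz = 0)
    }
    res <- do.call(rbind, centers)
    res$resname <- "ALA"
    res$label <- residue_label(res$chain, res$resno, "", res$resname)

    lines <- character(0)
    serial <- 0L
    for (r in seq_len(nrow(res))) {
      # out-of-plane offsets make dihedrals non-degenerate; deterministic
      h <- 0.4 * sin(1.7 * r + c(0, 2, 4))
      offs <- rbind(c(-1.2, 0.35, h[1]), c(0, -0.35, h[2]), c(1.2, 0.35, h[3]))
      nm <- c("N", "CA", "C")
      el <- c("N", "C", "C")
      for (a in 1:3) {
        serial <- serial + 1L
        lines <- c(lines, sprintf(
          "ATOM  %5d  %-3s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, nm[a], res$resname[r], res$chain[r], res$resno[r],
          res$cx[r] + offs[a, 1], res$cy[r] + offs[a, 2], res$cz[r] + offs[a, 3],
          1.0, 0.0, el[a]))
      }
      if (r == n_a) lines <- c(lines, "TER")
    }
    lines <- c(lines, "END")

    # B rows follow the A rows in `res`; aligned position j is row n_a + j
    planted <- data.frame(
      label_a = res$label[contact_pos],
      label_b = res$label[n_a + contact_pos],
      stringsAsFactors = FALSE)

    manifest <- list(
      n_a = n_a, n_b = n_b, seed = seed,
      residues = res[, c("chain", "resno", "resname", "label",
                         "cx", "cy", "cz")],
      planted_pairs = planted,
      r_contact = 8.0,
      gaps = if (is.null(gap))
        data.frame(chain = character(), after = integer()) else gap)
    membership <- setNames(ifelse(res$chain == "A", "A", "B"), res$label)
    list(pdb_text = lines, membership = membership, manifest = manifest)
  })
}

#' Generate a toy pair-energy table and matching pseudo-FMO text
#'
#' Emulates an FMO pair-interaction table for a [make_toy_complex()]
#' fixture: every planted contact pair receives an attractive energy of
#' `-energy_scale` (plus optional Gaussian noise), sequence-adjacent
#' intra-chain pairs receive `-energy_scale/2` (the peptide-like
#' interactions), and one non-contact cross pair receives a small
#' repulsive energy so repulsive-interaction paths are exercised.  PIEDA
#' components are a fixed decomposition of each total.  All energies are
#' rounded to 1e-6 kcal/mol so that parsing the emitted pseudo-FMO text
#' with [parse_gamess_fmo()] reproduces the table exactly.
#'
#' @param manifest Manifest from [make_toy_complex()].
#' @param energy_scale Magnitude of planted contact energies, kcal/mol.
#' @param noise_sd Gaussian noise on the energies, kcal/mol (0 = exact).
#' @param seed Integer seed.
#' @return List with `pie` (a [pie_table()]) and `fmo_text` (character
#'   vector in the dialect [parse_gamess_fmo()] accepts).
#' @export
make_toy_pie_table <- function(manifest, energy_scale = 5, noise_sd = 0,
                               seed = 1L) {
  res <- manifest$residues
  labels <- res$label
  n <- length(labels)
  with_prn_seed(seed, {
    rows <- list()
    add <- function(i, j, e) {
      if (i > j) { t <- i; i <- j; j <- t }
      rows[[length(rows) + 1L]] <<- c(i = i, j = j, e = e)
    }
    nz <- function(e) round(e + (if (noise_sd > 0) rnorm(1, 0, noise_sd) else 0), 6)

    for (p in seq_len(nrow(manifest$planted_pairs)))
      add(match(manifest$planted_pairs$label_a[p], labels),
          match(manifest$planted_pairs$label_b[p], labels),
          nz(-energy_scale))
    for (ch in unique(res$chain)) {
      idx <- which(res$chain == ch)
      if (length(idx) > 1L)
        for (t in seq_len(length(idx) - 1L))
          add(idx[t], idx[t + 1L], nz(-energy_scale / 2))
    }
    far <- setdiff(which(res$chain == "B"),
                   match(manifest$planted_pairs$label_b, labels))
    if (length(far) && manifest$n_a >= 1L)
      add(1L, far[1L], nz(energy_scale / 10))  # one repulsive cross pair

    tab <- as.data.frame(do.call(rbind, rows))
    names(tab) <- c("i", "j", "e_tot")
    tab$i <- as.integer(tab$i); tab$j <- as.integer(tab$j)
    com <- res[, c("cx", "cy", "cz")]
    tab$r_frag <- round(sqrt(rowSums((com[tab$i, ] - com[tab$j, ])^2)), 4)
    tab$es <- round(0.55 * tab$e_tot, 6)
    tab$ex <- round(0.05 * abs(tab$e_tot), 6)
    tab$ct <- round(0.15 * tab$e_tot, 6)
    tab$di <- round(tab$e_tot - tab$es - tab$ex - tab$ct, 6)
    pie <- pie_table(labels, tab, source = "fmo")

    txt <- c(
      " ---------------------------------------------------------------",
      " Two-body FMO pair interaction energies / PIEDA, units: kcal/mol",
      " ---------------------------------------------------------------",
      sprintf("%5s%5s%4s%4s%10s%10s%12s%12s%14s%14s%14s%14s%14s",
              "I", "J", "DL", "Z", "R", "Q(I->J)", "dE", "dD*V",
              "total", "Ees", "Eex", "Ect+mix", "Edisp"))
    df <- pie$pairs
    for (r in seq_len(nrow(df)))
      txt <- c(txt, sprintf(
        "%5d%5d%4d%4d%10.4f%10.4f%12.4f%12.4f%14.6f%14.6f%14.6f%14.6f%14.6f",
        df$i[r], df$j[r], 0L, 0L, df$r_frag[r], 0, 0, 0,
        df$e_tot[r], df$es[r], df$ex[r], df$ct[r], df$di[r]))
    txt <- c(txt, "", " FRAGMENT NAMES",
             sprintf(" FRAGMENT %d %s", seq_len(n), labels))
    list(pie = pie, fmo_text = txt)
  })
}

#' Generate a toy Amber topology and matching structure
#'
#' A linear chain of `n_res` two-atom pseudo-residues with bonds inside
#' each residue and between consecutive residues, two Lennard-Jones atom
#' types and seeded alternating partial charges.  The emitted prmtop text
#' carries proper `%FLAG`/`%FORMAT` sections; the matching PDB text has
#' the same atom order, so [compute_ff_pies()] accepts the pair.  Bonded
#' 1-2/1-3 pairs and scaled 1-4 pairs all occur across residue boundaries,
#' exercising the exclusion rules.
#'
#' @param n_res Number of residues (>= 2).
#' @param seed Integer seed.
#' @return List with `prmtop_text`, `pdb_text` and a `manifest` (atom
#'   table with charges, types and coordinates; bond list).
#' @export
make_toy_topology <- function(n_res = 3L, seed = 1L) {
  stopifnot(n_res >= 2L)
  with_prn_seed(seed, {
    natom <- 2L * n_res
    res_of <- rep(seq_len(n_res), each = 2L)
    q <- round(runif(natom, 0.15, 0.45) * rep(c(1, -1), n_res), 4)
    tind <- rep(c(1L, 2L), n_res)
    x <- 3 * (seq_len(natom) - 1) / 2 + rep(c(0, 0.9), n_res)
    y <- round(0.3 * sin(seq_len(natom)), 3)
    z <- round(0.2 * cos(2 * seq_len(natom)), 3)

    bonds <- cbind(seq(1, natom - 1L, by = 2L), seq(2, natom, by = 2L))
    if (n_res > 1L)
      bonds <- rbind(bonds, cbind(seq(2, natom - 2L, by = 2L),
                                  seq(3, natom - 1L, by = 2L)))
    # LJ types: eps (kcal/mol), rstar (A); pair coefficients from the
    # standard combination A = eps R*^12, B = 2 eps R*^6, R* = R*_i + R*_j
    eps <- c(0.109, 0.086); rstar <- c(1.908, 1.487)
    ntypes <- 2L
    combo <- function(i, j) {
      e <- sqrt(eps[i] * eps[j]); rs <- rstar[i] + rstar[j]
      c(A = e * rs^12, B = 2 * e * rs^6)
    }
    ljpairs <- list(combo(1, 1), combo(1, 2), combo(2, 2))
    acoef <- vapply(ljpairs, `[`, 0, "A")
    bcoef <- vapply(ljpairs, `[`, 0, "B")
    ico <- matrix(c(1L, 2L, 2L, 3L), 2, 2)  # type-pair -> coefficient index

    fmtE <- function(v) .chunk_lines(sprintf("%16.8E", v), 5L)
    fmtI <- function(v) .chunk_lines(sprintf("%8d", v), 10L)
    fmtA <- function(v) .chunk_lines(sprintf("%-4s", v), 20L)
    pointers <- integer(31)
    pointers[1] <- natom; pointers[2] <- ntypes
    pointers[4] <- nrow(bonds)  # MBONA
    pointers[12] <- n_res

    txt <- c(
      "%VERSION  VERSION_STAMP = V0001.000  DATE = 01/01/00  00:00:00",
      "%FLAG TITLE", "%FORMAT(20a4)", "toy linear chain",
      "%FLAG POINTERS", "%FORMAT(10I8)", fmtI(pointers),
      "%FLAG CHARGE", "%FORMAT(5E16.8)", fmtE(q * AMBER_CHARGE_SCALE),
      "%FLAG ATOM_TYPE_INDEX", "%FORMAT(10I8)", fmtI(tind),
      "%FLAG NONBONDED_PARM_INDEX", "%FORMAT(10I8)", fmtI(as.integer(ico)),
      "%FLAG RESIDUE_LABEL", "%FORMAT(20a4)", fmtA(rep("TOY", n_res)),
      "%FLAG RESIDUE_POINTER", "%FORMAT(10I8)", fmtI(seq(1L, natom, by = 2L)),
      "%FLAG LENNARD_JONES_ACOEF", "%FORMAT(5E16.8)", fmtE(acoef),
      "%FLAG LENNARD_JONES_BCOEF", "%FORMAT(5E16.8)", fmtE(bcoef),
      "%FLAG BONDS_INC_HYDROGEN", "%FORMAT(10I8)",
      "%FLAG BONDS_WITHOUT_HYDROGEN", "%FORMAT(10I8)",
      fmtI(as.integer(t(cbind((bonds - 1L) * 3L, 1L))))
    )

    pdb <- character(0)
    for (a in seq_len(natom))
      pdb <- c(pdb, sprintf(
        "ATOM  %5d  %-3s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        a, paste0("C", 1L + (a - 1L) %% 2L), "TOY", "A", res_of[a],
        x[a], y[a], z[a], 1.0, 0.0, "C"))
    pdb <- c(pdb, "END")

    manifest <- list(n_res = n_res, seed = seed,
                     atoms = data.frame(res = res_of, q = q, type = tind,
                                        x = x, y = y, z = z),
                     bonds = bonds, eps = eps, rstar = rstar)
    list(prmtop_text = txt, pdb_text = pdb, manifest = manifest)
  })
}

.chunk_lines <- function(fields, per_line) {
  if (!length(fields)) return(character(0))
  grp <- ceiling(seq_along(fields) / per_line)
  vapply(split(fields, grp), paste, "", collapse = "")
}
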