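# PDB input: residues become network nodes; geometry for distance criteria.

# IUPAC 2021 standard atomic weights (conventional values) for elements
# commonly seen in PDB entries.  Names are upper-case element symbols.
.element_masses <- c(
  H = 1.008, D = 2.014, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
  P = 30.974, SE = 78.971, F = 18.998, CL = 35.45, BR = 79.904, I = 126.904,
  NA1 = 22.990, MG = 24.305, K = 39.098, CA = 40.078, MN = 54.938,
  FE = 55.845, CO = 58.933, NI = 58.693, CU = 63.546, ZN = 65.38,
  LI = 6.94, B = 10.81, AL = 26.982, SI = 28.085, V = 50.942, CR = 51.996,
  MO = 95.95, W = 183.84, CD = 112.414, HG = 200.592
)
names(.element_masses)[names(.element_masses) == "NA1"] <- "NA"

#' Standard atomic mass of an element
#'
#' @param element Character vector of element symbols (case-insensitive).
#' @return Numeric vector of masses in atomic mass units; `NA` for unknown
#'   symbols.
#' @examples
#' element_mass(c("C", "Fe"))
#' @export
element_mass <- function(element) {
  unname(.element_masses[toupper(element)])
}

# Infer the element for each atom record: trust the PDB element column when
# it is a known symbol, otherwise fall back to the first letter of the atom
# name (PDB files are inconsistent here; the fallback is deterministic).
infer_element <- function(elesy, atom_name) {
  el <- toupper(trimws(ifelse(is.na(elesy), "", elesy)))
  bad <- !(el %in% names(.element_masses))
  if (any(bad)) {
    first <- toupper(sub("^[^A-Za-z]*([A-Za-z]).*$", "\\1", atom_name[bad]))
    el[bad] <- first
  }
  el
}

.water_names <- c("HOH", "WAT", "DOD", "H2O")

#' Parse a PDB file into a residue-level structure model
#'
#' Reads ATOM (and optionally HETATM) records of the first model and groups
#' them into residues, the future network nodes.  Each residue is identified
#' by its chain, file residue number and insertion code; numbering is used
#' exactly as printed.  For alternate-location atoms only the
#' highest-occupancy conformer is kept (ties broken by altloc letter order).
#' Numbering gaps within a chain are recorded, since a gap is often used to
#' delimit monomers in supramolecular analyses.
#'
#' @param path Path to a PDB file.
#' @param include_het Keep HETATM residues (ligands, nucleic acids,
#'   saccharides) as nodes.  Default `FALSE`.
#' @param drop_waters Drop water residues (HOH/WAT/DOD) even when
#'   `include_het = TRUE`.  Default `TRUE`.
#' @return A `prn_structure`: list with elements
#'   \describe{
#'     \item{atoms}{data frame of kept atom records (chain, resno, icode,
#'       resname, name, element, x, y, z, occ, altloc, mass, res_index).}
#'     \item{residues}{data frame, one row per residue in file order
#'       (chain, resno, icode, resname, label, n_atoms).}
#'     \item{gaps}{data frame (chain, after): numbering gaps, `after` being
#'       the residue number preceding the gap.}
#'     \item{chain_ids}{chains in order of first appearance.}
#'   }
#' @seealso [center_of_mass()], [build_dprn()]
#' @export
parse_pdb <- function(path, include_het = FALSE, drop_waters = TRUE) {
  if (!file.exists(path)) prn_stop(paste0("file not found: ", path), "prn_io_error")
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) prn_stop(
      paste0("no ATOM/HETATM records readable from ", path, " (", conditionMessage(e), ")"),
      "prn_no_atoms_error")
  )
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0L)
    prn_stop(paste0("no ATOM/HETATM records in ", path), "prn_no_atoms_error")

  if (!include_het) at <- at[at$type == "ATOM", , drop = FALSE]
  if (drop_waters) at <- at[!(at$resid %in% .water_names), , drop = FALSE]
  if (nrow(at) == 0L)
    prn_stop(paste0("no atom records left after filtering in ", path),
             "prn_no_atoms_error")

  if (anyNA(at$x) || anyNA(at$y) || anyNA(at$z)) {
    bad <- which(is.na(at$x) | is.na(at$y) | is.na(at$z))[1L]
    ln <- .find_malformed_line(path, at$eleno[bad])
    prn_stop(sprintf("malformed coordinates for atom serial %s (line %s)",
                     at$eleno[bad], ln), "prn_malformed_record_error")
  }

  chain <- ifelse(is.na(at$chain), "", at$chain)
  icode <- ifelse(is.na(at$insert), "", at$insert)
  altloc <- ifelse(is.na(at$alt), "", at$alt)
  occ <- ifelse(is.na(at$o), 1, at$o)

  atoms <- data.frame(
    chain = chain, resno = at$resno, icode = icode, resname = at$resid,
    name = at$elety, element = infer_element(at$elesy, at$elety),
    x = at$x, y = at$y, z = at$z, occ = occ, altloc = altloc,
    stringsAsFactors = FALSE
  )
  atoms$mass <- element_mass(atoms$element)
  atoms$mass[is.na(atoms$mass)] <- 12.011  # unknown elements: carbon-like

  # altloc resolution: within (residue, atom name) keep highest occupancy,
  # ties broken by altloc letter order ("" sorts first)
  key <- paste(atoms$chain, atoms$resno, atoms$icode, atoms$name, sep = "\r")
  ord <- order(key, -atoms$occ, atoms$altloc)
  atoms <- atoms[ord, , drop = FALSE]
  atoms <- atoms[!duplicated(key[ord]), , drop = FALSE]

  # restore file order of residues, then atoms within residue
  rkey <- paste(atoms$chain, atoms$resno, atoms$icode, sep = "\r")
  rkey_all <- paste(chain, at$resno, icode, sep = "\r")
  res_order <- unique(rkey_all)
  atoms <- atoms[order(match(rkey, res_order)), , drop = FALSE]
  rownames(atoms) <- NULL

  rkey <- paste(atoms$chain, atoms$resno, atoms$icode, sep = "\r")
  atoms$res_index <- match(rkey, res_order)

  fr <- atoms[!duplicated(atoms$res_index), , drop = FALSE]
  residues <- data.frame(
    chain = fr$chain, resno = fr$resno, icode = fr$icode, resname = fr$resname,
    label = residue_label(fr$chain, fr$resno, fr$icode, fr$resname),
    n_atoms = as.integer(table(atoms$res_index)[as.character(fr$res_index)]),
    stringsAsFactors = FALSE
  )
  rownames(residues) <- NULL

  gaps <- .find_gaps(residues)
  structure(
    list(atoms = atoms, residues = residues, gaps = gaps,
         chain_ids = unique(residues$chain), source = path),
    class = "prn_structure"
  )
}

# canonical node label "chain:number[:icode]:name" (stable in text reports)
residue_label <- function(chain, resno, icode, resname) {
  ic <- ifelse(is.na(icode) | icode == "", "", paste0(":", icode))
  paste0(chain, ":", resno, ic, ":", resname)
}

.find_gaps <- function(residues) {
  out <- list()
  for (ch in unique(residues$chain)) {
    nos <- residues$resno[residues$chain == ch]
    nos <- nos[!duplicated(nos)]
    jump <- which(diff(nos) > 1L)
    if (length(jump))
      out[[ch]] <- data.frame(chain = ch, after = nos[jump],
                              stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(chain = character(), after = integer(),
                      stringsAsFactors = FALSE))
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

# locate the file line of an atom serial whose coordinates failed to parse
.find_malformed_line <- function(path, serial) {
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM|HETATM)", lines)
  idx <- which(rec & suppressWarnings(
    as.integer(substr(lines, 7, 11)) == as.integer(serial)))
  if (length(idx)) idx[1L] else NA_integer_
}

#' @export
print.prn_structure <- function(x, ...) {
  cat(sprintf("prn_structure: %d residues, %d atoms, chains {%s}\n",
              nrow(x$residues), nrow(x$atoms),
              paste(x$chain_ids, collapse = ",")))
  if (nrow(x$gaps))
    cat(sprintf("  numbering gaps: %s\n",
                paste(sprintf("%s after %d", x$gaps$chain, x$gaps$after),
                      collapse = "; ")))
  invisible(x)
}

#' Residue centres of mass
#'
#' Mass-weighted mean coordinate of each residue.  Hydrogens are included
#' whenever present in the file.  The centre of mass drives the distance
#' criterion \eqn{R_{ij} \le R_{lim}} of D-PRNs and the optional secondary
#' distance criterion of PIE-PRNs.
#'
#' @param structure A `prn_structure` from [parse_pdb()].
#' @param residue Optional residue selector: integer index or node label.
#'   When omitted, all residues are returned.
#' @return A numeric matrix (n x 3, rownames = node labels) or, for a
#'   single selected residue, a length-3 vector (angstroms).
#' @export
center_of_mass <- function(structure, residue = NULL) {
  stopifnot(inherits(structure, "prn_structure"))
  at <- structure$atoms
  m <- at$mass
  if (any(m <= 0) || anyNA(m))
    prn_stop("non-positive atom mass encountered", "prn_degenerate_residue_error")
  tot <- tapply(m, at$res_index, sum)
  if (any(tot <= 0))
    prn_stop("residue with zero total mass", "prn_degenerate_residue_error")
  cx <- tapply(m * at$x, at$res_index, sum) / tot
  cy <- tapply(m * at$y, at$res_index, sum) / tot
  cz <- tapply(m * at$z, at$res_index, sum) / tot
  idx <- as.character(seq_len(nrow(structure$residues)))
  com <- cbind(x = cx[idx], y = cy[idx], z = cz[idx])
  rownames(com) <- structure$residues$label
  if (is.null(residue)) return(com)
  if (is.character(residue)) residue <- match(residue, structure$residues$label)
  if (is.na(residue) || residue < 1 || residue > nrow(com))
    prn_stop("unknown residue selector", "prn_io_error")
  com[residue, ]
}
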