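# Graph serialization (GEXF 1.2 / GraphML) and the pipeline driver.

#' Write a network to GEXF or GraphML
#'
#' Serializes nodes, edges and all numeric/text attributes.  GraphML goes
#' through igraph's writer; GEXF 1.2 is generated directly.  Reading the
#' file back with [read_prn_graph()] reconstructs an isomorphic graph with
#' equal attribute values (floats formatted at full precision).
#'
#' @param g A `PrnGraph`.
#' @param path Output file path.
#' @param format `"gexf"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_prn_graph <- function(g, path, format = c("gexf", "graphml")) {
  if (length(format) == 1L && !format %in% c("gexf", "graphml"))
    prn_stop(paste0("unknown graph format: ", format), "prn_format_error")
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
    return(invisible(path))
  }
  .write_gexf(g, path)
  invisible(path)
}

.xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub("\"", "&quot;", x, fixed = TRUE)
}

.gexf_type <- function(v) {
  if (is.logical(v)) "boolean" else if (is.numeric(v)) "double" else "string"
}

.gexf_fmt <- function(v) {
  if (is.logical(v)) ifelse(v, "true", "false")
  else if (is.numeric(v)) sprintf("%.17g", v)
  else .xml_escape(as.character(v))
}

.write_gexf <- function(g, path) {
  nattr <- setdiff(igraph::vertex_attr_names(g), "name")
  eattr <- setdiff(igraph::edge_attr_names(g), character(0))
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(paste0(...), con)
  wl('<?xml version="1.0" encoding="UTF-8"?>')
  wl('<gexf xmlns="http://www.gexf.net/1.2draft" version="1.2">')
  wl('  <graph mode="static" defaultedgetype="undirected">')
  kind <- igraph::graph_attr(g, "kind")
  if (!is.null(kind)) wl('    <meta><creator>prnkit</creator><description>',
                         .xml_escape(kind), '</description></meta>')
  wl('    <attributes class="node">')
  for (k in seq_along(nattr))
    wl(sprintf('      <attribute id="%d" title="%s" type="%s"/>',
               k - 1L, .xml_escape(nattr[k]),
               .gexf_type(igraph::vertex_attr(g, nattr[k]))))
  wl('    </attributes>')
  wl('    <attributes class="edge">')
  for (k in seq_along(eattr))
    wl(sprintf('      <attribute id="%d" title="%s" type="%s"/>',
               k - 1L, .xml_escape(eattr[k]),
               .gexf_type(igraph::edge_attr(g, eattr[k]))))
  wl('    </attributes>')
  wl('    <nodes>')
  nm <- igraph::V(g)$name
  for (v in seq_len(igraph::vcount(g))) {
    if (length(nattr)) {
      wl(sprintf('      <node id="%s" label="%s">',
                 .xml_escape(nm[v]), .xml_escape(nm[v])))
      wl('        <attvalues>')
      for (k in seq_along(nattr)) {
        val <- igraph::vertex_attr(g, nattr[k])[v]
        if (!is.na(val))
          wl(sprintf('          <attvalue for="%d" value="%s"/>',
                     k - 1L, .gexf_fmt(val)))
      }
      wl('        </attvalues>')
      wl('      </node>')
    } else {
      wl(sprintf('      <node id="%s" label="%s"/>',
                 .xml_escape(nm[v]), .xml_escape(nm[v])))
    }
  }
  wl('    </nodes>')
  wl('    <edges>')
  if (igraph::ecount(g)) {
    ends <- igraph::ends(g, igraph::E(g), names = TRUE)
    for (e in seq_len(igraph::ecount(g))) {
      wl(sprintf('      <edge id="%d" source="%s" target="%s">',
                 e - 1L, .xml_escape(ends[e, 1]), .xml_escape(ends[e, 2])))
      wl('        <attvalues>')
      for (k in seq_along(eattr)) {
        val <- igraph::edge_attr(g, eattr[k])[e]
        if (!is.na(val))
          wl(sprintf('          <attvalue for="%d" value="%s"/>',
                     k - 1L, .gexf_fmt(val)))
      }
      wl('        </attvalues>')
      wl('      </edge>')
    }
  }
  wl('    </edges>')
  wl('  </graph>')
  wl('</gexf>')
}

#' Read a network written by [write_prn_graph()]
#'
#' @param path File path.
#' @param format `"gexf"` or `"graphml"`.
#' @return An igraph graph with the serialized attributes.
#' @export
read_prn_graph <- function(path, format = c("gexf", "graphml")) {
  if (length(format) == 1L && !format %in% c("gexf", "graphml"))
    prn_stop(paste0("unknown graph format: ", format), "prn_format_error")
  format <- match.arg(format)
  if (format == "graphml")
    return(igraph::read_graph(path, format = "graphml"))
  .read_gexf(path)
}

.read_gexf <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  adef <- list(node = list(), edge = list())
  for (cls in c("node", "edge")) {
    defs <- xml2::xml_find_all(doc, sprintf(".//attributes[@class='%s']/attribute", cls))
    adef[[cls]] <- data.frame(
      id = xml2::xml_attr(defs, "id"),
      title = xml2::xml_attr(defs, "title"),
      type = xml2::xml_attr(defs, "type"),
      stringsAsFactors = FALSE)
  }
  cast <- function(vals, type) {
    if (type == "double") as.numeric(vals)
    else if (type == "boolean") vals == "true"
    else vals
  }
  nodes <- xml2::xml_find_all(doc, ".//nodes/node")
  ids <- xml2::xml_attr(nodes, "id")
  g <- igraph::make_empty_graph(n = length(ids), directed = FALSE)
  igraph::V(g)$name <- ids
  pull_attvals <- function(elems, defs) {
    lapply(seq_len(nrow(defs)), function(k) {
      vals <- vapply(elems, function(el) {
        av <- xml2::xml_find_first(
          el, sprintf("./attvalues/attvalue[@for='%s']", defs$id[k]))
        if (inherits(av, "xml_missing")) NA_character_
        else xml2::xml_attr(av, "value")
      }, "")
      cast(vals, defs$type[k])
    })
  }
  if (nrow(adef$node)) {
    nav <- pull_attvals(as.list(nodes), adef$node)
    for (k in seq_len(nrow(adef$node)))
      g <- igraph::set_vertex_attr(g, adef$node$title[k], value = nav[[k]])
  }
  edges <- xml2::xml_find_all(doc, ".//edges/edge")
  if (length(edges)) {
    src <- match(xml2::xml_attr(edges, "source"), ids)
    tgt <- match(xml2::xml_attr(edges, "target"), ids)
    g <- igraph::add_edges(g, rbind(src, tgt))
    if (nrow(adef$edge)) {
      eav <- pull_attvals(as.list(edges), adef$edge)
      for (k in seq_len(nrow(adef$edge)))
        g <- igraph::set_edge_attr(g, adef$edge$title[k], value = eav[[k]])
    }
  }
  desc <- xml2::xml_find_first(doc, ".//meta/description")
  if (!inherits(desc, "xml_missing"))
    g <- igraph::set_graph_attr(g, "kind", xml2::xml_text(desc))
  g
}

# ---------------------------------------------------------------------------
# Pipeline driver

.fmt6 <- function(x) {
  if (is.numeric(x)) sprintf("%.6f", x) else as.character(x)
}

.write_report <- function(df, path) {
  out <- df
  for (cn in names(out)) if (is.numeric(out[[cn]])) out[[cn]] <- .fmt6(out[[cn]])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# turn monomer selections (chains like "A" or ranges like "A:1-20") into a
# membership vector over the structure's residues
.monomer_membership <- function(structure, monomer_a, monomer_b) {
  res <- structure$residues
  pick <- function(sels) {
    hit <- rep(FALSE, nrow(res))
    for (s in sels) {
      if (grepl(":", s, fixed = TRUE)) {
        p <- strsplit(s, "[:-]")[[1]]
        hit <- hit | (res$chain == p[1] & res$resno >= as.integer(p[2]) &
                        res$resno <= as.integer(p[3]))
      } else hit <- hit | res$chain == s
    }
    hit
  }
  in_a <- pick(monomer_a); in_b <- pick(monomer_b)
  if (any(in_a & in_b))
    prn_stop("monomer selections overlap", "prn_membership_error")
  memb <- rep(NA_character_, nrow(res))
  memb[in_a] <- "A"; memb[in_b] <- "B"
  if (anyNA(memb))
    prn_stop("residues not covered by the monomer selections",
             "prn_membership_error")
  setNames(memb, res$label)
}

#' Run a full analysis pipeline
#'
#' Drives build, optional supersystem split and the requested analyses,
#' writing deterministic tab-separated reports (energies in kcal/mol,
#' distances in angstroms, `%.6f` formatting) plus a run log with the
#' criteria, node/edge counts and package version.  Two runs with the same
#' config and seed produce byte-identical files.
#'
#' @param config A list with elements:
#'   \describe{
#'     \item{pdb}{path to the structure (required).}
#'     \item{fmo, prmtop}{at most one: energy source for a PIE-PRN; when
#'       neither is given a D-PRN is built.}
#'     \item{criteria}{a [build_criteria()] (or list of its arguments).}
#'     \item{monomer_a, monomer_b}{chain ids or `"chain:from-to"` ranges;
#'       required by nda/svd/spie/binding.}
#'     \item{analyses}{subset of `"edges"`, `"centrality"`, `"partition"`,
#'       `"nda"`, `"svd"`, `"spie"`, `"binding"`, `"export"`.}
#'     \item{centrality_kinds}{kinds for the centrality report.}
#'     \item{seed}{integer seed (partitions).}
#'     \item{out_dir}{output directory (created).}
#'     \item{export_format}{`"gexf"` and/or `"graphml"`.}
#'   }
#' @return Named character vector of written file paths, invisibly.
#' @export
run_analysis <- function(config) {
  req <- function(x, msg) if (is.null(x)) prn_stop(msg, "prn_config_error") else x
  pdb <- req(config$pdb, "config$pdb is required")
  if (!file.exists(pdb)) prn_stop(paste0("missing input: ", pdb), "prn_config_error")
  analyses <- if (is.null(config$analyses)) c("edges", "centrality") else config$analyses
  known <- c("edges", "centrality", "partition", "nda", "svd", "spie",
             "binding", "export")
  bad <- setdiff(analyses, known)
  if (length(bad))
    prn_stop(paste0("unknown analyses: ", paste(bad, collapse = ", ")),
             "prn_config_error")
  needs_split <- intersect(analyses, c("nda", "svd", "spie", "binding"))
  if (length(needs_split) &&
      (is.null(config$monomer_a) || is.null(config$monomer_b)))
    prn_stop(paste0(paste(needs_split, collapse = "/"),
                    " require monomer_a and monomer_b definitions"),
             "prn_config_error")
  if (!is.null(config$fmo) && !is.null(config$prmtop))
    prn_stop("give either fmo or prmtop, not both", "prn_config_error")
  if (length(intersect(analyses, c("spie", "binding"))) &&
      is.null(config$fmo) && is.null(config$prmtop))
    prn_stop("spie/binding need an energy source (fmo or prmtop)",
             "prn_config_error")

  crit <- config$criteria
  if (!inherits(crit, "build_criteria")) crit <- do.call(build_criteria, as.list(crit))
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  out_dir <- req(config$out_dir, "config$out_dir is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  structure_ <- parse_pdb(pdb, include_het = isTRUE(config$include_het))
  pie <- NULL
  if (!is.null(config$fmo)) {
    parsed <- parse_gamess_fmo(config$fmo)
    pie <- parsed$pie
  } else if (!is.null(config$prmtop)) {
    pie <- compute_ff_pies(structure_, config$prmtop)
  }
  g <- if (is.null(pie)) build_dprn(structure_, crit)
       else build_pieprn(pie, crit, structure = structure_)

  split <- NULL
  if (length(needs_split) || "export" %in% analyses &&
      !is.null(config$monomer_a)) {
    if (!is.null(config$monomer_a) && !is.null(config$monomer_b)) {
      memb <- .monomer_membership(structure_, config$monomer_a, config$monomer_b)
      # PIE labels may be fragment labels; membership is over residue labels
      memb <- memb[intersect(names(memb), igraph::V(g)$name)]
      if (length(memb) < igraph::vcount(g))
        prn_stop("graph nodes not covered by monomer membership",
                 "prn_membership_error")
      split <- split_supersystem(g, memb)
      g <- split$g
    }
  }

  files <- character(0)
  p <- function(f) file.path(out_dir, f)

  if ("edges" %in% analyses)
    files["edges"] <- .write_report(edge_table(g), p("edges.tsv"))

  if ("centrality" %in% analyses) {
    kinds <- if (is.null(config$centrality_kinds)) c("degree", "closeness", "betweenness")
             else config$centrality_kinds
    df <- data.frame(node = igraph::V(g)$name, stringsAsFactors = FALSE)
    for (kk in kinds) {
      vals <- if (kk == "etot") total_energy_centrality(g)$values
              else if (kk == "efficiency") efficiency_centrality(g)$values
              else node_centrality(g, kk)$values
      df[[kk]] <- unname(vals[df$node])
    }
    files["centrality"] <- .write_report(df, p("centrality.tsv"))
  }

  if ("partition" %in% analyses) {
    part <- louvain_communities(g, seed = seed)
    df <- data.frame(node = names(part$membership),
                     community = part$membership,
                     stringsAsFactors = FALSE)
    attr(df, "modularity") <- part$modularity
    files["partition"] <- .write_report(df, p("communities.tsv"))
  }

  if ("nda" %in% analyses) {
    kinds <- if (is.null(config$nda_kinds)) {
      if (is.null(pie)) c("degree", "efficiency") else c("etot", "efficiency")
    } else config$nda_kinds
    df <- data.frame(node = igraph::V(split$g)$name, stringsAsFactors = FALSE)
    for (kk in kinds) df[[paste0("delta_", kk)]] <-
      unname(nda(split, kk)$delta[df$node])
    files["nda"] <- .write_report(df, p("nda.tsv"))
  }

  if ("svd" %in% analyses) {
    m <- ppi_matrix(split, mode = "block",
                    sign_filter = if (is.null(config$svd_sign)) "attractive"
                                  else config$svd_sign)
    sv <- svd_motifs(m)
    df <- data.frame(i = seq_len(sv$k), sigma = sv$sigma, f = sv$f_series)
    files["svd"] <- .write_report(df, p("svd_motifs.tsv"))
    doms <- lapply(seq_len(min(4L, sv$k)), function(i)
      cbind(motif = i, dominant_motif_nodes(sv, m, i, side = "A")))
    files["svd_nodes"] <- .write_report(do.call(rbind, doms), p("svd_nodes.tsv"))
  }

  if ("spie" %in% analyses)
    files["spie"] <- .write_report(
      spie_data(split, pie, min_abs = if (is.null(config$spie_min_abs)) 0
                                       else config$spie_min_abs),
      p("spie.tsv"))

  if ("binding" %in% analyses) {
    memb <- setNames(igraph::V(split$g)$monomer, igraph::V(split$g)$name)
    be <- binding_energies(pie, memb,
                           mode = if (is.null(config$binding_mode)) "symmetric"
                                  else config$binding_mode)
    df <- data.frame(node = names(be$contributions),
                     binding_energy = unname(be$contributions),
                     stringsAsFactors = FALSE)
    files["binding"] <- .write_report(df, p("binding.tsv"))
  }

  if ("export" %in% analyses) {
    fmts <- if (is.null(config$export_format)) "gexf" else config$export_format
    for (fmt in fmts)
      files[paste0("export_", fmt)] <-
        write_prn_graph(g, p(paste0("graph.", fmt)), fmt)
  }

  log_lines <- c(
    paste0("prnkit ", as.character(utils::packageVersion("prnkit"))),
    paste0("pdb: ", basename(pdb)),
    paste0("energy source: ",
           if (!is.null(config$fmo)) "fmo" else
             if (!is.null(config$prmtop)) "forcefield" else "none (D-PRN)"),
    paste0("criteria: e_lim=", .fmt_or_na(crit$e_lim),
           " r_lim=", .fmt_or_na(crit$r_lim),
           " term=", crit$energy_term,
           " include_covalent=", crit$include_covalent,
           " weight_scheme=", crit$weight_scheme),
    paste0("seed: ", seed),
    paste0("nodes: ", igraph::vcount(g), "  edges: ", igraph::ecount(g)),
    if (!is.null(split))
      paste0("split: N_A=", split$n_a, " N_B=", split$n_b,
             " N_PPI=", split$n_ppi,
             " interface edges=", igraph::ecount(split$g_ppi)),
    paste0("analyses: ", paste(analyses, collapse = ","))
  )
  writeLines(log_lines, file.path(out_dir, "run.log"))
  files["log"] <- file.path(out_dir, "run.log")
  invisible(files)
}

.fmt_or_na <- function(x) if (is.null(x)) "NA" else sprintf("%.6f", x)
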