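#' Read a residue numbering mapping table
#'
#' Tab-separated columns `chain`, `resid`, `role`, `generic_id` mapping author
#' (PDB) residue numbers to generic numbers (Ballesteros-Weinstein for
#' receptors, Common G-protein Numbering for G proteins). Duplicate
#' (chain, resid) rows and empty generic ids are format errors.
#'
#' @param path file path.
#' @return data.frame of class `residue_mapping` with normalized generic ids.
#' @export
read_mapping_table <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                           colClasses = "character", fileEncoding = "UTF-8")
  need <- c("chain", "resid", "role", "generic_id")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols)) {
    stop("mapping table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (any(!nzchar(trimws(tab$generic_id)))) {
    stop("mapping table has row(s) with empty generic_id")
  }
  tab$resid <- as.integer(tab$resid)
  tab$role <- match.arg(tab$role, c("receptor", "gprotein"), several.ok = TRUE)
  key <- paste(tab$chain, tab$resid)
  if (anyDuplicated(key)) {
    stop("duplicate (chain, resid) in mapping table: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  tab$generic_id <- normalize_generic_id(tab$generic_id)
  class(tab) <- c("residue_mapping", "data.frame")
  tab
}

#' Look up residues in a mapping table
#'
#' Residues absent from the table are an error listing every offender, never a
#' silent drop.
#'
#' @param mapping a `residue_mapping` from [read_mapping_table()].
#' @param chain,resid parallel vectors identifying residues.
#' @return data.frame with one row per query (`chain`, `resid`, `role`,
#'   `generic_id`), in query order.
#' @export
lookup_residue <- function(mapping, chain, resid) {
  stopifnot(length(chain) == length(resid))
  key <- paste(chain, as.integer(resid))
  tab_key <- paste(mapping$chain, mapping$resid)
  idx <- match(key, tab_key)
  if (anyNA(idx)) {
    stop("residue(s) absent from mapping table: ",
         paste(unique(key[is.na(idx)]), collapse = "; "))
  }
  out <- mapping[idx, c("chain", "resid", "role", "generic_id")]
  rownames(out) <- NULL
  out
}

#' Read a region definition table
#'
#' Tab-separated columns `generic_id`, `region` assigning each generic residue
#' number to one structural region (TM1-TM7, H8, ICL1-3 on the receptor;
#' N-term, beta segments/loops, hns1, hgh4, core-other, alpha5-core,
#' alpha5-tip on the G protein). Region boundaries are data, not code: ship
#' alternative presets as alternative files.
#'
#' @param path file path.
#' @return named character vector region keyed by generic_id.
#' @export
read_region_table <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                           colClasses = "character", fileEncoding = "UTF-8")
  if (!all(c("generic_id", "region") %in% names(tab))) {
    stop("region table needs columns generic_id, region")
  }
  ids <- normalize_generic_id(tab$generic_id)
  if (anyDuplicated(ids)) {
    stop("generic_id mapped to more than one region: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  stats::setNames(tab$region, ids)
}

#' Read conservation flags for G-protein residues
#'
#' Tab-separated columns `generic_id`, `conserved` (0/1 or TRUE/FALSE). The
#' flags are user data, typically derived from a Gs/Gi/Gq alignment.
#'
#' @param path file path.
#' @return named logical vector keyed by generic_id (TRUE = conserved).
#' @export
read_conservation_table <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                           fileEncoding = "UTF-8")
  if (!all(c("generic_id", "conserved") %in% names(tab))) {
    stop("conservation table needs columns generic_id, conserved")
  }
  flags <- as.logical(tab$conserved)
  if (anyNA(flags)) flags <- as.logical(as.integer(tab$conserved))
  if (anyNA(flags)) stop("conserved column must be logical or 0/1")
  stats::setNames(flags, normalize_generic_id(tab$generic_id))
}

#' Read an experimental coupling table
#'
#' Tab-separated columns `region`, `dlogEC50`: the change in log coupling
#' potency of a region-swapped chimeric G protein relative to wild type.
#'
#' @param path file path.
#' @return named numeric vector keyed by region.
#' @export
read_coupling_table <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                           fileEncoding = "UTF-8")
  if (!all(c("region", "dlogEC50") %in% names(tab))) {
    stop("coupling table needs columns region, dlogEC50")
  }
  stats::setNames(as.numeric(tab$dlogEC50), tab$region)
}

# Convert a Bayesian network or moral graph to an igraph object.
as_igraph_network <- function(net) {
  if (inherits(net, "contact_bn")) {
    g <- igraph::make_empty_graph(n = 0, directed = TRUE)
    g <- igraph::add_vertices(g, length(net$nodes), name = net$nodes)
    if (nrow(net$edges) > 0L) {
      g <- igraph::add_edges(
        g, rbind(match(net$edges$from, net$nodes), match(net$edges$to, net$nodes)),
        strength = net$edges$strength)
    }
    g
  } else if (inherits(net, "moral_graph")) {
    g <- igraph::make_empty_graph(n = 0, directed = FALSE)
    g <- igraph::add_vertices(g, length(net$nodes), name = net$nodes)
    if (nrow(net$edges) > 0L) {
      g <- igraph::add_edges(
        g, rbind(match(net$edges$a, net$nodes), match(net$edges$b, net$nodes)))
    }
    g
  } else {
    stop("write_network expects a contact_bn or moral_graph")
  }
}

#' Export a network for external graph tools
#'
#' Writes a learned Bayesian network (directed, with a `strength` edge
#' attribute) or a moral graph (undirected, unweighted) in a format Cytoscape
#' and friends can read.
#'
#' @param net a `contact_bn` or `moral_graph`.
#' @param path output file path.
#' @param format one of `"graphml"`, `"sif"`, `"edgelist"`.
#' @export
write_network <- function(net, path, format = c("graphml", "sif", "edgelist")) {
  format <- match.arg(format)
  g <- as_igraph_network(net)
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
  } else if (format == "sif") {
    rel <- if (igraph::is_directed(g)) "depends_on" else "linked"
    el <- igraph::as_edgelist(g)
    lines <- if (nrow(el)) paste(el[, 1L], rel, el[, 2L], sep = "\t") else character(0)
    iso <- setdiff(igraph::V(g)$name, c(el))
    writeLines(c(lines, iso), path, useBytes = FALSE)
  } else {
    el <- igraph::as_edgelist(g)
    df <- data.frame(from = el[, 1L], to = el[, 2L])
    if (igraph::is_directed(g) && igraph::ecount(g) > 0L) {
      df$strength <- igraph::E(g)$strength
    }
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                       fileEncoding = "UTF-8")
  }
  invisible(path)
}

#' Read back an exported GraphML network
#'
#' Round-trip companion to [write_network()]; returns the node and edge sets
#' (and `strength` attribute when present).
#'
#' @param path GraphML file path.
#' @return an igraph graph.
#' @export
read_network <- function(path) {
  igraph::read_graph(path, format = "graphml")
}

#' Write an analysis report as JSON
#'
#' All tabular analysis outputs (cooperativity tables, JSD matrices,
#' robustness summaries) serialize through this helper.
#'
#' @param x a list / data.frame.
#' @param path output path.
#' @export
write_report_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(path)
}
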