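# Cross-complex network comparison: moralization, common subgraphs,
# Markov neighborhoods, and Jensen-Shannon divergence of empirical joints.

# canonical unordered edge representation: endpoints sorted lexicographically
undirected_edge_df <- function(a, b) {
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  df <- unique(data.frame(a = a, b = b, stringsAsFactors = FALSE))
  df <- df[df$a != df$b, , drop = FALSE]
  df[order(df$a, df$b), , drop = FALSE]
}

#' Moralize a directed Bayesian network
#'
#' Three steps: identify each node's parents; add an undirected edge between
#' every pair of parents not already connected ("marrying" co-parents); drop
#' the direction of every original edge. The result is a simple undirected,
#' unweighted graph.
#'
#' @param net a `contact_bn`.
#' @param source optional identifier recorded on the output.
#' @return a `moral_graph`: `nodes`, undirected `edges` (columns `a`, `b`),
#'   `source`.
#' @export
moralize <- function(net, source = NA_character_) {
  a <- net$edges$from
  b <- net$edges$to
  for (v in net$nodes) {
    pa <- net$parents[[v]]
    if (length(pa) >= 2L) {
      prs <- utils::combn(sort(pa), 2L)
      a <- c(a, prs[1L, ])
      b <- c(b, prs[2L, ])
    }
  }
  edges <- if (length(a)) undirected_edge_df(a, b) else
    data.frame(a = character(0), b = character(0), stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  structure(list(nodes = net$nodes, edges = edges, source = source),
            class = "moral_graph")
}

#' @export
print.moral_graph <- function(x, ...) {
  cat(sprintf("<moral_graph> %d nodes, %d undirected edges (source: %s)\n",
              length(x$nodes), nrow(x$edges), x$source))
  invisible(x)
}

#' Largest common subnetwork across moralized graphs
#'
#' Keeps every undirected edge whose node-label pair occurs in at least
#' `min_support` of the input graphs, then returns the largest connected
#' component of the kept edge set (by edge count; ties broken by node count,
#' then by lexicographically smallest node). Node identity is by canonical
#' contact-node label, which makes this a label-intersection problem.
#'
#' @param graphs list of `moral_graph`s (>= 2).
#' @param min_support minimal number of graphs an edge must appear in.
#' @return a `common_subgraph`: `nodes`, `edges` (with per-edge `support`),
#'   `min_support`.
#' @export
common_subgraph <- function(graphs, min_support) {
  stopifnot(length(graphs) >= 2L)
  if (min_support < 1L || min_support > length(graphs)) {
    stop("min_support must lie in [1, number of graphs]")
  }
  keys <- unlist(lapply(graphs, function(g) {
    if (nrow(g$edges) == 0L) return(character(0))
    paste(g$edges$a, g$edges$b, sep = "\r")
  }))
  support <- table(keys)
  kept <- names(support)[support >= min_support]
  empty <- structure(list(nodes = character(0),
                          edges = data.frame(a = character(0), b = character(0),
                                             support = integer(0),
                                             stringsAsFactors = FALSE),
                          min_support = min_support),
                     class = "common_subgraph")
  if (length(kept) == 0L) return(empty)
  parts <- do.call(rbind, strsplit(kept, "\r", fixed = TRUE))
  edges <- data.frame(a = parts[, 1L], b = parts[, 2L],
                      support = as.integer(support[kept]),
                      stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges[, c("a", "b")], directed = FALSE)
  comp <- igraph::components(g)
  edge_comp <- comp$membership[edges$a]
  sizes <- vapply(seq_len(comp$no), function(ci) sum(edge_comp == ci), 1L)
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) { # ties: node count, then smallest node label
    ncounts <- comp$csize[best]
    best <- best[ncounts == max(ncounts)]
    if (length(best) > 1L) {
      firsts <- vapply(best, function(ci) {
        min(names(comp$membership)[comp$membership == ci])
      }, character(1L))
      best <- best[which.min(firsts)]
    }
  }
  sel <- edge_comp == best[1L]
  edges <- edges[sel, , drop = FALSE]
  edges <- edges[order(edges$a, edges$b), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = sort(unique(c(edges$a, edges$b))), edges = edges,
                 min_support = min_support),
            class = "common_subgraph")
}

#' Markov neighborhood of a node
#'
#' The set of nodes directly connected to the node of interest: the union of
#' its parents and children (graph adjacency). Note this is not the Markov
#' blanket — co-parents are excluded.
#'
#' @param net a `contact_bn`.
#' @param node node label.
#' @return character vector of neighboring node labels.
#' @export
markov_neighborhood <- function(net, node) {
  node <- normalize_generic_id(node)
  if (!node %in% net$nodes) stop("unknown node: ", node)
  sort(unique(c(net$parents[[node]],
                net$edges$to[net$edges$from == node])))
}

#' Empirical joint distribution over a node subset
#'
#' Tabulates the binary state vectors of the selected columns over all frames
#' with optional additive smoothing:
#' p(state) = (count + pseudocount) / (n_frames + pseudocount * 2^m).
#'
#' @param data a [fingerprint_matrix()].
#' @param nodes ordered node subset (columns of `data`).
#' @param pseudocount additive smoothing per state (0 = raw frequencies).
#' @param state_cap refuse subsets whose state space exceeds this size.
#' @return a `joint_distribution`: `nodes`, `prob` (length 2^m, state i
#'   encodes node j as bit j-1), `pseudocount`.
#' @export
empirical_joint <- function(data, nodes, pseudocount = 0, state_cap = 2^20) {
  cols <- resolve_columns(data, nodes)
  m <- length(cols)
  if (2^m > state_cap) {
    stop("state space 2^", m, " exceeds cap ", state_cap,
         "; reduce the subgraph")
  }
  n <- nrow(data$values)
  denom <- n + pseudocount * 2^m
  if (denom <= 0) stop("no frames and no pseudocount: distribution undefined")
  code <- as.integer(data$values[, cols, drop = FALSE] %*% 2^(seq_len(m) - 1L))
  counts <- tabulate(code + 1L, nbins = 2^m)
  structure(list(nodes = node_labels(data)[cols],
                 prob = (counts + pseudocount) / denom,
                 pseudocount = pseudocount),
            class = "joint_distribution")
}

#' Jensen-Shannon divergence between two joint distributions
#'
#' JSD(P, Q) = KL(P || M)/2 + KL(Q || M)/2 with M = (P + Q)/2, natural-log
#' base, zero-probability states contributing zero. Bounded in [0, ln 2];
#' symmetric; zero iff P = Q.
#'
#' @param p,q `joint_distribution`s over the same node subset and ordering.
#' @return the divergence in nats.
#' @export
jsd <- function(p, q) {
  if (!identical(p$nodes, q$nodes)) {
    stop("joint distributions are over different node subsets/orderings")
  }
  pp <- p$prob; qq <- q$prob
  m <- (pp + qq) / 2
  kl <- function(a, b) {
    nz <- a > 0
    sum(a[nz] * (log(a[nz]) - log(b[nz])))
  }
  (kl(pp, m) + kl(qq, m)) / 2
}

#' Pairwise JSD matrix over complexes sharing a common subgraph
#'
#' Computes the empirical joint of each dataset over the common subgraph's
#' node set and compares all pairs by Jensen-Shannon divergence. Datasets
#' lacking any subgraph node are excluded and reported via the `excluded`
#' attribute (mirroring the treatment of complexes whose moral graph lacks
#' the common subgraph).
#'
#' @param datasets named list of [fingerprint_matrix()] objects.
#' @param subgraph a `common_subgraph` (or anything with `$nodes`).
#' @param pseudocount smoothing per state passed to [empirical_joint()].
#' @return symmetric numeric matrix with zero diagonal, one row per eligible
#'   dataset; attribute `excluded` lists the dropped dataset names.
#' @export
jsd_matrix <- function(datasets, subgraph, pseudocount = 0.5) {
  stopifnot(length(names(datasets)) == length(datasets))
  nodes <- subgraph$nodes
  if (length(nodes) == 0L) stop("common subgraph has no nodes")
  eligible <- vapply(datasets, function(d) all(nodes %in% node_labels(d)),
                     logical(1L))
  excluded <- names(datasets)[!eligible]
  datasets <- datasets[eligible]
  if (length(datasets) < 2L) {
    stop("fewer than 2 datasets contain the common subgraph (excluded: ",
         paste(excluded, collapse = ", "), ")")
  }
  joints <- lapply(datasets, empirical_joint, nodes = nodes,
                   pseudocount = pseudocount)
  k <- length(joints)
  out <- matrix(0, k, k, dimnames = list(names(datasets), names(datasets)))
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      out[i, j] <- out[j, i] <- jsd(joints[[i]], joints[[j]])
    }
  }
  attr(out, "excluded") <- excluded
  out
}
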