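# Dirichlet-multinomial (BDeu) family scoring for binary contact variables.
#
# The network score is decomposable: it is the sum over nodes of the log
# marginal likelihood of the node's column given its parents' configurations,
# with the equivalent sample size spread uniformly over parameter cells
# (alpha_jk = ess / (r * q) for r = 2 states and q parent configurations).
# This score is score-equivalent: Markov-equivalent DAGs score identically.

# raw BDeu log marginal likelihood; data is an integer 0/1 matrix,
# node/parents are column indices
bdeu_family_score <- function(values, node, parents, ess) {
  n <- nrow(values)
  if (n == 0L) return(0)
  k <- length(parents)
  q <- 2^k
  a_jk <- ess / (2 * q)
  a_j <- ess / q
  x <- values[, node]
  if (k == 0L) {
    cfg <- rep(0L, n)
  } else {
    cfg <- as.integer(values[, parents, drop = FALSE] %*% 2^(seq_len(k) - 1L))
  }
  joint <- tabulate(cfg * 2L + x + 1L, nbins = 2L * q)
  n_jk <- matrix(joint, nrow = 2L) # rows: x = 0, 1; cols: parent config
  n_j <- colSums(n_jk)
  occ <- n_j > 0L # unoccupied configs contribute lgamma(a) - lgamma(a) = 0
  sum(lgamma(a_j) - lgamma(a_j + n_j[occ])) +
    sum(lgamma(a_jk + n_jk[, occ, drop = FALSE]) - lgamma(a_jk))
}

# memoizing wrapper; cache is an environment local to one learning/scoring run
cached_family_score <- function(values, node, parents, ess, cache) {
  key <- if (length(parents)) {
    paste0(node, "|", paste(sort.int(parents), collapse = ","))
  } else {
    paste0(node, "|")
  }
  hit <- cache[[key]]
  if (!is.null(hit)) return(hit)
  val <- bdeu_family_score(values, node, parents, ess)
  cache[[key]] <- val
  val
}

resolve_columns <- function(data, cols) {
  if (is.character(cols)) {
    idx <- match(normalize_generic_id(cols), node_labels(data))
    if (anyNA(idx)) {
      stop("node(s) not in data: ", paste(cols[is.na(idx)], collapse = ", "))
    }
    idx
  } else {
    as.integer(cols)
  }
}

#' BDeu log marginal likelihood of one node given a parent set
#'
#' The decomposable building block of the network score: the Dirichlet-
#' multinomial marginal likelihood of the node's binary column under each
#' configuration of its parents, with `ess` pseudo-observations spread
#' uniformly over parameter cells.
#'
#' @param data a [fingerprint_matrix()].
#' @param node column name or index of the child variable.
#' @param parents column names or indices of the parents (may be empty).
#' @param ess equivalent sample size (> 0).
#' @param max_parents cap on the parent-set size; exceeding it is an error.
#' @return log marginal likelihood (a single number; 0 for zero frames).
#' @export
family_score <- function(data, node, parents = character(0), ess = 1.0,
                         max_parents = Inf) {
  stopifnot(inherits(data, "fingerprint_matrix"), ess > 0)
  node <- resolve_columns(data, node)
  parents <- if (length(parents)) resolve_columns(data, parents) else integer(0)
  if (node %in% parents) stop("node cannot be its own parent")
  if (length(parents) > max_parents) {
    stop("parent set size ", length(parents), " exceeds cap ", max_parents)
  }
  bdeu_family_score(data$values, node, parents, ess)
}

#' Total network score
#'
#' Sum of BDeu family scores over all nodes given their parent sets in the
#' network. Cyclic input is a structure error.
#'
#' @param net a `contact_bn` (or anything with `$nodes` and `$parents`).
#' @param data a [fingerprint_matrix()] containing all network nodes.
#' @param ess equivalent sample size.
#' @return total log marginal likelihood.
#' @export
network_score <- function(net, data, ess = 1.0) {
  cols <- resolve_columns(data, net$nodes)
  parents_idx <- lapply(net$parents, function(p) cols[match(p, net$nodes)])
  if (!is_acyclic_parents(parents_idx)) stop("network is cyclic")
  cache <- new.env(parent = emptyenv())
  total <- 0
  for (i in seq_along(cols)) {
    total <- total + cached_family_score(data$values, cols[i], parents_idx[[i]],
                                         ess, cache)
  }
  total
}

#' Strength of one edge
#'
#' The log ratio of the marginal likelihood of the network with the edge to
#' the network without it, which by decomposability reduces to the child's
#' family-score difference, divided by the number of frames so strengths are
#' comparable across data sets of different length.
#'
#' @param net a `contact_bn` containing the edge.
#' @param data the [fingerprint_matrix()] the network was learned on.
#' @param from,to node labels of the directed edge `from -> to`.
#' @param ess equivalent sample size.
#' @return per-observation log likelihood ratio (positive for edges a
#'   converged score-maximizing search retains).
#' @export
edge_strength <- function(net, data, from, to, ess = 1.0) {
  from <- normalize_generic_id(from); to <- normalize_generic_id(to)
  pa <- net$parents[[match(to, net$nodes)]]
  if (is.null(pa) || !(from %in% pa)) stop("edge not in network: ", from, " -> ", to)
  cols <- resolve_columns(data, net$nodes)
  child <- cols[match(to, net$nodes)]
  pa_idx <- cols[match(pa, net$nodes)]
  with_e <- bdeu_family_score(data$values, child, pa_idx, ess)
  without <- bdeu_family_score(data$values, child,
                               setdiff(pa_idx, cols[match(from, net$nodes)]), ess)
  (with_e - without) / nrow(data$values)
}

# acyclicity by Kahn's algorithm on a parents-list representation
is_acyclic_parents <- function(parents) {
  n <- length(parents)
  indeg <- lengths(parents)
  children <- vector("list", n)
  for (v in seq_len(n)) {
    for (u in parents[[v]]) children[[u]] <- c(children[[u]], v)
  }
  queue <- which(indeg == 0L)
  seen <- 0L
  while (length(queue)) {
    u <- queue[[1L]]; queue <- queue[-1L]
    seen <- seen + 1L
    for (v in children[[u]]) {
      indeg[v] <- indeg[v] - 1L
      if (indeg[v] == 0L) queue <- c(queue, v)
    }
  }
  seen == n
}
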