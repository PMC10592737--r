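# Score-based structure learning: greedy hill climbing over single-edge
# add / delete / reverse moves with random restarts, maximizing the
# decomposable BDeu network score.

# can `dst` be reached from `src` following children links, optionally
# ignoring the single directed edge skip_from -> skip_to?
dag_reachable <- function(children, src, dst, skip_from = 0L, skip_to = 0L) {
  stack <- src
  seen <- logical(length(children))
  while (length(stack)) {
    u <- stack[[length(stack)]]; stack <- stack[-length(stack)]
    if (u == dst) return(TRUE)
    if (seen[u]) next
    seen[u] <- TRUE
    kids <- children[[u]]
    if (u == skip_from) kids <- kids[kids != skip_to]
    stack <- c(stack, kids[!seen[kids]])
  }
  FALSE
}

children_from_parents <- function(parents) {
  children <- vector("list", length(parents))
  for (v in seq_along(parents)) {
    for (u in parents[[v]]) children[[u]] <- c(children[[u]], v)
  }
  lapply(children, function(k) if (is.null(k)) integer(0) else k)
}

# One greedy ascent from a start topology. Moves are enumerated in a fixed
# lexicographic order (child ascending; deletions, additions, reversals; the
# other endpoint ascending) and the first move attaining the maximal score
# gain is taken, which makes the search deterministic given the start.
hill_climb <- function(values, active, parents, ess, max_parents, cache,
                       eps = 1e-9) {
  n <- length(parents)
  fam <- numeric(n)
  for (v in seq_len(n)) {
    fam[v] <- cached_family_score(values, v, parents[[v]], ess, cache)
  }
  children <- children_from_parents(parents)
  repeat {
    best_delta <- eps
    best <- NULL
    for (v in active) {
      pa <- parents[[v]]
      for (u in pa) { # deletions
        d <- cached_family_score(values, v, setdiff(pa, u), ess, cache) - fam[v]
        if (d > best_delta) { best_delta <- d; best <- c(1L, u, v) }
      }
      if (length(pa) < max_parents) { # additions
        for (u in active) {
          if (u == v || u %in% pa) next
          if (dag_reachable(children, v, u)) next
          d <- cached_family_score(values, v, c(pa, u), ess, cache) - fam[v]
          if (d > best_delta) { best_delta <- d; best <- c(2L, u, v) }
        }
      }
      for (u in pa) { # reversals u->v  =>  v->u
        if (length(parents[[u]]) >= max_parents) next
        if (dag_reachable(children, u, v, skip_from = u, skip_to = v)) next
        d <- (cached_family_score(values, v, setdiff(pa, u), ess, cache) - fam[v]) +
          (cached_family_score(values, u, c(parents[[u]], v), ess, cache) - fam[u])
        if (d > best_delta) { best_delta <- d; best <- c(3L, u, v) }
      }
    }
    if (is.null(best)) break
    type <- best[1L]; u <- best[2L]; v <- best[3L]
    if (type == 1L) {
      parents[[v]] <- setdiff(parents[[v]], u)
      children[[u]] <- setdiff(children[[u]], v)
    } else if (type == 2L) {
      parents[[v]] <- c(parents[[v]], u)
      children[[u]] <- c(children[[u]], v)
    } else {
      parents[[v]] <- setdiff(parents[[v]], u)
      children[[u]] <- setdiff(children[[u]], v)
      parents[[u]] <- c(parents[[u]], v)
      children[[v]] <- c(children[[v]], u)
    }
    fam[v] <- cached_family_score(values, v, parents[[v]], ess, cache)
    fam[u] <- cached_family_score(values, u, parents[[u]], ess, cache)
  }
  list(parents = parents, score = sum(fam))
}

# random start DAG over the active nodes: random topological order, each
# forward edge included with probability p, parent sets truncated to the cap
random_start_parents <- function(n, active, p, max_parents) {
  parents <- replicate(n, integer(0), simplify = FALSE)
  m <- length(active)
  if (m < 2L || p <= 0) return(parents)
  ord <- sample(active)
  for (j in 2L:m) {
    cand <- ord[seq_len(j - 1L)]
    pa <- cand[stats::runif(j - 1L) < p]
    if (length(pa) > max_parents) pa <- pa[seq_len(max_parents)]
    parents[[ord[j]]] <- pa
  }
  parents
}

# cheap order-sensitive checksum so learn metadata can witness its input
data_digest <- function(values) {
  v <- as.numeric(values)
  sprintf("%dx%d-%.0f", nrow(values), ncol(values),
          sum(v * (seq_along(v) %% 911)) %% 1e9)
}

#' Learn a Bayesian network over contact variables
#'
#' Greedy hill climbing over add/delete/reverse single-edge moves under the
#' BDeu score, restarted from the empty graph (restart 0) and from random
#' DAGs with per-edge probability 2/(n-1) (remaining restarts). The highest
#' scoring network over all restarts is returned, with per-edge strengths on
#' the per-observation scale. Deterministic given (data, seed, restarts, ess,
#' max_parents). Constant columns are kept as isolated, flagged nodes and
#' never acquire edges.
#'
#' @param data a [fingerprint_matrix()].
#' @param restarts number of random restarts (default 50).
#' @param seed integer RNG seed for the restart topologies.
#' @param ess BDeu equivalent sample size.
#' @param max_parents cap on parent-set size.
#' @return a `contact_bn`: nodes, directed `edges` (with `strength`), parent
#'   sets, total `score`, and learning metadata.
#' @export
learn_structure <- function(data, restarts = 50L, seed = 1L, ess = 1.0,
                            max_parents = 5L) {
  stopifnot(inherits(data, "fingerprint_matrix"), restarts >= 1L, ess > 0)
  values <- data$values
  n <- ncol(values)
  labels <- colnames(values)
  cst <- constant_nodes(data)
  active <- which(!labels %in% cst)
  if (length(active) == 0L) stop("degenerate data: all columns are constant")
  if (length(active) < 2L) stop("need at least 2 non-constant columns")
  if (nrow(values) < 10L) warning("fewer than 10 frames; scores will be noisy")

  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)

  cache <- new.env(parent = emptyenv())
  p_edge <- if (length(active) > 1L) 2 / (length(active) - 1L) else 0
  best <- NULL
  for (r in seq_len(restarts) - 1L) {
    start <- if (r == 0L) {
      replicate(n, integer(0), simplify = FALSE)
    } else {
      random_start_parents(n, active, p_edge, max_parents)
    }
    res <- hill_climb(values, active, start, ess, max_parents, cache)
    if (is.null(best) || res$score > best$score) best <- res
  }

  build_contact_bn(data, best$parents, ess,
                   meta = list(restarts = restarts, seed = seed, ess = ess,
                               max_parents = max_parents,
                               n_frames = nrow(values),
                               constant_nodes = cst,
                               data_digest = data_digest(values)))
}

# assemble the exported network object from an index parents list
build_contact_bn <- function(data, parents_idx, ess, meta = list()) {
  labels <- node_labels(data)
  edges <- do.call(rbind, lapply(seq_along(parents_idx), function(v) {
    if (length(parents_idx[[v]]) == 0L) return(NULL)
    data.frame(from = labels[parents_idx[[v]]], to = labels[v],
               stringsAsFactors = FALSE)
  }))
  if (is.null(edges)) {
    edges <- data.frame(from = character(0), to = character(0),
                        strength = numeric(0), stringsAsFactors = FALSE)
  }
  net <- structure(
    list(nodes = labels,
         edges = edges,
         parents = stats::setNames(
           lapply(parents_idx, function(p) labels[p]), labels),
         score = NA_real_, score_per_obs = NA_real_, meta = meta),
    class = "contact_bn")
  net$score <- network_score(net, data, ess)
  net$score_per_obs <- if (nrow(data$values) > 0L) net$score / nrow(data$values) else 0
  if (nrow(net$edges) > 0L) {
    net$edges$strength <- vapply(seq_len(nrow(net$edges)), function(i) {
      edge_strength(net, data, net$edges$from[i], net$edges$to[i], ess)
    }, numeric(1L))
    ord <- order(net$edges$from, net$edges$to)
    net$edges <- net$edges[ord, , drop = FALSE]
    rownames(net$edges) <- NULL
  }
  net
}

#' Construct a Bayesian network from an explicit edge list
#'
#' Builds a `contact_bn` over the columns of `data` with the given directed
#' edges, computing strengths and the total score. Useful for rescoring fixed
#' or hand-specified topologies.
#'
#' @param data a [fingerprint_matrix()].
#' @param edges two-column matrix/data.frame of node labels (`from`, `to`).
#' @param ess BDeu equivalent sample size.
#' @param meta optional metadata list.
#' @return a `contact_bn`.
#' @export
contact_bn <- function(data, edges, ess = 1.0, meta = list()) {
  labels <- node_labels(data)
  parents_idx <- replicate(length(labels), integer(0), simplify = FALSE)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(edges)) {
    from <- match(normalize_generic_id(edges[[1L]]), labels)
    to <- match(normalize_generic_id(edges[[2L]]), labels)
    if (anyNA(from) || anyNA(to)) stop("edge endpoint not among data columns")
    for (i in seq_along(from)) {
      parents_idx[[to[i]]] <- union(parents_idx[[to[i]]], from[i])
    }
  }
  if (!is_acyclic_parents(parents_idx)) stop("edge list is cyclic")
  build_contact_bn(data, parents_idx, ess, meta)
}

#' @export
print.contact_bn <- function(x, ...) {
  cat(sprintf("<contact_bn> %d nodes, %d edges, score %.3f (%.5f/frame)\n",
              length(x$nodes), nrow(x$edges), x$score, x$score_per_obs))
  if (length(x$meta$constant_nodes)) {
    cat("constant (isolated) nodes:",
        paste(x$meta$constant_nodes, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Enumerate every DAG on n labeled nodes
#'
#' Each unordered node pair independently carries no edge or one of the two
#' orientations; cyclic assignments are discarded. With n = 3 this yields the
#' 25 possible DAGs. Intended for exhaustive-search oracles on small n.
#'
#' @param n number of labeled nodes (kept small; 3^(n(n-1)/2) assignments).
#' @return list of parents-lists (each a list of integer parent vectors).
#' @export
enumerate_dags <- function(n) {
  stopifnot(n >= 1L, n <= 5L)
  pairs <- if (n >= 2L) utils::combn(n, 2L) else matrix(integer(0), nrow = 2L)
  m <- ncol(pairs)
  out <- list()
  for (code in seq_len(3^m) - 1L) {
    parents <- replicate(n, integer(0), simplify = FALSE)
    c0 <- code
    for (j in seq_len(m)) {
      state <- c0 %% 3L; c0 <- c0 %/% 3L
      a <- pairs[1L, j]; b <- pairs[2L, j]
      if (state == 1L) parents[[b]] <- c(parents[[b]], a)
      if (state == 2L) parents[[a]] <- c(parents[[a]], b)
    }
    if (is_acyclic_parents(parents)) out[[length(out) + 1L]] <- parents
  }
  out
}

#' Best score over all DAGs on the data's nodes, by exhaustive enumeration
#'
#' Scores every DAG from [enumerate_dags()] with the BDeu network score and
#' returns the maximum. An independent oracle for the hill-climbing search on
#' tiny problems.
#'
#' @param data a [fingerprint_matrix()] with at most 5 columns.
#' @param ess BDeu equivalent sample size.
#' @return list with `score` (the global maximum) and `n_dags` enumerated.
#' @export
exhaustive_best_score <- function(data, ess = 1.0) {
  values <- data$values
  n <- ncol(values)
  dags <- enumerate_dags(n)
  cache <- new.env(parent = emptyenv())
  best <- -Inf
  for (parents in dags) {
    s <- 0
    for (v in seq_len(n)) {
      s <- s + cached_family_score(values, v, parents[[v]], ess, cache)
    }
    if (s > best) best <- s
  }
  list(score = best, n_dags = length(dags))
}
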