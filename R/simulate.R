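# Synthetic fixtures: fingerprint matrices sampled from a known planted
# dependency structure, plus toy coordinates, regions and conservation flags,
# so every pipeline stage is testable without trajectory data.

RECEPTOR_REGIONS <- c("TM1", "TM2", "TM3", "TM4", "TM5", "TM6", "TM7",
                      "H8", "ICL1", "ICL2", "ICL3")
GPROTEIN_REGIONS <- c("N-term", "hns1", "b2b3", "b6", "hgh4", "core-other",
                      "a5-core", "a5-tip")

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr)) # use (and advance) the current RNG
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  force(expr)
}

#' Sample a random DAG
#'
#' Orders the nodes uniformly at random and includes each forward edge with
#' probability `edge_prob`, truncating parent sets to `max_parents`.
#'
#' @param n_nodes number of nodes.
#' @param edge_prob probability of each forward edge.
#' @param max_parents cap on parent-set size.
#' @param seed optional RNG seed (NULL uses the current RNG state).
#' @return list with `parents` (list of integer parent vectors) and `order`
#'   (the sampled topological order).
#' @export
sample_random_dag <- function(n_nodes, edge_prob, max_parents = Inf,
                              seed = NULL) {
  stopifnot(n_nodes >= 1L, edge_prob >= 0, edge_prob <= 1)
  with_seed(seed, {
    parents <- replicate(n_nodes, integer(0), simplify = FALSE)
    ord <- sample.int(n_nodes)
    if (n_nodes >= 2L && edge_prob > 0) {
      for (j in 2L:n_nodes) {
        cand <- ord[seq_len(j - 1L)]
        pa <- cand[stats::runif(j - 1L) < edge_prob]
        if (length(pa) > max_parents) pa <- pa[seq_len(max_parents)]
        parents[[ord[j]]] <- pa
      }
    }
    list(parents = parents, order = ord)
  })
}

#' Planted generative model over binary contact variables
#'
#' Builds explicit conditional probability tables from a noisy-OR rule:
#' a child is the OR of its parents' values, flipped with probability `flip`
#' (so a single-parent child copies its parent with probability 1 - flip);
#' roots are Bernoulli(`p_root`). Explicit per-node CPTs may be supplied
#' instead (vector of P(value = 1) per parent configuration, parents ordered
#' as given, first parent = least significant bit).
#'
#' @param parents list of integer parent vectors defining the DAG.
#' @param nodes node names (default n1..nN).
#' @param n_frames frames to sample.
#' @param seed RNG seed used by [sample_fingerprints()].
#' @param flip noisy-OR flip probability.
#' @param p_root P(1) for parentless nodes.
#' @param cpts optional named list of explicit CPT vectors.
#' @return a `planted_model`.
#' @export
planted_model <- function(parents, nodes = NULL, n_frames = 5000L, seed = 1L,
                          flip = 0.1, p_root = 0.5, cpts = NULL) {
  n <- length(parents)
  if (is.null(nodes)) nodes <- paste0("n", seq_len(n))
  stopifnot(length(nodes) == n, flip >= 0, flip <= 1, p_root >= 0, p_root <= 1)
  if (!is_acyclic_parents(parents)) stop("planted structure must be a DAG")
  full_cpts <- vector("list", n)
  for (v in seq_len(n)) {
    k <- length(parents[[v]])
    if (!is.null(cpts) && !is.null(cpts[[nodes[v]]])) {
      cpt <- cpts[[nodes[v]]]
      if (length(cpt) != 2^k) stop("CPT for ", nodes[v], " must have 2^", k,
                                   " entries")
      full_cpts[[v]] <- cpt
    } else if (k == 0L) {
      full_cpts[[v]] <- p_root
    } else {
      cfg <- seq_len(2^k) - 1L
      any_on <- cfg > 0L # OR of parent bits
      full_cpts[[v]] <- ifelse(any_on, 1 - flip, flip)
    }
  }
  structure(list(nodes = nodes, parents = parents, cpts = full_cpts,
                 n_frames = as.integer(n_frames), seed = as.integer(seed),
                 flip = flip, p_root = p_root),
            class = "planted_model")
}

topological_order <- function(parents) {
  n <- length(parents)
  indeg <- lengths(parents)
  children <- children_from_parents(parents)
  queue <- which(indeg == 0L)
  out <- integer(0)
  while (length(queue)) {
    u <- queue[[1L]]; queue <- queue[-1L]
    out <- c(out, u)
    for (v in children[[u]]) {
      indeg[v] <- indeg[v] - 1L
      if (indeg[v] == 0L) queue <- c(queue, v)
    }
  }
  if (length(out) != n) stop("not a DAG")
  out
}

#' Sample a fingerprint matrix from a planted model
#'
#' Ancestral sampling of `n_frames` independent binary vectors, deterministic
#' given the model's seed.
#'
#' @param model a [planted_model()].
#' @return a [fingerprint_matrix()].
#' @export
sample_fingerprints <- function(model) {
  stopifnot(inherits(model, "planted_model"))
  n <- length(model$nodes)
  nf <- model$n_frames
  with_seed(model$seed, {
    vals <- matrix(0L, nrow = nf, ncol = n, dimnames = list(NULL, model$nodes))
    for (v in topological_order(model$parents)) {
      pa <- model$parents[[v]]
      k <- length(pa)
      p <- if (k == 0L) rep(model$cpts[[v]], nf) else {
        cfg <- as.integer(vals[, pa, drop = FALSE] %*% 2^(seq_len(k) - 1L))
        model$cpts[[v]][cfg + 1L]
      }
      vals[, v] <- as.integer(stats::runif(nf) < p)
    }
    fingerprint_matrix(vals, provenance = sprintf(
      "planted model (%d nodes, seed %d)", n, model$seed))
  })
}

#' Undirected skeleton F1 score against a planted structure
#'
#' Precision/recall/F1 of the learned network's undirected edge set against
#' the planted DAG's skeleton (edge direction ignored, since it is not
#' identifiable from observational data under a score-equivalent criterion).
#'
#' @param net a `contact_bn` (or `moral_graph`... anything with `$edges`).
#' @param true_edges two-column matrix/data.frame of planted edges (labels).
#' @return list `precision`, `recall`, `f1`, `tp`, `fp`, `fn`.
#' @export
skeleton_f1 <- function(net, true_edges) {
  canon <- function(a, b) {
    swap <- a > b
    tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
    unique(paste(a, b, sep = "\r"))
  }
  learned <- if (inherits(net, "moral_graph")) {
    canon(net$edges$a, net$edges$b)
  } else if (nrow(net$edges)) {
    canon(net$edges$from, net$edges$to)
  } else character(0)
  true_edges <- as.data.frame(true_edges, stringsAsFactors = FALSE)
  truth <- if (nrow(true_edges)) canon(true_edges[[1L]], true_edges[[2L]]) else
    character(0)
  tp <- length(intersect(learned, truth))
  fp <- length(setdiff(learned, truth))
  fn <- length(setdiff(truth, learned))
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  list(precision = precision, recall = recall, f1 = f1, tp = tp, fp = fp, fn = fn)
}

#' Complete synthetic interface fixture
#'
#' Emulates one GPCR:G protein complex end to end: contact nodes assigned to
#' receptor x G-protein residue pairs, residues assigned round-robin to the
#' standard region inventories, C-alpha coordinates placed on a 3-D lattice
#' wide enough that both neighboring (<= 10 A) and allosteric (> 10 A) node
#' pairs exist, a planted hub node with several strong dependencies, noisy-OR
#' conditionals, and alternating G-protein residues marked unconserved.
#'
#' @param n_receptor_res,n_gprot_res residues per side.
#' @param n_nodes contact nodes (<= n_receptor_res * n_gprot_res).
#' @param n_frames frames to sample.
#' @param seed RNG seed (fully determines the bundle).
#' @param flip noisy-OR flip probability of the planted conditionals.
#' @param hub_children number of children planted under the hub node.
#' @param edge_prob edge probability of the random background DAG.
#' @return a `fixture_bundle`: `fingerprints`, `model`, `edges` (planted,
#'   labels), `hub`, `ca_coords`, `regions`, `conserved`, `seed`.
#' @export
make_interface_fixture <- function(n_receptor_res = 10L, n_gprot_res = 8L,
                                   n_nodes = 20L, n_frames = 5000L, seed = 1L,
                                   flip = 0.1, hub_children = 5L,
                                   edge_prob = 0.08) {
  stopifnot(n_nodes <= n_receptor_res * n_gprot_res, n_nodes >= 2L)
  with_seed(seed, {
    rec_ids <- vapply(seq_len(n_receptor_res), function(i) {
      sprintf("%d%s%d", ((i - 1L) %% 7L) + 1L, BW_TIMES, 40L + i)
    }, character(1L))
    gp_ids <- sprintf("G.X%d.%02d", ((seq_len(n_gprot_res) - 1L) %% 4L) + 1L,
                      10L + seq_len(n_gprot_res))
    regions <- c(
      stats::setNames(rep_len(RECEPTOR_REGIONS, n_receptor_res), rec_ids),
      stats::setNames(rep_len(GPROTEIN_REGIONS, n_gprot_res), gp_ids))
    conserved <- stats::setNames(seq_len(n_gprot_res) %% 2L == 0L, gp_ids)

    # C-alpha lattice: receptor along x at y = 0, G protein along x at y = 4;
    # 4 A spacing guarantees pairs on both sides of the 10 A split
    ca <- data.frame(
      generic_id = c(rec_ids, gp_ids),
      x = c(4 * seq_len(n_receptor_res), 4 * seq_len(n_gprot_res)),
      y = c(rep(0, n_receptor_res), rep(4, n_gprot_res)),
      z = 0, stringsAsFactors = FALSE)

    # contact nodes = distinct residue pairs
    grid <- expand.grid(r = seq_len(n_receptor_res), g = seq_len(n_gprot_res))
    pick <- sample.int(nrow(grid), n_nodes)
    labels <- contact_node_id(rec_ids[grid$r[pick]], gp_ids[grid$g[pick]])

    # planted DAG: a hub (node 1) with strong children, random edges elsewhere
    hub <- 1L
    parents <- replicate(n_nodes, integer(0), simplify = FALSE)
    kids <- 1L + sample.int(n_nodes - 1L, hub_children)
    for (v in kids) parents[[v]] <- hub
    rest <- setdiff(seq_len(n_nodes), c(hub, kids))
    if (length(rest) >= 2L) {
      sub <- sample_random_dag(length(rest), edge_prob, max_parents = 2L)
      for (j in seq_along(rest)) {
        parents[[rest[j]]] <- union(parents[[rest[j]]], rest[sub$parents[[j]]])
      }
    }
    # keep the hub's planted degree strictly maximal
    degree <- function(pl) {
      d <- lengths(pl)
      for (v in seq_along(pl)) for (u in pl[[v]]) d[u] <- d[u] + 1L
      d
    }
    repeat {
      d <- degree(parents)
      rival <- which(d >= d[hub] & seq_len(n_nodes) != hub)
      rival <- rival[vapply(rival, function(v) length(setdiff(parents[[v]], hub)) > 0L,
                            logical(1L))]
      if (length(rival) == 0L) break
      v <- rival[1L]
      parents[[v]] <- parents[[v]][-match(setdiff(parents[[v]], hub)[1L], parents[[v]])]
    }

    model <- planted_model(parents, nodes = labels, n_frames = n_frames,
                           seed = sample.int(2^30, 1L), flip = flip)
    fp <- sample_fingerprints(model)
    edges <- do.call(rbind, lapply(seq_len(n_nodes), function(v) {
      if (!length(parents[[v]])) return(NULL)
      data.frame(from = labels[parents[[v]]], to = labels[v],
                 stringsAsFactors = FALSE)
    }))
    structure(list(fingerprints = fp, model = model, edges = edges,
                   hub = labels[hub], ca_coords = ca, regions = regions,
                   conserved = conserved, seed = seed),
              class = "fixture_bundle")
  })
}

#' Write a fixture bundle as a plain-text directory
#'
#' Emits everything a pipeline run needs: fingerprint TSV, residue mapping
#' TSV (synthetic author numbering), region TSV, conservation TSV, C-alpha
#' coordinates as a PDB file (synthetic lattice, receptor chain R, G protein
#' chain G), and the planted model as JSON.
#'
#' @param bundle a `fixture_bundle`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fingerprint_table(bundle$fingerprints, file.path(dir, "fingerprints.tsv"))
  ids <- bundle$ca_coords$generic_id
  is_gp <- startsWith(ids, "G.")
  mapping <- data.frame(chain = ifelse(is_gp, "G", "R"),
                        resid = seq_along(ids),
                        role = ifelse(is_gp, "gprotein", "receptor"),
                        generic_id = ids)
  utils::write.table(mapping, file.path(dir, "mapping.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  utils::write.table(
    data.frame(generic_id = names(bundle$regions), region = bundle$regions),
    file.path(dir, "regions.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE, fileEncoding = "UTF-8")
  utils::write.table(
    data.frame(generic_id = names(bundle$conserved),
               conserved = as.integer(bundle$conserved)),
    file.path(dir, "conserved.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE, fileEncoding = "UTF-8")
  pdb_lines <- vapply(seq_along(ids), function(i) {
    sprintf("ATOM  %5d  CA  GLY %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            i, ifelse(is_gp[i], "G", "R"), i, bundle$ca_coords$x[i],
            bundle$ca_coords$y[i], bundle$ca_coords$z[i])
  }, character(1L))
  writeLines(c(pdb_lines, "END"), file.path(dir, "calpha.pdb"))
  jsonlite::write_json(
    list(nodes = bundle$model$nodes,
         edges = bundle$edges, hub = bundle$hub,
         flip = bundle$model$flip, p_root = bundle$model$p_root,
         n_frames = bundle$model$n_frames, seed = bundle$seed),
    file.path(dir, "model.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
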