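# Allosteric edge classification and the two robustness protocols:
# random topology perturbation and frame resampling.

#' Classify network edges as neighboring or allosteric
#'
#' An edge links two contact nodes, i.e. four residues (two receptor, two
#' G protein). The edge distance is computed from the reference C-alpha
#' coordinates over the four cross residue pairs (receptor_u-receptor_v,
#' receptor_u-gprotein_v, gprotein_u-receptor_v, gprotein_u-gprotein_v),
#' excluding pairs of identical residues: the minimum by default (`mean` and
#' `centroid` are selectable). Edges at or under the cutoff (default 10 A)
#' are `neighboring`, farther ones `allosteric`.
#'
#' @param net a `contact_bn` (or `moral_graph`).
#' @param ca_coords data.frame with columns `generic_id`, `x`, `y`, `z`
#'   giving one C-alpha position per residue, or a 3-column matrix with
#'   generic ids as rownames.
#' @param cutoff neighboring/allosteric split distance in Angstrom.
#' @param mode `"min"`, `"mean"` or `"centroid"` cross-pair summary.
#' @return data.frame `from`, `to`, `distance`, `class`.
#' @export
classify_edges <- function(net, ca_coords, cutoff = 10.0,
                           mode = c("min", "mean", "centroid")) {
  mode <- match.arg(mode)
  if (is.matrix(ca_coords)) {
    ca_coords <- data.frame(generic_id = rownames(ca_coords),
                            x = ca_coords[, 1L], y = ca_coords[, 2L],
                            z = ca_coords[, 3L], stringsAsFactors = FALSE)
  }
  ids <- normalize_generic_id(ca_coords$generic_id)
  co <- coords_of(ca_coords)
  rownames(co) <- ids
  edges <- if (inherits(net, "moral_graph")) {
    data.frame(from = net$edges$a, to = net$edges$b, stringsAsFactors = FALSE)
  } else {
    net$edges[, c("from", "to"), drop = FALSE]
  }
  residues <- function(node) unlist(parse_contact_node_id(node)[, c("receptor_id", "gprotein_id")])
  need <- unique(unlist(lapply(unique(c(edges$from, edges$to)), residues)))
  missing_res <- setdiff(need, ids)
  if (length(missing_res)) {
    stop("no C-alpha coordinate for residue(s): ",
         paste(missing_res, collapse = ", "))
  }
  dist_class <- function(u, v) {
    ru <- residues(u); rv <- residues(v)
    pairs <- rbind(c(ru[1L], rv[1L]), c(ru[1L], rv[2L]),
                   c(ru[2L], rv[1L]), c(ru[2L], rv[2L]))
    pairs <- pairs[pairs[, 1L] != pairs[, 2L], , drop = FALSE]
    if (mode == "centroid") {
      cu <- colMeans(co[ru, , drop = FALSE])
      cv <- colMeans(co[rv, , drop = FALSE])
      return(sqrt(sum((cu - cv)^2)))
    }
    dd <- sqrt(rowSums((co[pairs[, 1L], , drop = FALSE] -
                          co[pairs[, 2L], , drop = FALSE])^2))
    if (mode == "min") min(dd) else mean(dd)
  }
  d <- vapply(seq_len(nrow(edges)), function(i) dist_class(edges$from[i], edges$to[i]),
              numeric(1L))
  data.frame(from = edges$from, to = edges$to, distance = d,
             class = ifelse(d <= cutoff, "neighboring", "allosteric"),
             stringsAsFactors = FALSE)
}

robustness_report <- function(protocol, original_score, trial_scores, seed,
                              ci_level = NA_real_) {
  rep <- list(protocol = protocol,
              n_trials = length(trial_scores),
              original_score = original_score,
              trial_scores = trial_scores,
              fraction_below_original = mean(trial_scores < original_score),
              ci_level = ci_level,
              ci_bounds = c(NA_real_, NA_real_),
              original_within_ci = NA,
              seed = seed)
  if (!is.na(ci_level)) {
    a <- (1 - ci_level) / 2
    rep$ci_bounds <- unname(stats::quantile(trial_scores, c(a, 1 - a), type = 1))
    rep$original_within_ci <- original_score >= rep$ci_bounds[1L] &&
      original_score <= rep$ci_bounds[2L]
  }
  class(rep) <- "robustness_report"
  rep
}

#' @export
print.robustness_report <- function(x, ...) {
  cat(sprintf("<robustness_report> %s: %d trials, original score %.4f\n",
              x$protocol, x$n_trials, x$original_score))
  cat(sprintf("fraction of trials below original: %.4f\n",
              x$fraction_below_original))
  if (!is.na(x$ci_level)) {
    cat(sprintf("%.2f CI of trial scores: [%.4f, %.4f]; original within: %s\n",
                x$ci_level, x$ci_bounds[1L], x$ci_bounds[2L],
                x$original_within_ci))
  }
  invisible(x)
}

#' Topology perturbation test
#'
#' Applies small random local perturbations (by default 2 random edge
#' additions/removals, acyclicity preserved, illegal draws resampled) to the
#' learned topology, rescores each perturbed network on the same data, and
#' reports the fraction of perturbed scores that fall strictly below the
#' original. For a model close to the score optimum this fraction is near 1.
#'
#' @param net the learned `contact_bn`.
#' @param data the [fingerprint_matrix()] it was learned on.
#' @param n number of perturbation trials.
#' @param seed RNG seed.
#' @param move_budget edge moves per trial (0 reproduces the original score).
#' @param ess BDeu equivalent sample size (defaults to the network's).
#' @return a `robustness_report` with protocol `"perturbation"`.
#' @export
perturbation_test <- function(net, data, n = 1000L, seed = 1L,
                              move_budget = 2L, ess = NULL) {
  if (n < 1L) stop("need at least one perturbation trial")
  if (move_budget < 0L) stop("move_budget must be >= 0")
  if (is.null(ess)) ess <- net$meta$ess %||% 1.0
  labels <- node_labels(data)
  cols <- seq_along(labels)
  parents0 <- lapply(net$parents[labels], function(p) match(p, labels))
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  cache <- new.env(parent = emptyenv())
  score_parents <- function(parents) {
    s <- 0
    for (v in cols) s <- s + cached_family_score(data$values, v, parents[[v]], ess, cache)
    s
  }
  original <- score_parents(parents0)
  nn <- length(labels)
  if (nn < 2L) stop("network too small to perturb")
  trial_scores <- numeric(n)
  for (t in seq_len(n)) {
    parents <- parents0
    children <- children_from_parents(parents)
    moves_done <- 0L
    tries <- 0L
    while (moves_done < move_budget) {
      tries <- tries + 1L
      if (tries > 10000L) stop("no legal perturbation found; degenerate network")
      uv <- sample.int(nn, 2L)
      u <- uv[1L]; v <- uv[2L]
      if (u %in% parents[[v]]) {
        parents[[v]] <- setdiff(parents[[v]], u)
        children[[u]] <- setdiff(children[[u]], v)
      } else if (!dag_reachable(children, v, u)) {
        parents[[v]] <- c(parents[[v]], u)
        children[[u]] <- c(children[[u]], v)
      } else {
        next
      }
      moves_done <- moves_done + 1L
    }
    trial_scores[t] <- score_parents(parents)
  }
  robustness_report("perturbation", original, trial_scores, seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Frame-resampling sensitivity test
#'
#' Resamples the frames with replacement to the original frame count `n`
#' times, rescores the fixed network topology on each resample (per frame, so
#' scores are comparable), and checks whether the original per-frame score
#' lies within the empirical confidence interval of the resampled scores.
#'
#' @param net the `contact_bn` whose topology is held fixed.
#' @param data the [fingerprint_matrix()] (>= 10 frames).
#' @param n number of resampling trials.
#' @param seed RNG seed.
#' @param ci confidence level in (0, 1) for the empirical interval.
#' @param ess BDeu equivalent sample size (defaults to the network's).
#' @return a `robustness_report` with protocol `"sensitivity"`.
#' @export
sensitivity_test <- function(net, data, n = 1000L, seed = 1L, ci = 0.99,
                             ess = NULL) {
  if (ci <= 0 || ci >= 1) stop("ci must lie strictly inside (0, 1)")
  if (nrow(data$values) < 10L) stop("need at least 10 frames")
  if (n < 1L) stop("need at least one resampling trial")
  if (is.null(ess)) ess <- net$meta$ess %||% 1.0
  labels <- node_labels(data)
  nf <- nrow(data$values)
  # precompute per-family joint state codes so each trial is a tabulate()
  fams <- lapply(labels, function(v) {
    vi <- match(v, labels)
    pa <- match(net$parents[[v]], labels)
    k <- length(pa)
    cfg <- if (k == 0L) rep(0L, nf) else
      as.integer(data$values[, pa, drop = FALSE] %*% 2^(seq_len(k) - 1L))
    list(code = cfg * 2L + data$values[, vi] + 1L, q = 2^k)
  })
  score_idx <- function(idx) {
    s <- 0
    for (f in fams) {
      tb <- tabulate(f$code[idx], nbins = 2L * f$q)
      n_jk <- matrix(tb, nrow = 2L)
      n_j <- colSums(n_jk)
      occ <- n_j > 0L
      a_jk <- ess / (2 * f$q); a_j <- ess / f$q
      s <- s + sum(lgamma(a_j) - lgamma(a_j + n_j[occ])) +
        sum(lgamma(a_jk + n_jk[, occ, drop = FALSE]) - lgamma(a_jk))
    }
    s / length(idx)
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  original <- score_idx(seq_len(nf))
  trial_scores <- vapply(seq_len(n), function(t) {
    score_idx(sample.int(nf, nf, replace = TRUE))
  }, numeric(1L))
  robustness_report("sensitivity", original, trial_scores, seed, ci_level = ci)
}
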