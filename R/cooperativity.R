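#' Node strengths (cooperativity) of a learned network
#'
#' The cooperativity of a contact node is the sum of the strengths of all
#' edges incident to it, regardless of direction. High values mark contacts
#' whose presence co-varies with many others.
#'
#' @param net a `contact_bn`.
#' @return named numeric vector over all network nodes (0 for isolated ones).
#' @export
node_strengths <- function(net) {
  out <- stats::setNames(numeric(length(net$nodes)), net$nodes)
  if (nrow(net$edges)) {
    for (i in seq_len(nrow(net$edges))) {
      s <- net$edges$strength[i]
      out[net$edges$from[i]] <- out[net$edges$from[i]] + s
      out[net$edges$to[i]] <- out[net$edges$to[i]] + s
    }
  }
  out
}

#' Rank nodes by cooperativity and flag the top quartile
#'
#' Sorts nodes by descending strength (ties broken by node label) and flags
#' the `ceiling(q * N)` strongest. Optional polarity and region annotations
#' are carried into the table.
#'
#' @param strengths named strength vector from [node_strengths()].
#' @param q fraction of nodes to flag (default 0.25, the top quartile).
#' @param polarity optional named vector ("polar"/"nonpolar") per node.
#' @param regions optional named region vector (generic_id -> region) used to
#'   annotate both residues of each node.
#' @return data.frame of class `cooperativity_table`: `node`, `receptor_id`,
#'   `gprotein_id`, `node_strength`, `polarity`, `receptor_region`,
#'   `gprotein_region`, `rank`, `top_quartile`.
#' @export
rank_top_quartile <- function(strengths, q = 0.25, polarity = NULL,
                              regions = NULL) {
  if (length(strengths) < 1L) stop("need at least one node")
  if (q <= 0 || q > 1) stop("quartile fraction must lie in (0, 1]")
  ord <- order(-strengths, names(strengths))
  nodes <- names(strengths)[ord]
  parts <- parse_contact_node_id(nodes)
  n_flag <- ceiling(q * length(nodes))
  tab <- data.frame(
    node = nodes,
    receptor_id = parts$receptor_id,
    gprotein_id = parts$gprotein_id,
    node_strength = unname(strengths[ord]),
    polarity = if (is.null(polarity)) NA_character_ else unname(polarity[nodes]),
    receptor_region = NA_character_,
    gprotein_region = NA_character_,
    rank = seq_along(nodes),
    top_quartile = seq_along(nodes) <= n_flag,
    stringsAsFactors = FALSE)
  if (!is.null(regions)) {
    tab$receptor_region <- lookup_region(regions, tab$receptor_id)
    tab$gprotein_region <- lookup_region(regions, tab$gprotein_id)
  }
  class(tab) <- c("cooperativity_table", "data.frame")
  tab
}

lookup_region <- function(regions, ids) {
  r <- unname(regions[ids])
  if (anyNA(r)) {
    stop("generic_id(s) without a region: ",
         paste(unique(ids[is.na(r)]), collapse = ", "))
  }
  r
}

#' Aggregate cooperative contacts over structural regions
#'
#' Cross-tabulates the top-quartile (cooperative) nodes by receptor region x
#' G-protein region, optionally restricted by polarity. Two normalizations
#' per G-protein region are emitted: `fraction` divides each cell by that
#' region's total cooperative contacts (rows sum to 1 wherever the region has
#' a flagged node), and `fraction_of_all` divides by all of the region's
#' contacts in the table, cooperative or not.
#'
#' @param table a `cooperativity_table` with region annotations.
#' @param regions optional region vector to (re)annotate the table.
#' @param polarity `"all"`, `"polar"` or `"nonpolar"` filter on flagged nodes.
#' @return list with matrices `counts`, `fraction`, `fraction_of_all`
#'   (G-protein regions in rows, receptor regions in columns).
#' @export
aggregate_by_region <- function(table, regions = NULL,
                                polarity = c("all", "polar", "nonpolar")) {
  polarity <- match.arg(polarity)
  if (!is.null(regions)) {
    table$receptor_region <- lookup_region(regions, table$receptor_id)
    table$gprotein_region <- lookup_region(regions, table$gprotein_id)
  }
  if (anyNA(table$receptor_region) || anyNA(table$gprotein_region)) {
    stop("table lacks region annotations; supply `regions`")
  }
  keep_pol <- if (polarity == "all") rep(TRUE, nrow(table)) else
    !is.na(table$polarity) & table$polarity == polarity
  gp_levels <- sort(unique(table$gprotein_region))
  rec_levels <- sort(unique(table$receptor_region))
  flagged <- table[table$top_quartile & keep_pol, , drop = FALSE]
  counts <- table(factor(flagged$gprotein_region, levels = gp_levels),
                  factor(flagged$receptor_region, levels = rec_levels))
  counts <- unclass(as.matrix(counts))
  row_coop <- rowSums(counts)
  all_by_gp <- table(factor(table$gprotein_region[keep_pol], levels = gp_levels))
  fraction <- sweep(counts, 1L, pmax(row_coop, 1L), "/")
  fraction[row_coop == 0L, ] <- 0
  fraction_of_all <- sweep(counts, 1L, pmax(as.numeric(all_by_gp), 1), "/")
  list(counts = counts, fraction = fraction, fraction_of_all = fraction_of_all)
}

#' G-protein region selectivity scores
#'
#' For each G-protein region, the mean node strength over nodes that are both
#' in the top cooperativity quartile and formed by an unconserved G-protein
#' residue. Regions with no qualifying node are reported with a null (NA)
#' score, never dropped.
#'
#' @param table a `cooperativity_table` with `gprotein_region` annotations.
#' @param conserved named logical vector (generic_id -> TRUE when conserved
#'   across G-protein subtypes), covering every G-protein residue in the table.
#' @return data.frame `region`, `cooperativity_score`, `n_contributing_residues`.
#' @export
region_selectivity_scores <- function(table, conserved) {
  if (anyNA(table$gprotein_region)) stop("table lacks G-protein region annotations")
  flags <- conserved[table$gprotein_id]
  if (anyNA(flags)) {
    stop("missing conservation flag for: ",
         paste(unique(table$gprotein_id[is.na(flags)]), collapse = ", "))
  }
  qualifying <- table$top_quartile & !flags
  regions <- sort(unique(table$gprotein_region))
  out <- data.frame(
    region = regions,
    cooperativity_score = NA_real_,
    n_contributing_residues = 0L,
    stringsAsFactors = FALSE)
  for (i in seq_along(regions)) {
    sel <- qualifying & table$gprotein_region == regions[i]
    out$n_contributing_residues[i] <- sum(sel)
    if (any(sel)) out$cooperativity_score[i] <- mean(table$node_strength[sel])
  }
  class(out) <- c("selectivity_scores", "data.frame")
  out
}

#' Correlate region selectivity scores with experimental coupling changes
#'
#' Pairs the computed region scores with measured coupling changes (e.g.
#' delta-log EC50 of region-swapped chimeras) over the regions present in
#' both, excluding null scores, and reports both Pearson and Spearman
#' correlations.
#'
#' @param scores a `selectivity_scores` data.frame.
#' @param measured named numeric vector (region -> coupling change).
#' @return list: `pearson`, `spearman`, `pairs` (the paired table),
#'   `excluded` (regions dropped for null scores or absence from `measured`).
#' @export
correlate_with_coupling <- function(scores, measured) {
  common <- intersect(scores$region, names(measured))
  sub <- scores[scores$region %in% common & !is.na(scores$cooperativity_score), ,
                drop = FALSE]
  excluded <- setdiff(scores$region, sub$region)
  if (nrow(sub) < 3L) {
    stop("fewer than 3 paired regions with non-null scores (have ",
         nrow(sub), ")")
  }
  x <- sub$cooperativity_score
  y <- unname(measured[sub$region])
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: constant scores or measurements")
  }
  list(
    pearson = stats::cor(x, y, method = "pearson"),
    spearman = stats::cor(x, y, method = "spearman"),
    pairs = data.frame(region = sub$region, cooperativity_score = x,
                       measured = y, stringsAsFactors = FALSE),
    excluded = excluded)
}
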