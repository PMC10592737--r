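CONTACT_TYPES <- c("salt_bridge", "hydrogen_bond", "cation_pi", "pi_stack", "vdw")

# rows of `atoms` whose (resname, atom) is listed in a typing table
select_typed <- function(atoms, table) {
  keep <- rep(FALSE, nrow(atoms))
  for (rn in names(table)) {
    keep <- keep | (atoms$resname == rn & atoms$atom %in% table[[rn]])
  }
  atoms[keep, , drop = FALSE]
}

residue_key <- function(df) paste(df$chain, df$resid)

# unique residue-pair hits from an atom-level distance test
pair_hits <- function(a, b, dmat, cutoff) {
  hit <- which(dmat < cutoff, arr.ind = TRUE)
  if (nrow(hit) == 0L) return(NULL)
  unique(data.frame(
    chain_a = a$chain[hit[, 1L]], resid_a = a$resid[hit[, 1L]],
    chain_b = b$chain[hit[, 2L]], resid_b = b$resid[hit[, 2L]],
    stringsAsFactors = FALSE))
}

# explicit hydrogens bonded to a donor, or an idealized one placed opposite
# the donor's bonded heavy atoms
donor_hydrogens <- function(atoms, donor_row) {
  res_atoms <- atoms[atoms$chain == donor_row$chain & atoms$resid == donor_row$resid, ,
                     drop = FALSE]
  dpos <- c(donor_row$x, donor_row$y, donor_row$z)
  hyd <- res_atoms[res_atoms$element == "H", , drop = FALSE]
  if (nrow(hyd) > 0L) {
    dd <- cross_dist(matrix(dpos, nrow = 1L), coords_of(hyd))
    hyd <- hyd[dd[1L, ] < 1.25, , drop = FALSE]
    if (nrow(hyd) > 0L) return(coords_of(hyd))
  }
  ante_names <- DONOR_ANTECEDENTS[[donor_row$atom]]
  ante <- res_atoms[res_atoms$atom %in% ante_names, , drop = FALSE]
  if (nrow(ante) == 0L) return(NULL)
  dir <- dpos - colMeans(coords_of(ante))
  n <- sqrt(sum(dir^2))
  if (n == 0) return(NULL)
  matrix(dpos + dir / n, nrow = 1L)
}

# aromatic ring geometries (centroid + plane normal) for one selection
ring_geometries <- function(atoms) {
  keys <- unique(residue_key(atoms[atoms$resname %in% names(AROMATIC_RINGS), ,
                                   drop = FALSE]))
  out <- list()
  for (k in keys) {
    res <- atoms[residue_key(atoms) == k, , drop = FALSE]
    ring_names <- AROMATIC_RINGS[[res$resname[1L]]]
    ring <- res[res$atom %in% ring_names, , drop = FALSE]
    if (nrow(ring) < 3L) next
    geo <- ring_normal(coords_of(ring))
    out[[length(out) + 1L]] <- list(chain = res$chain[1L], resid = res$resid[1L],
                                    centroid = geo$centroid, normal = geo$normal)
  }
  out
}

#' Detect typed interface contacts in one coordinate frame
#'
#' Applies five geometric criteria between every receptor residue and every
#' G-protein residue: salt bridge (anion-cation atom distance below cutoff),
#' hydrogen bond (donor-acceptor distance below cutoff and donor-hydrogen-
#' acceptor deviation from linearity below the angle cutoff, using explicit
#' hydrogens when present and idealized placement otherwise), van der Waals
#' (heavy-atom distance below the Bondi radius sum plus a tolerance; a literal
#' inter-atom-gap rule is selectable via `vdw_gap_mode`), pi-stacking
#' (aromatic centroid distance and inter-plane angle), and cation-pi (cation
#' to ring centroid distance and ring-normal angle). A residue pair may fire
#' several criteria; each firing yields one record.
#'
#' @param atoms atom data.frame for one frame (columns `chain`, `resid`,
#'   `resname`, `atom`, `element`, `x`, `y`, `z`), e.g. one element of
#'   [read_structure_frames()].
#' @param receptor_chains,gprotein_chains chain ids of the two selections.
#' @param config a [contactbn_config()].
#' @return data.frame with one row per (residue pair, interaction type):
#'   columns `receptor_chain`, `receptor_resid`, `gprotein_chain`,
#'   `gprotein_resid`, `type`.
#' @export
detect_contacts <- function(atoms, receptor_chains, gprotein_chains,
                            config = contactbn_config()) {
  if (is.null(atoms$element)) atoms$element <- infer_element(atoms$atom)
  atoms$resname <- toupper(atoms$resname)
  atoms$atom <- toupper(atoms$atom)
  rec <- atoms[atoms$chain %in% receptor_chains, , drop = FALSE]
  gp <- atoms[atoms$chain %in% gprotein_chains, , drop = FALSE]
  if (nrow(rec) == 0L || nrow(gp) == 0L) {
    stop("empty selection: receptor has ", nrow(rec), " atoms, G protein ",
         nrow(gp))
  }
  rec_h <- rec[rec$element != "H", , drop = FALSE]
  gp_h <- gp[gp$element != "H", , drop = FALSE]

  hits <- list()
  add_hits <- function(df, type, swap = FALSE) {
    if (is.null(df) || nrow(df) == 0L) return(invisible())
    rec_side <- if (swap) c("chain_b", "resid_b") else c("chain_a", "resid_a")
    gp_side <- if (swap) c("chain_a", "resid_a") else c("chain_b", "resid_b")
    hits[[length(hits) + 1L]] <<- data.frame(
      receptor_chain = df[[rec_side[1L]]], receptor_resid = df[[rec_side[2L]]],
      gprotein_chain = df[[gp_side[1L]]], gprotein_resid = df[[gp_side[2L]]],
      type = type, stringsAsFactors = FALSE)
  }

  # salt bridges, both charge orientations
  for (swap in c(FALSE, TRUE)) {
    an <- select_typed(if (swap) gp_h else rec_h, SALT_ANIONS)
    ca <- select_typed(if (swap) rec_h else gp_h, SALT_CATIONS)
    if (nrow(an) && nrow(ca)) {
      d <- cross_dist(coords_of(an), coords_of(ca))
      add_hits(pair_hits(an, ca, d, config$salt_bridge_dist), "salt_bridge",
               swap = swap)
    }
  }

  # hydrogen bonds, donor on either side; backbone N donors added on the fly
  backbone_donors <- function(sel) {
    sel[sel$atom == "N" & sel$resname != "PRO", , drop = FALSE]
  }
  for (swap in c(FALSE, TRUE)) {
    don_sel <- if (swap) gp_h else rec_h
    acc_sel <- if (swap) rec_h else gp_h
    don <- rbind(select_typed(don_sel, HBOND_DONORS), backbone_donors(don_sel))
    acc <- rbind(select_typed(acc_sel, HBOND_ACCEPTORS),
                 acc_sel[acc_sel$atom == "O", , drop = FALSE])
    if (!nrow(don) || !nrow(acc)) next
    d <- cross_dist(coords_of(don), coords_of(acc))
    cand <- which(d < config$hbond_dist, arr.ind = TRUE)
    if (!nrow(cand)) next
    src_atoms <- if (swap) gp else rec # include hydrogens for explicit lookup
    keep <- logical(nrow(cand))
    for (i in seq_len(nrow(cand))) {
      drow <- don[cand[i, 1L], ]
      arow <- acc[cand[i, 2L], ]
      hpos <- donor_hydrogens(src_atoms, drow)
      if (is.null(hpos)) { # no way to orient: fall back to distance criterion
        keep[i] <- TRUE
        next
      }
      apos <- c(arow$x, arow$y, arow$z)
      dpos <- c(drow$x, drow$y, drow$z)
      for (hrow in seq_len(nrow(hpos))) {
        ang <- angle_deg(dpos - hpos[hrow, ], apos - hpos[hrow, ])
        if (!is.na(ang) && (180 - ang) < config$hbond_angle) {
          keep[i] <- TRUE
          break
        }
      }
    }
    cand <- cand[keep, , drop = FALSE]
    if (nrow(cand)) {
      df <- unique(data.frame(
        chain_a = don$chain[cand[, 1L]], resid_a = don$resid[cand[, 1L]],
        chain_b = acc$chain[cand[, 2L]], resid_b = acc$resid[cand[, 2L]],
        stringsAsFactors = FALSE))
      add_hits(df, "hydrogen_bond", swap = swap)
    }
  }

  # van der Waals over all heavy atoms with known radii
  ra <- VDW_RADII[rec_h$element]
  rb <- VDW_RADII[gp_h$element]
  ka <- !is.na(ra); kb <- !is.na(rb)
  if (any(ka) && any(kb)) {
    av <- rec_h[ka, , drop = FALSE]; bv <- gp_h[kb, , drop = FALSE]
    d <- cross_dist(coords_of(av), coords_of(bv))
    lim <- outer(ra[ka], rb[kb], "+") +
      if (isTRUE(config$vdw_gap_mode)) config$vdw_gap else config$vdw_tolerance
    hit <- which(d < lim, arr.ind = TRUE)
    if (nrow(hit)) {
      df <- unique(data.frame(
        chain_a = av$chain[hit[, 1L]], resid_a = av$resid[hit[, 1L]],
        chain_b = bv$chain[hit[, 2L]], resid_b = bv$resid[hit[, 2L]],
        stringsAsFactors = FALSE))
      add_hits(df, "vdw")
    }
  }

  # aromatic geometries for pi-stacking and cation-pi
  rec_rings <- ring_geometries(rec_h)
  gp_rings <- ring_geometries(gp_h)
  for (rr in rec_rings) {
    for (gr in gp_rings) {
      dd <- sqrt(sum((rr$centroid - gr$centroid)^2))
      if (dd < config$pi_stack_dist &&
          acute_angle(rr$normal, gr$normal) < config$pi_stack_angle) {
        add_hits(data.frame(chain_a = rr$chain, resid_a = rr$resid,
                            chain_b = gr$chain, resid_b = gr$resid,
                            stringsAsFactors = FALSE), "pi_stack")
      }
    }
  }
  for (swap in c(FALSE, TRUE)) {
    rings <- if (swap) rec_rings else gp_rings
    cats <- select_typed(if (swap) gp_h else rec_h, SALT_CATIONS)
    if (!nrow(cats) || !length(rings)) next
    for (ri in rings) {
      v <- sweep(coords_of(cats), 2L, ri$centroid)
      dd <- sqrt(rowSums(v^2))
      for (ci in which(dd < config$cation_pi_dist)) {
        if (acute_angle(ri$normal, v[ci, ]) < config$cation_pi_angle) {
          if (swap) {
            add_hits(data.frame(chain_a = cats$chain[ci], resid_a = cats$resid[ci],
                                chain_b = ri$chain, resid_b = ri$resid,
                                stringsAsFactors = FALSE), "cation_pi")
          } else {
            add_hits(data.frame(chain_a = ri$chain, resid_a = ri$resid,
                                chain_b = cats$chain[ci], resid_b = cats$resid[ci],
                                stringsAsFactors = FALSE), "cation_pi")
          }
        }
      }
    }
  }

  if (!length(hits)) {
    return(data.frame(receptor_chain = character(0), receptor_resid = integer(0),
                      gprotein_chain = character(0), gprotein_resid = integer(0),
                      type = character(0), stringsAsFactors = FALSE))
  }
  out <- unique(do.call(rbind, hits))
  rownames(out) <- NULL
  out
}

#' Contact records across all frames, with canonical node ids
#'
#' Runs [detect_contacts()] on every frame and converts author numbering to
#' generic numbering through a residue mapping, producing the long-format
#' record table the fingerprint encoder consumes. Without a mapping, nodes
#' are labelled `<chain><resid>` on each side (useful for toy systems only).
#'
#' @param frames list of atom data.frames (see [read_structure_frames()]).
#' @param receptor_chains,gprotein_chains chain ids of the two selections.
#' @param mapping optional `residue_mapping` from [read_mapping_table()].
#' @param config a [contactbn_config()].
#' @return data.frame with columns `frame` (0-based), `node`, `receptor_id`,
#'   `gprotein_id`, `type`.
#' @export
contact_records <- function(frames, receptor_chains, gprotein_chains,
                            mapping = NULL, config = contactbn_config()) {
  recs <- lapply(seq_along(frames), function(i) {
    df <- detect_contacts(frames[[i]], receptor_chains, gprotein_chains, config)
    if (nrow(df)) df$frame <- i - 1L
    df
  })
  recs <- do.call(rbind, recs[vapply(recs, nrow, 1L) > 0L])
  if (is.null(recs)) {
    return(data.frame(frame = integer(0), node = character(0),
                      receptor_id = character(0), gprotein_id = character(0),
                      type = character(0), stringsAsFactors = FALSE))
  }
  if (!is.null(mapping)) {
    rec_ids <- lookup_residue(mapping, recs$receptor_chain, recs$receptor_resid)$generic_id
    gp_ids <- lookup_residue(mapping, recs$gprotein_chain, recs$gprotein_resid)$generic_id
  } else {
    rec_ids <- paste0(recs$receptor_chain, recs$receptor_resid)
    gp_ids <- paste0(recs$gprotein_chain, recs$gprotein_resid)
  }
  out <- data.frame(frame = recs$frame,
                    node = contact_node_id(rec_ids, gp_ids),
                    receptor_id = rec_ids, gprotein_id = gp_ids,
                    type = recs$type, stringsAsFactors = FALSE)
  out[order(out$frame, out$node, out$type), , drop = FALSE]
}

#' Per-node contact frequencies
#'
#' The frequency of a contact node is the fraction of frames in which it has
#' at least one record of any interaction type (multiple types in one frame
#' count once).
#'
#' @param records record data.frame with columns `frame`, `node`.
#' @param n_frames total number of frames (>= 1).
#' @return named numeric vector of frequencies in `[0, 1]`.
#' @export
contact_frequencies <- function(records, n_frames) {
  stopifnot(n_frames >= 1L)
  if (nrow(records) == 0L) return(stats::setNames(numeric(0), character(0)))
  if (any(records$frame >= n_frames | records$frame < 0L)) {
    stop("record frame index outside [0, n_frames): inconsistent input")
  }
  u <- unique(records[, c("frame", "node")])
  counts <- table(u$node)
  stats::setNames(as.numeric(counts) / n_frames, names(counts))
}

#' Persistent contact nodes
#'
#' Keeps nodes whose frequency is strictly greater than the threshold
#' (default 0.20: present in more than 20% of frames).
#'
#' @param freqs named frequency vector from [contact_frequencies()].
#' @param threshold persistence threshold in `[0, 1]`.
#' @return character vector of persistent node ids.
#' @export
filter_persistent <- function(freqs, threshold = 0.20) {
  stopifnot(threshold >= 0, threshold <= 1)
  names(freqs)[freqs > threshold]
}

#' One-hot encode contact records into a fingerprint matrix
#'
#' Entry (f, n) is 1 when node n has at least one record in frame f. Columns
#' are restricted to the supplied node universe (typically the persistent
#' set); records for other nodes are ignored with one counted warning.
#'
#' @param records record data.frame with columns `frame`, `node`.
#' @param nodes character vector: the fixed node universe (column order).
#' @param n_frames total number of frames.
#' @return a [fingerprint_matrix()].
#' @export
encode_fingerprints <- function(records, nodes, n_frames) {
  stopifnot(n_frames >= 1L, length(nodes) >= 1L)
  nodes <- normalize_generic_id(nodes)
  vals <- matrix(0L, nrow = n_frames, ncol = length(nodes),
                 dimnames = list(NULL, nodes))
  if (nrow(records)) {
    if (any(records$frame >= n_frames)) stop("record frame index >= n_frames")
    idx <- match(records$node, nodes)
    outside <- sum(is.na(idx))
    if (outside > 0L) {
      warning(outside, " record(s) for nodes outside the universe ignored")
    }
    keep <- !is.na(idx)
    vals[cbind(records$frame[keep] + 1L, idx[keep])] <- 1L
  }
  fingerprint_matrix(vals, provenance = "encoded from contact records")
}

#' Classify contact nodes as polar or nonpolar
#'
#' A node is polar when its dominant interaction type (most frequent across
#' frames, ties broken in the order salt_bridge > hydrogen_bond > cation_pi >
#' pi_stack > vdw) is a salt bridge, hydrogen bond, or cation-pi contact.
#'
#' @param records record data.frame with columns `node`, `type` (and `frame`).
#' @param nodes nodes to classify; defaults to all nodes present in records.
#' @return named character vector, values `"polar"` or `"nonpolar"`.
#' @export
classify_polarity <- function(records, nodes = NULL) {
  if (is.null(nodes)) nodes <- unique(records$node)
  if (length(nodes) == 0L) return(stats::setNames(character(0), character(0)))
  polar_types <- c("salt_bridge", "hydrogen_bond", "cation_pi")
  out <- vapply(nodes, function(nd) {
    sub <- records[records$node == nd, , drop = FALSE]
    if (nrow(sub) == 0L) stop("node has no records: ", nd)
    counts <- table(factor(sub$type, levels = CONTACT_TYPES))
    dominant <- CONTACT_TYPES[which.max(counts)] # which.max honours level order
    if (dominant %in% polar_types) "polar" else "nonpolar"
  }, character(1L))
  stats::setNames(out, nodes)
}
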