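# Shared builders for the test suite: tiny fingerprint matrices, toy atom
# records, and rigid-body transforms. Everything is generated in code.

fp_from <- function(...) {
  cols <- list(...)
  fingerprint_matrix(do.call(cbind, lapply(cols, as.integer)) |>
                       `colnames<-`(names(cols)))
}

# one atom row for detect_contacts()
atom_row <- function(chain, resid, resname, atom, x, y, z, element = NULL) {
  if (is.null(element)) element <- contactbn:::infer_element(atom)
  data.frame(chain = chain, resid = resid, resname = resname, atom = atom,
             element = element, x = x, y = y, z = z, stringsAsFactors = FALSE)
}

atoms_bind <- function(...) do.call(rbind, list(...))

# a minimal Asp sidechain carboxylate on chain A and Arg guanidinium N on B,
# with the charged atoms `d` Angstrom apart
salt_bridge_frame <- function(d) {
  atoms_bind(
    atom_row("A", 1, "ASP", "CG", -1.5, 0, 0),
    atom_row("A", 1, "ASP", "OD1", 0, 0, 0),
    atom_row("A", 1, "ASP", "OD2", -0.5, 1.2, 0),
    atom_row("B", 2, "ARG", "NH1", d, 0, 0),
    atom_row("B", 2, "ARG", "CZ", d + 1.3, 0, 0))
}

# two lone carbon atoms (Leu side-chain tips) at separation d
carbon_pair_frame <- function(d) {
  atoms_bind(
    atom_row("A", 1, "LEU", "CD1", 0, 0, 0),
    atom_row("B", 2, "LEU", "CD1", d, 0, 0))
}

# Ser OG donor (with CB antecedent) on A and a backbone O acceptor on B.
# With `aligned`, the acceptor sits along the idealized O-H direction; when
# FALSE it sits behind the donor so the D-H-A geometry is far from linear.
hbond_frame <- function(d, aligned = TRUE) {
  ax <- if (aligned) d else -d
  atoms_bind(
    atom_row("A", 1, "SER", "CB", -1.4, 0, 0),
    atom_row("A", 1, "SER", "OG", 0, 0, 0),
    atom_row("B", 2, "GLY", "O", ax, 0, 0),
    atom_row("B", 2, "GLY", "C", ax + 1.2, 0.3, 0))
}

# random proper rotation + translation applied to every atom
rigid_transform <- function(atoms, seed) {
  set.seed(seed)
  m <- matrix(rnorm(9), 3)
  qr_d <- qr(m)
  rot <- qr.Q(qr_d) %*% diag(sign(diag(qr.R(qr_d))))
  if (det(rot) < 0) rot[, 1] <- -rot[, 1]
  shift <- rnorm(3, sd = 20)
  xyz <- as.matrix(atoms[, c("x", "y", "z")]) %*% t(rot)
  atoms$x <- xyz[, 1] + shift[1]
  atoms$y <- xyz[, 2] + shift[2]
  atoms$z <- xyz[, 3] + shift[3]
  atoms
}

# independent brute-force moral graph: nodes u,v are adjacent iff the DAG has
# an edge between them or they share a child (checked by triple enumeration)
brute_force_moral <- function(parents) {
  n <- length(parents)
  adj <- matrix(FALSE, n, n)
  for (v in seq_len(n)) for (u in parents[[v]]) adj[u, v] <- adj[v, u] <- TRUE
  for (child in seq_len(n)) {
    pa <- parents[[child]]
    if (length(pa) < 2) next
    for (i in seq_along(pa)) for (j in seq_along(pa)) {
      if (i < j) adj[pa[i], pa[j]] <- adj[pa[j], pa[i]] <- TRUE
    }
  }
  which(adj & upper.tri(adj), arr.ind = TRUE)
}

# moral edge set of a contact_bn as a canonical character vector "i-j"
moral_edge_keys <- function(mg, labels) {
  if (nrow(mg$edges) == 0) return(character(0))
  a <- match(mg$edges$a, labels); b <- match(mg$edges$b, labels)
  sort(paste(pmin(a, b), pmax(a, b), sep = "-"))
}

# fingerprint data with labelled binary columns from a matrix
fp_named <- function(m, labels) {
  colnames(m) <- labels
  fingerprint_matrix(m)
}
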