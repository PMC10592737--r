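# Atom typing tables for contact detection. These follow the conventions of
# widely used MD contact-analysis tooling; all geometric cutoffs live in the
# run config so the rules stay inspectable and overridable.

SALT_ANIONS <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
SALT_CATIONS <- list(LYS = "NZ", ARG = c("NE", "NH1", "NH2"))

HBOND_DONORS <- list(
  SER = "OG", THR = "OG1", TYR = "OH", CYS = "SG", ASN = "ND2", GLN = "NE2",
  HIS = c("ND1", "NE2"), TRP = "NE1", LYS = "NZ", ARG = c("NE", "NH1", "NH2"))

HBOND_ACCEPTORS <- list(
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = "OD1", GLN = "OE1",
  SER = "OG", THR = "OG1", TYR = "OH", HIS = c("ND1", "NE2"),
  MET = "SD", CYS = "SG")

AROMATIC_RINGS <- list(
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2"))

# antecedent heavy atoms used to place an idealized hydrogen on each donor
DONOR_ANTECEDENTS <- list(
  N = "CA", OG = "CB", OG1 = "CB", OH = "CZ", SG = "CB", ND2 = "CG",
  NE2 = c("CD", "CD2"), ND1 = c("CG", "CE1"), NE1 = c("CD1", "CE2"),
  NZ = "CE", NE = c("CD", "CZ"), NH1 = "CZ", NH2 = "CZ")

# Bondi van der Waals radii (Angstrom) by element
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, H = 1.20,
               F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90)

# Infer the element from a PDB atom name when no element column is present.
infer_element <- function(atom_name) {
  core <- sub("^[0-9']+", "", toupper(trimws(atom_name)))
  two <- substr(core, 1L, 2L)
  ifelse(two %in% c("CL", "BR", "SE"), two, substr(core, 1L, 1L))
}

#' Read coordinate frames from a (possibly multi-model) PDB file
#'
#' Each MODEL becomes one frame, in model order, with 0-based frame ids.
#' Requires the bio3d package.
#'
#' @param path PDB file path.
#' @return list of atom data.frames (columns `chain`, `resid`, `resname`,
#'   `atom`, `element`, `x`, `y`, `z`), one per frame.
#' @export
read_structure_frames <- function(path) {
  if (!requireNamespace("bio3d", quietly = TRUE)) {
    stop("the 'bio3d' package is required to read PDB files")
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  element <- if (!is.null(at$elesy) && any(nzchar(trimws(at$elesy)))) {
    toupper(trimws(at$elesy))
  } else {
    infer_element(at$elety)
  }
  base <- data.frame(
    chain = at$chain, resid = as.integer(at$resno), resname = toupper(at$resid),
    atom = toupper(trimws(at$elety)), element = element,
    stringsAsFactors = FALSE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  lapply(seq_len(nrow(xyz)), function(m) {
    co <- matrix(xyz[m, ], ncol = 3L, byrow = TRUE)
    cbind(base, data.frame(x = co[, 1L], y = co[, 2L], z = co[, 3L]))
  })
}

# --- small geometry helpers -------------------------------------------------

coords_of <- function(df) cbind(df$x, df$y, df$z)

# pairwise Euclidean distances between rows of two coordinate matrices
cross_dist <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) {
    return(matrix(numeric(0), nrow = nrow(a), ncol = nrow(b)))
  }
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

angle_deg <- function(u, v) {
  cu <- sqrt(sum(u^2)); cv <- sqrt(sum(v^2))
  if (cu == 0 || cv == 0) return(NA_real_)
  acos(pmin(1, pmax(-1, sum(u * v) / (cu * cv)))) * 180 / pi
}

# best-fit plane normal of a ring of >=3 points (SVD of centered coordinates)
ring_normal <- function(pts) {
  ctr <- colMeans(pts)
  sv <- svd(sweep(pts, 2L, ctr))
  list(centroid = ctr, normal = sv$v[, 3L])
}

# acute angle between two directions (planes have no orientation)
acute_angle <- function(u, v) {
  a <- angle_deg(u, v)
  min(a, 180 - a)
}
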