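# Covalent topology: per-residue bond templates plus peptide bonds.
# Contacts between atoms within three covalent-bond steps are excluded from
# mutation contact sets, since their spatial proximity reflects bond rigidity
# rather than an interaction.

.bond_templates <- local({
  bb <- list(c("N", "CA"), c("CA", "C"), c("C", "O"), c("C", "OXT"),
             c("CA", "CB"))
  sc <- list(
    ALA = list(),
    ARG = list(c("CB", "CG"), c("CG", "CD"), c("CD", "NE"), c("NE", "CZ"),
               c("CZ", "NH1"), c("CZ", "NH2")),
    ASN = list(c("CB", "CG"), c("CG", "OD1"), c("CG", "ND2")),
    ASP = list(c("CB", "CG"), c("CG", "OD1"), c("CG", "OD2")),
    CYS = list(c("CB", "SG")),
    GLN = list(c("CB", "CG"), c("CG", "CD"), c("CD", "OE1"), c("CD", "NE2")),
    GLU = list(c("CB", "CG"), c("CG", "CD"), c("CD", "OE1"), c("CD", "OE2")),
    GLY = list(),
    HIS = list(c("CB", "CG"), c("CG", "ND1"), c("CG", "CD2"),
               c("ND1", "CE1"), c("CD2", "NE2"), c("CE1", "NE2")),
    ILE = list(c("CB", "CG1"), c("CB", "CG2"), c("CG1", "CD1")),
    LEU = list(c("CB", "CG"), c("CG", "CD1"), c("CG", "CD2")),
    LYS = list(c("CB", "CG"), c("CG", "CD"), c("CD", "CE"), c("CE", "NZ")),
    MET = list(c("CB", "CG"), c("CG", "SD"), c("SD", "CE")),
    PHE = list(c("CB", "CG"), c("CG", "CD1"), c("CG", "CD2"),
               c("CD1", "CE1"), c("CD2", "CE2"), c("CE1", "CZ"),
               c("CE2", "CZ")),
    PRO = list(c("CB", "CG"), c("CG", "CD"), c("CD", "N")),
    SER = list(c("CB", "OG")),
    THR = list(c("CB", "OG1"), c("CB", "CG2")),
    TRP = list(c("CB", "CG"), c("CG", "CD1"), c("CG", "CD2"),
               c("CD1", "NE1"), c("NE1", "CE2"), c("CD2", "CE2"),
               c("CD2", "CE3"), c("CE2", "CZ2"), c("CE3", "CZ3"),
               c("CZ2", "CH2"), c("CZ3", "CH2")),
    TYR = list(c("CB", "CG"), c("CG", "CD1"), c("CG", "CD2"),
               c("CD1", "CE1"), c("CD2", "CE2"), c("CE1", "CZ"),
               c("CE2", "CZ"), c("CZ", "OH")),
    VAL = list(c("CB", "CG1"), c("CB", "CG2"))
  )
  lapply(sc, function(x) c(bb, x))
})

#' Infer the covalent bond set of a structure
#'
#' Bonds come from a per-residue template for the 20 standard residues
#' (pairs present in the template and in the structure) plus inter-residue
#' peptide bonds C(i)-N(i+1) between consecutive residues of a chain when
#' the two atoms are within 2 Angstrom. Waters are never bonded. Missing
#' heavy atoms simply yield fewer bonds.
#'
#' @param s A `bacv_structure`.
#' @return The structure with `bonds` set (2-column matrix of atom ids).
#' @export
infer_covalent_topology <- function(s) {
  a <- s$atoms
  prot <- which(!a$is_water)
  reskey <- paste(a$chain, a$resno, a$inscode)
  bonds <- list()
  for (r in unique(reskey[prot])) {
    idx <- prot[reskey[prot] == r]
    resname <- a$resname[idx[1]]
    tmpl <- .bond_templates[[resname]]
    if (is.null(tmpl)) next
    nm <- a$name[idx]
    for (b in tmpl) {
      i <- idx[match(b[1], nm)]
      j <- idx[match(b[2], nm)]
      if (!is.na(i) && !is.na(j)) bonds[[length(bonds) + 1]] <- c(i, j)
    }
  }
  # peptide bonds: C of one residue to N of the next residue in file order
  for (ch in unique(a$chain[prot])) {
    cidx <- prot[a$chain[prot] == ch]
    resids <- unique(reskey[cidx])
    if (length(resids) < 2) next
    for (t in seq_len(length(resids) - 1)) {
      i1 <- cidx[reskey[cidx] == resids[t]]
      i2 <- cidx[reskey[cidx] == resids[t + 1]]
      ci <- i1[match("C", a$name[i1])]
      ni <- i2[match("N", a$name[i2])]
      if (is.na(ci) || is.na(ni)) next
      d <- sqrt(sum((as.numeric(a[ci, c("x", "y", "z")]) -
                       as.numeric(a[ni, c("x", "y", "z")]))^2))
      if (d < 2.0) bonds[[length(bonds) + 1]] <- c(ci, ni)
    }
  }
  bm <- if (length(bonds) > 0) do.call(rbind, bonds) else
    matrix(integer(0), ncol = 2)
  # store as atom ids
  bm[] <- a$atom_id[bm]
  s$bonds <- bm
  s
}

bond_graph <- function(s) {
  stopifnot(!is.null(s$bonds))
  igraph::graph_from_edgelist(
    matrix(as.character(s$bonds), ncol = 2), directed = FALSE
  )
}

#' Covalent-bond step distances between atoms
#'
#' Shortest path length in the covalent bond graph; `Inf` for atoms with no
#' bond path (e.g. different chains). Two atoms are *covalent-bond nearby*
#' when their step distance is at most 3.
#'
#' @param s A `bacv_structure` with bonds inferred.
#' @param from,to Atom id vectors.
#' @return Matrix of step counts (`length(from)` x `length(to)`).
#' @export
covalent_steps <- function(s, from, to) {
  g <- bond_graph(s)
  vn <- igraph::V(g)$name
  out <- matrix(Inf, length(from), length(to),
                dimnames = list(from, to))
  fi <- match(as.character(from), vn)
  ti <- match(as.character(to), vn)
  if (any(!is.na(fi)) && any(!is.na(ti))) {
    d <- igraph::distances(g, v = vn[fi[!is.na(fi)]], to = vn[ti[!is.na(ti)]])
    out[!is.na(fi), !is.na(ti)] <- d
  }
  # unbonded atoms are at distance 0 from themselves
  for (k in seq_along(from)) {
    m <- which(to == from[k])
    if (length(m)) out[k, m] <- 0
  }
  out
}

#' Are two atoms covalent-bond nearby (within three bond steps)?
#' @param s A `bacv_structure` with bonds inferred.
#' @param a,b Atom ids.
#' @export
is_nearby <- function(s, a, b) {
  covalent_steps(s, a, b)[1, 1] <= 3
}

#' Atom ids within three covalent-bond steps of the given atoms
#' @keywords internal
nearby_atoms <- function(s, ids) {
  steps <- covalent_steps(s, ids, s$atoms$atom_id)
  s$atoms$atom_id[apply(steps <= 3, 2, any)]
}
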