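# Structure container: a protein quaternary structure as a data.frame of
# typed heavy atoms plus covalent bonds and a two-side chain partition.
# Hydrogens are never stored; crystallographic waters are kept as single
# oxygen atoms that belong to neither binding side.

.backbone_names <- c("N", "CA", "C", "O", "OXT")

new_structure <- function(atoms, sides, bonds = NULL) {
  atoms$atom_id <- seq_len(nrow(atoms))
  atoms$is_backbone <- !atoms$is_water & atoms$name %in% .backbone_names
  atoms$side <- NA_integer_
  atoms$side[!atoms$is_water & atoms$chain %in% sides[[1]]] <- 1L
  atoms$side[!atoms$is_water & atoms$chain %in% sides[[2]]] <- 2L
  if (!"vdw" %in% names(atoms)) atoms$vdw <- NA_real_
  if (!"type" %in% names(atoms)) atoms$type <- NA_integer_
  structure(list(atoms = atoms, sides = sides, bonds = bonds),
            class = "bacv_structure")
}

#' Parse a PDB file into a structure
#'
#' Reads ATOM/HETATM records (via bio3d), drops hydrogens and alternate
#' locations other than `' '`/`'A'`, keeps waters (HOH) as single oxygen
#' atoms, and partitions the protein chains into the two binding sides.
#' Atom order follows file order.
#'
#' @param pdb Path to a PDB file, or a character vector/scalar of PDB text.
#' @param sides List of two disjoint character vectors of chain identifiers,
#'   e.g. `list("A", c("B", "C"))`.
#' @return A `bacv_structure` (radii/types unassigned; see
#'   [assign_radii_and_types()]).
#' @export
parse_pdb <- function(pdb, sides) {
  stopifnot(length(sides) == 2, !anyDuplicated(unlist(sides)))
  if (length(pdb) > 1 || grepl("\n", pdb[1], fixed = TRUE) ||
      !file.exists(pdb[1])) {
    tf <- tempfile(fileext = ".pdb")
    on.exit(unlink(tf))
    writeLines(unlist(strsplit(pdb, "\n", fixed = TRUE)), tf)
    pdb <- tf
  }
  p <- bio3d::read.pdb(pdb, verbose = FALSE)
  a <- p$atom
  elem <- trimws(a$elesy)
  noelem <- is.na(elem) | elem == ""
  if (any(noelem)) {
    # derive element from the atom name (strip digits, take leading letter)
    nm <- gsub("[0-9']", "", trimws(a$elety[noelem]))
    elem[noelem] <- toupper(substr(nm, 1, 1))
  }
  keep <- toupper(elem) != "H" & toupper(elem) != "D" &
    (is.na(a$alt) | a$alt %in% c("", " ", "A"))
  a <- a[keep, , drop = FALSE]
  elem <- elem[keep]
  is_water <- a$resid %in% c("HOH", "WAT")
  atoms <- data.frame(
    name = trimws(a$elety), element = toupper(elem),
    resname = trimws(a$resid), chain = ifelse(is.na(a$chain), "", a$chain),
    resno = a$resno, inscode = ifelse(is.na(a$insert), "", a$insert),
    x = a$x, y = a$y, z = a$z, is_water = is_water,
    stringsAsFactors = FALSE
  )
  prot_chains <- unique(atoms$chain[!atoms$is_water])
  missing_chains <- setdiff(unlist(sides), prot_chains)
  if (length(missing_chains) > 0) {
    stop("side chains not present in file: ",
         paste(missing_chains, collapse = ", "))
  }
  uncovered <- setdiff(prot_chains, unlist(sides))
  if (length(uncovered) > 0) {
    stop("protein chains not covered by the side specification: ",
         paste(uncovered, collapse = ", "))
  }
  s <- new_structure(atoms, sides)
  for (sd in 1:2) {
    if (sum(s$atoms$side == sd, na.rm = TRUE) == 0) {
      stop("side ", sd, " has zero atoms")
    }
  }
  s
}

#' Serialise a structure to PDB text
#'
#' Writes standard ATOM/HETATM records (waters as HETATM HOH) via bio3d.
#'
#' @param s A `bacv_structure`.
#' @param file Optional path; when `NULL` the text is returned invisibly.
#' @return Character vector of PDB lines, invisibly when written to `file`.
#' @export
structure_to_pdb <- function(s, file = NULL) {
  a <- s$atoms
  tf <- if (is.null(file)) tempfile(fileext = ".pdb") else file
  bio3d::write.pdb(
    file = tf,
    type = ifelse(a$is_water, "HETATM", "ATOM"),
    xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
    resno = a$resno, resid = a$resname, eleno = a$atom_id,
    elety = a$name, chain = a$chain, insert = a$inscode,
    o = rep(1, nrow(a)), b = rep(0, nrow(a)), elesy = a$element
  )
  txt <- readLines(tf)
  if (is.null(file)) {
    unlink(tf)
    return(txt)
  }
  invisible(txt)
}

#' Subset a structure by atom id, preserving ids
#' @keywords internal
subset_structure <- function(s, atom_ids) {
  keep <- s$atoms$atom_id %in% atom_ids
  s$atoms <- s$atoms[keep, , drop = FALSE]
  rownames(s$atoms) <- NULL
  if (!is.null(s$bonds)) {
    bk <- s$bonds[, 1] %in% s$atoms$atom_id & s$bonds[, 2] %in% s$atoms$atom_id
    s$bonds <- s$bonds[bk, , drop = FALSE]
  }
  s
}

#' Locate the atoms of one residue
#' @keywords internal
residue_atoms <- function(s, chain, resno, inscode = "") {
  which(!s$atoms$is_water & s$atoms$chain == chain &
          s$atoms$resno == resno & s$atoms$inscode == inscode)
}

#' Build the alanine-mutant structure
#'
#' Removes the side-chain atoms beyond CB of the target residue ("mutated
#' atoms": everything except N, CA, C, O, CB and OXT). No repacking: the
#' remaining coordinates are untouched. Alanine targets (no change in heavy
#' atoms, assumed insignificant effect) and glycine targets (no CB) are
#' rejected.
#'
#' @param s A `bacv_structure`.
#' @param chain,resno,inscode Residue identifier.
#' @return The mutant `bacv_structure`; atom ids are preserved so contact
#'   sets of wild type and mutant are directly comparable.
#' @export
make_alanine_mutant <- function(s, chain, resno, inscode = "") {
  idx <- residue_atoms(s, chain, resno, inscode)
  if (length(idx) == 0) stop("residue ", chain, resno, " not found")
  resname <- s$atoms$resname[idx[1]]
  if (resname %in% c("ALA", "GLY")) {
    stop("alanine mutation of ", resname, " is not considered")
  }
  removed <- idx[!(s$atoms$name[idx] %in% c(.backbone_names, "CB"))]
  subset_structure(s, setdiff(s$atoms$atom_id, s$atoms$atom_id[removed]))
}

#' Atom ids of the mutated atoms of a residue
#' @keywords internal
mutated_atom_ids <- function(s, chain, resno, inscode = "") {
  idx <- residue_atoms(s, chain, resno, inscode)
  s$atoms$atom_id[idx][!(s$atoms$name[idx] %in% c(.backbone_names, "CB"))]
}

#' Split a complex into its two unbound partners
#'
#' Rigid split: each partner's atoms in isolation with unchanged
#' coordinates; waters are excluded from both halves.
#'
#' @param s A `bacv_structure` with sides defined.
#' @return List of two `bacv_structure`s.
#' @export
split_unbound <- function(s) {
  lapply(1:2, function(sd) {
    ids <- s$atoms$atom_id[!is.na(s$atoms$side) & s$atoms$side == sd]
    subset_structure(s, ids)
  })
}

#' @export
print.bacv_structure <- function(x, ...) {
  a <- x$atoms
  cat("bacv_structure:", sum(!a$is_water), "protein atoms in",
      length(unique(a$chain[!a$is_water])), "chain(s),",
      sum(a$is_water), "water(s)\n")
  cat("  sides:", paste(x$sides[[1]], collapse = ","), "|",
      paste(x$sides[[2]], collapse = ","), "\n")
  if (!is.null(x$bonds)) cat("  bonds:", nrow(x$bonds), "\n")
  invisible(x)
}

coords_matrix <- function(s, idx = seq_len(nrow(s$atoms))) {
  as.matrix(s$atoms[idx, c("x", "y", "z")])
}
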