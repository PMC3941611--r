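# Atomic typing and van der Waals radii for standard-residue heavy atoms.
#
# Heavy atoms are grouped into 8 classes by element, hybridisation and
# polarity/charge.  The grouping is deliberately parametric: every downstream
# computation takes the typing table as data, so an alternative 8-class scheme
# can be swapped in without touching code.

#' The 8 default atomic type codes
#'
#' Code 1: aliphatic (sp3) carbon; 2: sp2 carbon (carbonyl, carboxyl,
#' guanidinium and aromatic ring carbons); 3: neutral nitrogen (backbone
#' amide, side-chain amide, aromatic ring N); 4: charged nitrogen (LYS NZ,
#' ARG guanidinium nitrogens); 5: neutral oxygen with at most one hydrogen
#' (carbonyl, amide and hydroxyl O); 6: carboxylate oxygen (ASP/GLU and
#' C-terminal OXT); 7: oxygen bearing more than one hydrogen, i.e. the water
#' oxygen class; 8: sulfur.
#'
#' @format Named integer vector of length 8.
#' @export
acv_atom_types <- c(
  C.ali = 1L, C.sp2 = 2L, N.neutral = 3L, N.charged = 4L,
  O.neutral = 5L, O.carboxyl = 6L, O.water = 7L, S = 8L
)

#' Default van der Waals radii by atomic type
#'
#' Chothia-style radii as used by common ASA programs: aliphatic C 1.87,
#' sp2/aromatic C 1.76, N 1.65, O 1.40, S 1.85 (all in Angstrom).
#'
#' @format Numeric vector of length 8, indexed by type code.
#' @export
acv_type_radii <- c(1.87, 1.76, 1.65, 1.65, 1.40, 1.40, 1.40, 1.85)

# per-residue heavy atom -> type code; backbone atoms shared by all residues
.backbone_types <- c(N = 3L, CA = 1L, C = 2L, O = 5L, OXT = 6L)

.sidechain_types <- list(
  ALA = c(CB = 1L),
  ARG = c(CB = 1L, CG = 1L, CD = 1L, NE = 4L, CZ = 2L, NH1 = 4L, NH2 = 4L),
  ASN = c(CB = 1L, CG = 2L, OD1 = 5L, ND2 = 3L),
  ASP = c(CB = 1L, CG = 2L, OD1 = 6L, OD2 = 6L),
  CYS = c(CB = 1L, SG = 8L),
  GLN = c(CB = 1L, CG = 1L, CD = 2L, OE1 = 5L, NE2 = 3L),
  GLU = c(CB = 1L, CG = 1L, CD = 2L, OE1 = 6L, OE2 = 6L),
  GLY = c(),
  HIS = c(CB = 1L, CG = 2L, ND1 = 3L, CD2 = 2L, CE1 = 2L, NE2 = 3L),
  ILE = c(CB = 1L, CG1 = 1L, CG2 = 1L, CD1 = 1L),
  LEU = c(CB = 1L, CG = 1L, CD1 = 1L, CD2 = 1L),
  LYS = c(CB = 1L, CG = 1L, CD = 1L, CE = 1L, NZ = 4L),
  MET = c(CB = 1L, CG = 1L, SD = 8L, CE = 1L),
  PHE = c(CB = 1L, CG = 2L, CD1 = 2L, CD2 = 2L, CE1 = 2L, CE2 = 2L, CZ = 2L),
  PRO = c(CB = 1L, CG = 1L, CD = 1L),
  SER = c(CB = 1L, OG = 5L),
  THR = c(CB = 1L, OG1 = 5L, CG2 = 1L),
  TRP = c(CB = 1L, CG = 2L, CD1 = 2L, CD2 = 2L, NE1 = 3L, CE2 = 2L,
          CE3 = 2L, CZ2 = 2L, CZ3 = 2L, CH2 = 2L),
  TYR = c(CB = 1L, CG = 2L, CD1 = 2L, CD2 = 2L, CE1 = 2L, CE2 = 2L,
          CZ = 2L, OH = 5L),
  VAL = c(CB = 1L, CG1 = 1L, CG2 = 1L)
)

#' Default atom typing table
#'
#' One row per (residue, atom name) with the type code of
#' [acv_atom_types] and the van der Waals radius. Covers all heavy atoms of
#' the 20 standard residues (including OXT) plus the water oxygen
#' (`HOH`/`O`), which is assigned the oxygen-with-more-than-one-hydrogen
#' class.
#'
#' @return A data.frame with columns `resname`, `atom`, `type`, `vdw`.
#' @export
default_type_table <- function() {
  rows <- lapply(names(.sidechain_types), function(res) {
    tt <- c(.backbone_types, .sidechain_types[[res]])
    data.frame(resname = res, atom = names(tt), type = unname(tt),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab <- rbind(tab, data.frame(resname = "HOH", atom = "O",
                               type = acv_atom_types[["O.water"]],
                               stringsAsFactors = FALSE))
  tab$vdw <- acv_type_radii[tab$type]
  tab
}

#' Assign radii and atomic types to a structure
#'
#' Every heavy atom of a standard residue (and every water oxygen) receives
#' exactly one of the 8 atomic type codes and its van der Waals radius from
#' the typing table.
#'
#' @param s A `bacv_structure`.
#' @param type_table Typing table as returned by [default_type_table()].
#' @param on_unknown `"error"` to fail on an atom missing from the table,
#'   `"skip"` to drop it with a warning.
#' @return The structure with `type` and `vdw` columns filled.
#' @export
assign_radii_and_types <- function(s, type_table = default_type_table(),
                                   on_unknown = c("error", "skip")) {
  on_unknown <- match.arg(on_unknown)
  stopifnot(inherits(s, "bacv_structure"))
  key <- paste(s$atoms$resname, s$atoms$name)
  tkey <- paste(type_table$resname, type_table$atom)
  idx <- match(key, tkey)
  if (anyNA(idx)) {
    bad <- unique(key[is.na(idx)])
    if (on_unknown == "error") {
      stop("atoms not covered by the typing table: ",
           paste(head(bad, 5), collapse = ", "))
    }
    warning("dropping ", sum(is.na(idx)), " atom(s) not in typing table: ",
            paste(head(bad, 5), collapse = ", "))
    s <- subset_structure(s, s$atoms$atom_id[!is.na(idx)])
    idx <- idx[!is.na(idx)]
  }
  s$atoms$type <- type_table$type[idx]
  s$atoms$vdw <- type_table$vdw[idx]
  s
}

#' Number of side-chain heavy atoms beyond CB, per residue type
#' @keywords internal
mutated_atom_names <- function(resname) {
  sc <- .sidechain_types[[resname]]
  if (is.null(sc)) stop("unknown residue type: ", resname)
  setdiff(names(sc), "CB")
}
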