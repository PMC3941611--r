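# Idealized peptide geometry for synthetic fixtures and the ALA-X-ALA
# reference tripeptides. Residues are built from internal coordinates
# (standard bond lengths/angles, extended torsions); rings are closed to
# within a few hundredths of an Angstrom. No physical realism is claimed:
# downstream code needs only coordinates, radii and types.

# place atom X given bonded atom A, angle reference B, torsion reference C
.place_atom <- function(A, B, C, len, ang_deg, tor_deg) {
  ang <- ang_deg * pi / 180
  tor <- tor_deg * pi / 180
  ab <- A - B
  bc <- C - B
  n1 <- ab / sqrt(sum(ab^2))
  v <- bc - sum(bc * n1) * n1
  n2 <- v / sqrt(sum(v^2))
  n3 <- -c(n1[2] * n2[3] - n1[3] * n2[2],
           n1[3] * n2[1] - n1[1] * n2[3],
           n1[1] * n2[2] - n1[2] * n2[1])
  A + len * (-cos(ang) * n1 + sin(ang) * (cos(tor) * n2 + sin(tor) * n3))
}

# side-chain z-matrix entries: atom, A (bonded), B, C, length, angle, torsion
# references may be any previously placed atom of the residue
.sc_zmat <- list(
  ALA = list(),
  ARG = list(c("CG","CB","CA","N",1.52,114.1,180), c("CD","CG","CB","CA",1.52,111.3,180),
             c("NE","CD","CG","CB",1.46,112.0,180), c("CZ","NE","CD","CG",1.33,124.2,180),
             c("NH1","CZ","NE","CD",1.33,120.0,0), c("NH2","CZ","NE","CD",1.33,120.0,180)),
  ASN = list(c("CG","CB","CA","N",1.52,112.6,180), c("OD1","CG","CB","CA",1.23,120.8,0),
             c("ND2","CG","CB","CA",1.33,116.4,180)),
  ASP = list(c("CG","CB","CA","N",1.52,112.6,180), c("OD1","CG","CB","CA",1.25,118.4,0),
             c("OD2","CG","CB","CA",1.25,118.4,180)),
  CYS = list(c("SG","CB","CA","N",1.81,114.4,180)),
  GLN = list(c("CG","CB","CA","N",1.52,114.1,180), c("CD","CG","CB","CA",1.52,112.6,180),
             c("OE1","CD","CG","CB",1.23,120.8,0), c("NE2","CD","CG","CB",1.33,116.4,180)),
  GLU = list(c("CG","CB","CA","N",1.52,114.1,180), c("CD","CG","CB","CA",1.52,112.6,180),
             c("OE1","CD","CG","CB",1.25,118.4,0), c("OE2","CD","CG","CB",1.25,118.4,180)),
  GLY = list(),
  HIS = list(c("CG","CB","CA","N",1.50,113.8,180), c("ND1","CG","CB","CA",1.37,126.0,90),
             c("CD2","CG","CB","CA",1.37,126.0,-90), c("CE1","ND1","CG","CB",1.37,108.0,180),
             c("NE2","CD2","CG","CB",1.37,108.0,180)),
  ILE = list(c("CG1","CB","CA","N",1.53,110.4,180), c("CG2","CB","CA","N",1.53,110.5,-60),
             c("CD1","CG1","CB","CA",1.53,113.8,180)),
  LEU = list(c("CG","CB","CA","N",1.53,116.3,180), c("CD1","CG","CB","CA",1.53,110.7,180),
             c("CD2","CG","CB","CA",1.53,110.7,60)),
  LYS = list(c("CG","CB","CA","N",1.52,114.1,180), c("CD","CG","CB","CA",1.52,111.3,180),
             c("CE","CD","CG","CB",1.52,111.3,180), c("NZ","CE","CD","CG",1.49,111.9,180)),
  MET = list(c("CG","CB","CA","N",1.52,114.1,180), c("SD","CG","CB","CA",1.81,112.7,180),
             c("CE","SD","CG","CB",1.79,100.8,180)),
  PHE = list(c("CG","CB","CA","N",1.50,113.8,180), c("CD1","CG","CB","CA",1.39,120.0,90),
             c("CD2","CG","CB","CA",1.39,120.0,-90), c("CE1","CD1","CG","CB",1.39,120.0,180),
             c("CE2","CD2","CG","CB",1.39,120.0,180), c("CZ","CE1","CD1","CG",1.39,120.0,0)),
  PRO = list(c("CG","CB","CA","N",1.50,104.5,-30), c("CD","CG","CB","CA",1.50,104.5,35)),
  SER = list(c("OG","CB","CA","N",1.42,110.8,180)),
  THR = list(c("OG1","CB","CA","N",1.42,109.5,180), c("CG2","CB","CA","N",1.53,110.5,-60)),
  TRP = list(c("CG","CB","CA","N",1.50,113.8,180), c("CD1","CG","CB","CA",1.37,126.0,90),
             c("CD2","CG","CB","CA",1.40,126.0,-90), c("NE1","CD1","CG","CB",1.37,108.0,180),
             c("CE2","CD2","CG","CB",1.40,108.0,180), c("CE3","CD2","CE2","NE1",1.40,122.0,180),
             c("CZ3","CE3","CD2","CE2",1.39,118.0,0), c("CH2","CZ3","CE3","CD2",1.39,121.0,0),
             c("CZ2","CH2","CZ3","CE3",1.39,121.0,0)),
  TYR = list(c("CG","CB","CA","N",1.50,113.8,180), c("CD1","CG","CB","CA",1.39,120.0,90),
             c("CD2","CG","CB","CA",1.39,120.0,-90), c("CE1","CD1","CG","CB",1.39,120.0,180),
             c("CE2","CD2","CG","CB",1.39,120.0,180), c("CZ","CE1","CD1","CG",1.39,120.0,0),
             c("OH","CZ","CE1","CD1",1.38,120.0,180)),
  VAL = list(c("CG1","CB","CA","N",1.53,110.5,180), c("CG2","CB","CA","N",1.53,110.5,-60))
)

.element_of <- function(name) substr(gsub("[0-9]", "", name), 1, 1)

#' Build an idealized peptide chain
#'
#' Places backbone atoms with standard bond geometry at the given phi/psi
#' torsions (fully extended by default) and grows side chains from
#' per-residue internal-coordinate templates with extended rotamers.
#'
#' @param sequence Character vector of three-letter residue codes.
#' @param chain Chain identifier.
#' @param phi,psi Backbone torsions in degrees (recycled over residues).
#' @param start_resno First residue number.
#' @return Data.frame of atoms (`name`, `element`, `resname`, `chain`,
#'   `resno`, `inscode`, `x`, `y`, `z`, `is_water`).
#' @export
build_peptide <- function(sequence, chain = "A", phi = 180, psi = 180,
                          start_resno = 1) {
  nres <- length(sequence)
  phi <- rep_len(phi, nres)
  psi <- rep_len(psi, nres)
  rows <- list()
  prevC <- prevCA <- prevN <- NULL
  for (r in seq_len(nres)) {
    res <- sequence[r]
    if (is.null(.sc_zmat[[res]])) stop("unknown residue type: ", res)
    pos <- list()
    if (r == 1) {
      pos$N <- c(0, 0, 0)
      pos$CA <- c(1.458, 0, 0)
      ang <- 111.2 * pi / 180
      pos$C <- pos$CA + 1.525 * c(-cos(ang), sin(ang), 0)
    } else {
      pos$N <- .place_atom(prevC, prevCA, prevN, 1.329, 116.2, psi[r - 1])
      pos$CA <- .place_atom(pos$N, prevC, prevCA, 1.458, 121.7, 180)
      pos$C <- .place_atom(pos$CA, pos$N, prevC, 1.525, 111.2, phi[r])
    }
    pos$O <- .place_atom(pos$C, pos$CA, pos$N, 1.231, 120.8,
                         (psi[r] + 180) %% 360)
    if (res != "GLY") {
      pos$CB <- .place_atom(pos$CA, pos$N, pos$C, 1.521, 110.5, 122.5)
    }
    for (z in .sc_zmat[[res]]) {
      pos[[z[1]]] <- .place_atom(pos[[z[2]]], pos[[z[3]]], pos[[z[4]]],
                                 as.numeric(z[5]), as.numeric(z[6]),
                                 as.numeric(z[7]))
    }
    nm <- names(pos)
    rows[[r]] <- data.frame(
      name = nm, element = .element_of(nm), resname = res, chain = chain,
      resno = start_resno + r - 1, inscode = "",
      x = vapply(pos, `[`, 0, 1), y = vapply(pos, `[`, 0, 2),
      z = vapply(pos, `[`, 0, 3), is_water = FALSE,
      stringsAsFactors = FALSE
    )
    prevN <- pos$N; prevCA <- pos$CA; prevC <- pos$C
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Extended ALA-X-ALA tripeptide structure for one residue type
#'
#' The reference conformation used to compute the maximum backbone and
#' side-chain ASA of residue type X.
#'
#' @param resname Central residue three-letter code.
#' @return A `bacv_structure` with radii/types assigned and the middle
#'   residue at position 2.
#' @export
ala_x_ala <- function(resname) {
  atoms <- build_peptide(c("ALA", resname, "ALA"), chain = "A")
  s <- new_structure(atoms, sides = list("A", character(0)))
  # a single-chain reference: bypass two-side validation
  assign_radii_and_types(s)
}

#' Compute the maximum backbone/side-chain ASA reference table
#'
#' Runs [compute_asa()] on extended ALA-X-ALA tripeptides and sums the ASA
#' of the central residue's backbone and side-chain atoms. The shipped
#' [max_asa_table] constant was produced by this function with the default
#' probe (1.4) and 960 sphere points.
#'
#' @inheritParams compute_asa
#' @return Data.frame with `resname`, `max_bb`, `max_sc`.
#' @export
compute_max_asa_table <- function(probe = 1.4, n_sphere_points = 960) {
  res <- names(.sc_zmat)
  out <- lapply(res, function(rn) {
    s <- ala_x_ala(rn)
    asa <- compute_asa(s, probe, n_sphere_points)
    mid <- s$atoms$resno == 2
    bb <- s$atoms$is_backbone
    data.frame(resname = rn,
               max_bb = sum(asa[mid & bb]),
               max_sc = sum(asa[mid & !bb]))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
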