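# Solvent accessible surface area and the relative/local burial terms used
# to weight contacts. ASA is computed numerically (Shrake-Rupley) with a
# deterministic Fibonacci-spiral point set, probe radius 1.4 A and 960
# sphere points by default. Waters are excluded from all ASA computations.

#' Per-atom solvent accessible surface area
#'
#' Shrake-Rupley numerical ASA over the structure's non-water atoms.
#' Deterministic for fixed settings.
#'
#' @param s A `bacv_structure` with radii assigned, or a numeric n x 3
#'   coordinate matrix (then `radii` must be given).
#' @param probe Probe radius in Angstrom.
#' @param n_sphere_points Number of test points per atom sphere.
#' @param radii Radii vector when `s` is a bare coordinate matrix.
#' @return Numeric vector of ASA values (Angstrom^2); named by atom id when
#'   called on a structure.
#' @export
compute_asa <- function(s, probe = 1.4, n_sphere_points = 960, radii = NULL) {
  if (inherits(s, "bacv_structure")) {
    idx <- which(!s$atoms$is_water)
    xyz <- coords_matrix(s, idx)
    radii <- s$atoms$vdw[idx]
    if (anyNA(radii)) stop("assign radii and types first")
    out <- cpp_shrake_rupley(xyz, radii, probe, as.integer(n_sphere_points))
    names(out) <- s$atoms$atom_id[idx]
    return(out)
  }
  xyz <- as.matrix(s)
  stopifnot(ncol(xyz) == 3, length(radii) == nrow(xyz))
  cpp_shrake_rupley(xyz, radii, probe, as.integer(n_sphere_points))
}

#' Atom-level relative ASA and burial
#'
#' `E = ASA / asa_ref` and `B = max(0, 1 - E)`. The reference 50 Angstrom^2
#' is roughly half the ASA of an isolated water molecule
#' (4 x 3.14 x 2.8^2 = 98.47).
#'
#' @param asa Numeric vector of atom ASA values.
#' @param asa_ref Reference area (Angstrom^2).
#' @return List with vectors `E` and `B`.
#' @export
atom_relative_terms <- function(asa, asa_ref = 50) {
  E <- asa / asa_ref
  list(E = E, B = pmax(0, 1 - E))
}

#' Residue-level relative ASA and burial
#'
#' Backbone and side-chain ASA are each scaled by the residue type's
#' maximum from the reference table; burial is the clamped complement.
#'
#' @param asa_bb,asa_sc Backbone / side-chain ASA sums of one residue.
#' @param resname Three-letter residue code.
#' @param table Max-ASA reference table (see [max_asa_table]).
#' @return List with `E_bb`, `B_bb`, `E_sc`, `B_sc`.
#' @export
residue_relative_terms <- function(asa_bb, asa_sc, resname,
                                   table = max_asa_table) {
  row <- match(resname, table$resname)
  if (anyNA(row)) stop("residue type missing from max-ASA table: ",
                       paste(unique(resname[is.na(row)]), collapse = ", "))
  E_bb <- asa_bb / table$max_bb[row]
  E_sc <- ifelse(table$max_sc[row] > 0, asa_sc / table$max_sc[row], 0)
  list(E_bb = E_bb, B_bb = pmax(0, 1 - E_bb),
       E_sc = E_sc, B_sc = pmax(0, 1 - E_sc))
}

#' Local relative ASA and burial of an atom
#'
#' The product of the atom-level term with its residue's backbone-level
#' (for N, CA, C, O, OXT) or side-chain-level term.
#'
#' @param E_i,B_i Atom-level terms.
#' @param res Residue-level terms as from [residue_relative_terms()].
#' @param is_backbone Logical: backbone atom?
#' @return List with `E_loc` and `B_loc`.
#' @export
local_terms <- function(E_i, B_i, res, is_backbone) {
  E_loc <- E_i * ifelse(is_backbone, res$E_bb, res$E_sc)
  B_loc <- B_i * ifelse(is_backbone, res$B_bb, res$B_sc)
  list(E_loc = E_loc, B_loc = B_loc)
}

.profile_one_state <- function(s, asa, probe, npts) {
  a <- s$atoms[!s$atoms$is_water, , drop = FALSE]
  at <- atom_relative_terms(asa)
  reskey <- paste(a$chain, a$resno, a$inscode)
  asa_bb <- tapply(asa * a$is_backbone, reskey, sum)
  asa_sc <- tapply(asa * !a$is_backbone, reskey, sum)
  resname <- tapply(a$resname, reskey, `[`, 1)
  rk <- names(asa_bb)
  rt <- residue_relative_terms(as.numeric(asa_bb), as.numeric(asa_sc),
                               as.character(resname))
  m <- match(reskey, rk)
  res_at <- list(E_bb = rt$E_bb[m], B_bb = rt$B_bb[m],
                 E_sc = rt$E_sc[m], B_sc = rt$B_sc[m])
  loc <- local_terms(at$E, at$B, res_at, a$is_backbone)
  list(
    atoms = data.frame(atom_id = a$atom_id, asa = asa, E = at$E, B = at$B,
                       E_loc = loc$E_loc, B_loc = loc$B_loc),
    residues = data.frame(reskey = rk, resname = as.character(resname),
                          asa_bb = as.numeric(asa_bb),
                          asa_sc = as.numeric(asa_sc),
                          E_bb = rt$E_bb, B_bb = rt$B_bb,
                          E_sc = rt$E_sc, B_sc = rt$B_sc)
  )
}

#' Bound- and unbound-state ASA profile of a complex
#'
#' Computes per-atom ASA on the full complex (bound state) and on the rigid
#' split of the two binding partners (unbound state), then derives the
#' relative ASA (`E`), burial (`B`) and their local (atom x residue)
#' products for every non-water atom in both states.
#'
#' @param s A `bacv_structure` with radii/types assigned and sides defined.
#' @param probe Probe radius (Angstrom).
#' @param n_sphere_points Sphere points per atom.
#' @return A `bacv_asa_profile`: list with data.frames `bound` and
#'   `unbound` (atom-level, keyed by atom id) and the residue-level tables.
#' @export
asa_profile <- function(s, probe = 1.4, n_sphere_points = 960) {
  asa_b <- compute_asa(s, probe, n_sphere_points)
  pb <- .profile_one_state(s, unname(asa_b), probe, n_sphere_points)
  halves <- split_unbound(s)
  pu <- lapply(halves, function(h) {
    asa <- compute_asa(h, probe, n_sphere_points)
    .profile_one_state(h, unname(asa), probe, n_sphere_points)
  })
  unbound_atoms <- rbind(pu[[1]]$atoms, pu[[2]]$atoms)
  unbound_atoms <- unbound_atoms[order(unbound_atoms$atom_id), , drop = FALSE]
  rownames(unbound_atoms) <- NULL
  structure(list(bound = pb$atoms, unbound = unbound_atoms,
                 bound_residues = pb$residues,
                 unbound_residues = rbind(pu[[1]]$residues, pu[[2]]$residues),
                 probe = probe, n_sphere_points = n_sphere_points),
            class = "bacv_asa_profile")
}

#' Look up a per-atom column of an ASA profile
#'
#' @param profile A `bacv_asa_profile`.
#' @param atom_ids Atom ids to look up.
#' @param column Column name, e.g. `"B_loc"` or `"E_loc"`.
#' @param state `"bound"` or `"unbound"`.
#' @param default Value returned for atoms absent from the profile (waters).
#' @return Numeric vector aligned with `atom_ids`.
#' @export
profile_lookup <- function(profile, atom_ids, column = "B_loc",
                           state = c("bound", "unbound"), default = NA_real_) {
  state <- match.arg(state)
  tab <- profile[[state]]
  out <- tab[[column]][match(atom_ids, tab$atom_id)]
  out[is.na(out)] <- default
  out
}
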