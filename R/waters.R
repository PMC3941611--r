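# Bound-water detection: a crystallographic water is treated as part of the
# interface when it is held by enough potential hydrogen bonds.

#' Detect bound water molecules
#'
#' A water is *bound* iff (i) it has at least 3 potential hydrogen-bond
#' contacts, or (ii) it has exactly 2 potential hydrogen-bond contacts and
#' at least 2 further contacts with distance below 4 Angstrom. A potential
#' hydrogen-bond contact is a donor/acceptor pair of heavy atoms (N or O)
#' within 3.2 Angstrom. Water-water contacts are never counted.
#'
#' @param s A `bacv_structure` with radii/types assigned.
#' @param hbond_dist Hydrogen-bond distance threshold (Angstrom).
#' @param contact_dist General contact distance threshold (Angstrom).
#' @return Atom ids of bound water oxygens.
#' @export
detect_bound_waters <- function(s, hbond_dist = 3.2, contact_dist = 4.0) {
  a <- s$atoms
  wat <- which(a$is_water)
  if (length(wat) == 0) return(integer(0))
  prot <- which(!a$is_water)
  if (length(prot) == 0) return(integer(0))
  pw <- coords_matrix(s, wat)
  pp <- coords_matrix(s, prot)
  is_no <- a$element[prot] %in% c("N", "O")
  bound <- logical(length(wat))
  for (k in seq_along(wat)) {
    d <- sqrt(colSums((t(pp) - pw[k, ])^2))
    close <- d < contact_dist
    hb <- is_no & d < hbond_dist
    n_hb <- sum(hb)
    n_other <- sum(close & !hb)
    bound[k] <- n_hb >= 3 || (n_hb == 2 && n_other >= 2)
  }
  a$atom_id[wat[bound]]
}
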