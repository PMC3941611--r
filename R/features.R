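# 52-element atomic contact vector features for interfacial alanine
# mutations: a 36-element block over unordered atomic-type pairs built from
# the mutated/new contact sets (inverse squared distance, optionally
# weighted by local ASA burial), plus two 8-element blocks summing local
# relative ASA over the mutated residue's neighbourhood in the bound and
# unbound states.

.n_types <- 8L

# lexicographic index of the unordered type pair (a, b), a <= b
.pair_index_matrix <- local({
  m <- matrix(0L, .n_types, .n_types)
  k <- 0L
  for (a in 1:.n_types) for (b in a:.n_types) {
    k <- k + 1L
    m[a, b] <- m[b, a] <- k
  }
  m
})

pair_block_names <- local({
  nm <- character(36)
  k <- 0
  for (a in 1:.n_types) for (b in a:.n_types) {
    k <- k + 1
    nm[k] <- paste0("pair_", a, "_", b)
  }
  nm
})

.edge_key <- function(i, j) paste(pmin(i, j), pmax(i, j))

#' Mutated and new contact sets of an alanine mutation
#'
#' `M` holds the beta contacts of the wild-type graph absent from the
#' mutant graph, `N` the contacts newly formed in the mutant. Contacts
#' joining covalent-bond nearby atoms (within three bond steps in the
#' wild-type topology) are excluded from both sets; contacts common to both
#' graphs are discarded.
#'
#' @param g_wt,g_mut Wild-type and mutant `bacv_contact_graph`s built with
#'   identical parameters.
#' @param s Wild-type `bacv_structure` with bonds inferred.
#' @return List of data.frames `M` and `N` (columns `i`, `j`, `distance`).
#' @export
diff_contacts <- function(g_wt, g_mut, s) {
  if (!identical(g_wt$params, g_mut$params)) {
    stop("wild-type and mutant graphs built with different parameters")
  }
  bw <- beta_contacts(g_wt)
  bm <- beta_contacts(g_mut)
  kw <- .edge_key(bw$i, bw$j)
  km <- .edge_key(bm$i, bm$j)
  M <- bw[!(kw %in% km), , drop = FALSE]
  N <- bm[!(km %in% kw), , drop = FALSE]
  drop_nearby <- function(df) {
    if (nrow(df) == 0) return(df)
    ids <- unique(c(df$i, df$j))
    steps <- covalent_steps(s, ids, ids)
    near <- steps[cbind(match(df$i, ids), match(df$j, ids))] <= 3
    df[!near, , drop = FALSE]
  }
  list(M = drop_nearby(M), N = drop_nearby(N))
}

.acv_pair_block <- function(diff, s, weights_M = NULL, weights_N = NULL) {
  v <- numeric(36)
  types <- function(ids) s$atoms$type[match(ids, s$atoms$atom_id)]
  add <- function(df, sign, w) {
    if (nrow(df) == 0) return()
    ti <- types(df$i)
    tj <- types(df$j)
    idx <- .pair_index_matrix[cbind(ti, tj)]
    contrib <- sign * w / df$distance^2
    for (k in seq_along(idx)) v[idx[k]] <<- v[idx[k]] + contrib[k]
  }
  add(diff$M, +1, if (is.null(weights_M)) rep(1, nrow(diff$M)) else weights_M)
  add(diff$N, -1, if (is.null(weights_N)) rep(1, nrow(diff$N)) else weights_N)
  names(v) <- pair_block_names
  v
}

#' Basic (unweighted) ACV pair block
#'
#' Element (Ti, Tj) sums `1/d^2` over mutated contacts of that type pair
#' minus the same sum over new contacts.
#'
#' @param diff Output of [diff_contacts()].
#' @param s Wild-type structure (for atom types).
#' @return Named numeric vector of length 36.
#' @export
basic_acv <- function(diff, s) {
  .acv_pair_block(diff, s)
}

#' ASA-weighted ACV pair block
#'
#' Like [basic_acv()] but each contact contributes
#' `B_loc(x) * B_loc(y) / d^2`, down-weighting solvent-exposed atoms to
#' follow the water-exclusion hypothesis. Burial factors come from the
#' state in which a contact exists: the wild-type profile for mutated
#' contacts, the mutant profile for new contacts. Bound-water atoms (absent
#' from ASA profiles) carry unit burial.
#'
#' @param diff Output of [diff_contacts()].
#' @param s Wild-type structure.
#' @param profile_wt,profile_mut `bacv_asa_profile`s of the wild-type and
#'   mutant complexes.
#' @return Named numeric vector of length 36.
#' @export
weighted_acv <- function(diff, s, profile_wt, profile_mut) {
  wgt <- function(df, profile) {
    if (nrow(df) == 0) return(numeric(0))
    iswat <- s$atoms$is_water[match(c(df$i, df$j), s$atoms$atom_id)]
    b <- profile_lookup(profile, c(df$i, df$j), "B_loc", "bound")
    b[iswat] <- 1
    if (anyNA(b)) stop("missing ASA burial for a contact atom")
    b[seq_len(nrow(df))] * b[nrow(df) + seq_len(nrow(df))]
  }
  .acv_pair_block(diff, s,
                  weights_M = wgt(diff$M, profile_wt),
                  weights_N = wgt(diff$N, profile_mut))
}

#' Neighbourhood atom set of a mutated residue
#'
#' Atoms having a beta contact (at the 90-degree skeleton threshold) with
#' any mutated atom, together with the mutated atoms themselves; then, for
#' each member, its covalent-bond nearby atoms (within three steps) are
#' added. Waters are excluded.
#'
#' @param s Wild-type `bacv_structure` with bonds inferred.
#' @param g90 A `bacv_contact_graph` of `s` built at `beta_angle = 90`.
#' @param mutated_ids Atom ids of the mutated atoms.
#' @return Sorted vector of atom ids.
#' @export
neighborhood_set <- function(s, g90, mutated_ids) {
  bc <- beta_contacts(g90)
  touch <- bc$i %in% mutated_ids | bc$j %in% mutated_ids
  S <- unique(c(mutated_ids, bc$i[touch], bc$j[touch]))
  S <- setdiff(S, s$atoms$atom_id[s$atoms$is_water])
  S <- unique(c(S, nearby_atoms(s, S)))
  sort(setdiff(S, s$atoms$atom_id[s$atoms$is_water]))
}

#' Neighbourhood ACV block
#'
#' Per atomic type, the sum of local relative ASA (`E_loc`) over the
#' neighbourhood set, separately in the bound and unbound states.
#'
#' @param s Wild-type structure (for atom types).
#' @param S Atom ids from [neighborhood_set()].
#' @param profile `bacv_asa_profile` of the wild-type complex.
#' @return Named numeric vector of length 16 (8 bound then 8 unbound).
#' @export
neighborhood_vector <- function(s, S, profile) {
  tS <- s$atoms$type[match(S, s$atoms$atom_id)]
  vb <- vu <- numeric(.n_types)
  eb <- profile_lookup(profile, S, "E_loc", "bound")
  eu <- profile_lookup(profile, S, "E_loc", "unbound")
  for (t in seq_len(.n_types)) {
    vb[t] <- sum(eb[tS == t])
    vu[t] <- sum(eu[tS == t])
  }
  setNames(c(vb, vu), c(paste0("nbhd_b_", 1:.n_types),
                        paste0("nbhd_u_", 1:.n_types)))
}

#' Check the interface-contact requirement for a mutation
#'
#' The mutated atoms must have at least one distance-cutoff atomic contact
#' (`d < r_i + r_j + T_d`) with an atom of the partner side.
#' @keywords internal
has_partner_contact <- function(s, mutated_ids, T_d = 3.3) {
  a <- s$atoms
  mi <- match(mutated_ids, a$atom_id)
  own_side <- a$side[mi[1]]
  partner <- which(!is.na(a$side) & a$side != own_side)
  if (length(partner) == 0 || length(mi) == 0) return(FALSE)
  pm <- coords_matrix(s, partner)
  for (k in mi) {
    d <- sqrt(colSums((t(pm) - as.numeric(a[k, c("x", "y", "z")]))^2))
    if (any(d < a$vdw[k] + a$vdw[partner] + T_d)) return(TRUE)
  }
  FALSE
}

#' Featurize one alanine mutation
#'
#' Assembles the 52-element representation: the 36-element type-pair block
#' from the wild-type/mutant beta-contact graph difference (basic inverse
#' squared distance, or ASA-burial weighted) and the 16-element
#' neighbourhood block of summed local relative ASA in bound and unbound
#' states.
#'
#' @param s Wild-type `bacv_structure` (radii/types assigned, bonds
#'   inferred).
#' @param chain,resno,inscode Mutated residue.
#' @param params [contact_params()] for the pair-block graphs (the
#'   neighbourhood always uses `beta_angle = 90`).
#' @param mode `"asa"` for burial-weighted (default) or `"basic"`.
#' @param waters Water handling for the contact graphs.
#' @param cache Optional precomputed list with elements `g_feat`, `g90`,
#'   `profile` for the wild type (used by [featurize_mutations()]).
#' @return Named numeric vector of length 52.
#' @export
featurize_mutation <- function(s, chain, resno, inscode = "",
                               params = contact_params(),
                               mode = c("asa", "basic"),
                               waters = "bound", cache = NULL) {
  mode <- match.arg(mode)
  idx <- residue_atoms(s, chain, resno, inscode)
  if (length(idx) == 0) stop("residue ", chain, resno, " not found")
  mut_ids <- mutated_atom_ids(s, chain, resno, inscode)
  if (!has_partner_contact(s, mut_ids, params$T_d)) {
    stop("mutated atoms of ", chain, resno,
         " have no distance-cutoff contact with the partner side")
  }
  if (is.null(cache)) {
    cache <- list(
      g_feat = build_contact_graph(s, params, waters = waters),
      g90 = build_contact_graph(s, contact_params(params$T_d, 90),
                                waters = waters),
      profile = asa_profile(s)
    )
  }
  mut <- make_alanine_mutant(s, chain, resno, inscode)
  g_mut <- build_contact_graph(mut, params, waters = waters)
  diff <- diff_contacts(cache$g_feat, g_mut, s)
  pair <- if (mode == "basic") {
    basic_acv(diff, s)
  } else {
    profile_mut <- if (nrow(diff$N) > 0) asa_profile(mut) else cache$profile
    weighted_acv(diff, s, cache$profile, profile_mut)
  }
  S <- neighborhood_set(s, cache$g90, mut_ids)
  nbhd <- neighborhood_vector(s, S, cache$profile)
  c(pair, nbhd)
}

#' Featurize a mutation table
#'
#' Vectorised driver over a mutation table; wild-type graphs and ASA
#' profile are computed once. Mutations violating the dataset filters
#' (ALA/GLY targets, no partner contact) are skipped with a warning and
#' flagged in the result.
#'
#' @param s Wild-type `bacv_structure`.
#' @param mutations Data.frame with columns `chain`, `resno`, optionally
#'   `inscode`, `wt_res`, `ddg_exp`.
#' @inheritParams featurize_mutation
#' @return List with `X` (feature matrix, one row per kept mutation),
#'   `mutations` (kept rows) and `skipped` (dropped rows with reasons).
#' @export
featurize_mutations <- function(s, mutations, params = contact_params(),
                                mode = c("asa", "basic"), waters = "bound") {
  mode <- match.arg(mode)
  if (is.null(mutations$inscode)) mutations$inscode <- ""
  cache <- list(
    g_feat = build_contact_graph(s, params, waters = waters),
    g90 = build_contact_graph(s, contact_params(params$T_d, 90),
                              waters = waters),
    profile = asa_profile(s)
  )
  rows <- list()
  kept <- logical(nrow(mutations))
  reasons <- character(nrow(mutations))
  for (k in seq_len(nrow(mutations))) {
    m <- mutations[k, ]
    v <- tryCatch(
      featurize_mutation(s, m$chain, m$resno, m$inscode, params, mode,
                         waters, cache = cache),
      error = function(e) conditionMessage(e)
    )
    if (is.character(v)) {
      reasons[k] <- v
      warning("skipping mutation ", m$chain, m$resno, ": ", v)
    } else {
      kept[k] <- TRUE
      rows[[length(rows) + 1]] <- v
    }
  }
  X <- if (length(rows)) do.call(rbind, rows) else
    matrix(numeric(0), ncol = 52)
  rownames(X) <- paste0(mutations$chain[kept], mutations$resno[kept])
  list(X = X, mutations = mutations[kept, , drop = FALSE],
       skipped = cbind(mutations[!kept, , drop = FALSE],
                       reason = reasons[!kept]))
}
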