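# Beta-contact graphs.
#
# A beta contact between atoms i and j requires (i) distance below the sum
# of van der Waals radii plus a slack T_d, (ii) a shared Voronoi facet
# (equivalently, a Delaunay edge), and (iii) an empty forbidden region: no
# third atom may subtend an angle of at least the beta-skeleton threshold at
# the pair. The graph is produced by composing the three filters.

#' Contact graph parameters
#'
#' @param T_d Distance slack in Angstrom added to the radii sum; the default
#'   3.3 is the diameter of a water molecule (2.8) plus 0.5.
#' @param beta_angle Beta-skeleton angle threshold in degrees; 75 for the
#'   feature graphs, 90 for the mutated-residue neighbourhood.
#' @return A `bacv_contact_params` list.
#' @export
contact_params <- function(T_d = 3.3, beta_angle = 75) {
  stopifnot(T_d > 0, beta_angle > 0, beta_angle <= 180)
  structure(list(T_d = T_d, beta_angle = beta_angle),
            class = "bacv_contact_params")
}

#' Delaunay adjacency of a 3D point set
#'
#' Unordered edges of the 3D Delaunay triangulation, i.e. the pairs of
#' points sharing a Voronoi facet. Each candidate pair is tested exactly:
#' the set of empty-circumsphere centres is a convex region on the pair's
#' bisector plane, obtained by half-plane clipping; a pair is adjacent iff
#' that region has positive area. Fewer than 4 points return all pairs
#' (documented convention). Cospherical degeneracies can be broken with a
#' small deterministic jitter.
#'
#' @param points Numeric n x 3 matrix.
#' @param jitter Amplitude (Angstrom) of a deterministic, index-derived
#'   coordinate jitter applied before testing; 0 (default) disables it.
#' @return Integer m x 2 matrix of point indices, each row `i < j`.
#' @export
delaunay_adjacency <- function(points, jitter = 0) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3)
  n <- nrow(points)
  if (n < 2) return(matrix(integer(0), ncol = 2))
  if (n < 4) {
    idx <- t(utils::combn(n, 2))
    storage.mode(idx) <- "integer"
    return(idx)
  }
  if (jitter > 0) {
    # seedless deterministic hash jitter (fractional part of a scaled sine)
    k <- seq_len(n)
    for (d in 1:3) {
      h <- sin(k * 12.9898 + d * 78.233) * 43758.5453
      points[, d] <- points[, d] + (h - floor(h) - 0.5) * 2 * jitter
    }
  }
  cpp_delaunay_edges(points)
}

#' Distance filter on candidate contacts
#'
#' Keeps edge (i, j) iff `d(i, j) < vdw_i + vdw_j + T_d` (strict).
#'
#' @param edges Integer m x 2 matrix of point indices.
#' @param coords Numeric n x 3 coordinate matrix.
#' @param radii Numeric vector of van der Waals radii (length n).
#' @param T_d Distance slack (Angstrom).
#' @return Filtered edge matrix.
#' @export
distance_filter <- function(edges, coords, radii, T_d = 3.3) {
  if (nrow(edges) == 0) return(edges)
  d <- sqrt(rowSums((coords[edges[, 1], , drop = FALSE] -
                       coords[edges[, 2], , drop = FALSE])^2))
  edges[d < radii[edges[, 1]] + radii[edges[, 2]] + T_d, , drop = FALSE]
}

#' Interior angle subtended at a vertex
#'
#' The angle at `k` in the triangle (i, k, j), in degrees.
#'
#' @param k,i,j Numeric length-3 coordinate vectors.
#' @return Angle in `[0, 180]` degrees.
#' @export
angle_at_vertex <- function(k, i, j) {
  u <- i - k
  v <- j - k
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu < 1e-12 || nv < 1e-12) stop("zero-length arm at vertex")
  acos(max(-1, min(1, sum(u * v) / (nu * nv)))) * 180 / pi
}

#' Beta-skeleton filter
#'
#' Keeps edge (i, j) iff every other point k subtends an angle strictly
#' below `beta_angle` at k (an angle equal to the threshold rejects). The
#' scan over third atoms is bounded by the ball of radius
#' `d / sin(beta_angle)` around the endpoints, which contains every point
#' able to subtend the threshold angle.
#'
#' @param edges Integer m x 2 edge matrix (indices into `coords`).
#' @param coords Numeric n x 3 matrix of all atoms that can interrupt a
#'   contact (the whole structure, not only contact candidates).
#' @param beta_angle Angle threshold in degrees.
#' @return Filtered edge matrix.
#' @export
beta_filter <- function(edges, coords, beta_angle = 75) {
  if (nrow(edges) == 0) return(edges)
  keep <- cpp_beta_keep(as.matrix(coords), edges, beta_angle)
  edges[keep, , drop = FALSE]
}

#' Build the beta-contact graph of a structure
#'
#' Composes Delaunay adjacency, the van der Waals distance filter and the
#' beta-skeleton filter over the structure's atoms. With `waters = "bound"`
#' the bound waters (see [detect_bound_waters()]) participate as nodes;
#' water-water contacts are always dropped.
#'
#' @param s A `bacv_structure` with radii/types assigned.
#' @param params A [contact_params()] object.
#' @param waters `"bound"` to include bound waters, `"none"` for protein
#'   atoms only.
#' @param jitter Passed to [delaunay_adjacency()].
#' @return A `bacv_contact_graph`: list with `params`, `atom_ids` (node
#'   atoms) and `contacts`, a data.frame of all Delaunay edges between nodes
#'   with columns `i`, `j` (atom ids), `distance`, `passes_distance`,
#'   `is_beta`. The beta contacts are the rows with `is_beta`.
#' @export
build_contact_graph <- function(s, params = contact_params(),
                                waters = c("bound", "none"), jitter = 0) {
  waters <- match.arg(waters)
  stopifnot(inherits(params, "bacv_contact_params"))
  if (anyNA(s$atoms$vdw)) stop("assign radii and types first")
  node_idx <- which(!s$atoms$is_water)
  if (waters == "bound") {
    bw <- detect_bound_waters(s)
    node_idx <- sort(c(node_idx, which(s$atoms$atom_id %in% bw)))
  }
  ids <- s$atoms$atom_id[node_idx]
  xyz <- coords_matrix(s, node_idx)
  radii <- s$atoms$vdw[node_idx]
  iswat <- s$atoms$is_water[node_idx]

  edges <- delaunay_adjacency(xyz, jitter = jitter)
  if (nrow(edges) > 0) {
    # drop water-water pairs before any filtering
    edges <- edges[!(iswat[edges[, 1]] & iswat[edges[, 2]]), , drop = FALSE]
  }
  d_all <- if (nrow(edges) > 0) {
    sqrt(rowSums((xyz[edges[, 1], , drop = FALSE] -
                    xyz[edges[, 2], , drop = FALSE])^2))
  } else numeric(0)
  pass_d <- d_all < radii[edges[, 1]] + radii[edges[, 2]] + params$T_d
  cand <- edges[pass_d, , drop = FALSE]
  kept <- beta_filter(cand, xyz, params$beta_angle)
  key <- paste(kept[, 1], kept[, 2])
  is_beta <- pass_d
  is_beta[pass_d] <- paste(cand[, 1], cand[, 2]) %in% key
  contacts <- data.frame(
    i = ids[edges[, 1]], j = ids[edges[, 2]], distance = d_all,
    passes_distance = pass_d, is_beta = is_beta
  )
  structure(list(structure = s, params = params, waters = waters,
                 atom_ids = ids, contacts = contacts),
            class = "bacv_contact_graph")
}

#' Beta-contact edge set of a graph
#'
#' @param g A `bacv_contact_graph`.
#' @return Data.frame of beta contacts (`i`, `j`, `distance`).
#' @export
beta_contacts <- function(g) {
  g$contacts[g$contacts$is_beta, c("i", "j", "distance")]
}

#' Classify contacts relative to the binding interface
#'
#' Each beta contact is `"interface"` (its atoms lie on different sides),
#' `"within"` (same side) or `"water"` (involves a bound water, which counts
#' with neither side).
#'
#' @param g A `bacv_contact_graph`.
#' @return Data.frame of beta contacts with a `category` column.
#' @export
contact_categories <- function(g) {
  bc <- beta_contacts(g)
  a <- g$structure$atoms
  si <- a$side[match(bc$i, a$atom_id)]
  sj <- a$side[match(bc$j, a$atom_id)]
  bc$category <- ifelse(is.na(si) | is.na(sj), "water",
                        ifelse(si != sj, "interface", "within"))
  bc
}

#' Contacts across the binding interface
#'
#' @param g A `bacv_contact_graph`.
#' @return Data.frame of cross-side beta contacts.
#' @export
interface_contacts <- function(g) {
  cc <- contact_categories(g)
  cc[cc$category == "interface", c("i", "j", "distance")]
}

#' @export
print.bacv_contact_graph <- function(x, ...) {
  cat("bacv_contact_graph:", nrow(x$contacts), "Delaunay edges,",
      sum(x$contacts$passes_distance), "distance-cutoff contacts,",
      sum(x$contacts$is_beta), "beta contacts (T_d =", x$params$T_d,
      ", beta =", x$params$beta_angle, "deg)\n")
  invisible(x)
}
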