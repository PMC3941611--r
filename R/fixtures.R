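# Seeded synthetic fixtures: random atom clouds, toy two-chain complexes
# with optional waters, and linear-response mutation datasets. All
# generators are pure functions of their arguments (including the seed);
# the caller's RNG state is left untouched.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Seeded random point cloud with a minimum separation
#'
#' Rejection-sampled uniform points in a cubic box with all pairwise
#' distances at least `min_sep`, emulating non-overlapping heavy atoms.
#'
#' @param n Number of points.
#' @param box Box edge length (Angstrom).
#' @param min_sep Minimum pairwise distance (Angstrom).
#' @param seed Integer seed; identical arguments give identical output.
#' @param max_tries Attempts per point before declaring the packing
#'   infeasible.
#' @return Numeric n x 3 matrix.
#' @export
random_cloud <- function(n, box = 20, min_sep = 3, seed = 1,
                         max_tries = 2000) {
  stopifnot(min_sep > 0, n >= 1)
  with_seed(seed, {
    pts <- matrix(NA_real_, n, 3)
    for (k in seq_len(n)) {
      placed <- FALSE
      for (t in seq_len(max_tries)) {
        p <- runif(3, 0, box)
        if (k == 1 ||
            min(sqrt(rowSums((pts[seq_len(k - 1), , drop = FALSE] -
                                rep(p, each = k - 1))^2))) >= min_sep) {
          pts[k, ] <- p
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        stop("packing infeasible: could not place point ", k, " of ", n,
             " in a box of ", box, " A at separation ", min_sep)
      }
    }
    pts
  })
}

# numerically place a water oxygen so that it satisfies (or violates) the
# bound-water rules against the given structure
.place_bound_water <- function(s, kind = c("bound", "free")) {
  kind <- match.arg(kind)
  a <- s$atoms
  if (kind == "free") {
    # far from everything: no contact within 4 A
    return(c(max(a$x) + 20, max(a$y) + 20, max(a$z) + 20))
  }
  # search hydrogen-bond anchor triples among interface N/O atoms for a
  # position within 3.2 A of all three while clear of clashes elsewhere
  prot <- which(!a$is_water)
  no <- prot[a$element[prot] %in% c("N", "O")]
  xyz <- coords_matrix(s, prot)
  pno <- coords_matrix(s, no)
  # N/O atoms close to the other side (interface region)
  near_partner <- vapply(seq_along(no), function(k) {
    other <- prot[a$side[prot] != a$side[no[k]]]
    min(sqrt(colSums((t(coords_matrix(s, other)) - pno[k, ])^2))) < 9
  }, logical(1))
  cand <- which(near_partner)
  best_pos <- NULL
  best_obj <- Inf
  score <- function(p, anchors) {
    dh <- sqrt(colSums((t(anchors) - p)^2))
    dall <- sqrt(colSums((t(xyz) - p)^2))
    max(dh) + 10 * max(0, 2.4 - min(dall))
  }
  for (tri in utils::combn(cand, 3, simplify = FALSE)) {
    anchors <- pno[tri, , drop = FALSE]
    if (max(dist(anchors)) > 6.2) next
    fit <- optim(colMeans(anchors), score, anchors = anchors,
                 method = "Nelder-Mead", control = list(maxit = 300))
    if (fit$value < best_obj) {
      best_obj <- fit$value
      best_pos <- fit$par
    }
    if (best_obj < 3.0) break
  }
  if (is.null(best_pos)) stop("no hydrogen-bond pocket found for a bound water")
  best_pos
}

# rotate a built chain so the principal axis of its CA trace lies along x
# (CA1 -> CAn pointing in +x), centred at the origin
.axis_align <- function(df) {
  xyz <- as.matrix(df[, c("x", "y", "z")])
  ca <- xyz[df$name == "CA", , drop = FALSE]
  ctr <- colMeans(ca)
  xyz <- sweep(xyz, 2, ctr)
  sv <- svd(sweep(ca, 2, ctr))
  R <- sv$v
  if (det(R) < 0) R[, 3] <- -R[, 3]
  xyz <- xyz %*% R
  cav <- sweep(ca, 2, ctr) %*% R
  if (cav[nrow(cav), 1] < cav[1, 1]) {
    xyz[, 1:2] <- -xyz[, 1:2]  # 180-degree turn about z keeps chirality
  }
  df[, c("x", "y", "z")] <- xyz
  df
}

#' Toy two-chain protein complex
#'
#' Two short idealized helical peptide chains (A and B), each aligned with
#' its principal axis along x, posed side by side with a contact interface
#' running along their length. Optional waters are placed to satisfy
#' (`waters = "bound"`) or violate (`waters = "free"`) the bound-water
#' rules by construction.
#'
#' @param seq_a,seq_b Residue sequences of the two chains.
#' @param gap Minimum inter-chain atom distance after posing (Angstrom).
#' @param waters `"none"`, `"bound"`, `"free"` or `"both"`.
#' @param stagger Shift of chain B along its axis (Angstrom).
#' @param phi,psi Backbone torsions (degrees); helical by default.
#' @return A `bacv_structure` with radii/types assigned and covalent
#'   topology inferred.
#' @export
toy_complex <- function(seq_a = c("LYS", "TRP", "GLU", "SER", "ARG",
                                  "LEU", "THR", "ASN"),
                        seq_b = c("TYR", "LEU", "ASN", "PHE", "VAL",
                                  "GLN", "MET"),
                        gap = 3.2, waters = c("none", "bound", "free", "both"),
                        stagger = 0, phi = -57, psi = -47) {
  waters <- match.arg(waters)
  ca <- .axis_align(build_peptide(seq_a, chain = "A", phi = phi, psi = psi))
  cb <- .axis_align(build_peptide(seq_b, chain = "B", phi = phi, psi = psi))
  # flip B about the x axis so the two chains face each other across y
  cb$y <- -cb$y
  cb$x <- cb$x + stagger
  xyz_a <- as.matrix(ca[, c("x", "y", "z")])
  xyz_b <- as.matrix(cb[, c("x", "y", "z")])
  min_sep <- function(A, B) {
    d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
    sqrt(max(0, min(d2)))
  }
  # translate B upward until the closest approach reaches the gap
  dy <- 0
  while (min_sep(xyz_a, sweep(xyz_b, 2, c(0, dy, 0), "+")) < gap) {
    dy <- dy + 0.25
  }
  cb$y <- cb$y + dy
  atoms <- rbind(ca, cb)
  s <- new_structure(atoms, sides = list("A", "B"))
  s <- assign_radii_and_types(s)
  if (waters %in% c("bound", "both")) {
    s <- .add_water(s, .place_bound_water(s, "bound"))
  }
  if (waters %in% c("free", "both")) {
    s <- .add_water(s, .place_bound_water(s, "free"))
  }
  infer_covalent_topology(s)
}

.add_water <- function(s, pos) {
  w <- data.frame(name = "O", element = "O", resname = "HOH", chain = "W",
                  resno = max(s$atoms$resno) + 1 + sum(s$atoms$is_water),
                  inscode = "", x = pos[1], y = pos[2], z = pos[3],
                  is_water = TRUE, stringsAsFactors = FALSE)
  atoms <- rbind(s$atoms[, names(w)], w)
  s2 <- new_structure(atoms, sides = s$sides)
  assign_radii_and_types(s2)
}

#' Synthetic mutation table for a toy complex
#'
#' Lists every non-ALA/GLY residue whose side chain passes the
#' partner-contact filter, with a seeded experimental binding free energy
#' change: an exponential-tailed positive value so that a realistic
#' minority of mutations are hot spots (at least 2 kcal/mol).
#'
#' @param s A `bacv_structure` from [toy_complex()].
#' @param seed Integer seed.
#' @param hotspot_fraction Approximate fraction of hot spots.
#' @return Data.frame with `chain`, `resno`, `wt_res`, `ddg_exp`.
#' @export
toy_mutations <- function(s, seed = 1, hotspot_fraction = 0.25) {
  a <- s$atoms[!s$atoms$is_water, ]
  res <- unique(a[, c("chain", "resno", "resname")])
  res <- res[!(res$resname %in% c("ALA", "GLY")), , drop = FALSE]
  ok <- vapply(seq_len(nrow(res)), function(k) {
    ids <- mutated_atom_ids(s, res$chain[k], res$resno[k])
    length(ids) > 0 && has_partner_contact(s, ids)
  }, logical(1))
  res <- res[ok, , drop = FALSE]
  with_seed(seed, {
    n <- nrow(res)
    hot <- runif(n) < hotspot_fraction
    ddg <- ifelse(hot, 2 + rexp(n, rate = 0.5), runif(n, -0.5, 1.9))
    data.frame(chain = res$chain, resno = res$resno, wt_res = res$resname,
               ddg_exp = round(ddg, 2), stringsAsFactors = FALSE)
  })
}

#' Linear-response feature/ddG dataset
#'
#' Features drawn as independent standard normals; the response is the
#' linear combination with the given coefficients plus Gaussian noise.
#'
#' @param n Number of rows.
#' @param coef True coefficient vector (length 52 by default).
#' @param noise_sd Noise standard deviation (kcal/mol).
#' @param seed Integer seed.
#' @param intercept Constant offset added to the response.
#' @return List with `X`, `y` and the true `coef`.
#' @export
linear_response_dataset <- function(n = 400, coef = NULL, noise_sd = 0.5,
                                    seed = 1, intercept = 1) {
  with_seed(seed, {
    if (is.null(coef)) coef <- rnorm(52)
    X <- matrix(rnorm(n * length(coef)), n, length(coef))
    colnames(X) <- c(pair_block_names,
                     paste0("nbhd_b_", 1:8),
                     paste0("nbhd_u_", 1:8))[seq_along(coef)]
    y <- intercept + drop(X %*% coef) + rnorm(n, sd = noise_sd)
    list(X = X, y = y, coef = coef)
  })
}
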