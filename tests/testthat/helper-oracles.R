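# Independent brute-force oracles used to validate the geometric kernels.
# All are deliberately naive (full enumeration, no spatial index) and do not
# share code with the implementations they check.

# Delaunay edges by empty-circumsphere enumeration over all point quadruples
brute_delaunay <- function(pts) {
  n <- nrow(pts)
  stopifnot(n >= 4)
  edges <- matrix(0L, 0, 2)
  qs <- utils::combn(n, 4)
  for (q in seq_len(ncol(qs))) {
    idx <- qs[, q]
    A <- 2 * (pts[idx[2:4], , drop = FALSE] -
                matrix(pts[idx[1], ], 3, 3, byrow = TRUE))
    b <- rowSums(pts[idx[2:4], , drop = FALSE]^2) - sum(pts[idx[1], ]^2)
    if (abs(det(A)) < 1e-9) next   # coplanar quadruple
    ctr <- solve(A, b)
    r2 <- sum((pts[idx[1], ] - ctr)^2)
    rest <- pts[-idx, , drop = FALSE]
    d2 <- rowSums((rest - matrix(ctr, nrow(rest), 3, byrow = TRUE))^2)
    if (all(d2 > r2 + 1e-9)) {
      edges <- rbind(edges, t(utils::combn(idx, 2)))
    }
  }
  unique(edges[order(edges[, 1], edges[, 2]), , drop = FALSE])
}

edge_key <- function(e) {
  if (nrow(e) == 0) return(character(0))
  sort(paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
}

# O(n^3) beta-skeleton filter: plain loops over every edge and third point
brute_beta_filter <- function(edges, pts, beta_angle) {
  keep <- logical(nrow(edges))
  for (t in seq_len(nrow(edges))) {
    i <- edges[t, 1]
    j <- edges[t, 2]
    ok <- TRUE
    for (k in seq_len(nrow(pts))) {
      if (k == i || k == j) next
      if (angle_at_vertex(pts[k, ], pts[i, ], pts[j, ]) >= beta_angle) {
        ok <- FALSE
        break
      }
    }
    keep[t] <- ok
  }
  edges[keep, , drop = FALSE]
}

# naive breadth-first covalent step count on a bond edge list
brute_steps <- function(bonds, a, b) {
  if (a == b) return(0)
  frontier <- a
  seen <- a
  steps <- 0
  while (length(frontier) > 0) {
    steps <- steps + 1
    nxt <- unique(c(bonds[bonds[, 1] %in% frontier, 2],
                    bonds[bonds[, 2] %in% frontier, 1]))
    nxt <- setdiff(nxt, seen)
    if (b %in% nxt) return(steps)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  Inf
}

# naive basic-mode pair block: loops over contact sets, no vector tricks
brute_pair_block <- function(M, N, s) {
  v <- numeric(36)
  lab <- function(a, b) paste(min(a, b), max(a, b))
  labels <- character(0)
  k <- 0
  for (a in 1:8) for (b in a:8) {
    k <- k + 1
    labels[k] <- lab(a, b)
  }
  type_of <- function(id) s$atoms$type[s$atoms$atom_id == id]
  for (r in seq_len(nrow(M))) {
    key <- lab(type_of(M$i[r]), type_of(M$j[r]))
    v[labels == key] <- v[labels == key] + 1 / M$distance[r]^2
  }
  for (r in seq_len(nrow(N))) {
    key <- lab(type_of(N$i[r]), type_of(N$j[r]))
    v[labels == key] <- v[labels == key] - 1 / N$distance[r]^2
  }
  v
}

rigid_transform <- function(s, angles = c(0.4, -0.7, 1.2),
                            shift = c(5, -3, 8)) {
  cx <- cos(angles[1]); sx <- sin(angles[1])
  cy <- cos(angles[2]); sy <- sin(angles[2])
  cz <- cos(angles[3]); sz <- sin(angles[3])
  R <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3) %*%
    matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3) %*%
    matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3)
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")]) %*% R
  s$atoms$x <- xyz[, 1] + shift[1]
  s$atoms$y <- xyz[, 2] + shift[2]
  s$atoms$z <- xyz[, 3] + shift[3]
  s
}

# small shared fixtures (built once per test run)
toy_wt <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- toy_complex()
    val
  }
})

toy_wt_water <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- toy_complex(waters = "both")
    val
  }
})
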