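# Contact geometry: Delaunay adjacency, distance and beta-skeleton filters,
# and the composed contact graph.

test_that("tetrahedron and starred interior point triangulate correctly", {
  tet <- rbind(c(0, 0, 0), c(3, 0, 0), c(0, 3, 0), c(0, 0, 3))
  expect_equal(nrow(delaunay_adjacency(tet)), 6)
  inner <- rbind(tet, c(0.6, 0.6, 0.6))
  de <- delaunay_adjacency(inner)
  expect_equal(sum(de == 5), 4)  # interior point adjacent to all vertices
})

test_that("fewer than four points fall back to the all-pairs convention", {
  expect_equal(nrow(delaunay_adjacency(matrix(rnorm(9), 3, 3))), 3)
  expect_equal(nrow(delaunay_adjacency(matrix(rnorm(6), 2, 3))), 1)
})

test_that("Delaunay adjacency equals empty-circumsphere enumeration", {
  for (sd in 1:10) {
    pts <- random_cloud(n = 12 + (sd %% 4), box = 12, min_sep = 2.2,
                        seed = 100 + sd)
    expect_identical(edge_key(delaunay_adjacency(pts)),
                     edge_key(brute_delaunay(pts)),
                     label = paste("seed", sd))
  }
})

test_that("distance filter keeps strictly sub-threshold pairs only", {
  coords <- rbind(c(0, 0, 0), c(6.8, 0, 0))
  radii <- c(1.8, 1.8)
  e <- matrix(c(1L, 2L), 1)
  expect_equal(nrow(distance_filter(e, coords, radii, T_d = 3.3)), 1)
  coords[2, 1] <- 6.95
  expect_equal(nrow(distance_filter(e, coords, radii, T_d = 3.3)), 0)
  # touching spheres at T_d = 0 are excluded (strict inequality)
  coords[2, 1] <- 3.6
  expect_equal(nrow(distance_filter(e, coords, radii, T_d = 0)), 0)
})

test_that("vertex angles match the law of cosines", {
  # sides |AB| = 1.5, |BC| = |AC| = 3.6: angle at B rounds to 78 degrees
  A <- c(0, 0, 0)
  B <- c(1.5, 0, 0)
  xc <- (1.5^2 + 3.6^2 - 3.6^2) / (2 * 1.5)
  C <- c(xc, sqrt(3.6^2 - xc^2), 0)
  ang <- angle_at_vertex(B, A, C)
  expect_equal(round(ang), 78)
  expect_equal(ang, acos(1.5 / (2 * 3.6) ) * 180 / pi, tolerance = 1e-10)
  # Thales: right angle on the circle with the segment as diameter
  expect_equal(angle_at_vertex(c(1, 1, 0), c(0, 0, 0), c(2, 0, 0)), 90)
  # equilateral triangle
  expect_equal(angle_at_vertex(c(0.5, sqrt(3) / 2, 0), c(0, 0, 0),
                               c(1, 0, 0)), 60)
  expect_error(angle_at_vertex(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0)),
               "zero-length")
})

test_that("beta filter matches the cubic brute-force oracle", {
  for (sd in 1:25) {
    n <- 10 + (sd * 7) %% 21
    pts <- random_cloud(n = n, box = 14, min_sep = 2.0, seed = 200 + sd)
    edges <- t(utils::combn(n, 2))
    storage.mode(edges) <- "integer"
    d <- sqrt(rowSums((pts[edges[, 1], ] - pts[edges[, 2], ])^2))
    edges <- edges[d < 8, , drop = FALSE]
    for (ba in c(75, 90)) {
      expect_identical(edge_key(beta_filter(edges, pts, ba)),
                       edge_key(brute_beta_filter(edges, pts, ba)),
                       label = paste("seed", sd, "angle", ba))
    }
  }
})

test_that("a collinear midpoint interrupts any contact", {
  pts <- rbind(c(0, 0, 0), c(4, 0, 0), c(2, 0, 0))
  e <- matrix(c(1L, 2L), 1)
  expect_equal(nrow(beta_filter(e, pts, 180)), 0)
  # with no third atom the condition is vacuous
  expect_equal(nrow(beta_filter(e, pts[1:2, ], 75)), 1)
})

test_that("filters are nested and monotone in their parameters", {
  s <- toy_wt()
  g75 <- build_contact_graph(s, contact_params(3.3, 75))
  g90 <- build_contact_graph(s, contact_params(3.3, 90))
  ct75 <- g75$contacts
  ct90 <- g90$contacts
  k75 <- paste(ct75$i, ct75$j)[ct75$is_beta]
  k90 <- paste(ct90$i, ct90$j)[ct90$is_beta]
  kd <- paste(ct75$i, ct75$j)[ct75$passes_distance]
  expect_true(all(k75 %in% k90))       # beta(75) within beta(90)
  expect_true(all(k90 %in% kd))        # beta within distance-filtered
  expect_true(all(ct75$is_beta <= ct75$passes_distance))  # within Delaunay set
  # larger T_d never removes contacts
  g_big <- build_contact_graph(s, contact_params(4.5, 75))
  k_big <- with(g_big$contacts, paste(i, j)[is_beta])
  expect_true(all(k75 %in% k_big))
})

test_that("beta filter is invariant to atom and edge ordering", {
  pts <- random_cloud(n = 18, box = 14, min_sep = 2.2, seed = 42)
  edges <- t(utils::combn(18L, 2))
  storage.mode(edges) <- "integer"
  kept <- edge_key(beta_filter(edges, pts, 75))
  perm <- rev(seq_len(nrow(edges)))
  kept_perm <- edge_key(beta_filter(edges[perm, ], pts, 75))
  expect_identical(kept, kept_perm)
})

test_that("contact graphs are invariant under rigid motion", {
  s <- toy_wt()
  g1 <- build_contact_graph(s, contact_params(3.3, 75))
  g2 <- build_contact_graph(rigid_transform(s), contact_params(3.3, 75))
  b1 <- beta_contacts(g1)
  b2 <- beta_contacts(g2)
  expect_identical(paste(b1$i, b1$j), paste(b2$i, b2$j))
  expect_equal(b1$distance, b2$distance, tolerance = 1e-9)
})

test_that("graph equals the stagewise composition applied manually", {
  s <- toy_wt()
  params <- contact_params(3.3, 75)
  g <- build_contact_graph(s, params, waters = "none")
  idx <- which(!s$atoms$is_water)
  xyz <- as.matrix(s$atoms[idx, c("x", "y", "z")])
  de <- delaunay_adjacency(xyz)
  df <- distance_filter(de, xyz, s$atoms$vdw[idx], params$T_d)
  bf <- beta_filter(df, xyz, params$beta_angle)
  manual <- sort(paste(s$atoms$atom_id[idx][pmin(bf[, 1], bf[, 2])],
                       s$atoms$atom_id[idx][pmax(bf[, 1], bf[, 2])]))
  got <- beta_contacts(g)
  expect_identical(sort(paste(got$i, got$j)), manual)
})

test_that("interface classification partitions the beta contacts", {
  g <- build_contact_graph(toy_wt_water(), contact_params(3.3, 75))
  cc <- contact_categories(g)
  expect_equal(nrow(cc), sum(g$contacts$is_beta))
  expect_true(all(cc$category %in% c("interface", "within", "water")))
  expect_equal(nrow(interface_contacts(g)),
               sum(cc$category == "interface"))
  expect_gt(nrow(interface_contacts(g)), 0)
  # single-side structure has no interface contacts
  h <- split_unbound(toy_wt())[[1]]
  gh <- build_contact_graph(h, contact_params(3.3, 75))
  expect_equal(nrow(interface_contacts(gh)), 0)
})

test_that("water-water contacts are dropped from the graph", {
  g <- build_contact_graph(toy_wt_water(), contact_params(3.3, 90))
  a <- g$structure$atoms
  wi <- a$is_water[match(g$contacts$i, a$atom_id)]
  wj <- a$is_water[match(g$contacts$j, a$atom_id)]
  expect_false(any(wi & wj))
})
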