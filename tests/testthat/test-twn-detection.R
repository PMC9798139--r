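test_that("pair energy matches the term-by-term oracle and is symmetric", {
  set.seed(42)
  p <- tip3p_params()
  for (rep in 1:200) {
    a <- random_water(runif(3, -5, 5))
    b <- random_water(runif(3, -5, 5))
    if (sqrt(sum((a[1, ] - b[1, ])^2)) < 1e-3) next
    v <- pair_interaction_energy(a, b, p)
    expect_equal(v, oracle_pair_energy(a, b, p), tolerance = 1e-12)
    expect_equal(v, pair_interaction_energy(b, a, p), tolerance = 1e-10)
  }
})

test_that("pair energy vanishes at large separation and errors when singular", {
  set.seed(7)
  a <- random_water(c(0, 0, 0))
  b <- random_water(c(100, 0, 0))
  expect_lt(abs(pair_interaction_energy(a, b)), 0.01)
  expect_error(pair_interaction_energy(a, a), "singular")
})

test_that("minimum-image convention folds distant periodic images back", {
  set.seed(11)
  box <- c(20, 20, 20)
  a <- random_water(c(1, 1, 1))
  b_near <- a
  b_near[, 1] <- b_near[, 1] + 2.8
  b_image <- b_near
  b_image[, 1] <- b_image[, 1] - box[1]     # same molecule, shifted a box
  v_direct <- pair_interaction_energy(a, b_near, box = box)
  v_image <- pair_interaction_energy(a, b_image, box = box)
  expect_equal(v_image, v_direct, tolerance = 1e-12)
  expect_equal(v_direct,
               oracle_pair_energy(a, b_near, tip3p_params(), box = box),
               tolerance = 1e-12)
})

test_that("ideal hydrogen-bond dimer clears the criterion; 6 A pair does not", {
  d <- ideal_dimer(2.8)
  v <- pair_interaction_energy(d$donor, d$acceptor)
  expect_equal(v, oracle_pair_energy(d$donor, d$acceptor),
               tolerance = 1e-12)
  expect_lte(v, -2.25)
  far <- ideal_dimer(6)
  expect_gt(pair_interaction_energy(far$donor, far$acceptor), -2.25)
})

test_that("hbond_graph yields the expected edges on tiny frames", {
  expect_identical(nrow(hbond_graph(random_frame(0))$edges), 0L)
  set.seed(1)
  expect_identical(nrow(hbond_graph(random_frame(1))$edges), 0L)
  d <- ideal_dimer(2.8)
  f <- frame_from_waters(list(d$donor, d$acceptor))
  g <- hbond_graph(f)
  expect_identical(g$edges, cbind(i = 1L, j = 2L))
  far <- ideal_dimer(6)
  f6 <- frame_from_waters(list(far$donor, far$acceptor))
  expect_identical(nrow(hbond_graph(f6)$edges), 0L)
})

test_that("borderline pairs toggle edge membership exactly at the criterion", {
  # find the O-O separation where the ideal dimer energy crosses -2.25
  p <- tip3p_params()
  target <- function(r) {
    d <- ideal_dimer(r)
    oracle_pair_energy(d$donor, d$acceptor, p) - p$hbond_criterion
  }
  r_star <- uniroot(target, c(2.8, 6), tol = 1e-12)$root
  for (eps in c(-1e-4, 1e-4)) {
    d <- ideal_dimer(r_star + eps)
    f <- frame_from_waters(list(d$donor, d$acceptor))
    edges <- hbond_graph(f, p)$edges
    if (eps < 0) expect_identical(nrow(edges), 1L)   # deeper = bonded
    else expect_identical(nrow(edges), 0L)
  }
})

test_that("find_three_rings handles canonical small graphs", {
  tri <- cbind(c(1L, 2L, 1L), c(2L, 3L, 3L))
  expect_equal(unname(find_three_rings(tri, n = 3L)),
               matrix(c(1L, 2L, 3L), 1L))
  k4 <- t(utils::combn(4L, 2L))
  rings <- find_three_rings(k4, n = 4L)
  expect_identical(nrow(rings), 4L)             # C(4,3)
  expect_equal(unname(rings), t(utils::combn(4L, 3L)))
  expect_identical(nrow(find_three_rings(matrix(integer(0), ncol = 2L),
                                         n = 5L)), 0L)
})

test_that("triangle enumeration matches brute force on random graphs", {
  set.seed(99)
  for (rep in 1:60) {
    n <- sample(3:40, 1)
    prob <- runif(1, 0.02, 0.3)
    all_pairs <- t(utils::combn(n, 2L))
    edges <- all_pairs[runif(nrow(all_pairs)) < prob, , drop = FALSE]
    got <- find_three_rings(edges, n = n)
    want <- oracle_triangles_from_edges(edges, n)
    expect_equal(unname(got), unname(want))
  }
})

test_that("detect_twns finds planted triangles with correct centroids", {
  tri <- planted_triangle(c(2, -1, 3))
  f <- water_frame(tri$o, tri$h1, tri$h2, frame_index = 4L)
  rings <- detect_twns(f)
  expect_identical(nrow(rings), 1L)
  expect_equal(unlist(rings[1, c("centroid_x", "centroid_y",
                                 "centroid_z")], use.names = FALSE),
               c(2, -1, 3), tolerance = 1e-9)
  # centroid is the mean of the three oxygen positions
  expect_equal(unlist(rings[1, c("centroid_x", "centroid_y",
                                 "centroid_z")], use.names = FALSE),
               colMeans(f$o), tolerance = 1e-12)
  expect_true(all(unlist(rings[1, c("e_ij", "e_jk", "e_ik")]) <= -2.25))
})

test_that("a hydrogen-bonded chain without a cycle yields no ring", {
  d <- ideal_dimer(2.8)
  shift <- function(w, dx) { w[, 1] <- w[, 1] + dx; w }
  # four waters along +x, each donating to the next: path graph on 4 nodes
  waters <- list(d$donor, shift(d$donor, 2.8), shift(d$donor, 5.6),
                 shift(d$acceptor, 5.6))
  f <- frame_from_waters(waters)
  g <- hbond_graph(f)
  expect_identical(nrow(find_three_rings(g)), 0L)
  expect_identical(nrow(detect_twns(f)), 0L)
})

test_that("energies and ring detection are invariant under rigid motion", {
  set.seed(5)
  tri <- planted_triangle(c(0, 0, 0))
  extra <- random_water(c(6, 6, 0))
  f <- water_frame(rbind(tri$o, extra[1, ]), rbind(tri$h1, extra[2, ]),
                   rbind(tri$h2, extra[3, ]))
  R <- ora_rotation(c(1, 2, 3), 0.83)
  t_vec <- c(-4, 2, 9)
  move <- function(m) m %*% t(R) + matrix(t_vec, nrow(m), 3, byrow = TRUE)
  f2 <- water_frame(move(f$o), move(f$h1), move(f$h2))
  r1 <- detect_twns(f); r2 <- detect_twns(f2)
  expect_equal(r1[, c("water_i", "water_j", "water_k")],
               r2[, c("water_i", "water_j", "water_k")])
  expect_equal(unlist(r2[, c("e_ij", "e_jk", "e_ik")]),
               unlist(r1[, c("e_ij", "e_jk", "e_ik")]), tolerance = 1e-9)
  cen1 <- as.matrix(r1[, c("centroid_x", "centroid_y", "centroid_z")])
  cen2 <- as.matrix(r2[, c("centroid_x", "centroid_y", "centroid_z")])
  expect_equal(unname(cen2), unname(move(cen1)), tolerance = 1e-9)
})

test_that("adding a water never removes rings among the original waters", {
  set.seed(31)
  for (rep in 1:20) {
    f <- random_frame(sample(5:15, 1))
    before <- detect_twns(f)
    extra <- random_water(runif(3, -6, 6))
    if (min(sqrt(rowSums((f$o - matrix(extra[1, ], n_waters(f), 3,
                                       byrow = TRUE))^2))) < 0.5) next
    f2 <- water_frame(rbind(f$o, extra[1, ]), rbind(f$h1, extra[2, ]),
                      rbind(f$h2, extra[3, ]))
    after <- detect_twns(f2)
    key <- function(r) paste(r$water_i, r$water_j, r$water_k)
    among_original <- after[after$water_k <= n_waters(f), ]
    expect_true(all(key(before) %in% key(among_original)))
  }
})
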