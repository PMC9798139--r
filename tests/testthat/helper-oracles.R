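# Independent oracles used across the suite. These deliberately avoid the
# package's internal code paths: the energy oracle loops term by term, the
# triangle oracle scans every C(n,3) triple, and the water builder uses its
# own rotation code.

oracle_pair_energy <- function(a, b, params = tip3p_params(),
                               box = NULL) {
  q <- c(params$q_O, params$q_H, params$q_H)
  dist1 <- function(p, r) {
    d <- p - r
    if (!is.null(box)) d <- d - box * round(d / box)
    sqrt(sum(d^2))
  }
  e <- 0
  for (i in 1:3) for (j in 1:3)
    e <- e + params$coulomb_constant * q[i] * q[j] / dist1(a[i, ], b[j, ])
  roo <- dist1(a[1, ], b[1, ])
  e + params$A / roo^12 - params$C / roo^6
}

# all-triples brute force: triangle iff all three pair energies clear the
# criterion (energies from the term-by-term oracle, no prescreen)
oracle_rings <- function(frame, params = tip3p_params()) {
  n <- n_waters(frame)
  out <- matrix(integer(0), ncol = 3L)
  if (n < 3L) return(out)
  emat <- matrix(NA_real_, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    emat[i, j] <- oracle_pair_energy(get_water(frame, i),
                                     get_water(frame, j), params,
                                     box = frame$box)
  trips <- utils::combn(n, 3L)
  hit <- apply(trips, 2L, function(t)
    emat[t[1], t[2]] <= params$hbond_criterion &&
      emat[t[2], t[3]] <= params$hbond_criterion &&
      emat[t[1], t[3]] <= params$hbond_criterion)
  t(trips[, hit, drop = FALSE])
}

oracle_triangles_from_edges <- function(edges, n) {
  if (n < 3L) return(matrix(integer(0), ncol = 3L))
  adj <- matrix(FALSE, n, n)
  if (nrow(edges)) {
    adj[edges] <- TRUE
    adj[edges[, 2:1, drop = FALSE]] <- TRUE
  }
  trips <- utils::combn(n, 3L)
  hit <- apply(trips, 2L, function(t)
    adj[t[1], t[2]] && adj[t[2], t[3]] && adj[t[1], t[3]])
  t(trips[, hit, drop = FALSE])
}

# rotation helper independent of the package's Rodrigues implementation:
# axis-angle via quaternion
ora_rotation <- function(axis, theta) {
  a <- axis / sqrt(sum(axis^2))
  w <- cos(theta / 2); v <- sin(theta / 2) * a
  matrix(c(
    1 - 2 * (v[2]^2 + v[3]^2), 2 * (v[1] * v[2] - w * v[3]),
    2 * (v[1] * v[3] + w * v[2]),
    2 * (v[1] * v[2] + w * v[3]), 1 - 2 * (v[1]^2 + v[3]^2),
    2 * (v[2] * v[3] - w * v[1]),
    2 * (v[1] * v[3] - w * v[2]), 2 * (v[2] * v[3] + w * v[1]),
    1 - 2 * (v[1]^2 + v[2]^2)), 3L, 3L, byrow = TRUE)
}

# rigid TIP3P water at a given oxygen position with random orientation
random_water <- function(o_pos) {
  rOH <- 0.9572
  ang <- 104.52 * pi / 180
  ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
  R1 <- ora_rotation(ax, stats::runif(1, 0, 2 * pi))
  d1 <- as.vector(R1 %*% c(1, 0, 0))
  # second hydrogen: rotate d1 by the HOH angle about a random axis
  # perpendicular to d1
  perp <- stats::rnorm(3); perp <- perp - sum(perp * d1) * d1
  perp <- perp / sqrt(sum(perp^2))
  d2 <- as.vector(ora_rotation(perp, ang) %*% d1)
  rbind(o_pos, o_pos + rOH * d1, o_pos + rOH * d2, deparse.level = 0)
}

# frame of n randomly placed/oriented waters in a cubic box of given side,
# centred at the origin (no periodic wrap)
random_frame <- function(n, side = 12, frame_index = 1L) {
  if (n == 0L)
    return(water_frame(NULL, NULL, NULL, frame_index = frame_index))
  ws <- lapply(seq_len(n), function(i)
    random_water(stats::runif(3, -side / 2, side / 2)))
  water_frame(t(vapply(ws, function(w) w[1, ], numeric(3))),
              t(vapply(ws, function(w) w[2, ], numeric(3))),
              t(vapply(ws, function(w) w[3, ], numeric(3))),
              frame_index = frame_index)
}

# ideal near-linear hydrogen-bond dimer: donor O-H on the O-O axis,
# acceptor hydrogens pointing away; r_oo along +x
ideal_dimer <- function(r_oo = 2.8) {
  rOH <- 0.9572
  ang <- 104.52 * pi / 180
  d1 <- c(1, 0, 0)
  d2 <- as.vector(ora_rotation(c(0, 0, 1), ang) %*% d1)
  donor <- rbind(c(0, 0, 0), rOH * d1, rOH * d2, deparse.level = 0)
  b1 <- as.vector(ora_rotation(c(0, 0, 1), pi - ang / 2) %*% c(-1, 0, 0))
  b2 <- as.vector(ora_rotation(c(0, 0, 1), -(pi - ang / 2)) %*% c(-1, 0, 0))
  acceptor <- rbind(c(r_oo, 0, 0), c(r_oo, 0, 0) + rOH * b1,
                    c(r_oo, 0, 0) + rOH * b2, deparse.level = 0)
  list(donor = donor, acceptor = acceptor)
}

# direct textbook-formula correlation implementations, independent of
# stats::cor
ora_pearson <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}
ora_spearman <- function(x, y) ora_pearson(rank(x), rank(y))
ora_kendall <- function(x, y) {
  n <- length(x); s <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    s <- s + sign(x[i] - x[j]) * sign(y[i] - y[j])
  s / choose(n, 2)
}

frame_from_waters <- function(waters, frame_index = 1L, box = NULL,
                              check = TRUE) {
  water_frame(t(vapply(waters, function(w) w[1, ], numeric(3))),
              t(vapply(waters, function(w) w[2, ], numeric(3))),
              t(vapply(waters, function(w) w[3, ], numeric(3))),
              frame_index = frame_index, box = box, check = check)
}
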