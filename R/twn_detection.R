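#' TIP3P pair interaction energy between two water molecules
#'
#' Sums the nine Coulomb terms over the (O, H, H) x (O, H, H) charge-site
#' pairs and adds the single oxygen--oxygen Lennard-Jones term:
#' \eqn{v(a,b) = \sum_i \sum_j k_e q_i q_j / r_{ij} + A/r_{OO}^{12} -
#' C/r_{OO}^{6}}. The result is symmetric in its two arguments. When `box`
#' is supplied every site--site distance is evaluated under the
#' minimum-image convention.
#'
#' @param water_a,water_b 3 x 3 numeric matrices with rows O, H1, H2
#'   (coordinates in Angstrom), e.g. from [get_water()].
#' @param params A [tip3p_params()] object.
#' @param box Optional three periodic box lengths (Angstrom).
#' @return Interaction energy in kcal/mol.
#' @examples
#' tri <- planted_triangle(c(0, 0, 0))
#' f <- water_frame(tri$o, tri$h1, tri$h2)
#' pair_interaction_energy(get_water(f, 1), get_water(f, 2))
#' @export
pair_interaction_energy <- function(water_a, water_b,
                                    params = tip3p_params(), box = NULL) {
  stopifnot(inherits(params, "tip3p_params"))
  a <- .as_coord_matrix(water_a); b <- .as_coord_matrix(water_b)
  stopifnot(nrow(a) == 3L, nrow(b) == 3L)
  d_oo <- .site_dist(a[1, ], b[1, ], box)
  if (d_oo < 1e-6)
    stop("coincident oxygen positions (r_OO < 1e-6 A): energy singular",
         call. = FALSE)
  q <- c(params$q_O, params$q_H, params$q_H)
  e <- params$A / d_oo^12 - params$C / d_oo^6
  for (i in 1:3) for (j in 1:3) {
    e <- e + params$coulomb_constant * q[i] * q[j] /
      .site_dist(a[i, ], b[j, ], box)
  }
  e
}

# distance between two points, minimum-image when box given
.site_dist <- function(p, q, box = NULL) {
  d <- p - q
  if (!is.null(box)) d <- d - box * round(d / box)
  sqrt(sum(d * d))
}

# vectorised energies for index pairs (ia, ib) of one frame; the workhorse
# behind hbond_graph. Returns kcal/mol per pair.
.pair_energies <- function(frame, ia, ib, params) {
  if (length(ia) == 0L) return(numeric(0))
  sites <- list(frame$o, frame$h1, frame$h2)
  q <- c(params$q_O, params$q_H, params$q_H)
  box <- frame$box
  dist_ab <- function(pa, pb) {
    d <- pa - pb
    if (!is.null(box))
      d <- d - rep(box, each = nrow(d)) * round(d / rep(box, each = nrow(d)))
    sqrt(rowSums(d * d))
  }
  d_oo <- dist_ab(sites[[1]][ia, , drop = FALSE],
                  sites[[1]][ib, , drop = FALSE])
  if (any(d_oo < 1e-6))
    stop("coincident oxygen positions (r_OO < 1e-6 A) between waters ",
         ia[which(d_oo < 1e-6)[1]], " and ", ib[which(d_oo < 1e-6)[1]],
         call. = FALSE)
  e <- params$A / d_oo^12 - params$C / d_oo^6
  for (i in 1:3) for (j in 1:3) {
    rij <- dist_ab(sites[[i]][ia, , drop = FALSE],
                   sites[[j]][ib, , drop = FALSE])
    e <- e + params$coulomb_constant * q[i] * q[j] / rij
  }
  e
}

#' Hydrogen-bond graph of a frame
#'
#' Builds the undirected graph on water indices in which an edge joins two
#' waters whose TIP3P interaction energy is at or below the hydrogen-bond
#' criterion (the threshold itself counts as bonded). When the
#' oxygen--oxygen prescreen cutoff is positive, pairs whose O--O distance
#' exceeds it are skipped without an energy evaluation; the shipped test
#' suite demonstrates on random frames that the prescreened graph equals
#' the exhaustive one.
#'
#' @param frame A [water_frame()].
#' @param params A [tip3p_params()] object.
#' @return A list of class `hbond_graph` with elements `n` (number of
#'   waters), `edges` (two-column integer matrix, each row an edge with
#'   first index smaller) and `energies` (kcal/mol per edge).
#' @export
hbond_graph <- function(frame, params = tip3p_params()) {
  stopifnot(inherits(frame, "water_frame"), inherits(params, "tip3p_params"))
  n <- n_waters(frame)
  empty <- structure(list(n = n,
                          edges = matrix(integer(0), ncol = 2L,
                                         dimnames = list(NULL, c("i", "j"))),
                          energies = numeric(0)),
                     class = "hbond_graph")
  if (n < 2L) return(empty)
  pairs <- .all_pairs(n)
  ia <- pairs[, 1L]; ib <- pairs[, 2L]
  if (params$oo_prescreen_cutoff > 0) {
    d <- frame$o[ia, , drop = FALSE] - frame$o[ib, , drop = FALSE]
    if (!is.null(frame$box)) {
      bx <- rep(frame$box, each = nrow(d))
      d <- d - bx * round(d / bx)
    }
    keep <- rowSums(d * d) <= params$oo_prescreen_cutoff^2
    ia <- ia[keep]; ib <- ib[keep]
  }
  if (length(ia) == 0L) return(empty)
  e <- .pair_energies(frame, ia, ib, params)
  bonded <- e <= params$hbond_criterion
  edges <- cbind(i = as.integer(unname(ia[bonded])),
                 j = as.integer(unname(ib[bonded])))
  structure(list(n = n, edges = edges, energies = unname(e[bonded])),
            class = "hbond_graph")
}

.all_pairs <- function(n) {
  ia <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  ib <- sequence((n - 1L):1L, from = 2:n)
  cbind(ia, ib)
}

#' @export
print.hbond_graph <- function(x, ...) {
  cat(sprintf("hbond_graph: %d waters, %d hydrogen bonds\n",
              x$n, nrow(x$edges)))
  invisible(x)
}

#' Enumerate 3-membered rings (triangles) in a hydrogen-bond graph
#'
#' Returns every unordered triple of waters whose three pairwise hydrogen
#' bonds are all present, each triangle exactly once with indices in
#' ascending order. Enumeration intersects sorted adjacency lists per edge,
#' counting each triangle at its lowest-index edge.
#'
#' @param graph An `hbond_graph` (or a two-column integer edge matrix).
#' @param n Number of vertices; required only when `graph` is a bare edge
#'   matrix.
#' @return An integer matrix with columns `i`, `j`, `k` (ascending within
#'   each row), ordered lexicographically; zero rows when the graph is
#'   triangle-free.
#' @export
find_three_rings <- function(graph, n = NULL) {
  if (inherits(graph, "hbond_graph")) {
    edges <- graph$edges; n <- graph$n
  } else {
    edges <- graph
    if (is.null(n)) n <- if (length(edges)) max(edges) else 0L
  }
  out <- matrix(integer(0), ncol = 3L, dimnames = list(NULL, c("i", "j", "k")))
  if (is.null(edges) || nrow(edges) == 0L) return(out)
  adj <- vector("list", n)
  for (r in seq_len(nrow(edges))) {
    a <- edges[r, 1L]; b <- edges[r, 2L]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj <- lapply(adj, sort.int)
  tri <- vector("list", nrow(edges))
  for (r in seq_len(nrow(edges))) {
    a <- min(edges[r, ]); b <- max(edges[r, ])
    common <- intersect(adj[[a]], adj[[b]])
    common <- common[common > b]
    if (length(common))
      tri[[r]] <- cbind(a, b, common, deparse.level = 0)
  }
  tri <- do.call(rbind, tri)
  if (is.null(tri)) return(out)
  tri <- tri[order(tri[, 1L], tri[, 2L], tri[, 3L]), , drop = FALSE]
  dimnames(tri) <- list(NULL, c("i", "j", "k"))
  tri
}

#' Detect 3-membered topological water networks in one frame
#'
#' Composes [hbond_graph()] and [find_three_rings()]: a topological water
#' network (TWN) here is a 3-membered ring of three mutually
#' hydrogen-bonded waters. Each detected ring carries its three pair
#' energies and its centroid, the arithmetic mean of the three oxygen
#' positions.
#'
#' @param frame A [water_frame()].
#' @param params A [tip3p_params()] object.
#' @return A data frame of class `twn_rings` with one row per ring and
#'   columns `frame_index`, `water_i`, `water_j`, `water_k` (ascending
#'   triple), `e_ij`, `e_jk`, `e_ik` (kcal/mol) and
#'   `centroid_x`/`centroid_y`/`centroid_z` (Angstrom); rows sorted by
#'   ascending triple.
#' @examples
#' tri <- planted_triangle(c(0, 0, 0))
#' f <- water_frame(tri$o, tri$h1, tri$h2, frame_index = 1L)
#' detect_twns(f)
#' @export
detect_twns <- function(frame, params = tip3p_params()) {
  g <- hbond_graph(frame, params)
  tri <- find_three_rings(g)
  k <- nrow(tri)
  if (k == 0L) return(.empty_rings())
  # edge-energy lookup keyed on linearised pair index
  key <- (g$edges[, 1L] - 1) * g$n + g$edges[, 2L]
  emap <- g$energies[match(
    cbind((tri[, 1L] - 1) * g$n + tri[, 2L],
          (tri[, 2L] - 1) * g$n + tri[, 3L],
          (tri[, 1L] - 1) * g$n + tri[, 3L]),
    key)]
  emap <- matrix(emap, nrow = k)
  cen <- (frame$o[tri[, 1L], , drop = FALSE] +
            frame$o[tri[, 2L], , drop = FALSE] +
            frame$o[tri[, 3L], , drop = FALSE]) / 3
  out <- data.frame(frame_index = frame$frame_index,
                    water_i = tri[, 1L], water_j = tri[, 2L],
                    water_k = tri[, 3L],
                    e_ij = emap[, 1L], e_jk = emap[, 2L], e_ik = emap[, 3L],
                    centroid_x = cen[, 1L], centroid_y = cen[, 2L],
                    centroid_z = cen[, 3L])
  rownames(out) <- NULL
  class(out) <- c("twn_rings", "data.frame")
  out
}

.empty_rings <- function() {
  out <- data.frame(frame_index = integer(0), water_i = integer(0),
                    water_j = integer(0), water_k = integer(0),
                    e_ij = numeric(0), e_jk = numeric(0), e_ik = numeric(0),
                    centroid_x = numeric(0), centroid_y = numeric(0),
                    centroid_z = numeric(0))
  class(out) <- c("twn_rings", "data.frame")
  out
}

#' Detect rings across a whole trajectory
#'
#' @param frames A [water_trajectory()] or list of frames.
#' @param params A [tip3p_params()] object.
#' @return A `twn_rings` data frame stacking [detect_twns()] over frames in
#'   trajectory order.
#' @export
detect_twns_trajectory <- function(frames, params = tip3p_params()) {
  res <- lapply(frames, detect_twns, params = params)
  out <- do.call(rbind, res)
  if (is.null(out) || nrow(out) == 0L) return(.empty_rings())
  rownames(out) <- NULL
  class(out) <- c("twn_rings", "data.frame")
  out
}
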