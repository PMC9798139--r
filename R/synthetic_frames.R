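#' Specification for a synthetic water trajectory
#'
#' The generator plants, at chosen pocket locations, triangles of three
#' mutually hydrogen-bonded TIP3P waters (the ground-truth 3-membered
#' rings), optionally perturbed by Gaussian coordinate jitter, and fills
#' the surroundings with orientation-randomised background waters kept far
#' enough apart that they form no hydrogen bonds. Every downstream stage
#' -- detection, encoding, reordering, scoring -- can then be checked
#' against the planted truth without running molecular dynamics.
#'
#' @param n_frames Number of frames to generate.
#' @param planted_sites Ring centre(s): a length-3 vector or a k x 3
#'   matrix (Angstrom).
#' @param presence Per-site probability, in `[0,1]`, that the ring is
#'   realised in any given frame (recycled; default 1).
#' @param jitter_sigma Isotropic Gaussian noise, in Angstrom, added to
#'   every atom of the planted waters (default 0).
#' @param n_noise_waters Background waters per frame (default 0).
#' @param noise_box Three box lengths (Angstrom) of the placement region
#'   for background waters (default 40 x 40 x 40, centred on the origin).
#' @param min_noise_separation Minimum oxygen--oxygen distance, in
#'   Angstrom, between a background water and every other water (default
#'   6, beyond plausible hydrogen-bond range).
#' @param seed Integer RNG seed; the whole trajectory is reproducible from
#'   it.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_frames, planted_sites,
                           presence = 1, jitter_sigma = 0,
                           n_noise_waters = 0,
                           noise_box = c(40, 40, 40),
                           min_noise_separation = 6, seed = 1L) {
  if (is.null(dim(planted_sites)))
    planted_sites <- matrix(planted_sites, ncol = 3L, byrow = TRUE)
  planted_sites <- .as_coord_matrix(planted_sites)
  presence <- rep_len(as.numeric(presence), nrow(planted_sites))
  stopifnot(n_frames >= 1L, all(presence >= 0), all(presence <= 1),
            jitter_sigma >= 0, n_noise_waters >= 0,
            length(noise_box) == 3L, all(noise_box > 0),
            min_noise_separation > 0)
  structure(list(n_frames = as.integer(n_frames),
                 planted_sites = planted_sites, presence = presence,
                 jitter_sigma = jitter_sigma,
                 n_noise_waters = as.integer(n_noise_waters),
                 noise_box = as.numeric(noise_box),
                 min_noise_separation = min_noise_separation,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Rodrigues rotation matrix about unit axis by angle (radians)
.rotation_about <- function(axis, theta) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0),
              3L, 3L, byrow = TRUE)
  diag(3L) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

# uniform random rotation via QR with determinant fix (uses current RNG)
.random_rotation <- function() {
  Q <- qr.Q(qr(matrix(stats::rnorm(9L), 3L)))
  if (det(Q) < 0) Q[, 1L] <- -Q[, 1L]
  Q
}

#' Plant a hydrogen-bonded water triangle
#'
#' Places three rigid TIP3P waters whose oxygens form an equilateral
#' triangle of side 2.8 Angstrom (a typical water--water hydrogen-bond
#' O--O distance) centred at `center`. Hydrogens follow a cyclic
#' donor-acceptor pattern: each water's first hydrogen points exactly at
#' the next oxygen around the ring (a linear donated hydrogen bond) and
#' the second hydrogen is placed at the TIP3P internal angle of 104.52
#' degrees, rotated within the triangle plane away from the ring so it
#' does not clash with the neighbouring acceptor. At zero jitter all
#' three pair interaction energies are about -3.5 kcal/mol, comfortably
#' below the -2.25 kcal/mol hydrogen-bond criterion, so the triple is
#' detected as exactly one ring whose centroid coincides with `center`.
#'
#' Isotropic Gaussian jitter of scale `jitter_sigma` is drawn from the
#' current RNG state and added to every atom independently.
#'
#' @param center Length-3 ring centre (Angstrom).
#' @param jitter_sigma Gaussian noise scale in Angstrom (default 0).
#' @param rotation 3 x 3 rotation applied to the triangle about its
#'   centre before jittering (default identity; see
#'   `twnrencod:::.random_rotation`).
#' @return List with `o`, `h1`, `h2`: 3 x 3 coordinate matrices, one row
#'   per water.
#' @export
planted_triangle <- function(center, jitter_sigma = 0,
                             rotation = diag(3L)) {
  stopifnot(length(center) == 3L, jitter_sigma >= 0)
  side <- 2.8
  rc <- side / sqrt(3)                    # circumradius
  th <- c(90, 210, 330) * pi / 180
  o <- cbind(rc * cos(th), rc * sin(th), 0)
  h1 <- matrix(NA_real_, 3L, 3L); h2 <- matrix(NA_real_, 3L, 3L)
  hoh <- .TIP3P_HOH_DEG * pi / 180
  for (i in 1:3) {
    u <- o[(i %% 3L) + 1L, ] - o[i, ]
    u <- u / sqrt(sum(u^2))
    h1[i, ] <- o[i, ] + .TIP3P_R_OH * u
    # second O-H: HOH angle from the donor bond, swung in-plane away from
    # the ring interior (rotation about the negative triangle normal)
    v <- as.vector(.rotation_about(c(0, 0, -1), hoh) %*% u)
    h2[i, ] <- o[i, ] + .TIP3P_R_OH * v
  }
  place <- function(m) {
    m <- m %*% t(rotation)
    m <- m + matrix(center, 3L, 3L, byrow = TRUE)
    if (jitter_sigma > 0)
      m <- m + matrix(stats::rnorm(9L, sd = jitter_sigma), 3L, 3L)
    m
  }
  o_t <- place(o)
  # hydrogens ride with their oxygen's frame; jitter is per-atom
  list(o = o_t, h1 = place(h1), h2 = place(h2))
}

# a single TIP3P water: O at origin, standard internal geometry, rows O/H1/H2
.canonical_water <- function() {
  hoh <- .TIP3P_HOH_DEG * pi / 180
  rbind(c(0, 0, 0),
        c(.TIP3P_R_OH, 0, 0),
        .TIP3P_R_OH * c(cos(hoh), sin(hoh), 0))
}

#' Generate a synthetic water trajectory with planted rings
#'
#' Per frame, each planted site is realised independently with its
#' presence probability (in a fresh random orientation), then the
#' background waters are placed uniformly in the noise box by rejection
#' sampling so that every background oxygen keeps at least
#' `min_noise_separation` from all other oxygens. Each frame draws from
#' an RNG substream derived from the spec seed and the frame index, so
#' regeneration is reproducible frame by frame.
#'
#' @param spec A [synthetic_spec()].
#' @param path Optional output path; when given, the trajectory is also
#'   written as a multi-model PDB via [write_water_frames()].
#' @return A [water_trajectory()]. The realised site indices per frame
#'   are attached as attribute `"realized_sites"` (a list).
#' @export
generate_trajectory <- function(spec, path = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  k <- nrow(spec$planted_sites)
  half <- spec$noise_box / 2
  frames <- vector("list", spec$n_frames)
  realized_sites <- vector("list", spec$n_frames)
  for (f in seq_len(spec$n_frames)) {
    .set_frame_seed(spec$seed, f)
    realized <- if (k > 0L) which(stats::runif(k) <= spec$presence) else
      integer(0)
    realized_sites[[f]] <- realized
    o <- matrix(numeric(0), ncol = 3L)
    h1 <- o; h2 <- o
    for (s in realized) {
      tri <- planted_triangle(spec$planted_sites[s, ],
                              jitter_sigma = spec$jitter_sigma,
                              rotation = .random_rotation())
      o <- rbind(o, tri$o); h1 <- rbind(h1, tri$h1); h2 <- rbind(h2, tri$h2)
    }
    if (spec$n_noise_waters > 0L) {
      can <- .canonical_water()
      for (w in seq_len(spec$n_noise_waters)) {
        placed <- FALSE
        for (attempt in seq_len(10000L)) {
          pos <- stats::runif(3L, -half, half)
          if (nrow(o) == 0L ||
              min(rowSums((o - matrix(pos, nrow(o), 3L,
                                      byrow = TRUE))^2)) >=
              spec$min_noise_separation^2) {
            placed <- TRUE; break
          }
        }
        if (!placed)
          stop("could not place background water ", w, " after 10000 ",
               "attempts; enlarge noise_box or reduce n_noise_waters",
               call. = FALSE)
        rot <- .random_rotation()
        wat <- can %*% t(rot) + matrix(pos, 3L, 3L, byrow = TRUE)
        o <- rbind(o, wat[1, ]); h1 <- rbind(h1, wat[2, ])
        h2 <- rbind(h2, wat[3, ])
      }
    }
    # large jitter can break the rigid O-H sanity bounds by design
    frames[[f]] <- water_frame(o, h1, h2, frame_index = f,
                               check = spec$jitter_sigma == 0)
  }
  traj <- water_trajectory(frames)
  attr(traj, "realized_sites") <- realized_sites
  if (!is.null(path)) write_water_frames(traj, path)
  traj
}

.set_frame_seed <- function(seed, frame) {
  s <- (abs(as.numeric(seed)) * 1009 + as.numeric(frame) * 9973) %%
    2147483647
  set.seed(as.integer(s))
}

#' Read a synthetic-trajectory spec from YAML
#'
#' Keys mirror the [synthetic_spec()] arguments; `planted_sites` is a list
#' of `[x, y, z]` triples.
#'
#' @param path Path to the YAML file.
#' @return A [synthetic_spec()].
#' @export
read_synthetic_spec <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$n_frames) || is.null(cfg$planted_sites))
    stop("spec needs 'n_frames' and 'planted_sites'", call. = FALSE)
  sites <- do.call(rbind, lapply(cfg$planted_sites, as.numeric))
  args <- list(n_frames = cfg$n_frames, planted_sites = sites)
  for (key in c("presence", "jitter_sigma", "n_noise_waters",
                "noise_box", "min_noise_separation", "seed"))
    if (!is.null(cfg[[key]])) args[[key]] <- cfg[[key]]
  do.call(synthetic_spec, args)
}

#' Build a synthetic binding site around a pocket centre
#'
#' Places residue backbones deterministically on a sphere of radius
#' `radius` around `center` (C-alpha positions on a Fibonacci lattice,
#' N/C/O at idealised backbone offsets in the local tangent plane). The
#' geometry is not a real protein fold; it provides a fixed 4-atoms-per-
#' residue scaffold, in the standard N, CA, C, O order, for exercising the
#' encoding and comparison stages against planted rings. Synthetic by
#' construction -- not derived from any deposited structure.
#'
#' @param center Pocket centre (Angstrom, default origin).
#' @param n_residues Number of residues (default 16, giving 64 atoms).
#' @param radius Sphere radius in Angstrom (default 8).
#' @param protein_label Label for the site (default `"synthetic"`).
#' @return A [binding_site()].
#' @export
synthetic_binding_site <- function(center = c(0, 0, 0), n_residues = 16,
                                   radius = 8,
                                   protein_label = "synthetic") {
  stopifnot(n_residues >= 1L, radius > 0, length(center) == 3L)
  golden <- pi * (3 - sqrt(5))
  coords <- matrix(NA_real_, n_residues * 4L, 3L)
  for (r in seq_len(n_residues)) {
    z <- 1 - (2 * (r - 0.5)) / n_residues
    rho <- sqrt(max(0, 1 - z^2))
    phi <- golden * (r - 1)
    u <- c(rho * cos(phi), rho * sin(phi), z)     # outward normal
    # tangent frame at u
    t1 <- if (abs(u[3]) < 0.9) c(-u[2], u[1], 0) else c(1, 0, 0)
    t1 <- t1 - sum(t1 * u) * u; t1 <- t1 / sqrt(sum(t1^2))
    t2 <- c(u[2] * t1[3] - u[3] * t1[2],
            u[3] * t1[1] - u[1] * t1[3],
            u[1] * t1[2] - u[2] * t1[1])
    ca <- center + radius * u
    coords[(r - 1L) * 4L + 1L, ] <- ca - 1.46 * t1          # N
    coords[(r - 1L) * 4L + 2L, ] <- ca                      # CA
    coords[(r - 1L) * 4L + 3L, ] <- ca + 1.53 * t1          # C
    coords[(r - 1L) * 4L + 4L, ] <- ca + 1.53 * t1 + 1.23 * t2  # O
  }
  residues <- data.frame(chain = "A", resnum = seq_len(n_residues),
                         resname = "GLY")
  binding_site(protein_label, residues, coords)
}
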