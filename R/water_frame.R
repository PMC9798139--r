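#' Construct a single trajectory frame of water molecules
#'
#' A frame holds one snapshot of the mobile solvent: the oxygen and two
#' hydrogen coordinates of every water molecule, the frame index within the
#' trajectory, an optional time stamp and optional periodic box lengths.
#' The protein is restrained during the production run, so frames carry
#' waters only; the binding-site backbone coordinates are static and live
#' in a [binding_site()] object.
#'
#' @param o,h1,h2 Numeric matrices with one row per water and three columns
#'   (x, y, z in Angstrom): oxygen and the two hydrogen positions.
#' @param frame_index Non-negative integer identifying the frame.
#' @param time_ps Optional non-negative time stamp in picoseconds.
#' @param box Optional numeric vector of three periodic box lengths in
#'   Angstrom; when present, site--site distances use the minimum-image
#'   convention.
#' @param check Validate the rigid-water geometry (O--H distances within
#'   0.5--1.5 Angstrom). Default `TRUE`.
#'
#' @return An object of class `water_frame`.
#' @examples
#' w <- planted_triangle(c(0, 0, 0))
#' f <- water_frame(w$o, w$h1, w$h2, frame_index = 1L)
#' n_waters(f)
#' @export
water_frame <- function(o, h1, h2, frame_index = 0L, time_ps = NULL,
                        box = NULL, check = TRUE) {
  o <- .as_coord_matrix(o); h1 <- .as_coord_matrix(h1)
  h2 <- .as_coord_matrix(h2)
  if (nrow(o) != nrow(h1) || nrow(o) != nrow(h2))
    stop("o, h1, h2 must have one row per water molecule", call. = FALSE)
  if (!is.null(box)) {
    box <- as.numeric(box)
    stopifnot(length(box) == 3L, all(box > 0))
  }
  frame_index <- as.integer(frame_index)
  stopifnot(length(frame_index) == 1L, frame_index >= 0L)
  fr <- structure(
    list(frame_index = frame_index,
         time_ps = if (is.null(time_ps)) NA_real_ else as.numeric(time_ps),
         o = o, h1 = h1, h2 = h2, box = box),
    class = "water_frame")
  if (check) .check_water_geometry(fr)
  fr
}

.as_coord_matrix <- function(x) {
  if (is.null(x) || length(x) == 0L)
    return(matrix(numeric(0), ncol = 3L))
  x <- as.matrix(x)
  if (ncol(x) != 3L) stop("coordinates must have 3 columns", call. = FALSE)
  storage.mode(x) <- "double"
  if (any(!is.finite(x))) stop("coordinates must be finite", call. = FALSE)
  dimnames(x) <- NULL
  x
}

.check_water_geometry <- function(frame) {
  if (n_waters(frame) == 0L) return(invisible(frame))
  d1 <- sqrt(rowSums((frame$o - frame$h1)^2))
  d2 <- sqrt(rowSums((frame$o - frame$h2)^2))
  bad <- which(d1 <= 0.5 | d1 >= 1.5 | d2 <= 0.5 | d2 >= 1.5)
  if (length(bad))
    stop("water ", bad[1], " in frame ", frame$frame_index,
         " has O-H distance outside (0.5, 1.5) A: ",
         sprintf("%.3f / %.3f", d1[bad[1]], d2[bad[1]]), call. = FALSE)
  invisible(frame)
}

#' Number of water molecules in a frame
#' @param frame A [water_frame()].
#' @return Integer count.
#' @export
n_waters <- function(frame) {
  stopifnot(inherits(frame, "water_frame"))
  nrow(frame$o)
}

#' Extract one water as a 3 x 3 site-coordinate matrix
#'
#' Rows are ordered O, H1, H2 -- the order assumed by
#' [pair_interaction_energy()].
#'
#' @param frame A [water_frame()].
#' @param i Water index (1-based).
#' @return A 3 x 3 numeric matrix.
#' @export
get_water <- function(frame, i) {
  stopifnot(inherits(frame, "water_frame"),
            i >= 1L, i <= n_waters(frame))
  rbind(frame$o[i, ], frame$h1[i, ], frame$h2[i, ])
}

#' @export
print.water_frame <- function(x, ...) {
  cat(sprintf("water_frame %d: %d waters%s%s\n", x$frame_index,
              n_waters(x),
              if (is.na(x$time_ps)) "" else sprintf(", t = %g ps", x$time_ps),
              if (is.null(x$box)) "" else
                sprintf(", box %.1f x %.1f x %.1f A",
                        x$box[1], x$box[2], x$box[3])))
  invisible(x)
}

#' Assemble frames into a trajectory
#'
#' Checks that frame indices are unique and ascending.
#'
#' @param frames A list of [water_frame()] objects.
#' @return The list, classed `water_trajectory`.
#' @export
water_trajectory <- function(frames) {
  stopifnot(is.list(frames), length(frames) >= 1L,
            all(vapply(frames, inherits, logical(1), "water_frame")))
  idx <- vapply(frames, function(f) f$frame_index, integer(1))
  if (anyDuplicated(idx) || is.unsorted(idx, strictly = TRUE))
    stop("frame indices must be unique and ascending", call. = FALSE)
  structure(frames, class = "water_trajectory")
}

#' @export
print.water_trajectory <- function(x, ...) {
  nw <- vapply(x, n_waters, integer(1))
  cat(sprintf("water_trajectory: %d frames, %d-%d waters per frame\n",
              length(x), min(nw), max(nw)))
  invisible(x)
}

#' @export
`[.water_trajectory` <- function(x, i) {
  structure(unclass(x)[i], class = "water_trajectory")
}
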