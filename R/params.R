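#' TIP3P interaction parameters
#'
#' Parameter set for the rigid three-site TIP3P water model used to score
#' water--water interaction energies: partial charges on the oxygen and the
#' two hydrogens, the single oxygen-centred Lennard-Jones site, the
#' electrostatic conversion constant, the hydrogen-bond energy criterion,
#' and an optional oxygen--oxygen prescreen cutoff used to skip energy
#' evaluation for far-apart pairs.
#'
#' The interaction energy between two waters is the sum of the nine
#' charge--charge Coulomb terms over the (O, H, H) x (O, H, H) site pairs
#' plus one Lennard-Jones term on the oxygen--oxygen distance:
#' \deqn{v(a,b) = \sum_i \sum_j k_e \frac{q_i q_j}{r_{ij}}
#'   + \frac{A}{r_{OO}^{12}} - \frac{C}{r_{OO}^{6}}}
#' A pair counts as hydrogen bonded when \eqn{v(a,b)} is at or below
#' `hbond_criterion`.
#'
#' The electrostatic constant converts \eqn{e^2/\mathrm{\AA}} to
#' kcal/mol; the default 332.0636 is the conventional CHARMM/TIP3P value.
#' It is exposed here because published descriptions of the potential
#' often omit it.
#'
#' @param q_O Oxygen partial charge in elementary charges (default -0.834).
#' @param q_H Hydrogen partial charge in elementary charges (default 0.417).
#' @param A Repulsive Lennard-Jones coefficient, kcal A^12 / mol
#'   (default 582000).
#' @param C Attractive Lennard-Jones coefficient, kcal A^6 / mol
#'   (default 595).
#' @param coulomb_constant Electrostatic conversion constant,
#'   kcal A / (e^2 mol) (default 332.0636).
#' @param hbond_criterion Hydrogen-bond energy threshold in kcal/mol; a pair
#'   with interaction energy at or below this value is bonded
#'   (default -2.25).
#' @param oo_prescreen_cutoff Oxygen--oxygen distance in Angstrom above which
#'   a pair is skipped without energy evaluation (default 4.5); set to a
#'   non-positive value to disable the prescreen.
#'
#' @return An object of class `tip3p_params`.
#' @examples
#' p <- tip3p_params()
#' p$hbond_criterion
#' @export
tip3p_params <- function(q_O = -0.834, q_H = 0.417,
                         A = 582000, C = 595,
                         coulomb_constant = 332.0636,
                         hbond_criterion = -2.25,
                         oo_prescreen_cutoff = 4.5) {
  stopifnot(is.numeric(q_O), is.numeric(q_H), length(q_O) == 1L,
            length(q_H) == 1L)
  if (abs(q_O + 2 * q_H) > 1e-9)
    stop("water molecule must be neutral: q_O + 2*q_H = ",
         q_O + 2 * q_H, call. = FALSE)
  if (!(A > 0)) stop("Lennard-Jones A must be positive", call. = FALSE)
  if (!(C > 0)) stop("Lennard-Jones C must be positive", call. = FALSE)
  if (!(hbond_criterion < 0))
    stop("hbond_criterion must be negative (attractive)", call. = FALSE)
  structure(
    list(q_O = q_O, q_H = q_H, A = A, C = C,
         coulomb_constant = coulomb_constant,
         hbond_criterion = hbond_criterion,
         oo_prescreen_cutoff = oo_prescreen_cutoff),
    class = "tip3p_params")
}

#' @export
print.tip3p_params <- function(x, ...) {
  cat("TIP3P parameters\n")
  cat(sprintf("  charges: q_O = %g e, q_H = %g e\n", x$q_O, x$q_H))
  cat(sprintf("  LJ: A = %g kcal A^12/mol, C = %g kcal A^6/mol\n",
              x$A, x$C))
  cat(sprintf("  Coulomb constant: %g kcal A/(e^2 mol)\n",
              x$coulomb_constant))
  cat(sprintf("  H-bond criterion: %g kcal/mol\n", x$hbond_criterion))
  cat(sprintf("  O-O prescreen cutoff: %g A%s\n", x$oo_prescreen_cutoff,
              if (x$oo_prescreen_cutoff <= 0) " (disabled)" else ""))
  invisible(x)
}

# TIP3P rigid internal geometry (Angstrom / degrees)
.TIP3P_R_OH <- 0.9572
.TIP3P_HOH_DEG <- 104.52

#' Sentinel distance for frames without any retained water ring
#'
#' Frames in which no 3-membered water ring lies within the binding-site
#' inclusion radius carry this sentinel in the distance matrix. It is
#' classified into the outermost shell (class `"D"`) and valued at the
#' configurable cap (default 12 Angstrom) in frame-difference computations.
#'
#' @format A length-one numeric `NA`.
#' @export
NO_TWN <- NA_real_
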