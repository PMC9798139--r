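#' Inhibitory-activity table
#'
#' Holds one equilibrium dissociation constant (Kd, nM) per protein;
#' pairwise activity differences are derived as `|log10(Kd_i) -
#' log10(Kd_j)|`. Censored entries given as text bounds (e.g.
#' `"> 10000"`) are taken at the bound with a warning -- the only
#' defensible desk-scale treatment, and flagged so downstream readers
#' know the value is a floor.
#'
#' @param protein_label Character vector of unique protein labels.
#' @param kd_nM Numeric (or censored-text) Kd values in nM, parallel to
#'   `protein_label`.
#' @return A data frame of class `activity_table` with columns
#'   `protein_label`, `kd_nM`, `censored`.
#' @examples
#' activity_table(c("VEGFR2", "CDK2"), c(1.5, "> 10000"))
#' @export
activity_table <- function(protein_label, kd_nM) {
  protein_label <- as.character(protein_label)
  stopifnot(length(protein_label) == length(kd_nM))
  if (anyDuplicated(protein_label))
    stop("protein labels must be unique", call. = FALSE)
  censored <- logical(length(kd_nM))
  if (is.character(kd_nM)) {
    censored <- grepl("[<>]", kd_nM)
    parsed <- suppressWarnings(as.numeric(gsub("[<>,[:space:]]", "",
                                               kd_nM)))
    if (anyNA(parsed))
      stop("unparseable Kd value: ", kd_nM[which(is.na(parsed))[1]],
           call. = FALSE)
    if (any(censored))
      warning("censored Kd taken at the stated bound for: ",
              paste(protein_label[censored], collapse = ", "),
              call. = FALSE)
    kd_nM <- parsed
  }
  if (any(kd_nM <= 0)) stop("Kd must be positive", call. = FALSE)
  out <- data.frame(protein_label = protein_label, kd_nM = kd_nM,
                    censored = censored)
  class(out) <- c("activity_table", "data.frame")
  out
}

#' Pairwise activity differences on the log scale
#'
#' @param activities An [activity_table()].
#' @return Data frame with columns `protein_a`, `protein_b`,
#'   `activity_difference` (`|log10 Kd_a - log10 Kd_b|`), one row per
#'   unordered protein pair.
#' @export
activity_differences <- function(activities) {
  stopifnot(inherits(activities, "activity_table"))
  n <- nrow(activities)
  if (n < 2L) stop("need at least two proteins", call. = FALSE)
  pairs <- .all_pairs(n)
  lg <- log10(activities$kd_nM)
  data.frame(protein_a = activities$protein_label[pairs[, 1L]],
             protein_b = activities$protein_label[pairs[, 2L]],
             activity_difference = abs(lg[pairs[, 1L]] - lg[pairs[, 2L]]))
}

#' Correlate pairwise binding-site similarities with activity differences
#'
#' Joins a pairwise similarity table against pairwise log-activity
#' differences by unordered protein pair and computes the chosen
#' correlation coefficient. A method that captures hydration-network
#' resemblance well should yield similarities that anticorrelate with
#' activity differences: pockets that solvate alike tend to bind the same
#' inhibitor with similar affinity.
#'
#' @param similarities Data frame with columns `protein_a`, `protein_b`,
#'   `similarity`.
#' @param activities An [activity_table()], or a precomputed data frame
#'   with columns `protein_a`, `protein_b`, `activity_difference`.
#' @param method `"pearson"`, `"kendall"` or `"spearman"`.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
correlate <- function(similarities,
                      activities,
                      method = c("pearson", "kendall", "spearman")) {
  method <- match.arg(method)
  stopifnot(is.data.frame(similarities),
            all(c("protein_a", "protein_b", "similarity") %in%
                  names(similarities)))
  diffs <- if (inherits(activities, "activity_table"))
    activity_differences(activities) else activities
  stopifnot(all(c("protein_a", "protein_b", "activity_difference") %in%
                  names(diffs)))
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  idx <- match(key(similarities$protein_a, similarities$protein_b),
               key(diffs$protein_a, diffs$protein_b))
  if (anyNA(idx))
    stop("protein pair missing from the activity table: ",
         similarities$protein_a[which(is.na(idx))[1]], " / ",
         similarities$protein_b[which(is.na(idx))[1]], call. = FALSE)
  x <- similarities$similarity
  y <- diffs$activity_difference[idx]
  if (length(x) < 3L)
    stop("need at least 3 protein pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input vector: correlation undefined", call. = FALSE)
  stats::cor(x, y, method = method)
}
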