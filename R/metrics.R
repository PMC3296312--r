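#' Relative difference area/volume against ground truth
#'
#' v_kT is the count of elements differing between a label and the ground
#' truth (false positives plus false negatives); v_D normalizes it by the
#' ground-truth foreground size, so v_D = 0.25 means the disagreement amounts
#' to a quarter of the true object. Note v_D is not symmetric in its
#' arguments: the denominator is always the truth's size.
#'
#' @param label a \code{\link{label_image}} on the truth's grid.
#' @param truth the ground-truth \code{\link{label_image}}; must have a
#'   non-empty foreground (an empty truth has no defined relative error).
#' @return a list with \code{v_kT} (element count), \code{v_D} (fraction) and
#'   \code{V_truth} (truth foreground size in elements).
#' @examples
#' tr <- label_image(matrix(c(1, 1, 0, 0), 2))
#' vd(label_image(matrix(c(1, 0, 0, 0), 2)), tr)$v_D
#' @export
vd <- function(label, truth) {
  label <- as_label_like(label)
  truth <- as_label_like(truth)
  if (!same_geometry(label, truth)) stop("label and truth are on different grids")
  V_truth <- sum(truth)
  if (V_truth == 0) stop("ground truth has an empty foreground; v_D undefined")
  v_kT <- sum(label != truth)
  list(v_kT = v_kT, v_D = v_kT / V_truth, V_truth = V_truth)
}

#' Dice similarity coefficient
#'
#' DSC = 2|A intersect B| / (|A| + |B|), where |Z| is the foreground area or
#' volume in elements. Two empty sets are defined to have DSC 1 (perfect
#' agreement by convention).
#'
#' @param label,truth \code{\link{label_image}}s on one grid.
#' @return Dice coefficient in [0, 1].
#' @export
dsc <- function(label, truth) {
  label <- as_label_like(label)
  truth <- as_label_like(truth)
  if (!same_geometry(label, truth)) stop("label and truth are on different grids")
  a <- sum(label)
  b <- sum(truth)
  if (a + b == 0) return(1)
  2 * sum(label == 1L & truth == 1L) / (a + b)
}

#' Per-test error summary over a rater stack
#'
#' Mean, standard deviation and coefficient of variation of the per-rater
#' relative errors v_D against the ground truth — the quantities the
#' dissimilarity factors d_r and d_c estimate without the truth. Uses the
#' same standard-deviation convention as \code{\link{dissimilarity_factors}}.
#'
#' @param raters a \code{\link{rater_set}} with K >= 2.
#' @param truth ground-truth \code{\link{label_image}} (non-empty).
#' @param sd_type \code{"sample"} or \code{"population"}.
#' @return a list with \code{mean_vd}, \code{sd_vd}, \code{cv_vd} (defined as
#'   0 when all raters are exact) and the per-rater \code{v_D} vector.
#' @export
test_summary <- function(raters, truth, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  rs <- as_rater_set(raters)
  if (rs$K < 2L) stop("test_summary requires K >= 2 raters")
  v <- vapply(rs$raters, function(r) vd(r, truth)$v_D, numeric(1))
  mu <- mean(v)
  sdv <- stats::sd(v)
  if (sd_type == "population") sdv <- sdv * sqrt((rs$K - 1) / rs$K)
  list(mean_vd = mu, sd_vd = sdv, cv_vd = if (mu == 0) 0 else sdv / mu,
       v_D = v)
}
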