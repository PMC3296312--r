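#' Majority-vote label fusion
#'
#' Per-element majority (sum rule): each element receives the label most
#' often assigned by the raters. Ties — possible for even K — are broken
#' toward the foreground (label 1); this package uses that foreground tie
#' rule globally across all fusers.
#'
#' @param raters a \code{\link{rater_set}} (K >= 1).
#' @return the fused \code{\link{label_image}}.
#' @examples
#' rs <- rater_set(list(matrix(c(1, 0), 1), matrix(c(1, 1), 1),
#'                      matrix(c(0, 0), 1)))
#' as.integer(fuse_vote(rs))
#' @export
fuse_vote <- function(raters) {
  rs <- as_rater_set(raters)
  E <- decision_matrix(rs)
  counts <- rowSums(E)
  ref <- rs$raters[[1L]]
  label_image(array(as.integer(2 * counts >= rs$K), dim = dim(ref)),
              spacing = attr(ref, "spacing"), origin = attr(ref, "origin"))
}

#' Signed Euclidean distance map of a binary label
#'
#' Exact (not chamfer) Euclidean distance from every element center to the
#' nearest element center of the opposite label, negative inside the
#' foreground and positive outside. Zero is never assigned: a boundary
#' element takes the signed distance of its own side. Distances are measured
#' in index space; spacing metadata is ignored (the fusers operate on
#' isotropic grids).
#'
#' @param label a \code{\link{label_image}}, neither empty nor full (a label
#'   with no boundary has no finite distance map; see \code{\link{fuse_sba}}
#'   for how that degenerate case is handled during fusion).
#' @return an array of signed distances with the geometry of \code{label}.
#' @examples
#' row <- label_image(matrix(c(0, 0, 1, 0, 0), 1))
#' as.vector(signed_distance(row))  # +2 +1 -1 +1 +2
#' @export
signed_distance <- function(label) {
  label <- as_label_like(label)
  fg <- as.logical(label)
  n_fg <- sum(fg)
  if (n_fg == 0L || n_fg == length(fg)) {
    stop("signed_distance requires a non-empty, non-full label")
  }
  dims <- dim(label)
  out <- array(edt_signed_cpp(fg, dims), dim = dims)
  attr(out, "spacing") <- attr(label, "spacing")
  attr(out, "origin") <- attr(label, "origin")
  out
}

#' Shape-based averaging (SBA) label fusion
#'
#' A voting scheme in which each rater's vote at an element is its signed
#' Euclidean distance to that rater's segmentation boundary (negative inside).
#' The per-element mean signed distance over raters is thresholded at zero:
#' elements with non-positive mean distance become foreground (the global
#' foreground tie rule covers an exact zero). Distance maps are always
#' computed on the full grid, so the result is identical whether assembled on
#' the full grid or only on disputed elements.
#'
#' A rater whose label is entirely empty (or full) has no boundary; its map is
#' replaced by a constant +(resp. -) grid diagonal length, with a warning.
#'
#' @param raters a \code{\link{rater_set}} (K >= 1).
#' @return the fused \code{\link{label_image}}.
#' @export
fuse_sba <- function(raters) {
  rs <- as_rater_set(raters)
  ref <- rs$raters[[1L]]
  dims <- dim(ref)
  diag_len <- sqrt(sum((dims - 1)^2))
  acc <- array(0, dim = dims)
  for (k in seq_len(rs$K)) {
    r <- rs$raters[[k]]
    n_fg <- sum(r)
    if (n_fg == 0L) {
      warning("rater ", k, " has an empty foreground; using a constant ",
              "+diagonal distance map")
      acc <- acc + diag_len
    } else if (n_fg == length(r)) {
      warning("rater ", k, " has a full foreground; using a constant ",
              "-diagonal distance map")
      acc <- acc - diag_len
    } else {
      acc <- acc + signed_distance(r)
    }
  }
  label_image(array(as.integer(acc <= 0), dim = dims),
              spacing = attr(ref, "spacing"), origin = attr(ref, "origin"))
}

#' STAPLE label fusion
#'
#' Simultaneous Truth And Performance Level Estimation: a binary EM algorithm
#' that alternates between (E-step) the posterior probability W(x) that each
#' element is true foreground given current per-rater performance parameters,
#' and (M-step) re-estimating each rater's sensitivity p(e_k = 1 | T = 1) and
#' specificity p(e_k = 0 | T = 0) from W. The final label is W >= 0.5.
#'
#' By default all EM sums run over the disputed elements only (unanimous
#' elements are assigned directly), which both speeds up the algorithm and is
#' known to improve its results; note the performance estimates are then
#' conditional on disagreement. \code{restrict = "full"} runs the classic
#' full-grid EM, under which parameters of raters simulated from the STAPLE
#' generative model are recovered.
#'
#' The foreground prior g is fixed during EM. It defaults to the mean
#' foreground fraction over raters, computed on the restriction set.
#'
#' @param raters a \code{\link{rater_set}} with K >= 2.
#' @param max_iter maximum EM iterations.
#' @param tol convergence threshold on the change of the summed posterior
#'   \eqn{\sum_x W(x)} between iterations.
#' @param init_performance initial sensitivity and specificity for every
#'   rater (near-perfect start, the common convention).
#' @param prior optional fixed foreground prior in (0,1); default as above.
#' @param restrict \code{"disputed"} (default) or \code{"full"}.
#' @return a list with \code{label} (fused \code{\link{label_image}}),
#'   \code{performance} (list of \code{sensitivity}, \code{specificity},
#'   \code{foreground_prior}), \code{converged}, \code{n_iter}, and
#'   \code{loglik} (per-iteration observed-data log-likelihood trace, which
#'   is non-decreasing).
#' @export
fuse_staple <- function(raters, max_iter = 100L, tol = 1e-3,
                        init_performance = 0.99999, prior = NULL,
                        restrict = c("disputed", "full")) {
  restrict <- match.arg(restrict)
  rs <- as_rater_set(raters)
  if (rs$K < 2L) stop("STAPLE requires K >= 2 raters")
  ref <- rs$raters[[1L]]
  dm <- compute_disputed_mask(rs)
  E <- decision_matrix(rs)

  if (restrict == "disputed") {
    keep <- as.vector(dm$mask)
    if (!any(keep)) {
      # unanimity: nothing to estimate, input returned unchanged
      return(list(
        label = label_image(dm$unanimous, spacing = dm$spacing,
                            origin = dm$origin),
        performance = list(sensitivity = rep(1, rs$K),
                           specificity = rep(1, rs$K),
                           foreground_prior = mean(E)),
        converged = TRUE, n_iter = 0L, loglik = numeric(0)))
    }
    Es <- E[keep, , drop = FALSE]
  } else {
    Es <- E
  }

  eps <- 1e-5
  g <- if (is.null(prior)) mean(Es) else prior
  g <- min(max(g, eps), 1 - eps)
  sens <- rep(init_performance, rs$K)
  spec <- rep(init_performance, rs$K)
  n_el <- nrow(Es)
  sum_w_prev <- -Inf
  loglik <- numeric(0)
  converged <- FALSE
  iter <- 0L
  W <- NULL

  while (iter < max_iter) {
    iter <- iter + 1L
    # E-step in log space: a(x) ~ T=1, b(x) ~ T=0; one matrix-vector
    # product per hypothesis (the (1 - E) terms fold into constants)
    loga <- log(g) + sum(log(1 - sens)) +
      Es %*% (log(sens) - log(1 - sens))
    logb <- log(1 - g) + sum(log(spec)) +
      Es %*% (log(1 - spec) - log(spec))
    W <- as.vector(stats::plogis(loga - logb))
    m <- pmax(loga, logb)
    loglik <- c(loglik, sum(m + log(exp(loga - m) + exp(logb - m))))
    sum_w <- sum(W)
    if (abs(sum_w - sum_w_prev) < tol) { converged <- TRUE; break }
    sum_w_prev <- sum_w
    # M-step; degenerate denominators are clamped, not fatal
    denom1 <- sum_w
    denom0 <- n_el - sum_w
    sens <- if (denom1 > 0) colSums(W * Es) / denom1 else rep(0.5, rs$K)
    spec <- if (denom0 > 0) colSums((1 - W) * (1 - Es)) / denom0 else rep(0.5, rs$K)
    sens <- pmin(pmax(sens, eps), 1 - eps)
    spec <- pmin(pmax(spec, eps), 1 - eps)
  }
  if (!converged) {
    warning("STAPLE did not converge in ", max_iter, " iterations")
  }

  fused_labels <- as.integer(W >= 0.5)
  if (restrict == "disputed") {
    label <- assemble_fusion(dm, fused_labels)
  } else {
    label <- label_image(array(fused_labels, dim = dim(ref)),
                         spacing = attr(ref, "spacing"),
                         origin = attr(ref, "origin"))
  }
  list(label = label,
       performance = list(sensitivity = as.vector(sens),
                          specificity = as.vector(spec),
                          foreground_prior = g),
       converged = converged, n_iter = iter, loglik = loglik)
}
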