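#' Per-element label frequency
#'
#' Frequency of occurrence of the foreground label at each element over the
#' K raters: f(x, 1) = #\{k : e_k(x) = 1\} / K. The background frequency is
#' its complement, f(x, 0) = 1 - f(x, 1).
#'
#' @param raters a \code{\link{rater_set}}.
#' @return an array of foreground frequencies in [0, 1] on the raters' grid.
#' @export
label_frequency <- function(raters) {
  rs <- as_rater_set(raters)
  E <- decision_matrix(rs)
  ref <- rs$raters[[1L]]
  array(rowSums(E) / rs$K, dim = dim(ref))
}

#' Per-rater misclassification probability estimate
#'
#' For each rater k and element x, the estimated probability that rater k
#' misclassified x, taken as one minus the frequency with which the other
#' raters (k included) assigned the same label: p_k(x) = 1 - f(x, e_k(x)).
#'
#' @param raters a \code{\link{rater_set}}.
#' @return an N x K matrix of probabilities (elements in array order).
#' @export
rater_misclass_prob <- function(raters) {
  rs <- as_rater_set(raters)
  E <- decision_matrix(rs)
  f1 <- rowSums(E) / rs$K
  # f(x, e_k(x)) is f1 where the rater said 1, 1 - f1 where it said 0
  p <- (1 - f1) * E + f1 * (1 - E)
  dimnames(p) <- NULL
  p
}

#' Binomial majority probability
#'
#' Probability that a clear majority of B independent virtual raters, each
#' wrong (or foreground-voting) with probability p, form that majority:
#' the upper-half tail \eqn{\sum_{i=\lceil(B+1)/2\rceil}^{B} \binom{B}{i}
#' p^i (1-p)^{B-i}}. B must be odd so the binomial mass function splits
#' exactly into a lower and an upper part. Computed through the binomial
#' survival function, which is numerically stable for extreme p.
#'
#' @param p probability (vectorized), each in [0, 1].
#' @param B odd positive integer number of virtual raters (default 99, so the
#'   summation index runs from 50 to 99).
#' @return majority probabilities, same length as \code{p}.
#' @examples
#' majority_prob(0.5, 99)  # exactly 0.5 by symmetry
#' @export
majority_prob <- function(p, B = 99L) {
  B <- as.integer(B)
  if (length(B) != 1L || is.na(B) || B < 1L || B %% 2L == 0L) {
    stop("'B' must be a single odd positive integer")
  }
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("'p' must lie in [0, 1]")
  # P(X >= (B+1)/2) = 1 - P(X <= (B-1)/2)
  stats::pbinom((B - 1L) / 2, size = B, prob = p, lower.tail = FALSE)
}

# majority probabilities for the K+1 possible vote counts, used to vectorize
# the estimators below (p_k(x) and f(x,1) only take values c/K, c = 0..K)
majority_prob_table <- function(K, B) majority_prob((0:K) / K, B)

#' Estimated per-rater misclassified-element count
#'
#' v_k = sum over elements of the majority probability of p_k(x): the expected
#' number of elements at which a majority of B virtual raters would call
#' rater k wrong. A ground-truth-free stand-in for the true misclassified
#' count of rater k.
#'
#' @inheritParams majority_prob
#' @param raters a \code{\link{rater_set}}.
#' @return numeric vector of length K.
#' @export
estimate_rater_error <- function(raters, B = 99L) {
  rs <- as_rater_set(raters)
  E <- decision_matrix(rs)
  counts <- rowSums(E)
  Pm <- majority_prob_table(rs$K, B)
  # p_k(x) = (K - c)/K if e_k = 1 else c/K  ->  table lookup
  vk <- numeric(rs$K)
  for (k in seq_len(rs$K)) {
    idx <- ifelse(E[, k] == 1L, rs$K - counts, counts) + 1L
    vk[k] <- sum(Pm[idx])
  }
  vk
}

#' Estimated true foreground size
#'
#' V = sum over elements of the majority probability of f(x, 1): the expected
#' number of elements that a majority of B virtual raters would classify as
#' foreground. A ground-truth-free estimate of the true object size.
#'
#' @inheritParams estimate_rater_error
#' @return a single numeric value in [0, N].
#' @export
estimate_truth_size <- function(raters, B = 99L) {
  rs <- as_rater_set(raters)
  counts <- rowSums(decision_matrix(rs))
  Pm <- majority_prob_table(rs$K, B)
  sum(Pm[counts + 1L])
}

#' Dissimilarity factors of a rater stack
#'
#' The two ground-truth-free dissimilarity estimates driving fusion-strategy
#' selection: the dissimilarity coefficient d_c = sd(v_k) / mean(v_k)
#' (estimating the coefficient of variation of the raters' relative errors)
#' and the dissimilarity ratio d_r = mean(v_k) / V (estimating their mean
#' relative error), built from the binomial majority probabilities of the
#' per-element misclassification estimates.
#'
#' Conventions for degenerate stacks: if all raters are identical
#' (mean(v_k) = 0) both factors are defined as 0 and the result is flagged
#' \code{unanimous} — selection is then moot since every fuser returns the
#' input. If V = 0 while mean(v_k) > 0, d_r is \code{Inf} and flagged.
#'
#' @param raters a \code{\link{rater_set}} with K >= 2.
#' @param B odd virtual-rater count (default 99).
#' @param sd_type \code{"sample"} (n-1 denominator, the default) or
#'   \code{"population"} convention for sd(v_k).
#' @return an object of class \code{dissimilarity_pair}: list with
#'   \code{d_c}, \code{d_r}, \code{v_k}, \code{V}, \code{B},
#'   \code{unanimous}, \code{empty_truth}.
#' @export
dissimilarity_factors <- function(raters, B = 99L,
                                  sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  rs <- as_rater_set(raters)
  if (rs$K < 2L) stop("dissimilarity factors require K >= 2 raters")
  vk <- estimate_rater_error(rs, B)
  V <- estimate_truth_size(rs, B)
  mu <- mean(vk)
  sdv <- stats::sd(vk)
  if (sd_type == "population") sdv <- sdv * sqrt((rs$K - 1) / rs$K)
  unanimous <- mu == 0
  empty_truth <- !unanimous && V == 0
  d_c <- if (unanimous) 0 else sdv / mu
  d_r <- if (unanimous) 0 else if (empty_truth) Inf else mu / V
  structure(list(d_c = d_c, d_r = d_r, v_k = vk, V = V, B = as.integer(B),
                 unanimous = unanimous, empty_truth = empty_truth),
            class = "dissimilarity_pair")
}

#' @export
print.dissimilarity_pair <- function(x, ...) {
  cat("<dissimilarity_pair> d_c = ", signif(x$d_c, 5),
      ", d_r = ", signif(x$d_r, 5),
      if (x$unanimous) " (unanimous)" else "", "\n", sep = "")
  invisible(x)
}
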