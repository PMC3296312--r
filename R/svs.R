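# SVS: train scoring surfaces s_m(d_c, d_r) for the three base fusers from
# simulated tests with known ground truth, then select the best fuser for a
# new rater stack from its dissimilarity factors alone.

svs_methods <- c("STAPLE", "VOTE", "SBA")

run_base_fuser <- function(method, raters, staple_args = list()) {
  switch(method,
         STAPLE = do.call(fuse_staple, c(list(raters = raters), staple_args))$label,
         VOTE = fuse_vote(raters),
         SBA = fuse_sba(raters),
         stop("unknown fusion method: ", method))
}

#' Score fusion results against ground truth
#'
#' For each method m, v_m is the count of elements differing between its
#' fused result and the ground truth. The best method (lowest v_m) scores 1,
#' the worst scores 0, and intermediate methods are linearly interpolated:
#' s = (v_max - v_m) / (v_max - v_min). If all methods tie, every score is 1
#' and the test is flagged degenerate (such tests are kept in training so the
#' surfaces are not biased downward where the methods agree).
#'
#' @param truth ground-truth \code{\link{label_image}}.
#' @param fusions named list of fused \code{\link{label_image}}s, one per
#'   method, all on the truth's grid.
#' @return a list with \code{v_m} (named counts), \code{s} (named scores in
#'   [0, 1]) and \code{degenerate}.
#' @examples
#' tr <- label_image(matrix(0:1, 2, 5))
#' # identical results tie and are flagged degenerate
#' score_test(tr, list(A = tr, B = tr))$degenerate
#' @export
score_test <- function(truth, fusions) {
  truth <- as_label_like(truth)
  v_m <- vapply(fusions, function(f) sum(as_label_like(f) != truth), numeric(1))
  rng <- range(v_m)
  if (rng[1] == rng[2]) {
    s <- rep(1, length(v_m))
    names(s) <- names(v_m)
    return(list(v_m = v_m, s = s, degenerate = TRUE))
  }
  s <- (rng[2] - v_m) / (rng[2] - rng[1])
  list(v_m = v_m, s = s, degenerate = FALSE)
}

# Fit one clamped LOESS surface per method on the training points and tabulate
# it on a dense grid over the training bounding box for portable evaluation.
fit_scoring_surfaces <- function(points, span = 0.25, grid_n = 101L,
                                 provenance = list()) {
  stopifnot(nrow(points) >= 3L)
  dc_rng <- range(points$d_c)
  dr_rng <- range(points$d_r)
  pad <- function(r) if (diff(r) > 0) r else r + c(-1, 1) * max(1e-6, abs(r[1]) * 0.01)
  dc_rng <- pad(dc_rng)
  dr_rng <- pad(dr_rng)
  dc_axis <- seq(dc_rng[1], dc_rng[2], length.out = grid_n)
  dr_axis <- seq(dr_rng[1], dr_rng[2], length.out = grid_n)
  query <- expand.grid(d_c = dc_axis, d_r = dr_axis)

  surfaces <- list()
  spans <- numeric(0)
  for (m in svs_methods) {
    s <- points[[paste0("s_", m)]]
    sp <- span
    fit <- NULL
    repeat {
      fit <- tryCatch(
        stats::loess(s ~ d_c + d_r,
                     data = data.frame(d_c = points$d_c, d_r = points$d_r, s = s),
                     span = sp, degree = 1, family = "gaussian",
                     control = stats::loess.control(surface = "direct")),
        error = function(e) NULL, warning = function(w) NULL)
      ok <- !is.null(fit) &&
        all(is.finite(stats::predict(fit, newdata = query[c(1, nrow(query)), ])))
      if (ok || sp >= 1) break
      sp <- min(1, sp * 1.5)
      warning("widening LOESS span to ", signif(sp, 3), " for surface ", m)
    }
    if (is.null(fit)) {
      warning("LOESS failed for surface ", m, "; falling back to a linear fit")
      fit <- stats::lm(s ~ d_c + d_r,
                       data = data.frame(d_c = points$d_c, d_r = points$d_r, s = s))
    }
    z <- stats::predict(fit, newdata = query)
    z[!is.finite(z)] <- mean(s)
    z <- pmin(pmax(z, 0), 1)
    surfaces[[m]] <- matrix(z, nrow = grid_n)  # rows = d_c, cols = d_r
    spans[m] <- sp
  }

  structure(list(version = 1L, methods = svs_methods, span = span,
                 fitted_spans = spans,
                 grid = list(dc_axis = dc_axis, dr_axis = dr_axis,
                             scores = surfaces),
                 training_points = points, provenance = provenance),
            class = "svs_model")
}

#' Train an SVS scoring model
#'
#' For every training test: compute the dissimilarity factors (d_c, d_r) of
#' its rater stack, run the three base fusers, and score them against the
#' ground truth. One smooth surface s_m(d_c, d_r) is then fitted per method
#' by locally weighted linear regression (LOESS, degree 1) of the scores on
#' the factors, and tabulated on a dense \code{grid_n} x \code{grid_n} grid
#' over the training bounding box. Evaluation bilinearly interpolates inside
#' the box and clamps to the nearest edge outside it, so serialized models
#' are portable and deterministic.
#'
#' @param tests list of training tests, each a list with elements
#'   \code{raters} (a \code{\link{rater_set}}) and \code{truth} (a
#'   \code{\link{label_image}}); \code{\link{make_test_case}} output works
#'   directly.
#' @param span LOESS smoothing fraction (widened automatically, with a
#'   warning, if the local window holds too few points).
#' @param B odd virtual-rater count for the dissimilarity factors.
#' @param grid_n dense-grid resolution per axis.
#' @param staple_args extra arguments passed to \code{\link{fuse_staple}}.
#' @param provenance free-form descriptor (training-set id, seed) stored in
#'   the model.
#' @return an object of class \code{svs_model}.
#' @export
svs_train <- function(tests, span = 0.25, B = 99L, grid_n = 101L,
                      staple_args = list(), provenance = list()) {
  rows <- lapply(tests, function(tc) {
    fac <- dissimilarity_factors(tc$raters, B = B)
    fusions <- lapply(svs_methods, run_base_fuser, raters = tc$raters,
                      staple_args = staple_args)
    names(fusions) <- svs_methods
    sc <- score_test(tc$truth, fusions)
    data.frame(d_c = fac$d_c, d_r = fac$d_r,
               s_STAPLE = sc$s[["STAPLE"]], s_VOTE = sc$s[["VOTE"]],
               s_SBA = sc$s[["SBA"]],
               v_STAPLE = sc$v_m[["STAPLE"]], v_VOTE = sc$v_m[["VOTE"]],
               v_SBA = sc$v_m[["SBA"]],
               degenerate = sc$degenerate, unanimous = fac$unanimous)
  })
  points <- do.call(rbind, rows)
  svs_train_points(points, span = span, grid_n = grid_n,
                   provenance = c(provenance, list(B = as.integer(B))))
}

#' @rdname svs_train
#' @param points a precomputed training table with columns \code{d_c},
#'   \code{d_r}, \code{s_STAPLE}, \code{s_VOTE}, \code{s_SBA},
#'   \code{degenerate} — useful to train several model variants (e.g. 2D, 3D
#'   and combined) without rerunning the fusers.
#' @export
svs_train_points <- function(points, span = 0.25, grid_n = 101L,
                             provenance = list()) {
  if (all(points$degenerate)) {
    stop("all training tests are degenerate (every method tied); ",
         "cannot fit scoring surfaces")
  }
  if (sum(!points$degenerate) < 30L) {
    warning("fewer than 30 non-degenerate training tests; ",
            "scoring surfaces may be poorly constrained")
  }
  fit_scoring_surfaces(points, span = span, grid_n = grid_n,
                       provenance = provenance)
}

#' @export
print.svs_model <- function(x, ...) {
  cat("<svs_model> methods ", paste(x$methods, collapse = "/"),
      " | ", nrow(x$training_points), " training points | span ", x$span,
      "\n", sep = "")
  invisible(x)
}

#' Evaluate the scoring surfaces of a model
#'
#' Bilinear interpolation on the model's dense grid; query points outside the
#' training bounding box are clamped to the nearest edge. Scores are clamped
#' to [0, 1].
#'
#' @param model an \code{svs_model}.
#' @param d_c,d_r dissimilarity factors of the query case.
#' @return named numeric vector of scores, one per method.
#' @export
svs_scores <- function(model, d_c, d_r) {
  stopifnot(inherits(model, "svs_model"))
  g <- model$grid
  qc <- min(max(d_c, g$dc_axis[1]), g$dc_axis[length(g$dc_axis)])
  qr <- min(max(d_r, g$dr_axis[1]), g$dr_axis[length(g$dr_axis)])
  s <- vapply(model$methods, function(m) {
    # score matrix rows follow dc_axis (y), columns dr_axis (x)
    bilinear_grid(x = g$dr_axis, y = g$dc_axis, Z = g$scores[[m]],
                  xp = qr, yp = qc)
  }, numeric(1))
  pmin(pmax(s, 0), 1)
}

#' Weighted-vote meta fusion of several fused labels
#'
#' Element-wise weighted vote over the results of multiple fusion methods:
#' foreground wherever the weighted sum of foreground votes reaches half the
#' total weight (the global foreground tie rule). Used when scoring-surface
#' ties leave no unique best method. If all weights are zero an unweighted
#' majority is taken, with a warning.
#'
#' @param results list of >= 2 \code{\link{label_image}}s on one grid.
#' @param weights non-negative per-result weights.
#' @return the meta-fused \code{\link{label_image}}.
#' @export
meta_fuse <- function(results, weights) {
  stopifnot(length(results) >= 2L, length(weights) == length(results))
  if (any(weights < 0)) stop("meta-fusion weights must be non-negative")
  results <- lapply(results, as_label_like)
  ref <- results[[1L]]
  for (r in results[-1L]) {
    if (!same_geometry(r, ref)) stop("meta-fusion inputs are on different grids")
  }
  if (sum(weights) == 0) {
    warning("all meta-fusion weights are zero; falling back to an unweighted majority")
    weights <- rep(1, length(results))
  }
  acc <- array(0, dim = dim(ref))
  for (m in seq_along(results)) acc <- acc + weights[m] * results[[m]]
  label_image(array(as.integer(acc >= sum(weights) / 2), dim = dim(ref)),
              spacing = attr(ref, "spacing"), origin = attr(ref, "origin"))
}

#' Select and run the best fusion method for a rater stack
#'
#' Computes the stack's dissimilarity factors, evaluates the model's scoring
#' surfaces at (d_c, d_r), and runs only the top-scoring fuser (lazy
#' execution: selection needs the factors alone). On a score tie (within
#' \code{tie_tol}) all three fusers run and their results are meta-fused with
#' the scores as weights. A unanimous stack is returned directly without
#' fusion.
#'
#' @param raters a \code{\link{rater_set}} with K >= 2.
#' @param model a trained \code{svs_model}.
#' @param B odd virtual-rater count for the dissimilarity factors.
#' @param tie_tol score-tie tolerance.
#' @param staple_args extra arguments passed to \code{\link{fuse_staple}}.
#' @return a list with \code{label} (the fused \code{\link{label_image}}) and
#'   \code{report} (d_c, d_r, per-method scores, chosen \code{method} —
#'   a base method name, \code{"META"} on ties, or \code{"UNANIMOUS"}).
#' @export
svs_select <- function(raters, model, B = 99L, tie_tol = 1e-9,
                       staple_args = list()) {
  rs <- as_rater_set(raters)
  if (rs$K < 2L) stop("selection requires K >= 2 raters")
  fac <- dissimilarity_factors(rs, B = B)
  if (fac$unanimous) {
    return(list(label = rs$raters[[1L]],
                report = list(d_c = fac$d_c, d_r = fac$d_r, scores = NULL,
                              method = "UNANIMOUS")))
  }
  s <- svs_scores(model, fac$d_c, fac$d_r)
  top <- which(s >= max(s) - tie_tol)
  if (length(top) == 1L) {
    method <- model$methods[top]
    label <- run_base_fuser(method, rs, staple_args)
  } else {
    method <- "META"
    fusions <- lapply(model$methods, run_base_fuser, raters = rs,
                      staple_args = staple_args)
    label <- meta_fuse(fusions, pmax(s, 0))
  }
  list(label = label,
       report = list(d_c = fac$d_c, d_r = fac$d_r, scores = s,
                     method = method, tied = model$methods[top]))
}

#' Serialize and load SVS models
#'
#' Models are written as structured JSON (axes, dense score grids, training
#' points and provenance) at full numeric precision; a round trip preserves
#' surface evaluations.
#'
#' @param model an \code{svs_model}.
#' @param path JSON file path.
#' @export
write_svs_model <- function(model, path) {
  stopifnot(inherits(model, "svs_model"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA,
                       pretty = FALSE)
  invisible(path)
}

#' @rdname write_svs_model
#' @export
read_svs_model <- function(path) {
  m <- jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyMatrix = TRUE)
  m$grid$scores <- lapply(m$grid$scores, function(z) {
    if (!is.matrix(z)) z <- do.call(rbind, z)
    z
  })
  m$training_points <- as.data.frame(m$training_points)
  m$fitted_spans <- unlist(m$fitted_spans)
  structure(m, class = "svs_model")
}
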