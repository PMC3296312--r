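#' Binary label image
#'
#' Construct a binary label image: a 2D or 3D rectangular grid in which each
#' element carries a label 0 (background) or 1 (segmented object). This is the
#' common currency of the package: raters produce label images, fusers consume
#' stacks of them and return one.
#'
#' @param values a 2D matrix or 3D array whose elements are all exactly 0 or 1
#'   (integer, double or logical).
#' @param spacing element size along each axis, in arbitrary world units.
#'   Defaults to isotropic 1. Fusion math is purely index-based; spacing and
#'   origin are carried as geometry metadata for I/O and the simulators.
#' @param origin world coordinate of the first element along each axis.
#' @return an object of class \code{label_image}: an integer array with
#'   \code{spacing} and \code{origin} attributes.
#' @examples
#' img <- label_image(matrix(c(0, 1, 1, 0), 2, 2))
#' label_ndim(img)
#' @export
label_image <- function(values, spacing = NULL, origin = NULL) {
  if (is.null(dim(values))) stop("'values' must be a matrix or a 3D array")
  nd <- length(dim(values))
  if (nd < 2L || nd > 3L) stop("label images must have 2 or 3 axes, got ", nd)
  if (any(dim(values) < 1L)) stop("all grid dimensions must be >= 1")
  v <- as.vector(values)
  if (is.logical(v)) v <- as.integer(v)
  if (!all(v == 0 | v == 1)) {
    stop("label values must all be exactly 0 or 1 (no silent thresholding)")
  }
  out <- array(as.integer(v), dim = dim(values))
  if (is.null(spacing)) spacing <- rep(1, nd)
  if (is.null(origin)) origin <- rep(0, nd)
  if (length(spacing) != nd || length(origin) != nd) {
    stop("'spacing' and 'origin' must have one entry per axis")
  }
  attr(out, "spacing") <- as.numeric(spacing)
  attr(out, "origin") <- as.numeric(origin)
  class(out) <- c("label_image", class(out))
  out
}

#' @export
print.label_image <- function(x, ...) {
  cat("<label_image> ", paste(dim(x), collapse = " x "),
      " | foreground ", sum(x), "/", length(x),
      " | spacing ", paste(signif(attr(x, "spacing"), 4), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @rdname label_image
#' @param x an object.
#' @export
is_label_image <- function(x) inherits(x, "label_image")

#' @rdname label_image
#' @export
label_ndim <- function(x) length(dim(x))

# geometry equality used by rater_set and the fusers
same_geometry <- function(a, b) {
  identical(dim(a), dim(b)) &&
    isTRUE(all.equal(attr(a, "spacing"), attr(b, "spacing"))) &&
    isTRUE(all.equal(attr(a, "origin"), attr(b, "origin")))
}

as_label_like <- function(x) {
  if (is_label_image(x)) x else label_image(x)
}

#' Ordered stack of rater label images
#'
#' Bundle K binary label images of the same scene, all on one common grid,
#' into the decision structure consumed by every fuser. Element \code{[[k]]}
#' is rater k's segmentation.
#'
#' @param raters a list of \code{\link{label_image}} objects (or plain binary
#'   arrays, which are promoted), all with identical shape, spacing and origin.
#' @return an object of class \code{rater_set}.
#' @examples
#' rs <- rater_set(list(matrix(c(0, 1, 1, 1), 2), matrix(c(0, 1, 0, 1), 2)))
#' n_raters(rs)
#' @export
rater_set <- function(raters) {
  if (!is.list(raters) || length(raters) < 1L) {
    stop("'raters' must be a non-empty list of label images (K >= 1)")
  }
  raters <- lapply(raters, as_label_like)
  ref <- raters[[1L]]
  for (k in seq_along(raters)) {
    if (!same_geometry(raters[[k]], ref)) {
      stop("rater ", k, " is not on the same grid as rater 1 ",
           "(shape/spacing/origin must match)")
    }
  }
  structure(list(raters = raters, K = length(raters)), class = "rater_set")
}

#' @rdname rater_set
#' @param x an object.
#' @export
n_raters <- function(x) {
  if (inherits(x, "rater_set")) x$K else length(x)
}

#' @export
print.rater_set <- function(x, ...) {
  cat("<rater_set> K = ", x$K, " raters on a ",
      paste(dim(x$raters[[1L]]), collapse = " x "), " grid\n", sep = "")
  invisible(x)
}

as_rater_set <- function(x) {
  if (inherits(x, "rater_set")) x else rater_set(x)
}

# N x K decision matrix (columns = raters), the E of the data model
decision_matrix <- function(rs) {
  rs <- as_rater_set(rs)
  n <- length(rs$raters[[1L]])
  matrix(vapply(rs$raters, function(r) as.integer(r), integer(n)),
         nrow = n, ncol = rs$K)
}

#' Disputed-element mask of a rater stack
#'
#' Identify the elements on which the raters disagree. Unanimous elements
#' bypass fusion entirely: their common label is assigned directly, and every
#' fusion algorithm in this package operates on the disputed elements only
#' (which also markedly speeds up STAPLE).
#'
#' @param raters a \code{\link{rater_set}} (K >= 1).
#' @return an object of class \code{disputed_mask}: a list with \code{mask}
#'   (logical array, TRUE where raters disagree), \code{unanimous} (integer
#'   array carrying the agreed label where \code{mask} is FALSE, 0 elsewhere),
#'   and the reference geometry.
#' @examples
#' rs <- rater_set(list(matrix(c(0, 1), 1), matrix(c(0, 0), 1)))
#' compute_disputed_mask(rs)$mask
#' @export
compute_disputed_mask <- function(raters) {
  rs <- as_rater_set(raters)
  E <- decision_matrix(rs)
  counts <- rowSums(E)
  disputed <- counts > 0L & counts < rs$K
  ref <- rs$raters[[1L]]
  mask <- array(disputed, dim = dim(ref))
  unanimous <- array(0L, dim = dim(ref))
  unanimous[!mask] <- E[!disputed, 1L]
  structure(list(mask = mask, unanimous = unanimous,
                 spacing = attr(ref, "spacing"), origin = attr(ref, "origin")),
            class = "disputed_mask")
}

#' @export
print.disputed_mask <- function(x, ...) {
  cat("<disputed_mask> ", sum(x$mask), "/", length(x$mask),
      " disputed elements\n", sep = "")
  invisible(x)
}

#' Reassemble a full label image from unanimous and fused disputed labels
#'
#' Inverse of the disputed-element restriction: unanimous elements keep their
#' common label, disputed elements take the labels a fuser produced for them
#' (in array order of the TRUE entries of the mask).
#'
#' @param disputed a \code{\link{compute_disputed_mask}} result.
#' @param fused_disputed_labels vector of 0/1 labels, one per disputed element.
#' @return a \code{\link{label_image}}.
#' @export
assemble_fusion <- function(disputed, fused_disputed_labels) {
  if (!inherits(disputed, "disputed_mask")) stop("'disputed' must be a disputed_mask")
  nd <- sum(disputed$mask)
  if (length(fused_disputed_labels) != nd) {
    stop("expected ", nd, " disputed labels, got ", length(fused_disputed_labels))
  }
  vals <- disputed$unanimous
  vals[disputed$mask] <- as.integer(fused_disputed_labels)
  label_image(vals, spacing = disputed$spacing, origin = disputed$origin)
}

#' Read and write binary label images
#'
#' \code{read_label} reads a binary label image from NIfTI-1 (\code{.nii},
#' \code{.nii.gz}; 2D or 3D) or single-channel PNG (\code{.png}; 2D, pixel
#' values 0/255 mapped to 0/1). Any other value in the file is a hard error:
#' nothing is thresholded silently. \code{write_label} is the inverse.
#'
#' @param path file path; format chosen by extension.
#' @return \code{read_label} returns a \code{\link{label_image}}.
#' @export
read_label <- function(path) {
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    img <- RNifti::readNifti(path)
    vals <- as.array(img)
    if (length(dim(vals)) > 3L) dim(vals) <- dim(vals)[1:3]
    pix <- attr(img, "pixdim")
    nd <- length(dim(vals))
    spacing <- if (!is.null(pix)) pix[seq_len(nd)] else rep(1, nd)
    if (!all(vals == 0 | vals == 1)) {
      stop("non-binary values in ", path, "; labels must be exactly 0/1")
    }
    label_image(vals, spacing = spacing)
  } else if (grepl("\\.png$", path, ignore.case = TRUE)) {
    v <- png::readPNG(path)
    if (length(dim(v)) == 3L) {
      if (!all(apply(v, 3, identical, v[, , 1L]))) {
        stop("multi-channel PNG with differing channels in ", path)
      }
      v <- v[, , 1L]
    }
    if (!all(v == 0 | v == 1)) {
      stop("non-binary pixel values in ", path, "; expected 0 or 255 only")
    }
    # readPNG returns row = image row (y); transpose so axis 1 is x
    label_image(t(v)[, rev(seq_len(nrow(v))), drop = FALSE])
  } else {
    stop("unsupported label format: ", path, " (use .nii, .nii.gz or .png)")
  }
}

#' @rdname read_label
#' @param image a \code{\link{label_image}}.
#' @export
write_label <- function(image, path) {
  image <- as_label_like(image)
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    arr <- array(as.integer(image), dim = dim(image))
    nim <- RNifti::asNifti(arr)
    RNifti::pixdim(nim) <- attr(image, "spacing")
    RNifti::writeNifti(nim, path)
  } else if (grepl("\\.png$", path, ignore.case = TRUE)) {
    if (label_ndim(image) != 2L) stop("PNG output supports 2D labels only")
    m <- array(as.numeric(image), dim = dim(image))
    png::writePNG(t(m[, rev(seq_len(ncol(m))), drop = FALSE]), path)
  } else {
    stop("unsupported label format: ", path)
  }
  invisible(path)
}
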