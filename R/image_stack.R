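#' Image stacks
#'
#' A light container for 2D images and 3D image stacks: a numeric matrix or
#' 3D array (indexed `[y, x]` or `[y, x, z]`, with `x` the image column and
#' `z` the slice) plus a per-axis physical voxel spacing.
#'
#' @param values numeric matrix (2D) or 3D array of intensities (no
#'   infinities; NaN marks invalid pixels in analysis maps).
#' @param spacing numeric vector of per-axis physical sizes (e.g. micrometres
#'   per pixel), one entry per array dimension, or a single value recycled.
#'   Defaults to 1 along every axis.
#' @return An `image_stack`: the array with a `spacing` attribute.
#' @examples
#' img <- image_stack(matrix(runif(100), 10, 10), spacing = 0.5)
#' dim(img)
#' @export
image_stack <- function(values, spacing = 1) {
  if (is.null(dim(values))) stop("`values` must be a matrix or 3D array")
  nd <- length(dim(values))
  if (!nd %in% c(2L, 3L)) stop("`values` must be 2D or 3D")
  if (any(is.infinite(values))) stop("intensities must not be infinite")
  spacing <- rep_len(as.numeric(spacing), nd)
  if (any(spacing <= 0)) stop("spacing entries must be > 0")
  structure(values, spacing = spacing, class = c("image_stack", class(values)))
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<image_stack> %s  spacing: %s\n",
              paste(d, collapse = " x "),
              paste(signif(attr(x, "spacing"), 4), collapse = " x ")))
  cat(sprintf("  intensity range [%g, %g]\n",
              min(x, na.rm = TRUE), max(x, na.rm = TRUE)))
  invisible(x)
}

stack_spacing <- function(x) {
  sp <- attr(x, "spacing")
  if (is.null(sp)) rep(1, length(dim(x))) else sp
}

as_plain_array <- function(x) {
  attributes(x) <- list(dim = dim(x))
  x
}

check_grid <- function(x, name = deparse(substitute(x))) {
  if (is.null(dim(x)) || !length(dim(x)) %in% c(2L, 3L))
    stop(sprintf("`%s` must be a 2D or 3D array", name))
  invisible(x)
}

check_same_shape <- function(a, b, na = "first", nb = "second") {
  if (!identical(dim(a), dim(b)))
    stop(sprintf("%s and %s grids must share a shape (%s vs %s)", na, nb,
                 paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x")))
  invisible(NULL)
}
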