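#' Orientation estimation parameters
#'
#' Settings for the weighted orientation vector summation. In `"wo"`
#' (window-optimizing) mode the analysis window is chosen per pixel from the
#' local fiber thickness `d` as `2d + 1`; in `"fixed"` mode one window is
#' used everywhere.
#'
#' @param mode `"wo"` or `"fixed"`.
#' @param fixed_window odd window edge length in pixels (fixed mode only).
#' @param weight_distance_exponent exponent `e` of the inverse-distance
#'   weight `1 / r^e` applied to each neighbour's contribution.
#' @param use_intensity_weight multiply each neighbour's weight by its image
#'   intensity (on binary renderings this is a constant and has no effect).
#' @param circular_window restrict the square window to its inscribed disc,
#'   which makes the neighbourhood rotationally symmetric.
#' @param min_neighbors minimum number of contributing neighbours for a
#'   pixel to receive a valid orientation.
#' @param window_range allowed `[min, max]` for the adaptive window size.
#'   The default floor of 9 px keeps sub-9-px windows (where the direction
#'   lattice quantizes the axial estimate severely on 1-2 px fibers) from
#'   being selected; `2d + 1` applies unchanged wherever it exceeds the
#'   floor.
#' @return An `orientation_params` list.
#' @export
orientation_params <- function(mode = c("wo", "fixed"), fixed_window = NULL,
                               weight_distance_exponent = 1,
                               use_intensity_weight = TRUE,
                               circular_window = TRUE,
                               min_neighbors = 4L,
                               window_range = c(9L, 201L)) {
  mode <- match.arg(mode)
  if (mode == "fixed") {
    if (is.null(fixed_window)) stop("fixed mode requires `fixed_window`")
    fixed_window <- as.integer(fixed_window)
    if (fixed_window < 3L || fixed_window %% 2L == 0L)
      stop("`fixed_window` must be an odd integer >= 3")
  }
  if (weight_distance_exponent < 0) stop("`weight_distance_exponent` must be >= 0")
  min_neighbors <- as.integer(min_neighbors)
  if (min_neighbors < 1L) stop("`min_neighbors` must be >= 1")
  window_range <- as.integer(window_range)
  structure(list(mode = mode, fixed_window = fixed_window,
                 weight_distance_exponent = weight_distance_exponent,
                 use_intensity_weight = use_intensity_weight,
                 circular_window = circular_window,
                 min_neighbors = min_neighbors,
                 window_range = window_range),
            class = "orientation_params")
}

#' Adaptive analysis window from local thickness
#'
#' The window edge for a pixel of thickness `d` is `2 * round(d) + 1`
#' (rounding half up), clamped to `range` and forced odd.
#'
#' @param d positive thickness value(s) in pixels.
#' @param range `[min, max]` clamp for the window size.
#' @return odd integer window edge length(s).
#' @examples
#' window_size(5)    # 11
#' window_size(5.4)  # 11
#' window_size(1)    # 3
#' @export
window_size <- function(d, range = c(3L, 201L)) {
  if (any(d <= 0)) stop("thickness must be > 0")
  w <- 2L * as.integer(floor(d + 0.5)) + 1L
  w <- pmax(range[1], pmin(range[2], w))
  w - (1L - w %% 2L)  # keep odd after clamping
}

#' Pixel-wise 2D orientation by weighted vector summation
#'
#' For every foreground pixel, neighbouring foreground pixels inside the
#' analysis window contribute the doubled-angle unit vector of their
#' direction from the centre, weighted by intensity and inverse distance;
#' the summed vector, halved back, is the local fiber axis angle theta in
#' `[0, 180)` degrees (axial, measured from the +x image axis).
#'
#' @param img numeric image (intensities used for weighting), or `NULL` to
#'   weight by foreground membership only.
#' @param mask logical foreground mask.
#' @param thick thickness map from [local_thickness()] (wo mode).
#' @param params an [orientation_params()] object.
#' @return An `orientation_field` list: `theta` (degrees, `NA` = invalid),
#'   `valid`, `window_used`, `n_neighbors`.
#' @export
orient2d <- function(img, mask, thick = NULL, params = orientation_params()) {
  check_grid(mask)
  if (length(dim(mask)) != 2L) stop("orient2d expects 2D inputs")
  storage.mode(mask) <- "logical"
  if (is.null(img)) img <- array(1, dim(mask))
  check_same_shape(img, mask, "img", "mask")
  win <- resolve_windows(mask, thick, params)
  inten <- if (isTRUE(params$use_intensity_weight)) as.numeric(img)
           else rep(1, length(mask))
  res <- cpp_orient2d(as.logical(as.vector(mask)), inten, as.integer(win),
                      as.integer(dim(mask)), params$weight_distance_exponent,
                      isTRUE(params$circular_window), params$min_neighbors)
  theta <- array(res$theta, dim(mask))
  structure(list(theta = theta, phi = NULL,
                 valid = is.finite(theta),
                 window_used = array(as.integer(win), dim(mask)),
                 n_neighbors = array(res$n_neighbors, dim(mask)),
                 params = params),
            class = "orientation_field")
}

#' Voxel-wise 3D orientation by weighted dyadic summation
#'
#' The 3D analogue of [orient2d()]: neighbour directions accumulate a
#' weighted orientation (dyadic) tensor whose dominant eigenvector is the
#' local fiber axis, reported as azimuth `theta` (from +x, in the xy plane)
#' and polar angle `phi` (from +z), both in `[0, 180)` degrees. Voxels whose
#' leading eigenvalue is tied within `tie_tol` (isotropic neighbourhoods)
#' are invalid.
#'
#' @inheritParams orient2d
#' @param tie_tol relative eigenvalue-gap tolerance below which the axis is
#'   considered undefined.
#' @param centers optional integer matrix of voxel coordinates (rows of
#'   `[y, x, z]`) at which to evaluate; default all foreground voxels.
#'   Evaluating a subsample is useful for summary statistics on large
#'   stacks.
#' @return An `orientation_field` with `theta` and `phi` arrays.
#' @export
orient3d <- function(img, mask, thick = NULL, params = orientation_params(),
                     tie_tol = 1e-6, centers = NULL) {
  check_grid(mask)
  if (length(dim(mask)) != 3L) stop("orient3d expects 3D inputs")
  storage.mode(mask) <- "logical"
  if (is.null(img)) img <- array(1, dim(mask))
  check_same_shape(img, mask, "img", "mask")
  win <- resolve_windows(mask, thick, params)
  inten <- if (isTRUE(params$use_intensity_weight)) as.numeric(img)
           else rep(1, length(mask))
  ctr <- integer(0)
  if (!is.null(centers)) {
    stopifnot(is.matrix(centers), ncol(centers) == 3L)
    dm <- dim(mask)
    ctr <- as.integer((centers[, 1] - 1L) +
                      (centers[, 2] - 1L) * dm[1] +
                      (centers[, 3] - 1L) * dm[1] * dm[2])
  }
  res <- cpp_orient3d(as.logical(as.vector(mask)), inten, as.integer(win),
                      as.integer(dim(mask)), params$weight_distance_exponent,
                      isTRUE(params$circular_window), params$min_neighbors,
                      tie_tol, ctr)
  theta <- array(res$theta, dim(mask))
  phi <- array(res$phi, dim(mask))
  structure(list(theta = theta, phi = phi,
                 valid = is.finite(theta) & is.finite(phi),
                 window_used = array(as.integer(win), dim(mask)),
                 n_neighbors = array(res$n_neighbors, dim(mask)),
                 params = params),
            class = "orientation_field")
}

resolve_windows <- function(mask, thick, params) {
  if (params$mode == "fixed") {
    rep(params$fixed_window, length(mask))
  } else {
    if (is.null(thick)) stop("wo mode requires a thickness map")
    check_same_shape(thick, mask, "thick", "mask")
    w <- rep(3L, length(mask))
    fg <- as.vector(mask) & as.vector(thick) > 0
    w[fg] <- window_size(as.vector(thick)[fg], params$window_range)
    w
  }
}

#' @export
print.orientation_field <- function(x, ...) {
  d <- dim(x$theta)
  cat(sprintf("<orientation_field> %s  (%s)\n", paste(d, collapse = " x "),
              if (is.null(x$phi)) "2D: theta" else "3D: theta + phi"))
  cat(sprintf("  valid pixels: %d\n", sum(x$valid)))
  if (any(x$valid))
    cat(sprintf("  theta range [%0.1f, %0.1f] deg\n",
                min(x$theta[x$valid]), max(x$theta[x$valid])))
  invisible(x)
}
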