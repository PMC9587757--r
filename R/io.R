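#' Read a grayscale TIFF image or stack
#'
#' Single-page files become 2D [image_stack()]s; multi-page files become 3D
#' stacks with the page index as the `z` axis. Integer samples are returned
#' at their native scale (not normalized), float samples as stored
#' (NaN preserved).
#'
#' @param path path to a single- or multi-page grayscale TIFF.
#' @param spacing optional per-axis physical spacing passed to the stack.
#' @return An [image_stack()].
#' @export
read_stack <- function(path, spacing = 1) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path))
  # integer samples at native scale; float samples (where as.is is refused)
  # are already stored in physical units
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                    error = function(e) tiff::readTIFF(path, all = TRUE))
  if (!is.list(pages)) pages <- list(pages)
  for (p in pages) {
    if (length(dim(p)) == 3L)
      stop(sprintf("'%s' has multi-channel pages; only grayscale is supported",
                   path))
  }
  arr <- if (length(pages) == 1L) pages[[1]] else
    array(unlist(pages, use.names = FALSE),
          c(dim(pages[[1]]), length(pages)))
  image_stack(array(as.numeric(arr), dim(arr)), spacing)
}

#' Write an image or stack as a grayscale TIFF
#'
#' 3D stacks are written as multi-page TIFFs (slice = page). Integer-valued
#' data are stored at 8 or 16 bits; anything else (including `NaN`) is
#' stored as 32-bit IEEE float, so analysis maps in physical units round
#' trip losslessly.
#'
#' @param img matrix, array or [image_stack()].
#' @param path output path; the parent directory must exist.
#' @param bits `"auto"`, 8, 16, or 32. `"auto"` picks the smallest integer
#'   type that holds the data exactly, else 32-bit float.
#' @return `path`, invisibly.
#' @export
write_stack <- function(img, path, bits = "auto") {
  check_grid(img)
  dir <- dirname(path)
  if (!dir.exists(dir)) stop(sprintf("directory does not exist: '%s'", dir))
  v <- as_plain_array(img)
  pages <- split_pages(v)
  is_int <- all(is.finite(v)) && all(v >= 0) && all(v == round(v))
  if (identical(bits, "auto"))
    bits <- if (is_int && max(v) < 256) 8L
            else if (is_int && max(v) < 65536) 16L
            else 32L
  bits <- as.integer(bits)
  if (bits %in% c(8L, 16L)) {
    if (!is_int || max(v) >= 2^bits)
      stop(sprintf("data does not fit %d-bit integer storage", bits))
    scale <- 2^bits - 1
    tiff::writeTIFF(lapply(pages, function(p) p / scale), path,
                    bits.per.sample = bits, compression = "none")
  } else if (bits == 32L) {
    cpp_write_tiff_f32(pages, path)
  } else stop("`bits` must be \"auto\", 8, 16 or 32")
  invisible(path)
}

split_pages <- function(v) {
  if (length(dim(v)) == 2L) return(list(v))
  lapply(seq_len(dim(v)[3]), function(z) v[, , z])
}

#' Binarize an intensity image
#'
#' Global thresholding of the whole image or stack: either Otsu's method
#' (between-class variance maximization on a 256-bin histogram) or a fixed
#' threshold. Pixels strictly above the threshold are foreground.
#'
#' @param img matrix, array or [image_stack()].
#' @param method `"otsu"` or `"fixed"`.
#' @param threshold threshold intensity (required for `"fixed"`).
#' @return logical array of the same shape.
#' @export
binarize <- function(img, method = c("otsu", "fixed"), threshold = NULL) {
  method <- match.arg(method)
  check_grid(img)
  v <- as_plain_array(img)
  if (method == "fixed") {
    if (is.null(threshold)) stop("fixed method requires `threshold`")
  } else {
    rng <- range(v)
    if (rng[1] == rng[2]) stop("constant image: Otsu threshold is undefined")
    threshold <- otsu_threshold(v)
  }
  m <- v > threshold
  dim(m) <- dim(v)
  m
}

otsu_threshold <- function(v) {
  rng <- range(v)
  nb <- 256L
  br <- seq(rng[1], rng[2], length.out = nb + 1L)
  h <- tabulate(pmin(nb, findInterval(v, br, rightmost.closed = TRUE)), nb)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(nb))
  mu_t <- mu[nb]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  k <- which.max(sigma_b)
  br[k + 1L]
}

#' Export an orientation angle map as a hue-coded PNG
#'
#' Angles are mapped cyclically onto hue over the axial period (0 and 180
#' degrees share a color); invalid pixels are black. A color-wheel legend
#' strip is written alongside (suffix `_legend.png`).
#'
#' @param field an `orientation_field` from [orient2d()]/[orient3d()].
#' @param path output PNG path.
#' @param angle which angle to export: `"theta"` or `"phi"`.
#' @param slice slice index for 3D fields (default middle slice).
#' @return `path`, invisibly.
#' @export
export_orientation_png <- function(field, path, angle = c("theta", "phi"),
                                   slice = NULL) {
  angle <- match.arg(angle)
  a <- if (angle == "theta") field$theta else field$phi
  if (is.null(a)) stop(sprintf("field has no %s angle", angle))
  if (length(dim(a)) == 3L) {
    if (is.null(slice)) slice <- ceiling(dim(a)[3] / 2)
    a <- a[, , slice]
  }
  rgb_arr <- angle_to_rgb(a)
  png::writePNG(rgb_arr, path)
  # legend: hue wheel over [0, 180)
  leg <- matrix(seq(0, 179.999, length.out = 360), nrow = 24, ncol = 360,
                byrow = TRUE)
  png::writePNG(angle_to_rgb(leg),
                sub("\\.png$", "_legend.png", path))
  invisible(path)
}

angle_to_rgb <- function(a) {
  h <- (a %% 180) / 180
  ok <- is.finite(h)
  col <- matrix(0, length(h), 3)
  if (any(ok)) {
    cc <- t(grDevices::col2rgb(grDevices::hsv(h[ok], 1, 1))) / 255
    col[ok, ] <- cc
  }
  array(col, c(dim(a), 3))
}

#' Histogram of values as a probability table
#'
#' Bins values over a fixed range and returns per-bin probabilities that sum
#' to one, as used for orientation-angle distributions.
#'
#' @param values numeric vector (non-finite entries are dropped).
#' @param bins number of bins (>= 1).
#' @param range numeric `[lo, hi)` interval to bin over.
#' @param path optional CSV output path.
#' @return A tibble with `bin_left`, `bin_right`, `probability`.
#' @export
export_histogram <- function(values, bins = 18L, range = c(0, 180),
                             path = NULL) {
  values <- values[is.finite(values)]
  if (length(values) == 0L) stop("no finite values to bin")
  bins <- as.integer(bins)
  if (bins < 1L) stop("`bins` must be >= 1")
  br <- seq(range[1], range[2], length.out = bins + 1L)
  idx <- pmin(bins, pmax(1L, findInterval(values, br, rightmost.closed = TRUE)))
  counts <- tabulate(idx, bins)
  out <- tibble::tibble(bin_left = br[-length(br)], bin_right = br[-1],
                        probability = counts / sum(counts))
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}
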