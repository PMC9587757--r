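#' Directional variance of 2D axial angles
#'
#' Circular variance on doubled angles: `V = 1 - ||mean(cos 2t, sin 2t)||`.
#' 0 for identical orientations (mod 180), 1 for isotropically distributed
#' ones.
#'
#' @param thetas axial angles in degrees; non-finite entries are dropped.
#' @return A single value in `[0, 1]`.
#' @examples
#' directional_variance_2d(c(45, 45, 45))  # 0
#' directional_variance_2d(c(0, 90))       # 1
#' @export
directional_variance_2d <- function(thetas) {
  thetas <- thetas[is.finite(thetas)]
  if (length(thetas) < 2L) stop("need at least 2 finite angles")
  a <- thetas * pi / 90  # doubled angle in radians
  v <- 1 - sqrt(mean(cos(a))^2 + mean(sin(a))^2)
  min(1, max(0, v))
}

#' Directional variance of 3D axes
#'
#' Orientation-tensor variance: with `T = mean(u u^T)` over unit axes `u`,
#' `V = 3/2 * (1 - lambda1(T))`. 0 for identical axes, 1 for isotropic
#' axes (`lambda1 = 1/3`).
#'
#' @param theta,phi axial azimuth and polar angles in degrees (paired);
#'   pairs with non-finite entries are dropped.
#' @return A single value in `[0, 1]`.
#' @examples
#' directional_variance_3d(c(0, 0), c(0, 0))       # aligned: 0
#' directional_variance_3d(c(0, 90, 0), c(90, 90, 0))  # x, y, z: 1
#' @export
directional_variance_3d <- function(theta, phi) {
  ok <- is.finite(theta) & is.finite(phi)
  theta <- theta[ok]; phi <- phi[ok]
  if (length(theta) < 2L) stop("need at least 2 finite axis pairs")
  t <- theta * pi / 180; p <- phi * pi / 180
  u <- cbind(sin(p) * cos(t), sin(p) * sin(t), cos(p))
  T <- crossprod(u) / nrow(u)
  lam1 <- max(eigen(T, symmetric = TRUE, only.values = TRUE)$values)
  min(1, max(0, 1.5 * (1 - lam1)))
}

#' Local directional variance map
#'
#' Directional variance computed per pixel/voxel over the valid orientations
#' in a square/cubic neighbourhood: the 2D doubled-angle circular variance,
#' or the 3D orientation-tensor variance when the field has a polar angle.
#'
#' @param field an `orientation_field`.
#' @param neighborhood odd neighbourhood edge length in pixels.
#' @param min_count minimum number of valid orientations for a defined
#'   value.
#' @return A `variance_map`: numeric array of `V` in `[0, 1]` (NaN where
#'   undefined) with attributes `neighborhood` and `min_count`.
#' @export
local_variance_map <- function(field, neighborhood = 21L, min_count = 10L) {
  stopifnot(inherits(field, "orientation_field"))
  neighborhood <- as.integer(neighborhood)
  if (neighborhood < 1L || neighborhood %% 2L == 0L)
    stop("`neighborhood` must be a positive odd integer")
  if (!any(field$valid)) {
    v <- array(NA_real_, dim(field$theta))
  } else {
    dm <- dim(field$theta)
    v <- array(cpp_local_variance(as.numeric(field$theta),
                                  if (is.null(field$phi)) numeric(0)
                                  else as.numeric(field$phi),
                                  as.integer(dm), neighborhood,
                                  as.integer(min_count)), dm)
  }
  structure(v, neighborhood = neighborhood, min_count = as.integer(min_count),
            class = c("variance_map", class(v)))
}

#' Depth profile of a variance map
#'
#' Per-slice mean directional variance of a 3D variance map, against
#' physical depth.
#'
#' @param vmap a 3D `variance_map` (or plain 3D array of variances).
#' @param spacing_z physical slice spacing (e.g. micrometres).
#' @return A tibble with `slice`, `depth`, `variance_mean`, `n_valid`.
#' @export
depth_profile <- function(vmap, spacing_z = 1) {
  check_grid(vmap)
  if (length(dim(vmap)) != 3L) stop("depth_profile expects a 3D map")
  nz <- dim(vmap)[3]
  vm <- vapply(seq_len(nz), function(z) {
    s <- vmap[, , z]
    n <- sum(is.finite(s))
    c(if (n > 0) mean(s[is.finite(s)]) else NA_real_, n)
  }, numeric(2))
  tibble::tibble(slice = seq_len(nz),
                 depth = (seq_len(nz) - 1) * spacing_z,
                 variance_mean = vm[1, ],
                 n_valid = as.integer(vm[2, ]))
}

#' Thickness-stratified variance distributions
#'
#' Partitions valid pixels/voxels by physical fiber thickness and collects
#' the local directional variance distribution of each stratum.
#'
#' @param field an `orientation_field`.
#' @param thick thickness map in pixels (from [local_thickness()]).
#' @param edges increasing physical thickness thresholds (same units as
#'   `spacing`) splitting the data into `length(edges) + 1` strata.
#' @param spacing physical size per pixel (converts `thick` to the units of
#'   `edges`).
#' @param neighborhood,min_count passed to [local_variance_map()].
#' @param vmap optional precomputed variance map (skips recomputation).
#' @return A tibble with one row per pixel: `stratum` (factor with interval
#'   labels), `thickness` (physical units), `variance`.
#' @export
stratify_by_thickness <- function(field, thick, edges, spacing = 1,
                                  neighborhood = 21L, min_count = 10L,
                                  vmap = NULL) {
  stopifnot(inherits(field, "orientation_field"))
  check_same_shape(field$theta, thick, "field", "thick")
  if (is.unsorted(edges, strictly = TRUE)) stop("`edges` must be increasing")
  if (is.null(vmap))
    vmap <- local_variance_map(field, neighborhood, min_count)
  sel <- field$valid & is.finite(vmap)
  if (!any(sel)) warning("no valid pixels to stratify")
  phys <- as.vector(thick)[sel] * spacing
  br <- c(-Inf, edges, Inf)
  labs <- c(paste0("<", edges[1]),
            if (length(edges) > 1)
              paste0(utils::head(edges, -1), "-", edges[-1]),
            paste0(">=", edges[length(edges)]))
  tibble::tibble(
    stratum = cut(phys, br, labels = labs, right = FALSE),
    thickness = phys,
    variance = as.vector(vmap)[sel])
}
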