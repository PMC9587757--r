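#' Phantom specification
#'
#' Parameters for synthetic fiber images with exact per-pixel ground truth
#' (orientation, thickness, foreground mask). Fibers are straight or
#' sinusoidally curved axis segments dilated to their diameter: a pixel is
#' foreground iff its centre lies within D/2 of the axis. Diameter-1 fibers
#' are rendered as single-pixel digital (Bresenham) lines.
#'
#' @param dims image size: 2 entries (ny, nx) or 3 entries (ny, nx, nz),
#'   each >= 32.
#' @param diameters fiber diameters in pixels, each in (0, min(dims)/2).
#' @param n_fibers_per_diameter fibers drawn per diameter.
#' @param fiber_model `"straight"` or `"curvy"`.
#' @param curvature_amplitude sinusoidal centreline amplitude (px, curvy).
#' @param curvature_period sinusoidal centreline period (px, curvy).
#' @param intensity_fg,intensity_bg foreground / background intensity.
#' @param noise_sd additive Gaussian noise sd (0 = noiseless).
#' @param seed integer RNG seed; identical specs generate bit-identical
#'   phantoms.
#' @param overlap_policy `"forbid"` rejects placements that touch (within
#'   `gap`) an existing fiber; `"truth_by_nearest_axis"` allows crossings
#'   and assigns contested pixels to the axis they are closest to (in
#'   radius-relative units).
#' @param length_range fiber axis length range in pixels; the default
#'   (0.55-0.95 of the smallest image dimension) makes fibers span most of
#'   the field, as fiber ends are the hardest regions for any windowed
#'   orientation estimator.
#' @param gap minimum background separation between fibers (forbid policy).
#' @param edge_profile `"soft"` renders a one-pixel partial-volume intensity
#'   ramp at fiber edges (the mask is unaffected); `"flat"` renders binary
#'   intensities.
#' @param max_tries placement attempts per fiber before failing.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(dims, diameters, n_fibers_per_diameter = 1L,
                         fiber_model = c("straight", "curvy"),
                         curvature_amplitude = 0, curvature_period = 150,
                         intensity_fg = 1, intensity_bg = 0, noise_sd = 0,
                         seed = 1L,
                         overlap_policy = c("forbid", "truth_by_nearest_axis"),
                         length_range = NULL, gap = 4,
                         edge_profile = c("soft", "flat"),
                         max_tries = 200L) {
  fiber_model <- match.arg(fiber_model)
  overlap_policy <- match.arg(overlap_policy)
  edge_profile <- match.arg(edge_profile)
  dims <- as.integer(dims)
  if (!length(dims) %in% c(2L, 3L)) stop("`dims` needs 2 or 3 entries")
  if (any(dims < 32L)) stop("all `dims` entries must be >= 32")
  diameters <- as.numeric(diameters)
  if (any(diameters <= 0)) stop("all diameters must be > 0")
  if (any(diameters >= min(dims) / 2))
    stop("all diameters must be < min(dims) / 2")
  if (curvature_amplitude < 0) stop("`curvature_amplitude` must be >= 0")
  if (curvature_period <= 0) stop("`curvature_period` must be > 0")
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  if (intensity_fg <= 0) stop("`intensity_fg` must be > 0")
  if (intensity_bg < 0) stop("`intensity_bg` must be >= 0")
  if (is.null(length_range))
    length_range <- c(0.55, 0.95) * min(dims)
  structure(list(dims = dims, diameters = diameters,
                 n_fibers_per_diameter = as.integer(n_fibers_per_diameter),
                 fiber_model = fiber_model,
                 curvature_amplitude = curvature_amplitude,
                 curvature_period = curvature_period,
                 intensity_fg = intensity_fg, intensity_bg = intensity_bg,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 overlap_policy = overlap_policy,
                 length_range = as.numeric(length_range), gap = gap,
                 edge_profile = edge_profile,
                 max_tries = as.integer(max_tries)),
            class = "phantom_spec")
}

with_phantom_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
         else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Generate a straight-fiber 2D phantom
#'
#' Renders `n_fibers_per_diameter` straight fibers per diameter at uniform
#' random orientations and positions, largest first, and returns the image
#' together with exact ground truth.
#'
#' @param spec a [phantom_spec()] with 2 `dims` entries.
#' @return A `phantom` list: `image` ([image_stack()]), `truth` (list of
#'   `mask`, `theta` — and `phi` in 3D — and `thickness`), and `spec`.
#' @export
generate_straight_fibers_2d <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (length(spec$dims) != 2L) stop("2D generator requires 2 `dims` entries")
  if (spec$fiber_model != "straight") stop("fiber_model must be \"straight\"")
  generate_fibers_nd(spec)
}

#' Generate a curvy-fiber 2D phantom
#'
#' Fibers follow sinusoidally perturbed centrelines (amplitude
#' `curvature_amplitude`, period `curvature_period`, random phase); the
#' stored ground-truth orientation at each pixel is the analytic tangent
#' angle of the nearest centreline point. With zero amplitude the output is
#' identical to [generate_straight_fibers_2d()] for the same spec.
#'
#' @param spec a [phantom_spec()] with 2 `dims` entries and
#'   `fiber_model = "curvy"`.
#' @return A `phantom` list (see [generate_straight_fibers_2d()]).
#' @export
generate_curvy_fibers_2d <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (length(spec$dims) != 2L) stop("2D generator requires 2 `dims` entries")
  if (spec$fiber_model != "curvy") stop("fiber_model must be \"curvy\"")
  generate_fibers_nd(spec)
}

#' Generate a straight-cylinder 3D phantom
#'
#' Renders straight cylinders of constant diameter along uniformly random
#' 3D axes; ground truth stores the axial azimuth `theta` and polar angle
#' `phi` (degrees, `[0, 180)`) plus the diameter at every fiber voxel.
#'
#' @param spec a [phantom_spec()] with 3 `dims` entries.
#' @return A `phantom` list with `theta` and `phi` truth arrays.
#' @export
generate_fibers_3d <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (length(spec$dims) != 3L) stop("3D generator requires 3 `dims` entries")
  generate_fibers_nd(spec)
}

generate_fibers_nd <- function(spec) {
  nd <- length(spec$dims)
  dm <- spec$dims
  n <- prod(dm)
  mask <- array(FALSE, dm)
  inten <- array(spec$intensity_bg, dm)
  theta_t <- array(NA_real_, dm)
  phi_t <- if (nd == 3L) array(NA_real_, dm) else numeric(0)
  thick_t <- array(0, dm)
  claim <- array(Inf, dm)
  forbid <- spec$overlap_policy == "forbid"

  with_phantom_seed(spec$seed, {
    for (D in sort(spec$diameters, decreasing = TRUE)) {
      for (j in seq_len(spec$n_fibers_per_diameter)) {
        placed <- FALSE
        for (try in seq_len(spec$max_tries)) {
          len <- runif(1, spec$length_range[1], spec$length_range[2])
          ctr <- vapply(seq_len(nd), function(i) runif(1, 0, dm[i] - 1), 0)
          if (nd == 2L) {
            ang <- runif(1, 0, 180)
            center <- c(ctr[2], ctr[1])          # (x, y)
            phase <- runif(1, 0, 2 * pi)         # drawn for both models to
                                                 # keep RNG streams aligned
            pl <- polyline_2d(spec, ang, center, len, phase)
          } else {
            u <- random_axis3()
            center <- c(ctr[2], ctr[1], ctr[3])  # (x, y, z)
            phase <- runif(1, 0, 2 * pi)
            pl <- list(pts = rbind(center - len / 2 * u$u,
                                   center + len / 2 * u$u),
                       tang_theta = rep(u$theta, 2),
                       tang_phi = rep(u$phi, 2))
          }
          if (D < 1.5 && nd == 2L) {
            res <- place_bresenham(mask, inten, theta_t, thick_t, claim,
                                   pl, spec, forbid)
            if (is.list(res)) {
              mask <- res$mask; inten <- res$inten
              theta_t <- res$theta; thick_t <- res$thick
              claim <- res$claim
              placed <- TRUE
            }
          } else {
            placed <- cpp_place_polyline(mask, inten, theta_t, phi_t, thick_t,
                                         claim, dm, pl$pts, pl$tang_theta,
                                         if (nd == 3L) pl$tang_phi
                                         else numeric(length(pl$tang_theta)),
                                         D / 2, if (forbid) spec$gap else 0,
                                         spec$intensity_fg, spec$intensity_bg,
                                         forbid)
          }
          if (placed) break
        }
        if (!placed)
          stop(sprintf("could not place a diameter-%g fiber after %d tries",
                       D, spec$max_tries))
      }
    }
    if (spec$edge_profile == "flat") {
      inten <- array(ifelse(mask, spec$intensity_fg, spec$intensity_bg), dm)
    }
    if (spec$noise_sd > 0) {
      inten <- inten + array(stats::rnorm(n, 0, spec$noise_sd), dm)
    }
  })

  truth <- list(mask = mask, theta = theta_t,
                phi = if (nd == 3L) phi_t else NULL,
                thickness = thick_t)
  structure(list(image = image_stack(inten), truth = truth, spec = spec),
            class = "phantom")
}

polyline_2d <- function(spec, ang, center, len, phase) {
  a <- ang * pi / 180
  axis_dir <- c(cos(a), sin(a))
  perp_dir <- c(-sin(a), cos(a))
  if (spec$fiber_model == "curvy" && spec$curvature_amplitude > 0) {
    s <- seq(-len / 2, len / 2, by = 0.5)
    A <- spec$curvature_amplitude
    w <- 2 * pi / spec$curvature_period
    off <- A * sin(w * s + phase)
    slope <- A * w * cos(w * s + phase)
    pts <- cbind(center[1] + s * axis_dir[1] + off * perp_dir[1],
                 center[2] + s * axis_dir[2] + off * perp_dir[2])
    tang <- (ang + atan(slope) * 180 / pi) %% 180
    list(pts = pts, tang_theta = tang, tang_phi = rep(0, length(tang)))
  } else {
    pts <- rbind(center - len / 2 * axis_dir, center + len / 2 * axis_dir)
    list(pts = pts, tang_theta = rep(ang %% 180, 2), tang_phi = c(0, 0))
  }
}

random_axis3 <- function() {
  # uniform random axis: normal deviates normalized, sign-canonicalized so
  # (theta, phi) reconstructs the axis (y-component >= 0)
  v <- stats::rnorm(3)
  v <- v / sqrt(sum(v^2))
  if (v[2] < 0 || (v[2] == 0 && (v[1] < 0 || (v[1] == 0 && v[3] < 0))))
    v <- -v
  rxy <- sqrt(v[1]^2 + v[2]^2)
  theta <- if (rxy < 1e-12) 0 else (atan2(v[2], v[1]) * 180 / pi) %% 180
  phi <- acos(pmin(1, pmax(-1, v[3]))) * 180 / pi
  if (phi >= 180) phi <- phi - 180
  list(u = v, theta = theta, phi = phi)
}

place_bresenham <- function(mask, inten, theta_t, thick_t, claim, pl, spec,
                            forbid) {
  dm <- dim(mask)
  p0 <- round(pl$pts[1, ]); p1 <- round(pl$pts[2, ])
  cells <- bresenham(p0[1], p0[2], p1[1], p1[2])
  keep <- cells[, 1] >= 0 & cells[, 1] < dm[2] &
          cells[, 2] >= 0 & cells[, 2] < dm[1]
  cells <- cells[keep, , drop = FALSE]
  if (nrow(cells) == 0L) return(FALSE)
  ix <- cells[, 2] + 1L + cells[, 1] * dm[1]
  if (forbid) {
    g <- ceiling(spec$gap)
    for (dx in -g:g) for (dy in -g:g) {
      xx <- cells[, 1] + dx; yy <- cells[, 2] + dy
      ok <- xx >= 0 & xx < dm[2] & yy >= 0 & yy < dm[1]
      if (any(mask[yy[ok] + 1L + xx[ok] * dm[1]])) return(FALSE)
    }
  }
  mask[ix] <- TRUE
  inten[ix] <- pmax(inten[ix], spec$intensity_fg)
  upd <- claim[ix] > 0.5
  theta_t[ix[upd]] <- pl$tang_theta[1]
  thick_t[ix[upd]] <- 1
  claim[ix[upd]] <- 0.5
  list(mask = mask, inten = inten, theta = theta_t, thick = thick_t,
       claim = claim)
}

bresenham <- function(x0, y0, x1, y1) {
  dx <- abs(x1 - x0); dy <- abs(y1 - y0)
  sx <- if (x0 < x1) 1L else -1L
  sy <- if (y0 < y1) 1L else -1L
  err <- dx - dy
  out <- matrix(0L, dx + dy + 2L, 2L)
  i <- 0L
  repeat {
    i <- i + 1L
    out[i, ] <- c(x0, y0)
    if (x0 == x1 && y0 == y1) break
    e2 <- 2L * err
    if (e2 > -dy) { err <- err - dy; x0 <- x0 + sx }
    if (e2 < dx) { err <- err + dx; y0 <- y0 + sy }
  }
  out[seq_len(i), , drop = FALSE]
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> %s, %d fiber diameter(s): %s\n",
              paste(x$spec$dims, collapse = " x "),
              length(x$spec$diameters),
              paste(signif(sort(x$spec$diameters), 3), collapse = ", ")))
  cat(sprintf("  foreground: %d px (%.1f%%), model: %s, seed: %d\n",
              sum(x$truth$mask), 100 * mean(x$truth$mask),
              x$spec$fiber_model, x$spec$seed))
  invisible(x)
}

#' Write a phantom to disk
#'
#' Writes the rendered image, the ground-truth orientation and thickness
#' maps (32-bit float TIFF, degrees / pixels, NaN = background) and a
#' plain-text key/value sidecar recording the full generating spec.
#'
#' @param phantom a `phantom` from one of the generators.
#' @param dir output directory (created if missing).
#' @param prefix filename prefix.
#' @return The directory, invisibly.
#' @export
write_phantom <- function(phantom, dir, prefix = "phantom") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- function(s) file.path(dir, paste0(prefix, "_", s))
  write_stack(phantom$image, p("image.tif"), bits = 32L)
  th <- phantom$truth$theta; th[!phantom$truth$mask] <- NaN
  write_stack(th, p("theta_true.tif"), bits = 32L)
  if (!is.null(phantom$truth$phi)) {
    ph <- phantom$truth$phi; ph[!phantom$truth$mask] <- NaN
    write_stack(ph, p("phi_true.tif"), bits = 32L)
  }
  write_stack(phantom$truth$thickness, p("thickness_true.tif"), bits = 32L)
  s <- phantom$spec
  kv <- vapply(names(s), function(k)
    sprintf("%s = %s", k, paste(format(s[[k]], digits = 12), collapse = ", ")),
    character(1))
  writeLines(kv, p("spec.txt"))
  invisible(dir)
}
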