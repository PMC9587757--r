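#' Axial angular error
#'
#' Smallest rotation between two axial angles (period 180 degrees); always
#' in `[0, 90]`.
#'
#' @param a,b angles in degrees (vectorized).
#' @return error(s) in degrees.
#' @examples
#' angular_error_axial(179, 1)  # 2
#' angular_error_axial(0, 90)   # 90
#' @export
angular_error_axial <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}

#' 3D axis error
#'
#' Angle between two 3D axes given as (theta, phi) pairs in degrees:
#' `acos(|u_est . u_true|)`, in `[0, 90]`.
#'
#' @param theta_est,phi_est,theta_true,phi_true angles in degrees
#'   (vectorized).
#' @return error(s) in degrees.
#' @export
axis_error_3d <- function(theta_est, phi_est, theta_true, phi_true) {
  d2r <- pi / 180
  dot <- sin(phi_est * d2r) * sin(phi_true * d2r) *
           cos((theta_est - theta_true) * d2r) +
         cos(phi_est * d2r) * cos(phi_true * d2r)
  acos(pmin(1, abs(dot))) / d2r
}

#' Per-pixel error map against phantom truth
#'
#' @param field an `orientation_field`.
#' @param truth the `truth` element of a `phantom` (mask + theta
#'   and, in 3D, phi).
#' @param kind which error: `"theta"` (axial, 2D or 3D azimuth), `"phi"`
#'   (3D polar), or `"axis"` (3D angle between axes).
#' @return numeric array of errors in degrees on `truth$mask & field$valid`,
#'   NaN elsewhere, with attribute `n_valid` (pixels entering statistics)
#'   and `n_mask`.
#' @export
error_map <- function(field, truth, kind = c("theta", "phi", "axis")) {
  kind <- match.arg(kind)
  stopifnot(inherits(field, "orientation_field"))
  check_same_shape(field$theta, truth$mask, "field", "truth")
  sel <- truth$mask & field$valid
  if (!any(sel)) stop("no overlap between truth mask and valid estimates")
  e <- array(NA_real_, dim(field$theta))
  if (kind == "theta") {
    e[sel] <- angular_error_axial(field$theta[sel], truth$theta[sel])
  } else {
    if (is.null(field$phi) || is.null(truth$phi))
      stop(sprintf("kind \"%s\" needs 3D fields", kind))
    if (kind == "phi") {
      e[sel] <- angular_error_axial(field$phi[sel], truth$phi[sel])
    } else {
      e[sel] <- axis_error_3d(field$theta[sel], field$phi[sel],
                              truth$theta[sel], truth$phi[sel])
    }
  }
  structure(e, n_valid = sum(sel), n_mask = sum(truth$mask))
}

mean_errors <- function(field, truth, diams, kinds) {
  sel <- truth$mask & field$valid
  out <- list()
  for (kind in kinds) {
    e <- error_map(field, truth, kind)
    perD <- vapply(diams, function(D) {
      s <- sel & truth$thickness == D
      if (any(s)) mean(e[s]) else NA_real_
    }, 0)
    out[[kind]] <- list(pooled = mean(e[sel]),
                        balanced = mean(perD, na.rm = TRUE),
                        per_diameter = stats::setNames(perD, diams))
  }
  out
}

#' Compare adaptive and fixed analysis windows on phantoms
#'
#' Generates `n_images` phantoms (seeds `seed`, `seed + 1`, ...), runs the
#' thickness-adaptive ("wo") orientation estimator and the fixed-window
#' estimator at each requested window size, and reports mean angular errors
#' against ground truth.
#'
#' Two averages are reported for every method: `pooled` (all fiber pixels
#' weighted equally, so thick fibers dominate in proportion to their area)
#' and `balanced` (each fiber diameter class contributes equally). Errors
#' are averaged per image first, then across images.
#'
#' @param spec a [phantom_spec()]; its `seed` is replaced per image.
#' @param window_sizes odd fixed window sizes to test.
#' @param n_images number of phantom images.
#' @param seed base seed.
#' @param params an [orientation_params()] for the wo run (mode forced).
#' @param centers_per_image for 3D stacks, the number of randomly sampled
#'   foreground voxels per image at which orientation is evaluated
#'   (`Inf` = all; subsampling gives unbiased error means at a fraction of
#'   the cost).
#' @return A `comparison_report`: tibble of per-method/per-image errors
#'   plus attributes; see [tidy.comparison_report()].
#' @export
run_comparison <- function(spec, window_sizes = c(21L, 41L, 81L, 121L, 161L, 201L),
                           n_images = 4L, seed = spec$seed,
                           params = orientation_params(),
                           centers_per_image = Inf) {
  stopifnot(inherits(spec, "phantom_spec"))
  n_images <- as.integer(n_images)
  if (n_images < 1L) stop("`n_images` must be >= 1")
  nd <- length(spec$dims)
  kinds <- if (nd == 2L) "theta" else c("theta", "phi", "axis")
  rows <- list()

  for (im in seq_len(n_images)) {
    sp <- spec
    sp$seed <- as.integer(seed + im - 1L)
    ph <- if (nd == 2L) {
      if (sp$fiber_model == "curvy") generate_curvy_fibers_2d(sp)
      else generate_straight_fibers_2d(sp)
    } else generate_fibers_3d(sp)
    thick <- local_thickness(ph$truth$mask)
    centers <- NULL
    if (nd == 3L && is.finite(centers_per_image)) {
      idx <- which(ph$truth$mask)
      if (length(idx) > centers_per_image) {
        with_phantom_seed(sp$seed * 13L + 7L, {
          idx <- sort(sample(idx, centers_per_image))
        })
      }
      centers <- arrayInd(idx, dim(ph$truth$mask))
    }
    run_one <- function(p) {
      if (nd == 2L) orient2d(ph$image, ph$truth$mask, thick, p)
      else orient3d(ph$image, ph$truth$mask, thick, p, centers = centers)
    }
    methods <- c(list(wo = modifyList(params, list(mode = "wo", fixed_window = NULL))),
                 stats::setNames(lapply(window_sizes, function(w)
                   modifyList(params, list(mode = "fixed", fixed_window = as.integer(w)))),
                   paste0("fixed", window_sizes)))
    for (mn in names(methods)) {
      p <- methods[[mn]]
      class(p) <- "orientation_params"
      fld <- run_one(p)
      errs <- mean_errors(fld, ph$truth, sort(unique(spec$diameters)), kinds)
      for (kind in kinds) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          image = im, method = mn,
          window = if (mn == "wo") NA_integer_ else p$fixed_window,
          kind = kind,
          pooled_error = errs[[kind]]$pooled,
          balanced_error = errs[[kind]]$balanced,
          n_valid = attr(error_map(fld, ph$truth, kind), "n_valid"),
          n_mask = sum(ph$truth$mask))
      }
    }
  }
  out <- do.call(rbind, rows)
  structure(out, spec = spec, window_sizes = as.integer(window_sizes),
            n_images = n_images, seed = as.integer(seed),
            class = c("comparison_report", class(out)))
}

#' Summarize a comparison report per method
#'
#' @param x a `comparison_report` from [run_comparison()].
#' @param ... unused.
#' @return A tibble with per-method, per-angle-kind mean errors across
#'   images.
#' @method tidy comparison_report
#' @export
tidy.comparison_report <- function(x, ...) {
  df <- tibble::as_tibble(x)
  agg <- stats::aggregate(cbind(pooled_error, balanced_error) ~ method + kind,
                          df, mean)
  win <- vapply(agg$method, function(m)
    if (m == "wo") NA_integer_ else as.integer(sub("fixed", "", m)), 0L)
  out <- tibble::as_tibble(agg)
  out$window <- win
  out[order(out$kind, !is.na(out$window), out$window), ]
}

#' One-line summary of a comparison report
#'
#' @param x a `comparison_report`.
#' @param metric which error average to summarize.
#' @param ... unused.
#' @return A one-row tibble: wo error, best/median/worst fixed-window error
#'   and whether wo beats every fixed window (per angle kind, theta only
#'   for 2D).
#' @method glance comparison_report
#' @export
glance.comparison_report <- function(x, metric = c("balanced", "pooled"), ...) {
  metric <- match.arg(metric)
  td <- tidy.comparison_report(x)
  col <- paste0(metric, "_error")
  res <- lapply(split(td, td$kind), function(d) {
    wo <- d[[col]][d$method == "wo"]
    fx <- d[[col]][d$method != "wo"]
    tibble::tibble(kind = d$kind[1], wo_error = wo,
                   fixed_min = min(fx), fixed_median = stats::median(fx),
                   fixed_max = max(fx), wo_dominates = all(wo < fx))
  })
  do.call(rbind, res)
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report> %d image(s), %d fixed window(s), seed %d\n",
              attr(x, "n_images"), length(attr(x, "window_sizes")),
              attr(x, "seed")))
  print(glance.comparison_report(x))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
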