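# Independent brute-force oracles used across tests. These deliberately
# reimplement the definitions naively (double loops over pixels) so that the
# package's accelerated implementations are checked against first
# principles, not against themselves.

# exact distance to nearest background pixel centre; border treated as
# requested
brute_edt <- function(mask, border = c("background", "ignore")) {
  border <- match.arg(border)
  dm <- dim(mask)
  nd <- length(dm)
  idx_all <- arrayInd(seq_along(mask), dm)
  bg <- idx_all[!as.vector(mask), , drop = FALSE]
  out <- array(0, dm)
  fg_lin <- which(as.vector(mask))
  for (i in fg_lin) {
    p <- idx_all[i, ]
    d2 <- if (nrow(bg) > 0)
      min(colSums((t(bg) - p)^2)) else Inf
    if (border == "background") {
      # nearest out-of-image pixel centre along each axis
      db <- min(c(p, dm - p + 1))
      d2 <- min(d2, db^2)
    }
    out[i] <- sqrt(d2)
  }
  out
}

# brute-force local thickness on the refined, mirror-padded grid: for every
# fine pixel the max over all covering inscribed discs of 2 * EDT, then
# block-max back and crop
brute_local_thickness <- function(mask, refine = 2L) {
  dm0 <- dim(mask)
  nd <- length(dm0)
  e0 <- brute_edt(mask, "ignore")
  margin <- min(as.integer(ceiling(max(e0[is.finite(e0)]))) + 2L,
                as.integer(min(dm0)))
  refl <- function(n) c(rev(seq_len(margin)), seq_len(n),
                        n + 1L - seq_len(margin))
  idx <- lapply(dm0, refl)
  mask <- do.call(`[`, c(list(mask), idx, list(drop = FALSE)))
  dim(mask) <- dm0 + 2L * margin
  dm <- dim(mask)
  fdm <- dm * refine
  # upsample
  if (nd == 2L) {
    mu <- mask[rep(seq_len(dm[1]), each = refine),
               rep(seq_len(dm[2]), each = refine)]
  } else {
    mu <- mask[rep(seq_len(dm[1]), each = refine),
               rep(seq_len(dm[2]), each = refine),
               rep(seq_len(dm[3]), each = refine)]
  }
  e <- brute_edt(mu, border = "ignore")
  idx <- arrayInd(seq_along(mu), fdm)
  th <- array(0, fdm)
  fg <- which(as.vector(mu))
  for (m in fg) {
    d <- e[m]
    if (d <= 0 || !is.finite(d)) next
    cov <- which(colSums((t(idx) - idx[m, ])^2) <= d^2 + 1e-9)
    v <- 2 * d
    th[cov] <- pmax(th[cov], v)
  }
  th[!mu] <- 0
  # block max
  out <- array(0, dm)
  for (i in seq_along(out)) {
    p <- arrayInd(i, dm)
    rng <- lapply(seq_len(nd), function(k)
      ((p[k] - 1) * refine + 1):(p[k] * refine))
    blk <- do.call(`[`, c(list(th), rng))
    out[i] <- max(blk) / refine
  }
  out[!mask] <- 0
  crop <- lapply(dm0, function(n) seq_len(n) + margin)
  out <- do.call(`[`, c(list(out), crop, list(drop = FALSE)))
  dim(out) <- dm0
  out
}

# naive 2D weighted vector summation (mirrors the documented estimator)
brute_orient2d <- function(img, mask, win, expo = 1, circular = TRUE,
                           min_nb = 4L) {
  dm <- dim(mask)
  th <- array(NA_real_, dm)
  for (x in seq_len(dm[2])) for (y in seq_len(dm[1])) {
    if (!mask[y, x]) next
    r <- win[y, x] %/% 2
    cs <- 0; sn <- 0; n <- 0
    for (xx in max(1, x - r):min(dm[2], x + r)) {
      for (yy in max(1, y - r):min(dm[1], y + r)) {
        if (xx == x && yy == y) next
        if (!mask[yy, xx]) next
        dx <- xx - x; dy <- yy - y
        r2 <- dx^2 + dy^2
        if (circular && r2 > r^2) next
        w <- img[yy, xx] * r2^(-expo / 2)
        cs <- cs + w * (dx^2 - dy^2) / r2
        sn <- sn + w * (2 * dx * dy) / r2
        n <- n + 1L
      }
    }
    if (n >= min_nb) th[y, x] <- (0.5 * atan2(sn, cs) * 180 / pi) %% 180
  }
  th
}

# axis-aligned band mask helpers
band_mask <- function(nrow_, ncol_, rows) {
  m <- matrix(FALSE, nrow_, ncol_)
  m[rows, ] <- TRUE
  m
}

random_blob_mask <- function(ny, nx, p = 0.4, seed = 1) {
  set.seed(seed)
  matrix(runif(ny * nx) < p, ny, nx)
}

# value after a float32 storage round trip
float32_round <- function(x) {
  v <- as.vector(x)
  out <- vapply(v, function(z) {
    readBin(writeBin(as.numeric(z), raw(), size = 4), "numeric", size = 4)
  }, 0)
  array(out, dim(x))
}

# 8-connected component labelling (breadth-first)
label_components <- function(mask) {
  dm <- dim(mask)
  lab <- array(0L, dm)
  nxt <- 0L
  for (start in which(as.vector(mask) & lab == 0L)) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue)) {
      cur <- queue[[1]]
      queue <- queue[-1]
      p <- arrayInd(cur, dm)
      for (dy in -1:1) for (dx in -1:1) {
        yy <- p[1] + dy; xx <- p[2] + dx
        if (yy < 1 || yy > dm[1] || xx < 1 || xx > dm[2]) next
        q <- yy + (xx - 1L) * dm[1]
        if (mask[q] && lab[q] == 0L) {
          lab[q] <- nxt
          queue <- c(queue, q)
        }
      }
    }
  }
  lab
}
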