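# Shared fixtures and independent oracles, all built in code.

rand_mask <- function(h, w, p = 0.3) {
  matrix(rbinom(h * w, 1L, p), h, w)
}

# brute-force first-order moment (double loop), independent of the package
cog2d_oracle <- function(m) {
  si <- 0; sj <- 0; s <- 0
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    si <- si + i * m[i, j]; sj <- sj + j * m[i, j]; s <- s + m[i, j]
  }
  c(si / s, sj / s)
}

cog3d_oracle <- function(a) {
  d <- dim(a); si <- 0; sj <- 0; s <- 0
  for (k in seq_len(d[1])) for (i in seq_len(d[2])) for (j in seq_len(d[3])) {
    si <- si + i * a[k, i, j]; sj <- sj + j * a[k, i, j]
    s <- s + a[k, i, j]
  }
  c(si / s, sj / s)
}

# all-pairs signed distance oracle: boundary = foreground pixels with a
# 4-neighbor background pixel or on the image border
sdf_oracle <- function(m) {
  h <- nrow(m); w <- ncol(m)
  bnd <- NULL
  for (i in seq_len(h)) for (j in seq_len(w)) {
    if (m[i, j] == 1) {
      nb <- c(if (i > 1) m[i - 1, j] else 0L,
              if (i < h) m[i + 1, j] else 0L,
              if (j > 1) m[i, j - 1] else 0L,
              if (j < w) m[i, j + 1] else 0L)
      if (any(nb == 0L)) bnd <- rbind(bnd, c(i, j))
    }
  }
  if (is.null(bnd)) return(matrix(sqrt(h^2 + w^2), h, w))
  out <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    d <- sqrt(min((bnd[, 1] - i)^2 + (bnd[, 2] - j)^2))
    out[i, j] <- if (m[i, j] == 1) -d else d
  }
  out
}

# recursive-free flood fill component census (8-connectivity)
flood_components <- function(m) {
  h <- nrow(m); w <- ncol(m)
  lab <- matrix(0L, h, w); cur <- 0L
  for (j0 in seq_len(w)) for (i0 in seq_len(h)) {
    if (m[i0, j0] == 1L && lab[i0, j0] == 0L) {
      cur <- cur + 1L
      stack <- list(c(i0, j0)); lab[i0, j0] <- cur
      while (length(stack)) {
        p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
        for (di in -1:1) for (dj in -1:1) {
          ii <- p[1] + di; jj <- p[2] + dj
          if (ii >= 1 && ii <= h && jj >= 1 && jj <= w &&
              m[ii, jj] == 1L && lab[ii, jj] == 0L) {
            lab[ii, jj] <- cur
            stack[[length(stack) + 1L]] <- c(ii, jj)
          }
        }
      }
    }
  }
  lab
}

# elementwise cross-entropy / dice oracles over flattened maps
ce_oracle <- function(labels, p) {
  C <- dim(p)[1]
  pm <- matrix(p, nrow = C)
  lv <- as.integer(labels)
  tot <- 0
  for (n in seq_along(lv)) {
    pc <- min(max(pm[lv[n] + 1L, n], 1e-7), 1 - 1e-7)
    tot <- tot - log(pc)
  }
  tot / length(lv)
}

dice_loss_oracle <- function(labels, p) {
  C <- dim(p)[1]
  pm <- matrix(p, nrow = C)
  lv <- as.integer(labels)
  acc <- 0
  for (cc in 1:(C - 1)) {
    yc <- as.numeric(lv == cc)
    acc <- acc + 2 * sum(pm[cc + 1, ] * yc) /
      (sum(pm[cc + 1, ]) + sum(yc) + 1e-6)
  }
  1 - acc / (C - 1)
}

rand_cmap <- function(C, ...) {
  d <- c(C, ...)
  x <- array(stats::rexp(prod(d)), dim = d)
  tot <- apply(x, seq_along(d)[-1], sum)
  for (cc in seq_len(C)) {
    if (length(d) == 3L) x[cc, , ] <- x[cc, , ] / tot
    else x[cc, , , ] <- x[cc, , , ] / tot
  }
  x
}

# tiny phantom used across pipeline tests
tiny_phantom <- function(seed = 1L, depth = 12L, side = 32L, ...) {
  generate_phantom(phantom_config(
    depth = depth, height = side, width = side,
    lumen_radius_range = c(side / 12, side / 9),
    wall_thickness_range = c(1, side / 20),
    label_fraction = 0.25, seed = seed, ...))
}

# independent per-slice metric oracle used against evaluate_case
slice_metrics_oracle <- function(pred, truth) {
  area <- function(m) sum(m)
  contour_pts <- function(m) {
    h <- nrow(m); w <- ncol(m); pts <- NULL
    for (i in seq_len(h)) for (j in seq_len(w)) {
      if (m[i, j]) {
        edge <- FALSE
        for (di in -1:1) for (dj in -1:1) {
          ii <- i + di; jj <- j + dj
          if (ii < 1 || ii > h || jj < 1 || jj > w || !m[ii, jj])
            edge <- TRUE
        }
        if (edge) pts <- rbind(pts, c(i, j))
      }
    }
    pts
  }
  hd <- function(b, c) {
    h1 <- max(apply(b, 1, function(p)
      sqrt(min((c[, 1] - p[1])^2 + (c[, 2] - p[2])^2))))
    h2 <- max(apply(c, 1, function(p)
      sqrt(min((b[, 1] - p[1])^2 + (b[, 2] - p[2])^2))))
    max(h1, h2)
  }
  dsc <- function(x, y) if (sum(x) + sum(y) == 0) 1
    else 2 * sum(x & y) / (sum(x) + sum(y))
  pl <- pred == 1; po <- pred >= 1; pw <- pred == 2
  tl <- truth == 1; to <- truth >= 1; tw <- truth == 2
  lad <- abs(area(pl) - area(tl)) / area(tl)
  wad <- abs(area(po) - area(to)) / area(to)
  nw <- if (area(pl) > 0 && area(po) > area(pl)) {
    xi <- (area(po) - area(pl)) / area(pl)
    yi <- (area(to) - area(tl)) / area(tl)
    abs(xi - yi) / yi
  } else 2
  hdol <- if (area(pl) > 0)
    hd(contour_pts(pl), contour_pts(tl)) / sqrt(area(pl) / pi) else 2
  hdow <- if (area(po) > 0)
    hd(contour_pts(po), contour_pts(to)) / sqrt(area(po) / pi) else 2
  f <- function(x) max(0, 1 - x)
  d <- dsc(pw, tw)
  c(DSC = d, DSCL = dsc(pl, tl), DSCW = dsc(po, to), Lad = lad,
    Wad = wad, Nwid = nw, Hdol = hdol, Hdow = hdow,
    QS = 0.5 * d + 0.1 * (f(lad) + f(wad)) + 0.2 * f(nw) +
      0.05 * (f(hdol) + f(hdow)))
}
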