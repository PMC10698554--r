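#' Dice similarity coefficient
#'
#' `DSC = 2|X n Y| / (|X| + |Y|)`; two empty masks are defined to agree
#' perfectly (`DSC = 1`).
#'
#' @param x,y binary masks of equal shape.
#' @return scalar in \[0, 1\].
#' @export
dice <- function(x, y) {
  x <- as_binary_mask(x, "x"); y <- as_binary_mask(y, "y")
  if (length(x) != length(y))
    stop("shape mismatch between x and y", call. = FALSE)
  sx <- sum(x); sy <- sum(y)
  if (sx + sy == 0) return(1)
  2 * sum(x * y) / (sx + sy)
}

#' Relative area difference
#'
#' `|x_area - y_area| / y_area`, the lumen (Lad) and outer-wall (Wad) area
#' error relative to the ground truth.
#'
#' @param x_area predicted area (pixels).
#' @param y_area ground-truth area (pixels), must be positive.
#' @return scalar `>= 0`.
#' @export
area_difference <- function(x_area, y_area) {
  if (y_area <= 0) stop("empty ground truth", call. = FALSE)
  abs(x_area - y_area) / y_area
}

#' Normalized wall index difference
#'
#' The normalized wall index of a side is its wall area divided by its
#' lumen area, `(AW - AL) / AL`; Nwid is the relative difference between
#' the predicted and ground-truth indices:
#' `|(X_AW - X_AL)/X_AL - (Y_AW - Y_AL)/Y_AL| / ((Y_AW - Y_AL)/Y_AL)`.
#'
#' @param x_al,x_aw predicted lumen and outer-wall areas (`x_al > 0`).
#' @param y_al,y_aw ground-truth areas (`y_al > 0`, `y_aw > y_al`).
#' @return scalar `>= 0`, zero iff the indices agree.
#' @export
nwid <- function(x_al, x_aw, y_al, y_aw) {
  if (x_al <= 0 || y_al <= 0) stop("empty lumen area", call. = FALSE)
  if (y_aw <= y_al) stop("degenerate ground truth: y_aw <= y_al",
                         call. = FALSE)
  xi <- (x_aw - x_al) / x_al
  yi <- (y_aw - y_al) / y_al
  abs(xi - yi) / yi
}

#' Extract boundary pixel centers of a mask
#'
#' The contour is the set of foreground pixels having an 8-neighbor in the
#' background (or lying on the image border), returned as an `n x 2` matrix
#' of `(row, col)` coordinates.
#'
#' @param mask binary 2D matrix.
#' @return integer matrix of contour points (0 rows when the mask is
#'   empty).
#' @export
extract_contour <- function(mask) {
  m <- as_binary_mask(mask)
  h <- nrow(m); w <- ncol(m)
  if (sum(m) == 0) return(matrix(integer(0), 0, 2))
  pad <- matrix(0L, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- m
  inner <- matrix(TRUE, h, w)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    inner <- inner & pad[(2 + di):(h + 1 + di), (2 + dj):(w + 1 + dj)] == 1L
  }
  which(m == 1L & !inner, arr.ind = TRUE)
}

directed_hausdorff <- function(b, c) {
  # max over b of min distance to c
  max(vapply(seq_len(nrow(b)), function(i) {
    sqrt(min((c[, 1] - b[i, 1])^2 + (c[, 2] - b[i, 2])^2))
  }, numeric(1)))
}

#' Radius-normalized symmetric Hausdorff distance
#'
#' `max(h(B, C), h(C, B)) / sqrt(ref_area / pi)` where
#' `h(B, C) = max_b min_c ||b - c||`; the normaliser is the
#' equivalent-circle radius of the predicted region area.
#'
#' @param b,c point sets as `n x 2` matrices (both nonempty).
#' @param ref_area reference area in pixels (positive).
#' @return scalar `>= 0`.
#' @export
hausdorff_normalized <- function(b, c, ref_area) {
  b <- as.matrix(b); c <- as.matrix(c)
  if (nrow(b) == 0 || nrow(c) == 0)
    stop("empty contour point set", call. = FALSE)
  if (ref_area <= 0) stop("ref_area must be positive", call. = FALSE)
  max(directed_hausdorff(b, c), directed_hausdorff(c, b)) /
    sqrt(ref_area / pi)
}

#' Composite quantitative segmentation score
#'
#' `QS = 0.5 DSC + 0.1 (f(Lad) + f(Wad)) + 0.2 f(Nwid) +
#' 0.05 (f(Hdol) + f(Hdow))` with `f(x) = max(0, 1 - x)`; a perfect
#' segmentation scores 1.
#'
#' @param dsc wall-region Dice coefficient.
#' @param lad,wad,nwid,hdol,hdow the five error indicators.
#' @return scalar in \[0, 1\].
#' @export
quantitative_score <- function(dsc, lad, wad, nwid, hdol, hdow) {
  f <- function(x) pmax(0, 1 - x)
  0.5 * dsc + 0.1 * (f(lad) + f(wad)) + 0.2 * f(nwid) +
    0.05 * (f(hdol) + f(hdow))
}

# metrics for a single slice given 3-class prediction and truth matrices
slice_metrics <- function(pred_cls, true_cls) {
  px_l <- pred_cls == 1L; px_w <- pred_cls == 2L; px_o <- pred_cls >= 1L
  ty_l <- true_cls == 1L; ty_w <- true_cls == 2L; ty_o <- true_cls >= 1L
  worst <- 2  # f-clamped sentinel for degenerate predictions
  x_al <- sum(px_l); x_aw <- sum(px_o)
  y_al <- sum(ty_l); y_aw <- sum(ty_o)
  lad <- area_difference(x_al, y_al)
  wad <- area_difference(x_aw, y_aw)
  nw <- if (x_al > 0 && x_aw > x_al) nwid(x_al, x_aw, y_al, y_aw) else worst
  hdol <- if (x_al > 0) {
    hausdorff_normalized(extract_contour(matrix(px_l, nrow(pred_cls))),
                         extract_contour(matrix(ty_l, nrow(true_cls))),
                         x_al)
  } else worst
  hdow <- if (x_aw > 0) {
    hausdorff_normalized(extract_contour(matrix(px_o, nrow(pred_cls))),
                         extract_contour(matrix(ty_o, nrow(true_cls))),
                         x_aw)
  } else worst
  dsc <- dice(px_w, ty_w)
  data.frame(DSC = dsc,
             DSCL = dice(px_l, ty_l),
             DSCW = dice(px_o, ty_o),
             Lad = lad, Wad = wad, Nwid = nw, Hdol = hdol, Hdow = hdow,
             QS = quantitative_score(dsc, lad, wad, nw, hdol, hdow))
}

#' Evaluate a predicted label volume against ground truth
#'
#' Computes per-slice metrics on the evaluable slices and averages them
#' (unweighted): `DSC` on the wall region (class 2), `DSCL` on the lumen
#' (class 1), `DSCW` on the outer wall (classes 1 and 2), the area
#' differences `Lad`/`Wad`, the normalized wall index difference `Nwid`,
#' radius-normalized Hausdorff distances `Hdol`/`Hdow` on the lumen and
#' outer-wall contours, and the composite `QS`. Slices where the
#' prediction is degenerate (no lumen or no wall) score `DSC = 0` for the
#' missing region and a clamped worst-case value 2 for the affected
#' distance/index terms (so their `f(.)` contribution to QS is 0).
#'
#' @param pred predicted [new_label_volume()] (or `D x H x W` class array).
#' @param truth ground-truth [new_label_volume()].
#' @param slices slice indices to evaluate; default the truth's
#'   `labeled_slices`.
#' @return list of class `jcps_metrics` with the averaged fields and a
#'   `per_slice` data frame.
#' @export
evaluate_case <- function(pred, truth, slices = NULL) {
  pc <- if (inherits(pred, "jcps_labels")) pred$classes else pred
  stopifnot(inherits(truth, "jcps_labels"))
  tc <- truth$classes
  if (!all(dim(pc) == dim(tc)))
    stop("prediction and truth shapes differ", call. = FALSE)
  if (is.null(slices)) slices <- truth$labeled_slices
  slices <- as.integer(slices)
  if (length(slices) == 0L) stop("no evaluable slices", call. = FALSE)
  rows <- do.call(rbind, lapply(slices, function(k)
    cbind(slice = k, slice_metrics(pc[k, , ], tc[k, , ]))))
  avg <- colMeans(rows[, -1, drop = FALSE])
  structure(c(as.list(avg), list(per_slice = rows)),
            class = "jcps_metrics")
}

#' @export
print.jcps_metrics <- function(x, ...) {
  cat("Vessel-wall segmentation metrics (mean over",
      nrow(x$per_slice), "slices):\n")
  v <- unlist(x[c("DSC", "DSCL", "DSCW", "Lad", "Wad", "Nwid",
                  "Hdol", "Hdow", "QS")])
  print(round(v, 4))
  invisible(x)
}
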