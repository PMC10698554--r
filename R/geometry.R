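#' @useDynLib jcps, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

as_binary_mask <- function(mask, arg = "mask") {
  if (is.logical(mask)) return(array(as.integer(mask), dim = dim(mask)))
  if (!all(mask %in% c(0, 1)))
    stop(sprintf("'%s' must be binary (0/1 or logical)", arg), call. = FALSE)
  array(as.integer(mask), dim = dim(mask))
}

#' Center of gravity of a 2D binary mask
#'
#' First-order moment of the mask: the mean (row, col) coordinate of the
#' foreground pixels, used to localise the vessel lumen for patch cropping.
#'
#' @param mask binary `H x W` matrix (0/1 or logical).
#' @return list with `coords` (numeric `(i, j)`, 1-based pixel units) and
#'   `valid` (`FALSE` for an empty mask, in which case `coords` is `NA`).
#' @export
center_of_gravity_2d <- function(mask) {
  m <- as_binary_mask(mask)
  stopifnot(length(dim(m)) == 2L)
  s <- sum(m)
  if (s == 0) return(list(coords = c(NA_real_, NA_real_), valid = FALSE))
  rows <- row(m); cols <- col(m)
  list(coords = c(sum(rows * m) / s, sum(cols * m) / s), valid = TRUE)
}

#' In-plane center of gravity of a 3D mask chunk
#'
#' Pools the first-order moment over all slices of a depth-`d` chunk; only
#' the in-plane `(i, j)` coordinates are returned since the chunk fixes the
#' slice range.
#'
#' @param chunk binary `d x H x W` array.
#' @return list with `coords` (`(i, j)`) and `valid`.
#' @export
center_of_gravity_3d <- function(chunk) {
  m <- as_binary_mask(chunk, "chunk")
  stopifnot(length(dim(m)) == 3L)
  s <- sum(m)
  if (s == 0) return(list(coords = c(NA_real_, NA_real_), valid = FALSE))
  d <- dim(m)
  idx <- which(m == 1L, arr.ind = TRUE)
  list(coords = c(sum(idx[, 2]) / s, sum(idx[, 3]) / s), valid = TRUE)
}

#' Signed Euclidean distance map of a 2D mask
#'
#' The boundary is the set of foreground pixels having a 4-neighbor in the
#' background (image-border foreground pixels count as boundary). The value
#' at each pixel is the exact Euclidean distance between pixel centers to
#' the nearest boundary pixel, negative inside the region, zero on the
#' boundary, positive outside. An all-background mask yields the image
#' diagonal everywhere (no boundary exists).
#'
#' @param mask binary `H x W` matrix.
#' @return numeric `H x W` matrix of signed distances in pixel units.
#' @export
signed_distance_map <- function(mask) {
  m <- as_binary_mask(mask)
  stopifnot(length(dim(m)) == 2L)
  h <- nrow(m); w <- ncol(m)
  if (sum(m) == 0) return(matrix(sqrt(h^2 + w^2), h, w))
  pad <- matrix(0L, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- m
  inner <- pad[2:(h + 1), 1:w] & pad[2:(h + 1), 3:(w + 2)] &
    pad[1:h, 2:(w + 1)] & pad[3:(h + 2), 2:(w + 1)]
  boundary <- m == 1L & !inner
  d <- sqrt(edt_sq_cpp(matrix(as.integer(boundary), h, w)))
  d * ifelse(m == 1L, -1, 1)
}

round_half_up <- function(x) floor(x + 0.5)

#' Crop a fixed-size patch around a centroid
#'
#' The window is centered at the rounded centroid and shifted (never
#' zero-padded) so that it lies fully inside the image; the returned spec
#' records the origin so the patch can be pasted back.
#'
#' @param image 2D matrix.
#' @param center a centroid as returned by [center_of_gravity_2d()], or a
#'   numeric `(i, j)` pair.
#' @param size integer `(h, w)` patch size.
#' @return list with `patch` (`h x w` matrix) and `spec` (list with
#'   `origin`, `size`, `source_shape`).
#' @export
crop_patch_2d <- function(image, center, size) {
  stopifnot(length(dim(image)) == 2L, length(size) == 2L)
  if (is.list(center)) {
    if (!isTRUE(center$valid)) stop("center is not valid", call. = FALSE)
    center <- center$coords
  }
  size <- as.integer(size)
  dims <- dim(image)
  if (any(size > dims))
    stop("patch size exceeds image dimensions", call. = FALSE)
  origin <- round_half_up(center) - floor(size / 2)
  origin <- pmin(pmax(origin, 1L), dims - size + 1L)
  patch <- image[origin[1]:(origin[1] + size[1] - 1L),
                 origin[2]:(origin[2] + size[2] - 1L), drop = FALSE]
  list(patch = patch,
       spec = list(origin = as.integer(origin), size = size,
                   source_shape = dims))
}

#' Paste a patch back at its recorded origin
#'
#' Inverse of [crop_patch_2d()]: writes the patch into `canvas` at
#' `spec$origin`.
#'
#' @param canvas 2D matrix of the original shape.
#' @param patch the patch matrix.
#' @param spec the `spec` returned by [crop_patch_2d()].
#' @return the modified canvas.
#' @export
paste_patch_2d <- function(canvas, patch, spec) {
  o <- spec$origin; s <- spec$size
  stopifnot(all(dim(canvas) == spec$source_shape), all(dim(patch) == s))
  canvas[o[1]:(o[1] + s[1] - 1L), o[2]:(o[2] + s[2] - 1L)] <- patch
  canvas
}

#' Split a volume into overlapping depth chunks
#'
#' Chunks of `depth` slices start at stride `depth - overlap`; the final
#' chunk is shifted back so its last slice is the last slice of the volume,
#' so the chunk ranges cover every slice.
#'
#' @param volume a [new_volume()] or a `D x H x W` (or `C x D x H x W`)
#'   array; chunking is along the slice axis.
#' @param depth chunk depth `d`.
#' @param overlap number of shared slices between consecutive chunks,
#'   `0 <= overlap < depth`.
#' @return list of elements, each a list with `chunk` (the sub-array) and
#'   `spec` (list with `origin` = first slice index, `size` = depth,
#'   `source_depth`).
#' @export
chunk_volume <- function(volume, depth, overlap = depth %/% 2) {
  x <- if (inherits(volume, "jcps_volume")) volume$intensities else volume
  nd <- length(dim(x))
  stopifnot(nd %in% c(3L, 4L))
  slice_axis <- if (nd == 3L) 1L else 2L
  D <- dim(x)[slice_axis]
  depth <- as.integer(depth); overlap <- as.integer(overlap)
  if (!(overlap >= 0L && overlap < depth && depth <= D))
    stop("need 0 <= overlap < depth <= D", call. = FALSE)
  stride <- depth - overlap
  starts <- seq.int(1L, D - depth + 1L, by = stride)
  if (starts[length(starts)] != D - depth + 1L)
    starts <- c(starts, D - depth + 1L)
  lapply(starts, function(s) {
    sl <- s:(s + depth - 1L)
    chunk <- if (nd == 3L) x[sl, , , drop = FALSE]
      else x[, sl, , , drop = FALSE]
    list(chunk = chunk,
         spec = list(origin = as.integer(s), size = depth, source_depth = D))
  })
}

#' Stitch chunked probability maps back into a volume
#'
#' Overlapping slices receive the arithmetic mean of all contributing
#' probabilities, then channels are renormalised to the simplex; slices
#' covered once are copied unchanged.
#'
#' @param pieces list of lists with `map` (`C x d x h x w` probability
#'   array) and `spec` (from [chunk_volume()]).
#' @param out_shape integer `(C, D, h, w)`.
#' @param fusion `"mean"` (default) or `"max"` over overlapping
#'   contributions.
#' @return `C x D x h x w` probability array.
#' @export
stitch_predictions <- function(pieces, out_shape, fusion = c("mean", "max")) {
  fusion <- match.arg(fusion)
  acc <- array(if (fusion == "mean") 0 else -Inf, dim = out_shape)
  cnt <- integer(out_shape[2])
  for (p in pieces) {
    o <- p$spec$origin; d <- p$spec$size
    stopifnot(all(dim(p$map)[c(1, 3, 4)] == out_shape[c(1, 3, 4)]),
              dim(p$map)[2] == d, o >= 1, o + d - 1 <= out_shape[2])
    sl <- o:(o + d - 1L)
    if (fusion == "mean") acc[, sl, , ] <- acc[, sl, , ] + p$map
    else acc[, sl, , ] <- pmax(acc[, sl, , ], p$map)
    cnt[sl] <- cnt[sl] + 1L
  }
  if (any(cnt == 0L))
    stop("uncovered slices: ", paste(which(cnt == 0L), collapse = ", "),
         call. = FALSE)
  if (fusion == "mean")
    for (k in seq_len(out_shape[2])) acc[, k, , ] <- acc[, k, , ] / cnt[k]
  # renormalise to the simplex
  tot <- apply(acc, c(2, 3, 4), sum)
  for (c in seq_len(out_shape[1])) acc[c, , , ] <- acc[c, , , ] / tot
  acc
}

#' Keep only the largest connected component
#'
#' 8-connectivity in 2D, 26-connectivity in 3D. Ties are broken in favour of
#' the component first encountered in scan order. An empty mask is returned
#' unchanged.
#'
#' @param mask binary 2D matrix or 3D array.
#' @return binary mask of the same shape.
#' @export
largest_connected_component <- function(mask) {
  m <- as_binary_mask(mask)
  if (sum(m) == 0) return(m)
  if (length(dim(m)) == 2L) {
    lab <- label2d_cpp(m)
  } else if (length(dim(m)) == 3L) {
    d <- dim(m)
    lab <- array(label3d_cpp(as.integer(m), d[1], d[2], d[3]), dim = d)
  } else stop("mask must be 2D or 3D", call. = FALSE)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which.max(sizes)
  array(as.integer(lab == keep), dim = dim(m))
}

as_track_matrix <- function(centroids) {
  if (is.matrix(centroids)) return(centroids)
  t(vapply(centroids, function(c) {
    if (isTRUE(c$valid)) as.numeric(c$coords) else c(NA_real_, NA_real_)
  }, numeric(2)))
}

#' Repair a per-slice centroid track
#'
#' Exploits the spatial continuity of the vessel: slices where no lumen was
#' found (e.g. extreme stenosis) are filled by linear interpolation between
#' the nearest located neighbors (constant extrapolation at the stack ends),
#' and entries that jump away from the interpolation of their neighbors by
#' more than `tau` pixels (e.g. the centroid landing on the external branch
#' at a bifurcation) are replaced by that interpolation. The repair is
#' idempotent.
#'
#' @param centroids a `D x 2` matrix of `(i, j)` coordinates with `NA` rows
#'   for missing entries, or a list of centroids from
#'   [center_of_gravity_2d()].
#' @param tau outlier threshold in pixels; the default 24 keeps a vessel of
#'   diameter below 64 px inside a 96 px patch.
#' @return `D x 2` matrix with no missing entries.
#' @export
repair_centroid_track <- function(centroids, tau = 24) {
  x <- as_track_matrix(centroids)
  d <- nrow(x)
  valid <- stats::complete.cases(x)
  if (!any(valid)) stop("no vessel located", call. = FALSE)
  # fill missing entries by linear interpolation over slice index
  vi <- which(valid)
  for (col in 1:2)
    x[, col] <- stats::approx(vi, x[vi, col], xout = seq_len(d),
                              rule = 2)$y
  if (d <= 2) return(x)
  # greedy outlier replacement: repeatedly fix the worst deviation
  neighbor_pred <- function(x, k) {
    if (k == 1L) x[2, ] else if (k == d) x[d - 1L, ]
    else (x[k - 1L, ] + x[k + 1L, ]) / 2
  }
  for (iter in seq_len(d)) {
    dev <- vapply(seq_len(d),
                  function(k) sqrt(sum((x[k, ] - neighbor_pred(x, k))^2)),
                  numeric(1))
    worst <- which.max(dev)
    if (dev[worst] <= tau) break
    x[worst, ] <- neighbor_pred(x, worst)
  }
  x
}
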