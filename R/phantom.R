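#' Configuration for the synthetic black-blood vessel phantom
#'
#' Builds a validated configuration for [generate_phantom()]. The phantom
#' emulates the appearance of an axial black-blood carotid MR stack: a dark
#' lumen (blood signal suppressed) surrounded by a brighter vessel-wall
#' annulus, embedded in mid-gray noisy background. Optional features
#' reproduce the two classic failure zones of coarse vessel localisation:
#' a bifurcation (a second diverging branch appears in the image but is not
#' part of the target-vessel labels) and a stenosis (the lumen radius is
#' scaled down over a slice interval).
#'
#' @param depth,height,width volume dimensions (slices, rows, cols).
#' @param lumen_radius_range length-2 numeric, min/max lumen radius in pixels.
#' @param wall_thickness_range length-2 numeric, min/max wall thickness (px).
#' @param centerline_wobble std-dev (px) of the smooth per-slice centerline
#'   drift.
#' @param bifurcation logical; draw a second diverging branch.
#' @param bifurcation_start first slice (1-based) of the bifurcation; default
#'   two thirds of the stack.
#' @param stenosis logical; scale the lumen radius down over
#'   `stenosis_slices`.
#' @param stenosis_slices integer slice interval (1-based, inclusive).
#' @param stenosis_scale radius scale factor in (0, 1].
#' @param intensity_lumen,intensity_wall,intensity_background mean gray
#'   levels in \[0, 1\].
#' @param noise_sigma std-dev of additive Gaussian noise.
#' @param label_fraction fraction of slices carrying labels, in (0, 1].
#' @param seed integer RNG seed.
#' @return an object of class `phantom_config`.
#' @export
phantom_config <- function(depth = 40L, height = 64L, width = 64L,
                           lumen_radius_range = c(5, 8),
                           wall_thickness_range = c(2, 4),
                           centerline_wobble = 0.5,
                           bifurcation = FALSE, bifurcation_start = NULL,
                           stenosis = FALSE, stenosis_slices = NULL,
                           stenosis_scale = 0.5,
                           intensity_lumen = 0.15, intensity_wall = 0.7,
                           intensity_background = 0.35,
                           noise_sigma = 0.15,
                           label_fraction = 0.2, seed = 1L) {
  cfg <- list(
    depth = as.integer(depth), height = as.integer(height),
    width = as.integer(width),
    lumen_radius_range = as.numeric(lumen_radius_range),
    wall_thickness_range = as.numeric(wall_thickness_range),
    centerline_wobble = centerline_wobble,
    bifurcation = isTRUE(bifurcation),
    bifurcation_start = if (is.null(bifurcation_start))
      as.integer(ceiling(2 * depth / 3)) else as.integer(bifurcation_start),
    stenosis = isTRUE(stenosis),
    stenosis_slices = if (is.null(stenosis_slices)) integer(0)
      else as.integer(stenosis_slices),
    stenosis_scale = stenosis_scale,
    intensity_lumen = intensity_lumen, intensity_wall = intensity_wall,
    intensity_background = intensity_background,
    noise_sigma = noise_sigma,
    label_fraction = label_fraction, seed = as.integer(seed))
  class(cfg) <- "phantom_config"
  validate_phantom_config(cfg)
  cfg
}

validate_phantom_config <- function(cfg) {
  if (cfg$depth < 1L || cfg$height < 1L || cfg$width < 1L)
    stop("phantom_config: depth/height/width must be >= 1", call. = FALSE)
  if (length(cfg$lumen_radius_range) != 2L ||
      any(cfg$lumen_radius_range <= 0) ||
      diff(cfg$lumen_radius_range) < 0)
    stop("phantom_config: invalid field 'lumen_radius_range'", call. = FALSE)
  if (length(cfg$wall_thickness_range) != 2L ||
      any(cfg$wall_thickness_range <= 0) ||
      diff(cfg$wall_thickness_range) < 0)
    stop("phantom_config: invalid field 'wall_thickness_range'", call. = FALSE)
  if (max(cfg$lumen_radius_range) + max(cfg$wall_thickness_range) >=
      min(cfg$height, cfg$width) / 4)
    stop("phantom_config: vessel too large: lumen_radius_range + ",
         "wall_thickness_range must stay below min(height, width)/4",
         call. = FALSE)
  if (!(cfg$label_fraction > 0 && cfg$label_fraction <= 1))
    stop("phantom_config: invalid field 'label_fraction' (need (0,1])",
         call. = FALSE)
  if (!(cfg$stenosis_scale > 0 && cfg$stenosis_scale <= 1))
    stop("phantom_config: invalid field 'stenosis_scale' (need (0,1])",
         call. = FALSE)
  if (cfg$stenosis && length(cfg$stenosis_slices) == 0)
    stop("phantom_config: invalid field 'stenosis_slices' (empty)",
         call. = FALSE)
  invisible(cfg)
}

#' Construct a volume object
#'
#' A volume is the raw pipeline input: a `D x H x W` array of gray values
#' plus a per-slice usability flag (slices of insufficient image quality are
#' skipped by the training stages).
#'
#' @param intensities numeric `D x H x W` array.
#' @param quality_flags logical vector of length `D`; default all usable.
#' @param provenance free-text origin note.
#' @return an object of class `jcps_volume`.
#' @export
new_volume <- function(intensities, quality_flags = NULL,
                       provenance = "unspecified") {
  stopifnot(length(dim(intensities)) == 3L, all(is.finite(intensities)))
  d <- dim(intensities)[1]
  if (is.null(quality_flags)) quality_flags <- rep(TRUE, d)
  if (length(quality_flags) != d)
    stop("quality_flags length must equal the slice count", call. = FALSE)
  structure(list(intensities = intensities,
                 quality_flags = as.logical(quality_flags),
                 provenance = provenance),
            class = "jcps_volume")
}

#' Construct a label volume
#'
#' Categorical ground truth: 0 = background, 1 = lumen, 2 = wall. Labels are
#' only *valid* on `labeled_slices` (the labeled set A); all other slices
#' form the unlabeled set B and consumers must not read their classes.
#'
#' @param classes integer `D x H x W` array with values in \{0, 1, 2\}.
#' @param labeled_slices integer vector of 1-based slice indices.
#' @return an object of class `jcps_labels`.
#' @export
new_label_volume <- function(classes, labeled_slices) {
  stopifnot(length(dim(classes)) == 3L)
  d <- dim(classes)[1]
  labeled_slices <- sort(unique(as.integer(labeled_slices)))
  if (length(labeled_slices) &&
      (min(labeled_slices) < 1L || max(labeled_slices) > d))
    stop("labeled_slices out of range", call. = FALSE)
  if (!all(classes %in% 0:2))
    stop("classes must be in {0 (background), 1 (lumen), 2 (wall)}",
         call. = FALSE)
  structure(list(classes = classes, labeled_slices = labeled_slices),
            class = "jcps_labels")
}

# Run expr with an isolated, seeded RNG stream; the caller's RNG state is
# untouched.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Smooth 1D random track: Gaussian steps low-passed with a short moving
# average so consecutive slices move gradually.
smooth_track <- function(n, sd) {
  if (sd == 0 || n == 1L) return(rep(0, n))
  steps <- stats::rnorm(n, sd = sd)
  k <- min(5L, n)
  sm <- stats::filter(steps, rep(1 / k, k), sides = 2)
  sm[is.na(sm)] <- 0
  cumsum(as.numeric(sm))
}

disk_mask <- function(h, w, ci, cj, r) {
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  (rows - ci)^2 + (cols - cj)^2 <= r^2
}

#' Generate a synthetic black-blood vessel phantom
#'
#' Draws a smooth centerline through the stack, rasterises per slice a lumen
#' disk and a concentric wall annulus, and samples intensities as class mean
#' plus Gaussian noise (clipped to \[0, 1\]). Full labels are produced on all
#' slices; `labeled_slices` marks the random subset that plays the role of
#' the manual annotations (about 20% of slices by default). Identical seeds
#' give bit-identical output.
#'
#' @param config a [phantom_config()].
#' @return list with elements `volume` ([new_volume()]), `labels`
#'   ([new_label_volume()]) and `truth` (a list with the per-slice rounded
#'   centerline `centers` (`D x 2`), per-slice `lumen_radius` and
#'   `wall_thickness`, and for bifurcated phantoms the second branch track).
#' @export
generate_phantom <- function(config) {
  validate_phantom_config(config)
  cfg <- config
  D <- cfg$depth; H <- cfg$height; W <- cfg$width
  with_seed(cfg$seed, {
    margin <- max(cfg$lumen_radius_range) + max(cfg$wall_thickness_range) + 2
    ci <- H / 2 + smooth_track(D, cfg$centerline_wobble)
    cj <- W / 2 + smooth_track(D, cfg$centerline_wobble)
    ci <- pmin(pmax(ci, margin + 1), H - margin)
    cj <- pmin(pmax(cj, margin + 1), W - margin)
    centers <- cbind(round(ci), round(cj))

    rr <- cfg$lumen_radius_range
    radius <- if (diff(rr) == 0) rep(rr[1], D) else {
      base <- mean(rr) + smooth_track(D, diff(rr) / 4)
      pmin(pmax(base, rr[1]), rr[2])
    }
    tt <- cfg$wall_thickness_range
    thick <- if (diff(tt) == 0) rep(tt[1], D) else {
      base <- mean(tt) + smooth_track(D, diff(tt) / 4)
      pmin(pmax(base, tt[1]), tt[2])
    }
    if (cfg$stenosis) {
      sl <- cfg$stenosis_slices
      radius[sl[sl >= 1 & sl <= D]] <-
        radius[sl[sl >= 1 & sl <= D]] * cfg$stenosis_scale
    }

    # second branch: diverges from the main track after the bifurcation
    # start, slightly smaller caliber, present in the image only
    branch <- NULL
    if (cfg$bifurcation) {
      b0 <- cfg$bifurcation_start
      bslices <- seq.int(b0, D)
      off <- (seq_along(bslices) - 1) * 2 + 2  # grows 2 px per slice
      bj <- pmin(pmax(cj[bslices] + off, margin + 1), W - margin)
      branch <- list(slices = bslices,
                     centers = cbind(round(ci[bslices]), round(bj)),
                     radius = pmax(radius[bslices] * 0.7, 1.5))
    }

    classes <- array(0L, dim = c(D, H, W))
    img <- array(0, dim = c(D, H, W))
    for (k in seq_len(D)) {
      lum <- disk_mask(H, W, centers[k, 1], centers[k, 2], radius[k])
      outer <- disk_mask(H, W, centers[k, 1], centers[k, 2],
                         radius[k] + thick[k])
      wall <- outer & !lum
      cls <- matrix(0L, H, W)
      cls[wall] <- 2L
      cls[lum] <- 1L
      classes[k, , ] <- cls
      sl <- matrix(cfg$intensity_background, H, W)
      sl[wall] <- cfg$intensity_wall
      sl[lum] <- cfg$intensity_lumen
      if (!is.null(branch) && k %in% branch$slices) {
        i <- match(k, branch$slices)
        blum <- disk_mask(H, W, branch$centers[i, 1], branch$centers[i, 2],
                          branch$radius[i])
        bout <- disk_mask(H, W, branch$centers[i, 1], branch$centers[i, 2],
                          branch$radius[i] + thick[k])
        sl[bout & !blum & cls == 0L] <- cfg$intensity_wall
        sl[blum & cls == 0L] <- cfg$intensity_lumen
      }
      if (cfg$noise_sigma > 0)
        sl <- sl + matrix(stats::rnorm(H * W, sd = cfg$noise_sigma), H, W)
      img[k, , ] <- pmin(pmax(sl, 0), 1)
    }

    n_lab <- max(1L, round(cfg$label_fraction * D))
    labeled <- sort(sample.int(D, n_lab))

    list(volume = new_volume(img, provenance = "jcps phantom generator"),
         labels = new_label_volume(classes, labeled),
         truth = list(centers = centers, lumen_radius = radius,
                      wall_thickness = thick, branch = branch))
  })
}

#' Re-draw the labeled-slice subset
#'
#' Replaces `labeled_slices` by a uniformly random subset of size
#' `round(fraction * D)` (at least one slice). The class array is untouched:
#' consumers must honor `labeled_slices`.
#'
#' @param labels a [new_label_volume()] object.
#' @param fraction labeled fraction in (0, 1].
#' @param seed integer seed.
#' @param contiguous if `TRUE` draw one contiguous slice block instead of a
#'   uniform subset (robustness experiments).
#' @return a label volume with the new `labeled_slices`.
#' @export
subsample_labels <- function(labels, fraction, seed = 1L,
                             contiguous = FALSE) {
  stopifnot(inherits(labels, "jcps_labels"))
  if (!(fraction > 0 && fraction <= 1))
    stop("fraction must lie in (0, 1]", call. = FALSE)
  d <- dim(labels$classes)[1]
  n <- max(1L, round(fraction * d))
  with_seed(seed, {
    sel <- if (contiguous) {
      start <- sample.int(d - n + 1L, 1L)
      seq.int(start, start + n - 1L)
    } else sort(sample.int(d, n))
    new_label_volume(labels$classes, sel)
  })
}

#' Corrupt the true lumen mask with scattered fragments
#'
#' Returns the ground-truth lumen mask plus `n_fragments` small (at most
#' 5-pixel) spurious components placed away from the vessel, emulating the
#' scattered false positives a coarse segmentation can produce. Used to test
#' the largest-connected-component and centroid-repair post-processing.
#'
#' @param labels a [new_label_volume()] with valid classes on all slices
#'   (phantom ground truth).
#' @param n_fragments number of fragments per affected slice.
#' @param seed integer seed.
#' @return binary `D x H x W` lumen mask array.
#' @export
simulate_fragmented_coarse_mask <- function(labels, n_fragments, seed = 1L) {
  stopifnot(inherits(labels, "jcps_labels"))
  n_fragments <- as.integer(n_fragments)
  stopifnot(n_fragments >= 0L)
  dims <- dim(labels$classes)
  mask <- array(as.integer(labels$classes == 1L), dim = dims)
  if (n_fragments == 0L) return(mask)
  D <- dims[1]; H <- dims[2]; W <- dims[3]
  offs <- cbind(c(0, 1, 0, -1, 0), c(0, 0, 1, 0, -1))  # plus-shaped blob
  with_seed(seed, {
    for (k in seq_len(D)) {
      vessel <- labels$classes[k, , ] > 0L
      placed <- 0L
      guard <- 0L
      while (placed < n_fragments && guard < 1000L) {
        guard <- guard + 1L
        ci <- sample.int(H - 4L, 1L) + 2L
        cj <- sample.int(W - 4L, 1L) + 2L
        pts <- cbind(ci + offs[, 1], cj + offs[, 2])
        npx <- sample(1:5, 1L)
        pts <- pts[seq_len(npx), , drop = FALSE]
        # keep fragments well clear of the vessel
        box <- vessel[max(1, ci - 8):min(H, ci + 8),
                      max(1, cj - 8):min(W, cj + 8)]
        if (any(box)) next
        sl <- mask[k, , ]
        if (any(sl[pts] == 1L)) next
        sl[pts] <- 1L
        mask[k, , ] <- sl
        placed <- placed + 1L
      }
    }
    mask
  })
}
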