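#' Read a volume from disk
#'
#' Accepts NIfTI (`.nii`, `.nii.gz`) or the package's RDS array container
#' (`.rds`). NIfTI stores in-plane axes first; the reader permutes to the
#' package's `(slice, row, col)` order.
#'
#' @param path file path.
#' @return a [new_volume()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.nii(\\.gz)?$", path)) {
    arr <- tryCatch(as.array(RNifti::readNifti(path)),
                    error = function(e)
                      stop("corrupt NIfTI file: ", path, call. = FALSE))
    if (length(dim(arr)) != 3L)
      stop("expected a 3D NIfTI volume: ", path, call. = FALSE)
    new_volume(aperm(arr, c(3, 1, 2)), provenance = path)
  } else if (grepl("\\.rds$", path)) {
    obj <- readRDS(path)
    if (inherits(obj, "jcps_volume")) obj
    else new_volume(obj, provenance = path)
  } else stop("unknown volume format: ", path, call. = FALSE)
}

#' Write a volume to disk
#'
#' @param volume a [new_volume()].
#' @param path destination; extension selects NIfTI (`.nii`, `.nii.gz`)
#'   or the RDS container (`.rds`, exact round trip).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "jcps_volume"))
  if (grepl("\\.nii(\\.gz)?$", path)) {
    RNifti::writeNifti(RNifti::asNifti(aperm(volume$intensities,
                                             c(2, 3, 1))), path)
  } else if (grepl("\\.rds$", path)) {
    saveRDS(volume, path)
  } else stop("unknown volume format: ", path, call. = FALSE)
  invisible(path)
}

#' Write a label volume to disk
#'
#' Classes are stored as an unsigned 8-bit NIfTI volume (in-plane axes
#' first) or as the RDS container preserving `labeled_slices`.
#'
#' @param labels a [new_label_volume()].
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  stopifnot(inherits(labels, "jcps_labels"))
  if (grepl("\\.nii(\\.gz)?$", path)) {
    RNifti::writeNifti(RNifti::asNifti(aperm(labels$classes, c(2, 3, 1)),
                                       datatype = "uint8"), path)
  } else if (grepl("\\.rds$", path)) {
    saveRDS(labels, path)
  } else stop("unknown label format: ", path, call. = FALSE)
  invisible(path)
}

#' Read a label volume
#'
#' @param path `.nii`/`.nii.gz` (all slices marked labeled) or `.rds`.
#' @return a [new_label_volume()].
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.nii(\\.gz)?$", path)) {
    arr <- as.array(RNifti::readNifti(path))
    arr <- aperm(arr, c(3, 1, 2))
    new_label_volume(array(as.integer(round(arr)), dim = dim(arr)),
                     seq_len(dim(arr)[1]))
  } else if (grepl("\\.rds$", path)) {
    readRDS(path)
  } else stop("unknown label format: ", path, call. = FALSE)
}

#' Write a gray PNG preview of one slice
#'
#' @param volume a [new_volume()].
#' @param slice slice index.
#' @param path destination `.png`.
#' @param labels optional [new_label_volume()] overlaid as contours
#'   (lumen and wall boundaries brightened).
#' @return `path`, invisibly.
#' @export
write_slice_png <- function(volume, slice, path, labels = NULL) {
  img <- volume$intensities[slice, , ]
  img <- (img - min(img)) / max(max(img) - min(img), 1e-12)
  rgb <- array(img, dim = c(dim(img), 3))
  if (!is.null(labels)) {
    cls <- labels$classes[slice, , ]
    lb <- extract_contour(cls == 1L)
    wb <- extract_contour(cls >= 1L)
    if (nrow(lb)) { rgb[cbind(lb, 1)] <- 1; rgb[cbind(lb, 2)] <- 0.2
                    rgb[cbind(lb, 3)] <- 0.2 }
    if (nrow(wb)) { rgb[cbind(wb, 2)] <- 1; rgb[cbind(wb, 1)] <- 0.2
                    rgb[cbind(wb, 3)] <- 0.2 }
  }
  png::writePNG(rgb, path)
  invisible(path)
}

#' Serialise a trained network to a plain list
#'
#' Stores the network configuration, its kind and all parameter values so
#' the model can be rebuilt exactly with [load_model()].
#'
#' @param net a network from [build_unet()] or [build_coarse_net()].
#' @param kind `"unet"` or `"coarse"`.
#' @return a serialisable list.
#' @export
save_model <- function(net, kind = c("unet", "coarse")) {
  kind <- match.arg(kind)
  list(kind = kind, config = net$config,
       params = lapply(net$layers_flat, function(l) l$params))
}

#' Rebuild a network from [save_model()] output
#'
#' @param obj the saved list.
#' @return a network object with identical parameters.
#' @export
load_model <- function(obj) {
  net <- if (obj$kind == "coarse") build_coarse_net(obj$config)
    else build_unet(obj$config)
  stopifnot(length(net$layers_flat) == length(obj$params))
  for (i in seq_along(obj$params))
    net$layers_flat[[i]]$params <- obj$params[[i]]
  net
}

save_pair <- function(pair) list(net_a = save_model(pair$net_a),
                                 net_b = save_model(pair$net_b))
load_pair <- function(obj) list(net_a = load_model(obj$net_a),
                                net_b = load_model(obj$net_b))

#' Desk-scale run configuration
#'
#' A complete pipeline configuration sized for a single CPU: a small
#' phantom (by default 16 slices of 48 x 48 with 6 labeled slices), tiny
#' networks (base width 4, two levels) and short training stages. Used by
#' the `demo` command and as a template for custom runs.
#'
#' @param seed master seed; stage seeds are derived from it.
#' @param depth,height,width phantom dimensions.
#' @param label_fraction labeled-slice fraction.
#' @param iterations named list or vector with `coarse`, `cps2d`, `cps3d`
#'   iteration counts.
#' @param patch in-plane patch side (multiple of 4).
#' @param chunk_depth,chunk_overlap depth chunking.
#' @return nested configuration list understood by [run_pipeline()].
#' @export
demo_run_config <- function(seed = 1L, depth = 16L, height = 48L,
                            width = 48L, label_fraction = 0.375,
                            iterations = c(coarse = 150L, cps2d = 300L,
                                           cps3d = 150L),
                            patch = 24L, chunk_depth = 8L,
                            chunk_overlap = 4L) {
  seed <- as.integer(seed)
  list(
    seed = seed,
    phantom = phantom_config(depth = depth, height = height, width = width,
                             lumen_radius_range = c(3.5, 5),
                             wall_thickness_range = c(1.5, 2.5),
                             noise_sigma = 0.1,
                             label_fraction = label_fraction, seed = seed),
    nets = list(
      coarse = net_config(num_classes = 2L, base_channels = 4L,
                          depth = 2L, seed = seed + 11L),
      unet2d = net_config(num_classes = 3L, base_channels = 4L,
                          depth = 2L, seed = seed + 21L),
      unet3d = net_config(in_channels = 3L, num_classes = 3L,
                          base_channels = 4L, depth = 2L, dims = 3L,
                          seed = seed + 31L)),
    coarse = train_config("coarse", iterations = iterations[["coarse"]],
                          batch_size = 4L, seed = seed + 101L),
    cps2d = train_config("cps2d", iterations = iterations[["cps2d"]],
                         patch_size = c(patch, patch), seed = seed + 201L),
    cps3d = train_config("cps3d", iterations = iterations[["cps3d"]],
                         batch_size = 2L, labeled_batch_size = 1L,
                         lr = 0.02,
                         patch_size = c(patch, patch),
                         chunk_depth = chunk_depth,
                         chunk_overlap = chunk_overlap,
                         seed = seed + 301L))
}

#' Read a YAML run configuration
#'
#' The YAML mirrors [demo_run_config()]: top-level `seed` plus optional
#' `phantom`, `nets`, `coarse`, `cps2d`, `cps3d` blocks whose entries
#' override the demo defaults.
#'
#' @param path YAML file.
#' @return configuration list.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  seed <- as.integer(y$seed %||% 1L)
  cfg <- demo_run_config(seed = seed)
  if (!is.null(y$phantom))
    cfg$phantom <- do.call(phantom_config,
                           utils::modifyList(list(seed = seed), y$phantom))
  for (st in c("coarse", "cps2d", "cps3d")) {
    if (!is.null(y[[st]]))
      cfg[[st]] <- do.call(train_config,
                           utils::modifyList(
                             c(list(stage = st), unclass(cfg[[st]])[
                               setdiff(names(unclass(cfg[[st]])), "stage")]),
                             y[[st]]))
  }
  cfg
}

file_checksums <- function(files) {
  out <- tools::md5sum(files)
  stats::setNames(as.character(out), basename(names(out)))
}

#' Run the full pipeline end to end
#'
#' Generates (or loads) the data, trains all three stages, segments the
#' volume, evaluates against the ground truth and writes every artifact
#' (volumes, masks, centroid track, loss logs, metrics, PNG previews)
#' under `out_dir`, together with a manifest recording the configuration
#' and the MD5 checksum of every artifact. Reruns with the same
#' configuration produce byte-identical artifacts.
#'
#' @param config configuration list from [demo_run_config()] or
#'   [read_run_config()].
#' @param out_dir output directory (created if missing).
#' @return list with the trained stages, segmentation, metrics and the
#'   manifest, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  for (blk in c("phantom", "nets", "coarse", "cps2d", "cps3d"))
    if (is.null(config[[blk]]))
      stop("run configuration is missing the '", blk, "' block",
           call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ph <- generate_phantom(config$phantom)
  write_volume(ph$volume, file.path(out_dir, "volume.nii.gz"))
  write_labels(ph$labels, file.path(out_dir, "labels.rds"))
  fit <- train_jcps(ph$volume, ph$labels,
                    configs = config[c("nets", "coarse", "cps2d", "cps3d")])
  seg <- segment_volume(fit$coarse$net, fit$cps2d$pair, fit$cps3d$pair,
                        ph$volume, config$cps3d)
  heldout <- setdiff(seq_len(config$phantom$depth),
                     ph$labels$labeled_slices)
  metrics <- evaluate_case(seg$labels, ph$labels,
                           slices = if (length(heldout)) heldout
                             else ph$labels$labeled_slices)
  write_labels(seg$labels, file.path(out_dir, "segmentation.nii.gz"))
  utils::write.csv(fit$coarse$history,
                   file.path(out_dir, "loss_coarse.csv"),
                   row.names = FALSE)
  utils::write.csv(fit$cps2d$history,
                   file.path(out_dir, "loss_cps2d.csv"), row.names = FALSE)
  utils::write.csv(fit$cps3d$history,
                   file.path(out_dir, "loss_cps3d.csv"), row.names = FALSE)
  utils::write.csv(data.frame(slice = seq_len(nrow(seg$centroids)),
                              i = seg$centroids[, 1],
                              j = seg$centroids[, 2]),
                   file.path(out_dir, "centroids.csv"), row.names = FALSE)
  mid <- (config$phantom$depth + 1L) %/% 2L
  write_slice_png(ph$volume, mid, file.path(out_dir, "preview.png"),
                  labels = seg$labels)
  jsonlite::write_json(
    lapply(unclass(metrics)[names(metrics) != "per_slice"], unname),
    file.path(out_dir, "metrics.json"), auto_unbox = TRUE, digits = NA)
  arts <- c("volume.nii.gz", "labels.rds", "segmentation.nii.gz",
            "loss_coarse.csv", "loss_cps2d.csv", "loss_cps3d.csv",
            "centroids.csv", "preview.png", "metrics.json")
  manifest <- list(seed = config$seed,
                   phantom = unclass(config$phantom),
                   checksums = as.list(
                     file_checksums(file.path(out_dir, arts))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(fit = fit, segmentation = seg, metrics = metrics,
                 manifest = manifest))
}
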