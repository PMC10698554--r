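#' Training configuration for one pipeline stage
#'
#' Defaults follow the full-scale recipe (coarse: Adam, learning rate
#' 0.001 multiplied by 0.9 every 1000 iterations; fine stages: SGD with
#' momentum 0.9, weight decay 1e-4, poly learning-rate decay
#' `lr0 (1 - iter/max_iter)^0.9` from 0.01; Focal Tversky weights
#' `alpha = 0.7, beta = 0.3, gamma = 0.7`; fine-stage patch sizes 96 x 96
#' and 32 x 96 x 96). Desk-scale runs shrink `iterations`, `patch_size`
#' and `chunk_depth` (see [demo_run_config()]).
#'
#' @param stage one of `"coarse"`, `"cps2d"`, `"cps3d"`.
#' @param iterations training iterations (`>= 0`).
#' @param batch_size samples per iteration.
#' @param labeled_batch_size labeled samples per fine-stage batch
#'   (`<= batch_size`).
#' @param optimizer `"adam"` or `"sgd"`.
#' @param lr initial learning rate.
#' @param lr_schedule `"step"` or `"poly"`.
#' @param momentum,weight_decay SGD parameters.
#' @param patch_size in-plane patch `(h, w)` for the fine stages.
#' @param chunk_depth,chunk_overlap depth chunking of the 3D stage.
#' @param alpha,beta,gamma Focal Tversky weights of the coarse stage.
#' @param tau centroid-track outlier threshold (px).
#' @param seed integer seed governing batch sampling.
#' @return list of class `train_config`.
#' @export
train_config <- function(stage = c("coarse", "cps2d", "cps3d"),
                         iterations = 100L,
                         batch_size = if (stage == "coarse") 12L else 4L,
                         labeled_batch_size = 2L,
                         optimizer = if (stage == "coarse") "adam" else "sgd",
                         lr = if (stage == "coarse") 0.001 else 0.01,
                         lr_schedule = if (stage == "coarse") "step"
                           else "poly",
                         momentum = 0.9, weight_decay = 1e-4,
                         patch_size = c(96L, 96L),
                         chunk_depth = 32L,
                         chunk_overlap = chunk_depth %/% 2L,
                         alpha = 0.7, beta = 0.3, gamma = 0.7,
                         tau = 24, seed = 1L) {
  stage <- match.arg(stage)
  stopifnot(iterations >= 0L, labeled_batch_size <= batch_size)
  structure(list(stage = stage, iterations = as.integer(iterations),
                 batch_size = as.integer(batch_size),
                 labeled_batch_size = as.integer(labeled_batch_size),
                 optimizer = optimizer, lr = lr,
                 lr_schedule = lr_schedule, momentum = momentum,
                 weight_decay = weight_decay,
                 patch_size = as.integer(patch_size),
                 chunk_depth = as.integer(chunk_depth),
                 chunk_overlap = as.integer(chunk_overlap),
                 alpha = alpha, beta = beta, gamma = gamma, tau = tau,
                 seed = as.integer(seed)),
            class = "train_config")
}

stage_lr <- function(cfg, iter) {
  if (cfg$lr_schedule == "step") lr_step(cfg$lr, iter)
  else lr_poly(cfg$lr, iter, max(cfg$iterations, 1L))
}

norm_half_diag <- function(hw) sqrt(sum(hw^2)) / 2

#' Train the dual-task coarse segmentation network
#'
#' Trains the coarse network on the labeled, usable slices to predict both
#' the lumen classification (Focal Tversky loss) and the normalised signed
#' distance map (mean squared error), combined by homoscedastic
#' uncertainty weighting with the noise scales learned jointly with the
#' network.
#'
#' @param volume a [new_volume()].
#' @param labels a [new_label_volume()].
#' @param net_config a [net_config()] with `num_classes = 2`.
#' @param config a [train_config()] with `stage = "coarse"`.
#' @return list of class `stage_result` with `net`, `sigma` (the two
#'   learned noise scales), `history` (per-iteration data frame) and the
#'   config snapshot.
#' @export
train_coarse <- function(volume, labels, net_config, config) {
  stopifnot(inherits(volume, "jcps_volume"), inherits(labels, "jcps_labels"))
  pool <- intersect(labels$labeled_slices, which(volume$quality_flags))
  if (length(pool) == 0L) stop("no labeled usable slices", call. = FALSE)
  hw <- dim(volume$intensities)[2:3]
  hd <- norm_half_diag(hw)
  net <- build_coarse_net(net_config)
  hist <- NULL
  # log-variance parametrisation of the task noise scales, trained by Adam
  s <- c(0, 0); s_m <- c(0, 0); s_v <- c(0, 0)
  if (config$iterations > 0L) with_seed(config$seed, {
    opt <- make_optimizer(net, config$optimizer, lr = config$lr,
                          momentum = config$momentum,
                          weight_decay = config$weight_decay)
    targets <- lapply(pool, function(k) {
      lum <- labels$classes[k, , ] == 1L
      sdf <- pmin(pmax(signed_distance_map(lum) / hd, -1), 1)
      list(x = array(volume$intensities[k, , ], dim = c(1L, hw)),
           y = lum * 1, sdf = sdf)
    })
    hist_rows <- vector("list", config$iterations)
    for (iter in seq_len(config$iterations)) {
      batch <- sample.int(length(targets), config$batch_size,
                          replace = TRUE)
      zero_grads(net)
      lft_b <- 0; lsdf_b <- 0
      gs <- c(0, 0)
      for (ib in batch) {
        tg <- targets[[ib]]
        out <- net$forward(tg$x, train = TRUE)
        pfg <- matrix(out$probs[2, , ], hw[1], hw[2])
        lft <- focal_tversky_loss(pfg, tg$y, config$alpha, config$beta,
                                  config$gamma)
        lsdf <- sdf_regression_loss(out$sdf, tg$sdf)
        lft_b <- lft_b + lft / length(batch)
        lsdf_b <- lsdf_b + lsdf / length(batch)
        gp <- array(0, dim = dim(out$probs))
        gp[2, , ] <- focal_tversky_grad(pfg, tg$y, config$alpha,
                                        config$beta, config$gamma) *
          exp(-s[1]) / length(batch)
        gsdf <- 2 * (out$sdf - tg$sdf) / length(tg$sdf) *
          exp(-s[2]) / length(batch)
        net$backward(gp, gsdf)
      }
      # gradients of L = e^{-s1} Lft + e^{-s2} Lsdf + (s1 + s2)/2
      gs <- c(-exp(-s[1]) * lft_b + 0.5, -exp(-s[2]) * lsdf_b + 0.5)
      s_m <- 0.9 * s_m + 0.1 * gs
      s_v <- 0.999 * s_v + 0.001 * gs^2
      s <- s - 0.01 * (s_m / (1 - 0.9^iter)) /
        (sqrt(s_v / (1 - 0.999^iter)) + 1e-8)
      lr <- stage_lr(config, iter - 1L)
      opt$step(lr)
      total <- dual_task_loss(lft_b, lsdf_b, exp(s[1] / 2), exp(s[2] / 2))
      hist_rows[[iter]] <- data.frame(iter = iter, total = total,
                                      l_ft = lft_b, l_sdf = lsdf_b,
                                      sigma1 = exp(s[1] / 2),
                                      sigma2 = exp(s[2] / 2), lr = lr)
    }
    hist <- do.call(rbind, hist_rows)
  })
  structure(list(net = net, sigma = exp(s / 2),
                 history = hist %||% data.frame(),
                 config = config, net_config = net_config),
            class = "stage_result")
}

#' Coarse inference: lumen masks and repaired centroid track
#'
#' Runs the coarse network on every slice, keeps the largest connected
#' component of the argmax lumen mask, computes the per-slice center of
#' gravity and repairs the centroid track using the vessel's spatial
#' continuity.
#'
#' @param net trained coarse network (from [train_coarse()]).
#' @param volume a [new_volume()].
#' @param tau outlier threshold passed to [repair_centroid_track()].
#' @return list with `masks` (binary `D x H x W`), `centroids`
#'   (`D x 2`, repaired) and `raw_centroids` (with `NA` rows where no
#'   lumen was found).
#' @export
infer_coarse <- function(net, volume, tau = 24) {
  stopifnot(inherits(volume, "jcps_volume"))
  dims <- dim(volume$intensities)
  masks <- array(0L, dim = dims)
  raw <- matrix(NA_real_, dims[1], 2)
  for (k in seq_len(dims[1])) {
    x <- array(volume$intensities[k, , ], dim = c(1L, dims[2:3]))
    out <- net$forward(x, train = FALSE)
    lum <- argmax_map(out$probs) == 1L
    lum <- largest_connected_component(matrix(lum, dims[2], dims[3]))
    masks[k, , ] <- lum
    cg <- center_of_gravity_2d(lum)
    if (cg$valid) raw[k, ] <- cg$coords
  }
  centroids <- repair_centroid_track(raw, tau = tau)
  list(masks = masks, centroids = centroids, raw_centroids = raw)
}

# mean-softmax ensemble of a model pair (eval mode)
pair_predict <- function(pair, x) {
  (pair$net_a$forward(x, train = FALSE) +
     pair$net_b$forward(x, train = FALSE)) / 2
}

# supervised 2D loss gradient (cross-entropy + dice) for one patch
sup_grad_2d <- function(y, p, scale) {
  (cross_entropy_grad(y, p) + dice_grad(y, p)) * scale
}

#' Train the 2D cross-pseudo-supervision model pair
#'
#' Two U-Nets with different initialisations are trained on mixed batches
#' of labeled and unlabeled patches. Labeled patches contribute the
#' supervision loss (cross-entropy plus Dice, averaged over the two
#' networks); every patch contributes the cross-pseudo supervision loss in
#' which each network is supervised by the other's argmax pseudo labels,
#' weighted by the ramp-up schedule. After training, the ensemble pseudo
#' label `S2D` (argmax of the mean confidence map) is produced for every
#' patch.
#'
#' @param patches list of `h x w` image patches, one per slice.
#' @param labeled_idx indices into `patches` with labels (set A; nonempty).
#' @param labels list (parallel to `labeled_idx`) of `h x w` class
#'   matrices with values 0/1/2.
#' @param net_config a [net_config()] (`dims = 2`, `num_classes = 3`).
#' @param config a [train_config()] with `stage = "cps2d"`.
#' @param seed_pair two initialisation seeds for the pair.
#' @return `stage_result` with `pair`, `s2d` (list of pseudo-label
#'   matrices for all patches) and `history`.
#' @export
train_cps_2d <- function(patches, labeled_idx, labels, net_config, config,
                         seed_pair = c(net_config$seed, net_config$seed + 1000L)) {
  if (length(labeled_idx) == 0L) stop("labeled set A is empty", call. = FALSE)
  stopifnot(length(labels) == length(labeled_idx))
  pair <- build_model_pair(net_config, seed_pair[1], seed_pair[2])
  unlabeled_idx <- setdiff(seq_along(patches), labeled_idx)
  hist <- NULL
  if (config$iterations > 0L) with_seed(config$seed, {
    opt_a <- make_optimizer(pair$net_a, config$optimizer, lr = config$lr,
                            momentum = config$momentum,
                            weight_decay = config$weight_decay)
    opt_b <- make_optimizer(pair$net_b, config$optimizer, lr = config$lr,
                            momentum = config$momentum,
                            weight_decay = config$weight_decay)
    hist_rows <- vector("list", config$iterations)
    for (iter in seq_len(config$iterations)) {
      n_lab <- min(config$labeled_batch_size, config$batch_size)
      lab_pick <- sample(labeled_idx, n_lab, replace = TRUE)
      n_unl <- config$batch_size - n_lab
      unl_pool <- if (length(unlabeled_idx)) unlabeled_idx else labeled_idx
      unl_pick <- if (n_unl > 0) sample(unl_pool, n_unl, replace = TRUE)
        else integer(0)
      t <- (iter - 1L) / max(config$iterations - 1L, 1L)
      lam0 <- rampup_weight(t)
      zero_grads(pair$net_a); zero_grads(pair$net_b)
      l_sup <- 0; l_cps <- 0
      items <- c(lab_pick, unl_pick)
      n_items <- length(items)
      for (j in seq_len(n_items)) {
        k <- items[j]
        x <- array(patches[[k]], dim = c(1L, dim(patches[[k]])))
        pa <- pair$net_a$forward(x, train = TRUE)
        pb <- pair$net_b$forward(x, train = TRUE)
        ga <- array(0, dim = dim(pa))
        gb <- array(0, dim = dim(pb))
        if (j <= n_lab) {
          y <- labels[[match(k, labeled_idx)]]
          l_sup <- l_sup +
            (cross_entropy_loss(y, pa) + dice_loss(y, pa) +
               cross_entropy_loss(y, pb) + dice_loss(y, pb)) / 2 / n_lab
          ga <- ga + sup_grad_2d(y, pa, 0.5 / n_lab)
          gb <- gb + sup_grad_2d(y, pb, 0.5 / n_lab)
        }
        sa <- argmax_map(pa)
        sb <- argmax_map(pb)
        l_cps <- l_cps + (cross_entropy_loss(sb, pa) +
                            cross_entropy_loss(sa, pb)) / n_items
        ga <- ga + lam0 * cross_entropy_grad(sb, pa) / n_items
        gb <- gb + lam0 * cross_entropy_grad(sa, pb) / n_items
        pair$net_a$backward(ga)
        pair$net_b$backward(gb)
      }
      lr <- stage_lr(config, iter - 1L)
      opt_a$step(lr); opt_b$step(lr)
      hist_rows[[iter]] <- data.frame(
        iter = iter, total = total_loss_2d(l_sup, l_cps, t),
        l_sup = l_sup, l_cps = l_cps, lambda0 = lam0, lr = lr)
    }
    hist <- do.call(rbind, hist_rows)
  })
  s2d <- lapply(patches, function(px) {
    x <- array(px, dim = c(1L, dim(px)))
    argmax_map(pair_predict(pair, x))
  })
  structure(list(pair = pair, s2d = s2d, history = hist %||% data.frame(),
                 config = config, net_config = net_config,
                 seed_pair = seed_pair),
            class = "stage_result")
}

#' Train a single supervised 2D U-Net baseline
#'
#' The fully supervised reference: one U-Net trained on the labeled
#' patches alone with cross-entropy plus Dice, under the same optimizer
#' and schedule as the fine stages.
#'
#' @inheritParams train_cps_2d
#' @return `stage_result` with `net`, `history`.
#' @export
train_unet_supervised <- function(patches, labeled_idx, labels, net_config,
                                  config) {
  if (length(labeled_idx) == 0L) stop("labeled set A is empty", call. = FALSE)
  net <- build_unet(net_config)
  hist <- NULL
  if (config$iterations > 0L) with_seed(config$seed, {
    opt <- make_optimizer(net, config$optimizer, lr = config$lr,
                          momentum = config$momentum,
                          weight_decay = config$weight_decay)
    hist_rows <- vector("list", config$iterations)
    for (iter in seq_len(config$iterations)) {
      pick <- sample(labeled_idx, config$batch_size, replace = TRUE)
      zero_grads(net)
      l_sup <- 0
      for (k in pick) {
        x <- array(patches[[k]], dim = c(1L, dim(patches[[k]])))
        p <- net$forward(x, train = TRUE)
        y <- labels[[match(k, labeled_idx)]]
        l_sup <- l_sup + (cross_entropy_loss(y, p) + dice_loss(y, p)) /
          length(pick)
        net$backward(sup_grad_2d(y, p, 1 / length(pick)))
      }
      lr <- stage_lr(config, iter - 1L)
      opt$step(lr)
      hist_rows[[iter]] <- data.frame(iter = iter, total = l_sup, lr = lr)
    }
    hist <- do.call(rbind, hist_rows)
  })
  structure(list(net = net, history = hist %||% data.frame(),
                 config = config, net_config = net_config),
            class = "stage_result")
}

# assemble the 3D input: image window plus one-hot foreground channels of
# the 2D pseudo labels
chunk_input <- function(img_chunk, s2d_chunk) {
  d <- dim(img_chunk)
  x <- array(0, dim = c(3L, d))
  x[1, , , ] <- img_chunk
  x[2, , , ] <- (s2d_chunk == 1L) * 1
  x[3, , , ] <- (s2d_chunk == 2L) * 1
  x
}

# per-chunk 3D loss gradient assembly; returns loss components and applies
# backward passes. lambda = c(l1, l2, l3) overriding the schedule when set.
cps3d_losses_and_grads <- function(chunk, pa, pb, lam, apply_grads,
                                   pair = NULL, sup_scale = 1) {
  d <- dim(pa)[2]
  A <- chunk$labeled_in_chunk
  B <- chunk$unlabeled_in_chunk
  ga <- array(0, dim = dim(pa))
  gb <- array(0, dim = dim(pb))
  l_sup <- 0
  if (length(A)) {
    for (jj in seq_along(A)) {
      i <- A[jj]
      y <- chunk$labels_in_chunk[[jj]]
      pai <- pa[, i, , ]; pbi <- pb[, i, , ]
      l_sup <- l_sup +
        (cross_entropy_loss(y, pai) + dice_loss(y, pai) +
           cross_entropy_loss(y, pbi) + dice_loss(y, pbi))
      ga[, i, , ] <- ga[, i, , ] + (cross_entropy_grad(y, pai) +
                                      dice_grad(y, pai)) *
        sup_scale / (2 * length(A))
      gb[, i, , ] <- gb[, i, , ] + (cross_entropy_grad(y, pbi) +
                                      dice_grad(y, pbi)) *
        sup_scale / (2 * length(A))
    }
    l_sup <- l_sup / (2 * length(A))
  }
  sa <- argmax_map(pa); sb <- argmax_map(pb)
  l_cps <- cross_entropy_loss(sb, pa) + cross_entropy_loss(sa, pb)
  if (lam[1] != 0) {
    ga <- ga + lam[1] * cross_entropy_grad(sb, pa)
    gb <- gb + lam[1] * cross_entropy_grad(sa, pb)
  }
  l_ps <- 0
  if (length(B)) {
    for (i in B) {
      s2 <- chunk$s2d[i, , ]
      pai <- pa[, i, , ]; pbi <- pb[, i, , ]
      l_ps <- l_ps + cross_entropy_loss(s2, pai) + dice_loss(s2, pai) +
        cross_entropy_loss(s2, pbi) + dice_loss(s2, pbi)
      if (lam[2] != 0) {
        sc <- lam[2] / (2 * length(B))
        ga[, i, , ] <- ga[, i, , ] + (cross_entropy_grad(s2, pai) +
                                        dice_grad(s2, pai)) * sc
        gb[, i, , ] <- gb[, i, , ] + (cross_entropy_grad(s2, pbi) +
                                        dice_grad(s2, pbi)) * sc
      }
    }
    l_ps <- l_ps / (2 * length(B))
  }
  l_cs <- 0
  for (i in 1:(d - 1L)) {
    l_cs <- l_cs + cross_entropy_loss(sa[i + 1L, , ], pa[, i, , ]) +
      cross_entropy_loss(sb[i + 1L, , ], pb[, i, , ])
    if (lam[3] != 0) {
      ga[, i, , ] <- ga[, i, , ] +
        lam[3] / 2 * cross_entropy_grad(sa[i + 1L, , ], pa[, i, , ])
      gb[, i, , ] <- gb[, i, , ] +
        lam[3] / 2 * cross_entropy_grad(sb[i + 1L, , ], pb[, i, , ])
    }
  }
  for (i in 2:d) {
    l_cs <- l_cs + cross_entropy_loss(sa[i - 1L, , ], pa[, i, , ]) +
      cross_entropy_loss(sb[i - 1L, , ], pb[, i, , ])
    if (lam[3] != 0) {
      ga[, i, , ] <- ga[, i, , ] +
        lam[3] / 2 * cross_entropy_grad(sa[i - 1L, , ], pa[, i, , ])
      gb[, i, , ] <- gb[, i, , ] +
        lam[3] / 2 * cross_entropy_grad(sb[i - 1L, , ], pb[, i, , ])
    }
  }
  l_cs <- l_cs / 2
  if (apply_grads) {
    pair$net_a$backward(ga)
    pair$net_b$backward(gb)
  }
  list(l_sup = l_sup, l_cps = l_cps, l_ps = l_ps, l_cs = l_cs)
}

#' Train the 3D cross-pseudo-supervision model pair
#'
#' Two 3D U-Nets take depth chunks of the image concatenated with the
#' one-hot 2D pseudo labels and are trained under the four-term fine-stage
#' loss: supervision on the labeled slices inside each chunk, 3D
#' cross-pseudo supervision between the pair, pseudo-label supervision by
#' the 2D-stage labels on unlabeled slices, and the inter-slice continuity
#' loss. The consistency weights follow the ramp-up schedule
#' (`lambda1 = lambda3 = rampup_weight(t)`, `lambda2 = 1`) unless
#' overridden.
#'
#' @param chunks list of chunk descriptors, each a list with `x`
#'   (`3 x d x h x w` input from image + pseudo-label channels), `s2d`
#'   (`d x h x w` pseudo labels), `labeled_in_chunk` (in-chunk slice
#'   indices of set A), `labels_in_chunk` (parallel list of `h x w` class
#'   matrices), `unlabeled_in_chunk` (set B indices).
#' @param net_config a [net_config()] (`dims = 3`, `in_channels = 3`).
#' @param config a [train_config()] with `stage = "cps3d"`.
#' @param seed_pair initialisation seeds for the pair.
#' @param lambda_override optional numeric length-3 vector fixing
#'   `(lambda1, lambda2, lambda3)` (e.g. `c(0, 0, 0)` for the supervised
#'   ablation).
#' @return `stage_result` with `pair` and a per-term loss `history`.
#' @export
train_cps_3d <- function(chunks, net_config, config,
                         seed_pair = c(net_config$seed + 1L,
                                       net_config$seed + 1001L),
                         lambda_override = NULL) {
  stopifnot(length(chunks) >= 1L)
  pair <- list(net_a = NULL, net_b = NULL)
  ca <- net_config; ca$seed <- as.integer(seed_pair[1])
  cb <- net_config; cb$seed <- as.integer(seed_pair[2])
  pair$net_a <- build_unet(ca)
  pair$net_b <- build_unet(cb)
  hist <- NULL
  if (config$iterations > 0L) with_seed(config$seed, {
    opt_a <- make_optimizer(pair$net_a, config$optimizer, lr = config$lr,
                            momentum = config$momentum,
                            weight_decay = config$weight_decay)
    opt_b <- make_optimizer(pair$net_b, config$optimizer, lr = config$lr,
                            momentum = config$momentum,
                            weight_decay = config$weight_decay)
    hist_rows <- vector("list", config$iterations)
    for (iter in seq_len(config$iterations)) {
      pick <- sample.int(length(chunks), config$batch_size, replace = TRUE)
      t <- (iter - 1L) / max(config$iterations - 1L, 1L)
      lam <- if (is.null(lambda_override))
        c(rampup_weight(t), 1, rampup_weight(t)) else lambda_override
      zero_grads(pair$net_a); zero_grads(pair$net_b)
      comp <- c(l_sup = 0, l_cps = 0, l_ps = 0, l_cs = 0)
      for (k in pick) {
        ch <- chunks[[k]]
        pa <- pair$net_a$forward(ch$x, train = TRUE)
        pb <- pair$net_b$forward(ch$x, train = TRUE)
        # per-item gradient scale 1/|batch|: fold into lambda and sup scale
        res <- cps3d_losses_and_grads(
          ch, pa, pb,
          lam = lam / length(pick), apply_grads = TRUE, pair = pair,
          sup_scale = 1 / length(pick))
        comp <- comp + unlist(res) / length(pick)
      }
      lr <- stage_lr(config, iter - 1L)
      opt_a$step(lr); opt_b$step(lr)
      hist_rows[[iter]] <- data.frame(
        iter = iter,
        total = comp[["l_sup"]] + lam[1] * comp[["l_cps"]] +
          lam[2] * comp[["l_ps"]] + lam[3] * comp[["l_cs"]],
        l_sup = comp[["l_sup"]], l_cps = comp[["l_cps"]],
        l_ps = comp[["l_ps"]], l_cs = comp[["l_cs"]],
        lambda1 = lam[1], lambda2 = lam[2], lambda3 = lam[3], lr = lr)
    }
    hist <- do.call(rbind, hist_rows)
  })
  structure(list(pair = pair, history = hist %||% data.frame(),
                 config = config, net_config = net_config,
                 seed_pair = seed_pair),
            class = "stage_result")
}

#' Train the supervised 3D baseline
#'
#' Both members of the pair are trained on the labeled slices only (the
#' supervision term of the fine-stage loss), with the same batch sampling
#' as [train_cps_3d()]; it reproduces the ablation in which all
#' consistency weights are zero.
#'
#' @inheritParams train_cps_3d
#' @return `stage_result` with `pair` and `history`.
#' @export
train_unet3d_supervised <- function(chunks, net_config, config,
                                    seed_pair = c(net_config$seed + 1L,
                                                  net_config$seed + 1001L)) {
  res <- train_cps_3d(chunks, net_config, config, seed_pair,
                      lambda_override = c(0, 0, 0))
  res
}

# sup-only 3D trainer with an independent inner loop, used as the identity
# oracle for the zero-lambda ablation in the tests
train_unet3d_supervised_ref <- function(chunks, net_config, config,
                                        seed_pair) {
  pair <- list(
    net_a = build_unet(within_seed_cfg(net_config, seed_pair[1])),
    net_b = build_unet(within_seed_cfg(net_config, seed_pair[2])))
  hist <- NULL
  with_seed(config$seed, {
    opt_a <- make_optimizer(pair$net_a, config$optimizer, lr = config$lr,
                            momentum = config$momentum,
                            weight_decay = config$weight_decay)
    opt_b <- make_optimizer(pair$net_b, config$optimizer, lr = config$lr,
                            momentum = config$momentum,
                            weight_decay = config$weight_decay)
    hist_rows <- vector("list", config$iterations)
    for (iter in seq_len(config$iterations)) {
      pick <- sample.int(length(chunks), config$batch_size, replace = TRUE)
      zero_grads(pair$net_a); zero_grads(pair$net_b)
      l_sup <- 0
      for (k in pick) {
        ch <- chunks[[k]]
        pa <- pair$net_a$forward(ch$x, train = TRUE)
        pb <- pair$net_b$forward(ch$x, train = TRUE)
        A <- ch$labeled_in_chunk
        ga <- array(0, dim = dim(pa)); gb <- array(0, dim = dim(pb))
        if (length(A)) {
          for (jj in seq_along(A)) {
            i <- A[jj]; y <- ch$labels_in_chunk[[jj]]
            pai <- pa[, i, , ]; pbi <- pb[, i, , ]
            l_sup <- l_sup +
              (cross_entropy_loss(y, pai) + dice_loss(y, pai) +
                 cross_entropy_loss(y, pbi) + dice_loss(y, pbi)) /
              (2 * length(A) * length(pick))
            sc <- 1 / (2 * length(A) * length(pick))
            ga[, i, , ] <- ga[, i, , ] + (cross_entropy_grad(y, pai) +
                                            dice_grad(y, pai)) * sc
            gb[, i, , ] <- gb[, i, , ] + (cross_entropy_grad(y, pbi) +
                                            dice_grad(y, pbi)) * sc
          }
        }
        pair$net_a$backward(ga)
        pair$net_b$backward(gb)
      }
      lr <- stage_lr(config, iter - 1L)
      opt_a$step(lr); opt_b$step(lr)
      hist_rows[[iter]] <- data.frame(iter = iter, l_sup = l_sup, lr = lr)
    }
    hist <- do.call(rbind, hist_rows)
  })
  list(pair = pair, history = hist)
}

within_seed_cfg <- function(cfg, seed) { cfg$seed <- as.integer(seed); cfg }

#' Build training chunks for the 3D stage
#'
#' Splits the volume into overlapping depth chunks, crops each chunk
#' in-plane at the 3D center of gravity of the coarse lumen masks, and
#' attaches the 2D pseudo labels (as one-hot input channels and
#' supervision targets) plus the ground-truth labels of the chunk's
#' labeled slices.
#'
#' @param volume a [new_volume()].
#' @param coarse_masks binary `D x H x W` coarse lumen masks.
#' @param s2d_canvas integer `D x H x W` pseudo-label canvas (2D-stage
#'   argmax pasted back at the patch windows, background elsewhere).
#' @param labels a [new_label_volume()] (labels read on set A only).
#' @param centroids repaired `D x 2` centroid track (fallback when a
#'   chunk's coarse mask is empty).
#' @param config a [train_config()] with the chunking and patch
#'   parameters.
#' @return list of chunk descriptors for [train_cps_3d()].
#' @export
make_chunks_3d <- function(volume, coarse_masks, s2d_canvas, labels,
                           centroids, config) {
  pieces <- chunk_volume(volume$intensities, config$chunk_depth,
                         config$chunk_overlap)
  hw <- config$patch_size
  lapply(pieces, function(pc) {
    o <- pc$spec$origin; d <- pc$spec$size
    sl <- o:(o + d - 1L)
    q3 <- coarse_masks[sl, , , drop = FALSE]
    cg <- center_of_gravity_3d(q3)
    center <- if (cg$valid) cg$coords else colMeans(centroids[sl, , drop = FALSE])
    cp <- crop_patch_2d(volume$intensities[o, , ], center, hw)
    oi <- cp$spec$origin
    ri <- oi[1]:(oi[1] + hw[1] - 1L); rj <- oi[2]:(oi[2] + hw[2] - 1L)
    img <- pc$chunk[, ri, rj, drop = FALSE]
    s2d <- s2d_canvas[sl, ri, rj, drop = FALSE]
    A <- which(sl %in% labels$labeled_slices)
    list(x = chunk_input(img, s2d), s2d = s2d,
         labeled_in_chunk = A,
         labels_in_chunk = lapply(A, function(i)
           labels$classes[sl[i], ri, rj]),
         unlabeled_in_chunk = setdiff(seq_len(d), A),
         spec = list(origin = o, size = d, window = oi,
                     patch = hw, source = dim(volume$intensities)))
  })
}

#' Full-volume inference through the complete pipeline
#'
#' Runs the trained models end to end: coarse inference and centroid
#' repair, per-slice patch cropping, 2D pair ensemble pseudo labels,
#' depth chunking with pseudo-label input channels, 3D pair ensemble,
#' probability stitching (mean in overlaps) and paste-back into the
#' full-size canvas (background outside the patch windows).
#'
#' @param coarse_net trained coarse network.
#' @param pair2d trained 2D model pair.
#' @param pair3d trained 3D model pair.
#' @param volume a [new_volume()].
#' @param config a [train_config()] carrying `patch_size`, `chunk_depth`,
#'   `chunk_overlap` and `tau`.
#' @return list with `labels` (predicted [new_label_volume()], all slices
#'   marked labeled), `centroids`, and `s2d_canvas`.
#' @export
segment_volume <- function(coarse_net, pair2d, pair3d, volume, config) {
  dims <- dim(volume$intensities)
  D <- dims[1]; hw <- config$patch_size
  ic <- infer_coarse(coarse_net, volume, tau = config$tau)
  # 2D stage: per-slice patches and ensemble pseudo labels
  s2d_canvas <- array(0L, dim = dims)
  specs <- vector("list", D)
  for (k in seq_len(D)) {
    cp <- crop_patch_2d(volume$intensities[k, , ], ic$centroids[k, ], hw)
    specs[[k]] <- cp$spec
    p <- pair_predict(pair2d, array(cp$patch, dim = c(1L, hw)))
    s2d_canvas[k, , ] <- paste_patch_2d(matrix(0L, dims[2], dims[3]),
                                        argmax_map(p), cp$spec)
  }
  # 3D stage on chunks; accumulate probabilities on the full canvas
  d3 <- min(config$chunk_depth, D)
  ov <- min(config$chunk_overlap, d3 - 1L)
  pieces <- chunk_volume(volume$intensities, d3, ov)
  acc <- array(0, dim = c(3L, dims))
  cnt <- array(0L, dim = dims)
  for (pc in pieces) {
    o <- pc$spec$origin; dd <- pc$spec$size
    sl <- o:(o + dd - 1L)
    q3 <- ic$masks[sl, , , drop = FALSE]
    cg <- center_of_gravity_3d(q3)
    center <- if (cg$valid) cg$coords
      else colMeans(ic$centroids[sl, , drop = FALSE])
    cp <- crop_patch_2d(volume$intensities[o, , ], center, hw)
    oi <- cp$spec$origin
    ri <- oi[1]:(oi[1] + hw[1] - 1L); rj <- oi[2]:(oi[2] + hw[2] - 1L)
    img <- pc$chunk[, ri, rj, drop = FALSE]
    s2 <- s2d_canvas[sl, ri, rj, drop = FALSE]
    p3 <- pair_predict(pair3d, chunk_input(img, s2))
    acc[, sl, ri, rj] <- acc[, sl, ri, rj] + p3
    cnt[sl, ri, rj] <- cnt[sl, ri, rj] + 1L
  }
  classes <- array(0L, dim = dims)
  covered <- cnt > 0L
  # normalise and argmax on covered voxels
  for (k in seq_len(D)) {
    ck <- cnt[k, , ]
    if (!any(ck > 0L)) next
    pk <- acc[, k, , , drop = FALSE]
    pm <- matrix(pk, nrow = 3L)
    cov <- which(ck > 0L)
    pm_cov <- sweep(pm[, cov, drop = FALSE], 2, as.numeric(ck)[cov], "/")
    lab <- max.col(t(pm_cov), ties.method = "first") - 1L
    sl_cls <- matrix(0L, dims[2], dims[3])
    sl_cls[cov] <- lab
    classes[k, , ] <- sl_cls
  }
  list(labels = new_label_volume(classes, seq_len(D)),
       centroids = ic$centroids, s2d_canvas = s2d_canvas,
       coarse = ic)
}

#' Train the full coarse-to-fine pipeline on one partially labeled volume
#'
#' Orchestrates every stage: coarse dual-task training on the labeled
#' slices, coarse inference and centroid repair, per-slice patch cropping,
#' 2D cross-pseudo supervision over labeled and unlabeled patches,
#' pseudo-label canvas construction, 3D chunk assembly and 3D
#' cross-pseudo supervision.
#'
#' @param volume a [new_volume()].
#' @param labels a [new_label_volume()] (classes read on set A only).
#' @param configs list with `coarse`, `cps2d`, `cps3d` [train_config()]s
#'   and `nets` (list with `coarse`, `unet2d`, `unet3d` [net_config()]s).
#' @return list with the three stage results, the centroid track and the
#'   pseudo-label canvas.
#' @export
train_jcps <- function(volume, labels, configs) {
  res_c <- train_coarse(volume, labels, configs$nets$coarse,
                        configs$coarse)
  ic <- infer_coarse(res_c$net, volume, tau = configs$coarse$tau)
  dims <- dim(volume$intensities)
  hw <- configs$cps2d$patch_size
  patches <- vector("list", dims[1])
  specs <- vector("list", dims[1])
  for (k in seq_len(dims[1])) {
    cp <- crop_patch_2d(volume$intensities[k, , ], ic$centroids[k, ], hw)
    patches[[k]] <- cp$patch
    specs[[k]] <- cp$spec
  }
  A <- labels$labeled_slices
  lab_patches <- lapply(A, function(k) {
    o <- specs[[k]]$origin
    labels$classes[k, o[1]:(o[1] + hw[1] - 1L),
                   o[2]:(o[2] + hw[2] - 1L)]
  })
  res_2d <- train_cps_2d(patches, A, lab_patches, configs$nets$unet2d,
                         configs$cps2d)
  s2d_canvas <- array(0L, dim = dims)
  for (k in seq_len(dims[1]))
    s2d_canvas[k, , ] <- paste_patch_2d(matrix(0L, dims[2], dims[3]),
                                        res_2d$s2d[[k]], specs[[k]])
  chunks <- make_chunks_3d(volume, ic$masks, s2d_canvas, labels,
                           ic$centroids, configs$cps3d)
  res_3d <- train_cps_3d(chunks, configs$nets$unet3d, configs$cps3d)
  list(coarse = res_c, cps2d = res_2d, cps3d = res_3d,
       centroids = ic$centroids, s2d_canvas = s2d_canvas,
       configs = configs)
}

#' Semi-supervised gain study on the default phantom
#'
#' For each seed, generates the default phantom study volume (40 slices of
#' 64 x 64, 20% labeled), trains the coarse stage once, and compares three
#' method tiers on the held-out (unlabeled) slices by wall-region Dice:
#' a single supervised U-Net trained on the labeled patches alone, the 2D
#' cross-pseudo-supervision pair (its ensemble pseudo labels), and the
#' full joint 2D-3D pipeline (the stitched 3D-stage output).
#'
#' @param seeds integer vector of study seeds.
#' @param iterations named vector with `coarse`, `fine2d`, `cps3d`
#'   iteration counts (the supervised baseline and the 2D pair both train
#'   for `fine2d` iterations under identical schedules).
#' @param patch in-plane patch side.
#' @param chunk_depth,chunk_overlap depth chunking of the 3D stage.
#' @param lr3d initial learning rate of the 3D stage (the desk-scale
#'   iteration budget favours a slightly larger step than the full-scale
#'   recipe).
#' @param phantom_args extra arguments passed to [phantom_config()].
#' @return data frame with one row per seed and columns `dice_unet`,
#'   `dice_cps2d`, `dice_jcps` plus the mean centroid error of the coarse
#'   stage.
#' @export
semi_supervised_study <- function(seeds = 1:3,
                                  iterations = c(coarse = 200L,
                                                 fine2d = 400L,
                                                 cps3d = 500L),
                                  patch = 32L, chunk_depth = 8L,
                                  chunk_overlap = 4L, lr3d = 0.02,
                                  phantom_args = list()) {
  rows <- lapply(seeds, function(seed) {
    seed <- as.integer(seed)
    ph <- do.call(phantom_config, c(list(seed = seed), phantom_args))
    gen <- generate_phantom(ph)
    D <- ph$depth
    held <- setdiff(seq_len(D), gen$labels$labeled_slices)
    nets <- list(
      coarse = net_config(num_classes = 2L, seed = seed + 11L),
      unet2d = net_config(num_classes = 3L, seed = seed + 21L),
      unet3d = net_config(in_channels = 3L, num_classes = 3L, dims = 3L,
                          seed = seed + 31L))
    res_c <- train_coarse(gen$volume, gen$labels, nets$coarse,
                          train_config("coarse",
                                       iterations = iterations[["coarse"]],
                                       batch_size = 4L,
                                       seed = seed + 101L))
    ic <- infer_coarse(res_c$net, gen$volume)
    cerr <- mean(sqrt(rowSums((ic$centroids - gen$truth$centers)^2)))
    hw <- c(patch, patch)
    dims <- dim(gen$volume$intensities)
    patches <- vector("list", D); specs <- vector("list", D)
    for (k in seq_len(D)) {
      cp <- crop_patch_2d(gen$volume$intensities[k, , ],
                          ic$centroids[k, ], hw)
      patches[[k]] <- cp$patch; specs[[k]] <- cp$spec
    }
    A <- gen$labels$labeled_slices
    truth_patch <- function(k) {
      o <- specs[[k]]$origin
      gen$labels$classes[k, o[1]:(o[1] + hw[1] - 1L),
                         o[2]:(o[2] + hw[2] - 1L)]
    }
    lp <- lapply(A, truth_patch)
    cfg2 <- train_config("cps2d", iterations = iterations[["fine2d"]],
                         patch_size = hw, seed = seed + 201L)
    res_u <- train_unet_supervised(patches, A, lp, nets$unet2d, cfg2)
    dice_unet <- mean(vapply(held, function(k) {
      p <- res_u$net$forward(array(patches[[k]], dim = c(1L, hw)),
                             train = FALSE)
      dice(argmax_map(p) == 2L, truth_patch(k) == 2L)
    }, numeric(1)))
    res_2 <- train_cps_2d(patches, A, lp, nets$unet2d, cfg2)
    dice_cps2d <- mean(vapply(held, function(k)
      dice(res_2$s2d[[k]] == 2L, truth_patch(k) == 2L), numeric(1)))
    canvas <- array(0L, dim = dims)
    for (k in seq_len(D))
      canvas[k, , ] <- paste_patch_2d(matrix(0L, dims[2], dims[3]),
                                      res_2$s2d[[k]], specs[[k]])
    cfg3 <- train_config("cps3d", iterations = iterations[["cps3d"]],
                         batch_size = 2L, labeled_batch_size = 1L,
                         lr = lr3d,
                         patch_size = hw, chunk_depth = chunk_depth,
                         chunk_overlap = chunk_overlap,
                         seed = seed + 301L)
    chunks <- make_chunks_3d(gen$volume, ic$masks, canvas, gen$labels,
                             ic$centroids, cfg3)
    res_3 <- train_cps_3d(chunks, nets$unet3d, cfg3)
    seg <- segment_volume(res_c$net, res_2$pair, res_3$pair, gen$volume,
                          cfg3)
    dice_jcps <- mean(vapply(held, function(k)
      dice(seg$labels$classes[k, , ] == 2L,
           gen$labels$classes[k, , ] == 2L), numeric(1)))
    m <- evaluate_case(seg$labels, gen$labels, slices = held)
    data.frame(seed = seed, dice_unet = dice_unet,
               dice_cps2d = dice_cps2d, dice_jcps = dice_jcps,
               centroid_error = cerr, n_heldout = length(held),
               DSC = m$DSC, DSCL = m$DSCL, DSCW = m$DSCW, Lad = m$Lad,
               Wad = m$Wad, Nwid = m$Nwid, Hdol = m$Hdol, Hdow = m$Hdow,
               QS = m$QS)
  })
  do.call(rbind, rows)
}
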