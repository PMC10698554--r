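#' Network configuration
#'
#' Size-configurable contracts for the segmentation networks, so that
#' desk-scale tests can run tiny instances of the same architectures used
#' at full scale.
#'
#' @param in_channels input channels (1 for gray images; the 3D fine
#'   network adds one-hot pseudo-label channels).
#' @param base_channels width of the first encoder level; deeper levels
#'   double it. The fine networks follow the halved-width U-Net recipe.
#' @param depth number of encoder levels (pooling steps).
#' @param num_classes output classes `C >= 2`.
#' @param dims 2 or 3.
#' @param aspp_rates dilation rates of the parallel atrous branches of the
#'   coarse network's spatial pyramid.
#' @param seed integer seed for parameter initialisation.
#' @return list of class `net_config`.
#' @export
net_config <- function(in_channels = 1L, base_channels = 4L, depth = 2L,
                       num_classes = 2L, dims = 2L,
                       aspp_rates = c(1L, 2L, 4L), seed = 1L) {
  stopifnot(base_channels >= 1L, depth >= 1L, num_classes >= 2L,
            dims %in% c(2L, 3L))
  structure(list(in_channels = as.integer(in_channels),
                 base_channels = as.integer(base_channels),
                 depth = as.integer(depth),
                 num_classes = as.integer(num_classes),
                 dims = as.integer(dims),
                 aspp_rates = as.integer(aspp_rates),
                 seed = as.integer(seed)),
            class = "net_config")
}

# global-average-pooling branch of the spatial pyramid: GAP -> linear ->
# broadcast back over the spatial grid
layer_gap_linear <- function(cin, cout) {
  l <- new_layer("gap")
  l$params <- list(W = he_init(cout, cin), b = numeric(cout))
  l$grads <- list(W = matrix(0, cout, cin), b = numeric(cout))
  l$fwd <- function(x, train = TRUE) {
    d <- dim(x)
    v <- rowMeans(matrix(x, nrow = d[1]))
    z <- as.numeric(l$params$W %*% v + l$params$b)
    if (train) { l$v <- v; l$shape <- d }
    array(rep(z, times = prod(d[-1])), dim = c(length(z), d[-1]))
  }
  l$bwd <- function(g) {
    d <- l$shape
    gz <- rowSums(matrix(g, nrow = dim(g)[1]))
    l$grads$W <- l$grads$W + gz %*% t(l$v)
    l$grads$b <- l$grads$b + gz
    dv <- as.numeric(crossprod(l$params$W, gz)) / prod(d[-1])
    array(rep(dv, times = prod(d[-1])), dim = d)
  }
  l
}

concat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, dim = c(da[1] + db[1], da[-1]))
  idx_a <- seq_len(da[1])
  if (length(da) == 3L) {
    out[idx_a, , ] <- a; out[-idx_a, , ] <- b
  } else {
    out[idx_a, , , ] <- a; out[-idx_a, , , ] <- b
  }
  out
}

split_channels <- function(g, c_first) {
  if (length(dim(g)) == 3L)
    list(g[seq_len(c_first), , , drop = FALSE],
         g[-seq_len(c_first), , , drop = FALSE])
  else
    list(g[seq_len(c_first), , , , drop = FALSE],
         g[-seq_len(c_first), , , , drop = FALSE])
}

#' Build a U-Net segmentation network
#'
#' A contracting/expansive convolutional network with skip connections:
#' each level is two Conv-Norm-ReLU composites, downsampling by 2x max
#' pooling and upsampling by nearest-neighbor interpolation; the final 1x1
#' convolution and channel softmax emit a simplex-normalised confidence
#' map. Works in 2D and 3D according to `config$dims`.
#'
#' @param config a [net_config()].
#' @return a network object (environment) with `forward(x, train)`
#'   returning the `C x ...` probability array, `backward(gp)` for the
#'   gradient of a loss with respect to the probabilities, and
#'   `layers_flat` for optimizers.
#' @export
build_unet <- function(config) {
  stopifnot(inherits(config, "net_config"))
  dims <- config$dims
  b <- config$base_channels
  L <- config$depth
  ch <- b * 2^(seq_len(L) - 1L)
  chb <- b * 2^L
  net <- new.env(parent = emptyenv())
  net$config <- config
  with_seed(config$seed, {
    net$enc <- lapply(seq_len(L), function(l)
      conv_block(if (l == 1L) config$in_channels else ch[l - 1L],
                 ch[l], dims))
    net$pool <- lapply(seq_len(L), function(l) layer_maxpool(dims))
    net$bott <- conv_block(ch[L], chb, dims)
    net$up <- lapply(seq_len(L), function(l) layer_upsample(dims))
    net$dec <- lapply(seq_len(L), function(l) {
      upch <- if (l == L) chb else ch[l + 1L]
      conv_block(ch[l] + upch, ch[l], dims)
    })
    net$head <- layer_conv(ch[1L], config$num_classes, k = 1L, dims = dims)
    net$smax <- layer_softmax()
  })
  net$layers_flat <- collect_layers(list(net$enc, net$pool, net$bott,
                                         net$up, net$dec, net$head,
                                         net$smax))
  net$forward <- function(x, train = TRUE) {
    sp <- dim(x)[-1]
    if (any(sp %% 2^L != 0) || any(sp < 2^L))
      stop("input spatial dims must be multiples of 2^depth = ", 2^L,
           call. = FALSE)
    skips <- vector("list", L)
    h <- x
    for (l in seq_len(L)) {
      h <- seq_forward(net$enc[[l]], h, train)
      skips[[l]] <- h
      h <- net$pool[[l]]$fwd(h, train)
    }
    h <- seq_forward(net$bott, h, train)
    for (l in rev(seq_len(L))) {
      u <- net$up[[l]]$fwd(h, train)
      h <- concat_channels(skips[[l]], u)
      h <- seq_forward(net$dec[[l]], h, train)
    }
    logits <- net$head$fwd(h, train)
    net$smax$fwd(logits, train)
  }
  net$backward <- function(gp) {
    g <- net$smax$bwd(gp)
    g <- net$head$bwd(g)
    gskip <- vector("list", L)
    for (l in seq_len(L)) {
      g <- seq_backward(net$dec[[l]], g)
      sp <- split_channels(g, ch[l])
      gskip[[l]] <- sp[[1]]
      g <- net$up[[l]]$bwd(sp[[2]])
    }
    g <- seq_backward(net$bott, g)
    for (l in rev(seq_len(L))) {
      g <- net$pool[[l]]$bwd(g)
      g <- g + gskip[[l]]
      g <- seq_backward(net$enc[[l]], g)
    }
    invisible(g)
  }
  net
}

#' Build the dual-head coarse segmentation network
#'
#' An encoder / atrous-spatial-pyramid / decoder network in the
#' DeepLab-style: two pooling levels (downsampling factor 4), a pyramid of
#' parallel dilated convolutions plus a global-pooling branch on the
#' bottleneck features, and a decoder that upsamples by factor 4 and fuses
#' low-level features. Two parallel output heads emit, at full input
#' resolution, (a) the per-pixel class probabilities (softmax) and (b) a
#' signed-distance regression passed through `tanh` (normalised distance
#' units). Inputs whose sides are not multiples of 4 are padded internally
#' and the outputs cropped back.
#'
#' @param config a [net_config()] with `dims = 2`.
#' @return a network object with `forward(x, train)` returning
#'   `list(probs, sdf)` and `backward(gprobs, gsdf)`.
#' @export
build_coarse_net <- function(config) {
  stopifnot(inherits(config, "net_config"), config$dims == 2L)
  b <- config$base_channels
  rates <- config$aspp_rates
  nb <- length(rates) + 2L  # dilated branches + 1x1 branch + GAP branch
  net <- new.env(parent = emptyenv())
  net$config <- config
  with_seed(config$seed, {
    net$enc1 <- conv_block(config$in_channels, b)
    net$pool1 <- layer_maxpool()
    net$enc2 <- conv_block(b, 2L * b)
    net$pool2 <- layer_maxpool()
    net$enc3 <- conv_block(2L * b, 4L * b)
    net$aspp <- c(list(layer_conv(4L * b, b, k = 1L)),
                  lapply(rates, function(r) layer_conv(4L * b, b, dil = r)),
                  list(layer_gap_linear(4L * b, b)))
    net$fuse <- list(layer_conv(nb * b, 2L * b, k = 1L), layer_norm(2L * b),
                     layer_relu())
    net$up4 <- layer_upsample(factor = 4L)
    net$lowlevel <- layer_conv(b, b, k = 1L)
    net$decoder <- conv_block(3L * b, 2L * b)
    net$head_cls <- layer_conv(2L * b, config$num_classes, k = 1L)
    net$smax <- layer_softmax()
    net$head_sdf <- layer_conv(2L * b, 1L, k = 1L)
    net$tanh <- layer_tanh_scale(1)
  })
  net$layers_flat <- collect_layers(list(
    net$enc1, net$pool1, net$enc2, net$pool2, net$enc3, net$aspp, net$fuse,
    net$up4, net$lowlevel, net$decoder, net$head_cls, net$smax,
    net$head_sdf, net$tanh))
  net$forward <- function(x, train = TRUE) {
    d <- dim(x)
    hw <- d[-1]
    pad <- (4L - hw %% 4L) %% 4L
    net$pad <- pad; net$hw <- hw
    if (any(pad > 0L)) {
      xp <- array(0, dim = c(d[1], hw + pad))
      xp[, seq_len(hw[1]), seq_len(hw[2])] <- x
      x <- xp
    }
    e1 <- seq_forward(net$enc1, x, train)
    h <- net$pool1$fwd(e1, train)
    h <- seq_forward(net$enc2, h, train)
    h <- net$pool2$fwd(h, train)
    h <- seq_forward(net$enc3, h, train)
    branches <- lapply(net$aspp, function(l) l$fwd(h, train))
    a <- branches[[1]]
    for (i in 2:length(branches)) a <- concat_channels(a, branches[[i]])
    a <- seq_forward(net$fuse, a, train)
    u <- net$up4$fwd(a, train)
    low <- net$lowlevel$fwd(e1, train)
    hcat <- concat_channels(low, u)
    dec <- seq_forward(net$decoder, hcat, train)
    probs <- net$smax$fwd(net$head_cls$fwd(dec, train), train)
    sdf <- net$tanh$fwd(net$head_sdf$fwd(dec, train), train)
    i1 <- seq_len(hw[1]); i2 <- seq_len(hw[2])
    list(probs = probs[, i1, i2, drop = FALSE],
         sdf = matrix(sdf[1, i1, i2], hw[1], hw[2]))
  }
  net$backward <- function(gprobs, gsdf) {
    b <- net$config$base_channels
    hw <- net$hw; pad <- net$pad
    full <- hw + pad
    gp <- array(0, dim = c(dim(gprobs)[1], full))
    gp[, seq_len(hw[1]), seq_len(hw[2])] <- gprobs
    gs <- array(0, dim = c(1L, full))
    gs[1, seq_len(hw[1]), seq_len(hw[2])] <- gsdf
    gdec <- net$head_cls$bwd(net$smax$bwd(gp)) +
      net$head_sdf$bwd(net$tanh$bwd(gs))
    g <- seq_backward(net$decoder, gdec)
    sp <- split_channels(g, b)
    ge1_low <- net$lowlevel$bwd(sp[[1]])
    ga <- net$up4$bwd(sp[[2]])
    ga <- seq_backward(net$fuse, ga)
    # split pyramid gradient back into the parallel branches
    gh <- NULL
    offset <- 0L
    for (l in net$aspp) {
      gb <- ga[offset + seq_len(b), , , drop = FALSE]
      offset <- offset + b
      gin <- l$bwd(gb)
      gh <- if (is.null(gh)) gin else gh + gin
    }
    g <- seq_backward(net$enc3, gh)
    g <- net$pool2$bwd(g)
    g <- seq_backward(net$enc2, g)
    g <- net$pool1$bwd(g)
    g <- g + ge1_low
    g <- seq_backward(net$enc1, g)
    invisible(g)
  }
  net
}

#' Build a pair of identically structured, differently initialised networks
#'
#' The two members of a cross-pseudo-supervision pair share the same
#' architecture but start from independent random parameters.
#'
#' @param config a [net_config()].
#' @param seed_a,seed_b initialisation seeds for the two members.
#' @return list with `net_a` and `net_b`.
#' @export
build_model_pair <- function(config, seed_a, seed_b) {
  ca <- config; ca$seed <- as.integer(seed_a)
  cb <- config; cb$seed <- as.integer(seed_b)
  list(net_a = build_unet(ca), net_b = build_unet(cb))
}

#' Checksum of a network's parameters
#'
#' Deterministic builds with the same seed produce identical checksums.
#'
#' @param net a network object.
#' @return scalar sum of all parameter values.
#' @export
param_checksum <- function(net) sum(net_param_vector(net))
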