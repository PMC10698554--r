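# Minimal CNN layer engine with reverse-mode gradients.
#
# Feature maps are plain R arrays with the channel axis first
# (C x H x W in 2D, C x D x H x W in 3D); convolutions are stride-1 with
# "same" padding, computed as one BLAS matmul over an im2col matrix from
# the C++ kernels. Each layer is an environment with $fwd(x, train),
# $bwd(g) (accumulating parameter gradients), and named $params / $grads
# lists. Spatial down/upsampling uses 2x max pooling and nearest-neighbor
# upsampling. Normalisation uses per-sample spatial statistics, which keeps
# every forward pass deterministic and batch-size independent.

new_layer <- function(type) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  e$params <- list()
  e$grads <- list()
  e
}

he_init <- function(nrow, ncol) {
  matrix(stats::rnorm(nrow * ncol, sd = sqrt(2 / ncol)), nrow, ncol)
}

layer_conv <- function(cin, cout, k = 3L, dil = 1L, dims = 2L) {
  l <- new_layer("conv")
  K <- cin * k^dims
  l$params <- list(W = he_init(cout, K), b = numeric(cout))
  l$grads <- list(W = matrix(0, cout, K), b = numeric(cout))
  l$cin <- cin; l$cout <- cout; l$k <- as.integer(k)
  l$dil <- as.integer(dil); l$dims <- dims
  l$fwd <- function(x, train = TRUE) {
    d <- dim(x)
    l$shape <- d
    if (dims == 2L) {
      col <- im2col2d_cpp(as.numeric(x), d[1], d[2], d[3], l$k, l$k, l$dil)
      if (train) l$col <- col
      y <- l$params$W %*% col + l$params$b
    } else {
      # fused direct convolution: no im2col intermediate in 3D
      if (train) l$x <- as.numeric(x)
      y <- conv3d_fwd_cpp(as.numeric(x), l$params$W, l$params$b,
                          d[1], d[2], d[3], d[4], l$k)
    }
    array(y, dim = c(l$cout, d[-1]))
  }
  l$bwd <- function(g) {
    d <- l$shape
    if (dims == 2L) {
      gm <- matrix(g, nrow = l$cout)
      l$grads$W <- l$grads$W + tcrossprod(gm, l$col)
      l$grads$b <- l$grads$b + rowSums(gm)
      dcol <- crossprod(l$params$W, gm)
      dx <- col2im2d_cpp(dcol, d[1], d[2], d[3], l$k, l$k, l$dil)
    } else {
      r <- conv3d_bwd_cpp(l$x, l$params$W, as.numeric(g),
                          d[1], d[2], d[3], d[4], l$k)
      l$grads$W <- l$grads$W + r$dW
      l$grads$b <- l$grads$b + r$db
      dx <- r$dx
    }
    array(dx, dim = d)
  }
  l
}

layer_norm <- function(c) {
  l <- new_layer("norm")
  l$params <- list(gamma = rep(1, c), beta = numeric(c))
  l$grads <- list(gamma = numeric(c), beta = numeric(c))
  l$eps <- 1e-5
  l$fwd <- function(x, train = TRUE) {
    d <- dim(x)
    xm <- matrix(x, nrow = d[1])
    mu <- rowMeans(xm)
    va <- rowMeans(xm^2) - mu^2
    sd_ <- sqrt(va + l$eps)
    xhat <- (xm - mu) / sd_
    if (train) { l$xhat <- xhat; l$sd <- sd_; l$shape <- d }
    array(xhat * l$params$gamma + l$params$beta, dim = d)
  }
  l$bwd <- function(g) {
    d <- l$shape
    gm <- matrix(g, nrow = d[1])
    n <- ncol(gm)
    l$grads$gamma <- l$grads$gamma + rowSums(gm * l$xhat)
    l$grads$beta <- l$grads$beta + rowSums(gm)
    dxhat <- gm * l$params$gamma
    dx <- (dxhat - rowMeans(dxhat) -
             l$xhat * rowMeans(dxhat * l$xhat)) / l$sd
    array(dx, dim = d)
  }
  l
}

layer_relu <- function() {
  l <- new_layer("relu")
  l$fwd <- function(x, train = TRUE) {
    if (train) l$mask <- x > 0
    x * (x > 0)
  }
  l$bwd <- function(g) g * l$mask
  l
}

layer_maxpool <- function(dims = 2L) {
  l <- new_layer("maxpool")
  l$dims <- dims
  l$fwd <- function(x, train = TRUE) {
    d <- dim(x)
    r <- if (dims == 2L) maxpool2d_cpp(as.numeric(x), d[1], d[2], d[3])
    else maxpool3d_cpp(as.numeric(x), d[1], d[2], d[3], d[4])
    if (train) { l$idx <- r$idx; l$shape <- d }
    array(r$out, dim = c(d[1], d[-1] %/% 2L))
  }
  l$bwd <- function(g) {
    dx <- numeric(prod(l$shape))
    gv <- as.numeric(g)
    # argmax indices are unique per output cell within a pooling window
    # but windows never overlap, so plain assignment-with-accumulate works
    for (i in seq_along(gv)) dx[l$idx[i] + 1L] <- dx[l$idx[i] + 1L] + gv[i]
    array(dx, dim = l$shape)
  }
  l
}

layer_upsample <- function(dims = 2L, factor = 2L) {
  l <- new_layer("upsample")
  l$f <- as.integer(factor); l$dims <- dims
  l$fwd <- function(x, train = TRUE) {
    d <- dim(x)
    if (train) l$shape <- d
    f <- l$f
    if (dims == 2L)
      x[, rep(seq_len(d[2]), each = f), rep(seq_len(d[3]), each = f),
        drop = FALSE]
    else
      x[, rep(seq_len(d[2]), each = f), rep(seq_len(d[3]), each = f),
        rep(seq_len(d[4]), each = f), drop = FALSE]
  }
  l$bwd <- function(g) {
    d <- l$shape; f <- l$f
    if (dims == 2L) {
      gi <- array(g, dim = c(d[1], f, d[2], f, d[3]))
      array(colSums(aperm(gi, c(2, 4, 1, 3, 5)), dims = 2), dim = d)
    } else {
      gi <- array(g, dim = c(d[1], f, d[2], f, d[3], f, d[4]))
      array(colSums(aperm(gi, c(2, 4, 6, 1, 3, 5, 7)), dims = 3), dim = d)
    }
  }
  l
}

layer_softmax <- function() {
  l <- new_layer("softmax")
  l$fwd <- function(x, train = TRUE) {
    d <- dim(x)
    xm <- matrix(x, nrow = d[1])
    mx <- xm[1, ]
    for (cc in seq_len(d[1])[-1]) mx <- pmax(mx, xm[cc, ])
    e <- exp(sweep(xm, 2, mx))
    p <- sweep(e, 2, colSums(e), "/")
    if (train) { l$p <- p; l$shape <- d }
    array(p, dim = d)
  }
  l$bwd <- function(g) {
    gm <- matrix(g, nrow = l$shape[1])
    dot <- colSums(gm * l$p)
    array(l$p * sweep(gm, 2, dot), dim = l$shape)
  }
  l
}

layer_tanh_scale <- function(scale = 1) {
  l <- new_layer("tanh")
  l$scale <- scale
  l$fwd <- function(x, train = TRUE) {
    th <- tanh(x)
    if (train) l$th <- th
    l$scale * th
  }
  l$bwd <- function(g) g * l$scale * (1 - l$th^2)
  l
}

seq_forward <- function(layers, x, train = TRUE) {
  for (l in layers) x <- l$fwd(x, train)
  x
}

seq_backward <- function(layers, g) {
  for (l in rev(layers)) g <- l$bwd(g)
  g
}

conv_block <- function(cin, cout, dims = 2L) {
  list(layer_conv(cin, cout, dims = dims), layer_norm(cout), layer_relu(),
       layer_conv(cout, cout, dims = dims), layer_norm(cout), layer_relu())
}

collect_layers <- function(x) {
  if (is.environment(x)) return(list(x))
  unlist(lapply(x, collect_layers), recursive = FALSE)
}

net_param_vector <- function(net) {
  unlist(lapply(net$layers_flat, function(l) unlist(l$params)))
}

zero_grads <- function(net) {
  for (l in net$layers_flat)
    l$grads <- lapply(l$grads, function(g) g * 0)
  invisible(net)
}

# ---- optimizers -----------------------------------------------------------

make_optimizer <- function(net, type = c("sgd", "adam"), lr = 0.01,
                           momentum = 0.9, weight_decay = 1e-4,
                           beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                           extra = NULL) {
  type <- match.arg(type)
  opt <- new.env(parent = emptyenv())
  opt$type <- type; opt$lr <- lr; opt$t <- 0L
  opt$momentum <- momentum; opt$weight_decay <- weight_decay
  opt$beta1 <- beta1; opt$beta2 <- beta2; opt$eps <- eps
  opt$state <- lapply(net$layers_flat, function(l)
    lapply(l$params, function(p)
      list(m = p * 0, v = p * 0)))
  opt$extra <- extra  # optional list of extra scalar-parameter envs
  opt$step <- function(lr = opt$lr) {
    opt$t <- opt$t + 1L
    layers <- net$layers_flat
    for (i in seq_along(layers)) {
      l <- layers[[i]]
      for (nm in names(l$params)) {
        g <- l$grads[[nm]]
        if (opt$weight_decay > 0 && nm != "b" && nm != "beta")
          g <- g + opt$weight_decay * l$params[[nm]]
        st <- opt$state[[i]][[nm]]
        if (opt$type == "sgd") {
          st$m <- opt$momentum * st$m + g
          l$params[[nm]] <- l$params[[nm]] - lr * st$m
        } else {
          st$m <- opt$beta1 * st$m + (1 - opt$beta1) * g
          st$v <- opt$beta2 * st$v + (1 - opt$beta2) * g^2
          mhat <- st$m / (1 - opt$beta1^opt$t)
          vhat <- st$v / (1 - opt$beta2^opt$t)
          l$params[[nm]] <- l$params[[nm]] -
            lr * mhat / (sqrt(vhat) + opt$eps)
        }
        opt$state[[i]][[nm]] <- st
      }
    }
    invisible(opt)
  }
  opt
}

# learning-rate schedules
lr_step <- function(lr0, iter, every = 1000L, factor = 0.9) {
  lr0 * factor^(iter %/% every)
}

lr_poly <- function(lr0, iter, max_iter, power = 0.9) {
  lr0 * (1 - iter / max_iter)^power
}
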