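#' @title Loss functions for the coarse and fine segmentation stages
#' @description
#' All losses are pure functions of predictions and targets. Confidence
#' maps are arrays with the class channel first (`C x h x w` in 2D,
#' `C x d x h x w` in 3D), simplex-normalised at every pixel. Hard labels
#' take values in `0:(C-1)`. Probabilities are clipped to
#' `[1e-7, 1 - 1e-7]` before any logarithm, and pseudo-label targets are
#' constants (no gradient flows through an argmax).
#' @name jcps-losses
NULL

.P_CLIP <- 1e-7
.EPS <- 1e-6

clip_prob <- function(p) pmin(pmax(p, .P_CLIP), 1 - .P_CLIP)

#' Focal Tversky loss
#'
#' `(1 - T)^gamma` where the Tversky index
#' `T = |P.Y| / (|P.Y| + alpha |P(1-Y)| + beta |(1-P)Y|)` uses soft set
#' sizes; `alpha` and `beta` weight false positives and false negatives and
#' `gamma` is the focal exponent. Defaults follow the training recipe
#' (`alpha = 0.7, beta = 0.3, gamma = 0.7`).
#'
#' @param p predicted foreground probability map, entries in \[0, 1\].
#' @param y binary target of the same shape.
#' @param alpha,beta,gamma positive weights.
#' @return scalar loss in \[0, 1\].
#' @export
focal_tversky_loss <- function(p, y, alpha = 0.7, beta = 0.3, gamma = 0.7) {
  if (length(p) != length(y) ||
      (!is.null(dim(p)) && !is.null(dim(y)) && !all(dim(p) == dim(y))))
    stop("shape mismatch between p and y", call. = FALSE)
  stopifnot(alpha > 0, beta > 0, gamma > 0)
  tp <- sum(p * y)
  fp <- sum(p * (1 - y))
  fn <- sum((1 - p) * y)
  ti <- tp / (tp + alpha * fp + beta * fn + .EPS)
  (1 - ti)^gamma
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# gradient of focal_tversky_loss w.r.t. p
focal_tversky_grad <- function(p, y, alpha = 0.7, beta = 0.3, gamma = 0.7) {
  tp <- sum(p * y)
  fp <- sum(p * (1 - y))
  fn <- sum((1 - p) * y)
  den <- tp + alpha * fp + beta * fn + .EPS
  ti <- tp / den
  # dT/dp = (y*den - tp*(y + alpha*(1-y) - beta*y)) / den^2
  dti <- (y * den - tp * (y + alpha * (1 - y) - beta * y)) / den^2
  -gamma * (1 - ti)^(gamma - 1) * dti
}

#' Mean-squared-error loss on signed distance maps
#'
#' Regression loss of the coarse network's signed-distance head. Targets
#' are expected on the normalised scale produced by
#' [signed_distance_map()] divided by the patch half-diagonal, so values
#' stay in roughly \[-1, 1\].
#'
#' @param pred,target numeric arrays of equal shape.
#' @return scalar mean squared error.
#' @export
sdf_regression_loss <- function(pred, target) {
  if (length(pred) != length(target))
    stop("shape mismatch between pred and target", call. = FALSE)
  mean((pred - target)^2)
}

#' Homoscedastic dual-task weighting
#'
#' Combines the classification and regression losses of the coarse stage
#' with learned task-noise scales:
#' `L = L_FT / sigma1^2 + L_SDF / sigma2^2 + log(sigma1 * sigma2)`.
#' Minimising over the sigmas balances the two tasks during training
#' (stationarity gives `sigma^2 = 2 L`).
#'
#' @param l_ft,l_sdf scalar task losses.
#' @param sigma1,sigma2 positive noise scales.
#' @return scalar combined loss.
#' @export
dual_task_loss <- function(l_ft, l_sdf, sigma1, sigma2) {
  if (sigma1 <= 0 || sigma2 <= 0)
    stop("sigma1 and sigma2 must be positive", call. = FALSE)
  l_ft / sigma1^2 + l_sdf / sigma2^2 + log(sigma1 * sigma2)
}

# flatten a confidence map to C x N and labels to a vector
flatten_cmap <- function(p) {
  d <- dim(p)
  matrix(p, nrow = d[1])
}

#' Cross-entropy loss against hard labels
#'
#' Pixel-mean of `-log P[true class]`, probabilities clipped before the
#' logarithm.
#'
#' @param labels integer array of class indices in `0:(C-1)` (spatial
#'   shape).
#' @param p confidence map, class channel first, spatial shape matching
#'   `labels`.
#' @return scalar loss.
#' @export
cross_entropy_loss <- function(labels, p) {
  pm <- flatten_cmap(p)
  C <- nrow(pm)
  lv <- as.integer(labels)
  if (length(lv) != ncol(pm))
    stop("shape mismatch between labels and p", call. = FALSE)
  if (any(lv >= C) || any(lv < 0L))
    stop("label values must lie in [0, C)", call. = FALSE)
  picked <- pm[cbind(lv + 1L, seq_along(lv))]
  mean(-log(clip_prob(picked)))
}

# gradient of cross_entropy_loss w.r.t. p (same shape as p)
cross_entropy_grad <- function(labels, p) {
  pm <- flatten_cmap(p)
  lv <- as.integer(labels)
  g <- matrix(0, nrow(pm), ncol(pm))
  idx <- cbind(lv + 1L, seq_along(lv))
  pc <- pm[idx]
  gg <- numeric(length(lv))
  inside <- pc > .P_CLIP & pc < 1 - .P_CLIP
  gg[inside] <- -1 / pc[inside]
  g[idx] <- gg / length(lv)
  array(g, dim = dim(p))
}

#' Multi-class soft Dice loss
#'
#' `1 - mean_c 2 sum(P_c Y_c) / (sum(P_c) + sum(Y_c) + eps)` averaged over
#' the foreground classes `1:(C-1)`.
#'
#' @inheritParams cross_entropy_loss
#' @return scalar loss.
#' @export
dice_loss <- function(labels, p) {
  pm <- flatten_cmap(p)
  C <- nrow(pm)
  lv <- as.integer(labels)
  if (length(lv) != ncol(pm))
    stop("shape mismatch between labels and p", call. = FALSE)
  if (any(lv >= C) || any(lv < 0L))
    stop("label values must lie in [0, C)", call. = FALSE)
  ds <- vapply(seq_len(C - 1L), function(cc) {
    yc <- as.numeric(lv == cc)
    2 * sum(pm[cc + 1L, ] * yc) / (sum(pm[cc + 1L, ]) + sum(yc) + .EPS)
  }, numeric(1))
  1 - mean(ds)
}

dice_grad <- function(labels, p) {
  pm <- flatten_cmap(p)
  C <- nrow(pm)
  lv <- as.integer(labels)
  g <- matrix(0, nrow(pm), ncol(pm))
  for (cc in seq_len(C - 1L)) {
    yc <- as.numeric(lv == cc)
    pc <- pm[cc + 1L, ]
    num <- 2 * sum(pc * yc)
    den <- sum(pc) + sum(yc) + .EPS
    # d(1 - num/den)/dpc = -(2*yc*den - num) / den^2
    g[cc + 1L, ] <- -(2 * yc * den - num) / den^2 / (C - 1L)
  }
  array(g, dim = dim(p))
}

#' Hard pseudo labels from a confidence map
#'
#' Channel-argmax with deterministic tie-breaking (lowest class index
#' wins). The result is used as a supervision target only; no gradient is
#' associated with it.
#'
#' @param p confidence map, class channel first.
#' @return integer array of the spatial shape with values in `0:(C-1)`.
#' @export
argmax_map <- function(p) {
  pm <- flatten_cmap(p)
  lab <- max.col(t(pm), ties.method = "first") - 1L
  array(as.integer(lab), dim = dim(p)[-1])
}

#' Cross-pseudo supervision loss
#'
#' Two networks of a pair supervise each other with their argmax pseudo
#' labels: `lce(argmax P_b, P_a) + lce(argmax P_a, P_b)`. The pseudo-label
#' side of each term is a constant (stop-gradient).
#'
#' @param p_a,p_b confidence maps of equal shape.
#' @return scalar loss.
#' @export
cps_loss <- function(p_a, p_b) {
  if (!all(dim(p_a) == dim(p_b)))
    stop("shape mismatch between p_a and p_b", call. = FALSE)
  cross_entropy_loss(argmax_map(p_b), p_a) +
    cross_entropy_loss(argmax_map(p_a), p_b)
}

#' Pseudo-label supervision loss for the 3D stage
#'
#' On unlabeled slices the 2D-stage pseudo labels supervise both 3D
#' networks with cross-entropy plus Dice:
#' `(1 / (2|B|)) sum_{i in B} sum_m [lce(S2D_i, P3Dm(i)) + ld(S2D_i,
#' P3Dm(i))]`.
#'
#' @param s2d integer `d x h x w` array of 2D pseudo labels for the chunk.
#' @param p3d_pair list of two `C x d x h x w` confidence maps.
#' @param b integer indices (within the chunk) of unlabeled slices.
#' @return scalar loss; 0 when `b` is empty.
#' @export
pseudo_label_supervision_loss <- function(s2d, p3d_pair, b) {
  if (length(b) == 0L) return(0)
  b <- as.integer(b)
  total <- 0
  for (i in b) {
    si <- s2d[i, , ]
    if (anyNA(si))
      stop("missing pseudo label for slice ", i, call. = FALSE)
    for (m in 1:2) {
      pi <- p3d_pair[[m]][, i, , ]
      total <- total + cross_entropy_loss(si, pi) + dice_loss(si, pi)
    }
  }
  total / (2 * length(b))
}

#' Inter-slice continuity loss for the 3D stage
#'
#' Each prediction slice is penalised against the pseudo labels of its
#' neighbors, exploiting the spatial continuity of the vessel:
#' `(1/2) sum_m [ sum_{i=1}^{d-1} lce(S3Dm(i+1), P3Dm(i)) +
#' sum_{i=2}^{d} lce(S3Dm(i-1), P3Dm(i)) ]`,
#' where `S3Dm` is the slicewise argmax of `P3Dm` (stop-gradient).
#'
#' @param p3d_pair list of two `C x d x h x w` confidence maps with depth
#'   at least 2.
#' @return scalar loss.
#' @export
continuity_loss <- function(p3d_pair) {
  d <- dim(p3d_pair[[1]])[2]
  if (d < 2L) stop("continuity loss needs depth >= 2", call. = FALSE)
  total <- 0
  for (m in 1:2) {
    p <- p3d_pair[[m]]
    s <- argmax_map(p)  # d x h x w
    for (i in 1:(d - 1L))
      total <- total + cross_entropy_loss(s[i + 1L, , ], p[, i, , ])
    for (i in 2:d)
      total <- total + cross_entropy_loss(s[i - 1L, , ], p[, i, , ])
  }
  total / 2
}

#' Consistency-weight ramp-up schedule
#'
#' `lambda(t) = exp(-5 (1 - t)^2)` for normalised training progress
#' `t = iteration / max_iteration`, growing from `exp(-5)` to 1 so the
#' consistency losses only gain weight once predictions stabilise.
#'
#' @param t progress in \[0, 1\]; values outside are clamped with a
#'   warning.
#' @return scalar weight.
#' @export
rampup_weight <- function(t) {
  if (any(t < 0 | t > 1)) {
    warning("t clamped to [0, 1]")
    t <- pmin(pmax(t, 0), 1)
  }
  exp(-5 * (1 - t)^2)
}

#' Total 2D fine-stage loss
#'
#' `L2D = L2Ds + lambda0 L2Dcps` with `lambda0 = rampup_weight(t)`.
#'
#' @param sup supervision loss.
#' @param cps cross-pseudo supervision loss.
#' @param t training progress in \[0, 1\].
#' @return scalar.
#' @export
total_loss_2d <- function(sup, cps, t) {
  sup + rampup_weight(t) * cps
}

#' Total 3D fine-stage loss
#'
#' `L3D = L3Ds + lambda1 L3Dcps + lambda2 L3Dps + lambda3 L3Dcs` with
#' `lambda1 = lambda3 = rampup_weight(t)` and `lambda2 = 1`.
#'
#' @param sup,cps,ps,cs component losses.
#' @param t training progress in \[0, 1\].
#' @param lambda2 pseudo-label weight, fixed at 1.
#' @return scalar.
#' @export
total_loss_3d <- function(sup, cps, ps, cs, t, lambda2 = 1) {
  lam <- rampup_weight(t)
  sup + lam * cps + lambda2 * ps + lam * cs
}
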