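test_that("focal Tversky loss reproduces its closed forms", {
  y <- matrix(0, 6, 6); y[2:4, 2:4] <- 1
  expect_lt(focal_tversky_loss(y, y), 1e-4)          # perfect overlap
  p_disj <- matrix(0, 6, 6); p_disj[5:6, 5:6] <- 1
  expect_gt(focal_tversky_loss(p_disj, y), 0.999)    # disjoint
  # hand-worked case: |P.Y| = 2, |P-Y| = 1, |Y-P| = 1
  p <- c(1, 1, 1, 0, 0); yy <- c(1, 1, 0, 1, 0)
  expect_equal(focal_tversky_loss(p, yy, 0.7, 0.3, 0.7), (1 / 3)^0.7,
               tolerance = 1e-6)
  expect_error(focal_tversky_loss(matrix(0, 2, 2), matrix(0, 3, 3)),
               "shape")
  # alpha = beta = 0.5, gamma = 1 reduces to 1 - Dice on hard masks
  set.seed(21)
  for (i in 1:50) {
    a <- rand_mask(8, 8); b <- rand_mask(8, 8)
    if (sum(a) + sum(b) == 0) next
    expect_equal(focal_tversky_loss(a, b, 0.5, 0.5, 1), 1 - dice(a, b),
                 tolerance = 1e-4)
  }
})

test_that("SDF regression loss is the pixel MSE", {
  t <- matrix(rnorm(36), 6, 6)
  expect_equal(sdf_regression_loss(t, t), 0)
  expect_equal(sdf_regression_loss(t + 0.3, t), 0.09, tolerance = 1e-12)
  p <- matrix(rnorm(36), 6, 6)
  acc <- 0
  for (i in 1:6) for (j in 1:6) acc <- acc + (p[i, j] - t[i, j])^2
  expect_equal(sdf_regression_loss(p, t), acc / 36)
  expect_error(sdf_regression_loss(matrix(0, 2, 2), matrix(0, 2, 3)),
               "shape")
})

test_that("homoscedastic dual-task weighting has the stated stationary point", {
  expect_equal(dual_task_loss(0.4, 0.7, 1, 1), 1.1)
  expect_equal(dual_task_loss(0, 0, exp(0.4), exp(0.6)), 1)  # log s1 s2 = 1
  expect_error(dual_task_loss(1, 1, 0, 1), "positive")
  # numeric minimisation over the sigmas recovers sigma^2 = 2 L
  set.seed(22)
  for (i in 1:10) {
    a <- runif(1, 0.05, 2); b <- runif(1, 0.05, 2)
    opt <- optim(c(1, 1), function(s) dual_task_loss(a, b, s[1], s[2]),
                 method = "L-BFGS-B", lower = c(1e-3, 1e-3))
    expect_equal(opt$par[1]^2, 2 * a, tolerance = 1e-4)
    expect_equal(opt$par[2]^2, 2 * b, tolerance = 1e-4)
  }
})

test_that("cross-entropy and dice losses match per-pixel loop oracles", {
  onehot <- function(lab, C) {
    p <- array(0, dim = c(C, dim(lab)))
    for (cc in 0:(C - 1)) p[cc + 1, , ] <- (lab == cc) * 1
    p
  }
  lab <- matrix(sample(0:2, 36, TRUE), 6, 6)
  p1 <- onehot(lab, 3)
  expect_lt(cross_entropy_loss(lab, p1), 1e-5)
  expect_lt(dice_loss(lab, p1), 1e-4)
  unif <- array(0.5, dim = c(2, 4, 4))
  expect_equal(cross_entropy_loss(matrix(0L, 4, 4), unif), log(2))
  expect_error(cross_entropy_loss(matrix(5L, 4, 4), unif), "\\[0, C\\)")
  set.seed(23)
  for (i in 1:20) {
    p <- rand_cmap(3, 5, 7)
    lab <- matrix(sample(0:2, 35, TRUE), 5, 7)
    expect_equal(cross_entropy_loss(lab, p), ce_oracle(lab, p))
    expect_equal(dice_loss(lab, p), dice_loss_oracle(lab, p))
  }
})

test_that("cross-pseudo supervision equals the explicit argmax assembly", {
  oh <- array(0, dim = c(2, 3, 3)); oh[1, , ] <- 1
  expect_lt(cps_loss(oh, oh), 1e-5)
  oh2 <- array(0, dim = c(2, 3, 3)); oh2[2, , ] <- 1
  expect_equal(cps_loss(oh, oh2), 2 * -log(1e-7), tolerance = 1e-6)
  expect_error(cps_loss(oh, array(0.5, dim = c(2, 4, 4))), "shape")
  set.seed(24)
  for (i in 1:20) {
    pa <- rand_cmap(3, 6, 6); pb <- rand_cmap(3, 6, 6)
    expect_equal(cps_loss(pa, pb),
                 cross_entropy_loss(argmax_map(pb), pa) +
                   cross_entropy_loss(argmax_map(pa), pb))
  }
  # self-agreement is minimal for one-hot maps
  for (i in 1:10) {
    q <- rand_cmap(3, 4, 4)
    expect_lte(cps_loss(oh3 <- {
      z <- array(0, dim = c(3, 4, 4)); z[2, , ] <- 1; z
    }, oh3), cps_loss(oh3, q) + 1e-12)
  }
})

test_that("pseudo-label supervision averages ce + dice over B and the pair", {
  d <- 4
  pa <- rand_cmap(3, d, 5, 5); pb <- rand_cmap(3, d, 5, 5)
  s2d <- array(sample(0:2, d * 25, TRUE), dim = c(d, 5, 5))
  expect_equal(pseudo_label_supervision_loss(s2d, list(pa, pb),
                                             integer(0)), 0)
  B <- c(2L, 4L)
  hand <- 0
  for (i in B) for (p in list(pa, pb))
    hand <- hand + cross_entropy_loss(s2d[i, , ], p[, i, , ]) +
      dice_loss(s2d[i, , ], p[, i, , ])
  expect_equal(pseudo_label_supervision_loss(s2d, list(pa, pb), B),
               hand / 4)
  s_na <- s2d; s_na[2, 1, 1] <- NA
  expect_error(pseudo_label_supervision_loss(s_na, list(pa, pb), B),
               "slice 2")
  # one-hot maps equal to the pseudo labels give (near) zero
  oh <- array(0, dim = c(3, d, 5, 5))
  for (cc in 0:2) oh[cc + 1, , , ] <- (s2d == cc) * 1
  expect_lt(pseudo_label_supervision_loss(s2d, list(oh, oh), B), 1e-4)
})

test_that("continuity loss enumerates neighbor terms and favors smooth tracks", {
  d <- 4
  oh <- array(0, dim = c(3, d, 6, 6)); oh[2, , , ] <- 1
  expect_lt(continuity_loss(list(oh, oh)), 1e-5)
  expect_error(continuity_loss(list(oh[, 1, , , drop = FALSE],
                                    oh[, 1, , , drop = FALSE])), "depth")
  # two one-hot, class-swapped slices: 4 clipped ce terms halved
  sw <- array(0, dim = c(2, 2, 3, 3))
  sw[1, 1, , ] <- 1; sw[2, 2, , ] <- 1
  expect_equal(continuity_loss(list(sw, sw)), 2 * -log(1e-7),
               tolerance = 1e-6)
  # compositional check on random maps
  set.seed(25)
  for (i in 1:20) {
    pa <- rand_cmap(3, 3, 5, 5); pb <- rand_cmap(3, 3, 5, 5)
    hand <- 0
    for (p in list(pa, pb)) {
      s <- argmax_map(p)
      for (k in 1:2) hand <- hand + cross_entropy_loss(s[k + 1, , ],
                                                       p[, k, , ])
      for (k in 2:3) hand <- hand + cross_entropy_loss(s[k - 1, , ],
                                                       p[, k, , ])
    }
    expect_equal(continuity_loss(list(pa, pb)), hand / 2)
  }
  # a vessel drifting 1 px/slice scores lower than one jumping 10 px/slice
  soft_track <- function(step) {
    p <- array(0, dim = c(2, 3, 40, 40))
    for (k in 1:3) {
      m <- matrix(0, 40, 40)
      ci <- 10 + (k - 1) * step
      m[(row(m) - ci)^2 + (col(m) - 20)^2 <= 16] <- 1
      p[2, k, , ] <- 0.1 + 0.8 * m
      p[1, k, , ] <- 1 - p[2, k, , ]
    }
    p
  }
  slow <- soft_track(1); fast <- soft_track(10)
  expect_lt(continuity_loss(list(slow, slow)),
            continuity_loss(list(fast, fast)))
})

test_that("ramp-up schedule and total losses follow the printed forms", {
  expect_equal(rampup_weight(1), 1)
  expect_equal(rampup_weight(0), exp(-5))
  expect_equal(rampup_weight(0.5), exp(-1.25))
  grid <- seq(0, 1, length.out = 1000)
  expect_true(all(diff(rampup_weight(grid)) > 0))
  expect_warning(rampup_weight(1.2), "clamped")
  expect_equal(total_loss_2d(1, 1, 1), 2)
  expect_equal(total_loss_3d(1, 1, 1, 1, 1), 4)
  expect_equal(total_loss_2d(1, 0, 0), 1)
  set.seed(26)
  for (i in 1:10) {
    v <- runif(4); t <- runif(1)
    lam <- exp(-5 * (1 - t)^2)
    expect_equal(total_loss_2d(v[1], v[2], t), v[1] + lam * v[2])
    expect_equal(total_loss_3d(v[1], v[2], v[3], v[4], t),
                 v[1] + lam * v[2] + v[3] + lam * v[4])
  }
})

test_that("losses are permutation-equivariant over pixels", {
  set.seed(27)
  p <- rand_cmap(3, 4, 6); lab <- matrix(sample(0:2, 24, TRUE), 4, 6)
  y <- rand_mask(4, 6)
  perm <- sample(24)
  pp <- array(matrix(p, nrow = 3)[, perm], dim = dim(p))
  labp <- array(as.integer(lab)[perm], dim = dim(lab))
  yp <- array(as.numeric(y)[perm], dim = dim(y))
  expect_equal(cross_entropy_loss(lab, p), cross_entropy_loss(labp, pp))
  expect_equal(dice_loss(lab, p), dice_loss(labp, pp))
  pf <- matrix(p[2, , ], 4, 6)
  pfp <- matrix(as.numeric(pf)[perm], 4, 6)
  expect_equal(focal_tversky_loss(pf, y),
               focal_tversky_loss(pfp, matrix(as.numeric(y)[perm], 4, 6)))
})
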