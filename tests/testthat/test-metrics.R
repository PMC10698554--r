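test_that("dice coefficient covers its closed-form cases and is symmetric", {
  a <- matrix(0L, 4, 4); a[1:2, 1:2] <- 1L
  expect_equal(dice(a, a), 1)
  b <- matrix(0L, 4, 4); b[3:4, 3:4] <- 1L
  expect_equal(dice(a, b), 0)
  c2 <- matrix(0L, 4, 4); c2[2:3, 1:2] <- 1L  # |X|=|Y|=4, overlap 2
  expect_equal(dice(a, c2), 0.5)
  expect_equal(dice(matrix(0L, 3, 3), matrix(0L, 3, 3)), 1)
  expect_equal(dice(a, c2), dice(c2, a))
  expect_error(dice(a, matrix(0L, 3, 3)), "shape")
})

test_that("area difference is the relative error against truth", {
  expect_equal(area_difference(100, 100), 0)
  expect_equal(area_difference(110, 100), 0.1)
  expect_error(area_difference(10, 0), "empty ground truth")
  set.seed(31)
  for (i in 1:10) {
    x <- runif(1, 1, 500); y <- runif(1, 1, 500)
    expect_equal(area_difference(x, y), abs(x - y) / y)
  }
})

test_that("normalized wall index difference matches the printed formula", {
  expect_equal(nwid(100, 180, 100, 180), 0)
  expect_equal(nwid(100, 200, 100, 180), 0.25)
  expect_equal(nwid(50, 100, 100, 180), nwid(500, 1000, 100, 180))
  expect_error(nwid(100, 200, 100, 90), "degenerate")
  expect_error(nwid(0, 10, 100, 180), "empty lumen")
})

test_that("radius-normalized Hausdorff equals the double-loop oracle", {
  b <- cbind(c(1, 2, 3), c(1, 1, 2))
  expect_equal(hausdorff_normalized(b, b, pi), 0)
  expect_equal(hausdorff_normalized(cbind(0, 0), cbind(3, 4), pi), 5)
  expect_error(hausdorff_normalized(b[0, , drop = FALSE], b, 10), "empty")
  set.seed(32)
  for (i in 1:50) {
    b <- matrix(runif(2 * sample(2:12, 1), 0, 30), ncol = 2)
    c2 <- matrix(runif(2 * sample(2:12, 1), 0, 30), ncol = 2)
    ref <- runif(1, 1, 400)
    hbc <- max(apply(b, 1, function(p)
      sqrt(min((c2[, 1] - p[1])^2 + (c2[, 2] - p[2])^2))))
    hcb <- max(apply(c2, 1, function(p)
      sqrt(min((b[, 1] - p[1])^2 + (b[, 2] - p[2])^2))))
    expect_equal(hausdorff_normalized(b, c2, ref),
                 max(hbc, hcb) / sqrt(ref / pi))
    expect_equal(hausdorff_normalized(b, c2, ref),
                 hausdorff_normalized(c2, b, ref))
  }
})

test_that("quantitative score weights sum to one and clamp properly", {
  expect_equal(quantitative_score(1, 0, 0, 0, 0, 0), 1)
  expect_equal(quantitative_score(0, 1, 2, 1.5, 3, 1), 0)
  expect_equal(quantitative_score(0.8, 0.1, 0.1, 0.1, 0.3, 0.3), 0.83)
  # monotone: nonincreasing in each error, nondecreasing in DSC
  set.seed(33)
  for (i in 1:10) {
    v <- runif(6)
    base <- quantitative_score(v[1], v[2], v[3], v[4], v[5], v[6])
    expect_gte(quantitative_score(min(v[1] + 0.1, 1), v[2], v[3], v[4],
                                  v[5], v[6]), base)
    expect_lte(quantitative_score(v[1], v[2] + 0.1, v[3], v[4], v[5],
                                  v[6]), base)
    expect_lte(quantitative_score(v[1], v[2], v[3], v[4] + 0.1, v[5],
                                  v[6]), base)
  }
})

test_that("contour extraction yields boundary pixels only", {
  m <- matrix(0L, 10, 10); m[3:7, 4:8] <- 1L
  pts <- extract_contour(m)
  expect_gt(nrow(pts), 0)
  for (r in seq_len(nrow(pts))) {
    i <- pts[r, 1]; j <- pts[r, 2]
    expect_equal(m[i, j], 1L)
    nb <- expand.grid(di = -1:1, dj = -1:1)
    vals <- mapply(function(di, dj) {
      ii <- i + di; jj <- j + dj
      if (ii < 1 || ii > 10 || jj < 1 || jj > 10) 0L else m[ii, jj]
    }, nb$di, nb$dj)
    expect_true(any(vals == 0L))
  }
  expect_equal(nrow(extract_contour(matrix(0L, 4, 4))), 0)
})

test_that("case evaluation matches an independent per-slice oracle", {
  ph <- tiny_phantom(seed = 6L)
  expect_error(evaluate_case(ph$labels, ph$labels, slices = integer(0)),
               "no evaluable")
  m <- evaluate_case(ph$labels, ph$labels)
  expect_equal(m$DSC, 1); expect_equal(m$DSCL, 1); expect_equal(m$QS, 1)
  # dilating the outer boundary changes Wad but not Lad
  dil <- ph$labels$classes
  for (k in seq_len(dim(dil)[1])) {
    sl <- dil[k, , ]
    wall <- sl >= 1L
    grown <- wall |
      rbind(wall[-1, ], FALSE) | rbind(FALSE, wall[-nrow(wall), ]) |
      cbind(wall[, -1], FALSE) | cbind(FALSE, wall[, -ncol(wall)])
    sl[grown & sl == 0L] <- 2L
    dil[k, , ] <- sl
  }
  md <- evaluate_case(new_label_volume(dil, ph$labels$labeled_slices),
                      ph$labels)
  expect_equal(md$Lad, 0)
  expect_gt(md$Wad, 0)
  # five perturbed phantom cases against the standalone oracle
  set.seed(34)
  for (case in 1:5) {
    ph2 <- tiny_phantom(seed = case + 40L, depth = 4L)
    pred <- ph2$labels$classes
    # random erosion-like corruption: flip a few wall pixels to background
    idx <- which(pred == 2L)
    pred[sample(idx, length(idx) %/% 5)] <- 0L
    pv <- new_label_volume(pred, ph2$labels$labeled_slices)
    got <- evaluate_case(pv, ph2$labels, slices = 1:4)
    want <- colMeans(t(vapply(1:4, function(k)
      slice_metrics_oracle(pred[k, , ], ph2$labels$classes[k, , ]),
      numeric(9))))
    for (nm in names(want))
      expect_equal(got[[nm]], want[[nm]], tolerance = 1e-12, label = nm)
  }
})
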