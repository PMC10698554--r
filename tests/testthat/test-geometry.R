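test_that("2D center of gravity matches the first-order moment", {
  m <- matrix(0L, 8, 8); m[4, 6] <- 1L
  expect_equal(center_of_gravity_2d(m)$coords, c(4, 6))
  sq <- matrix(0L, 5, 5); sq[cbind(c(1, 1, 3, 3), c(1, 3, 1, 3))] <- 1L
  expect_equal(center_of_gravity_2d(sq)$coords, c(2, 2))
  expect_false(center_of_gravity_2d(matrix(0L, 4, 4))$valid)
  expect_error(center_of_gravity_2d(matrix(2, 3, 3)), "binary")
  set.seed(11)
  for (i in 1:100) {
    m <- rand_mask(16, 16)
    if (sum(m) == 0) next
    expect_identical(center_of_gravity_2d(m)$coords, cog2d_oracle(m))
  }
})

test_that("3D center of gravity pools in-plane moments over slices", {
  sl <- matrix(0L, 10, 10); sl[3:5, 6:8] <- 1L
  chunk <- array(rep(sl, 4), dim = c(10, 10, 4))
  chunk <- aperm(chunk, c(3, 1, 2))
  expect_equal(center_of_gravity_3d(chunk)$coords,
               center_of_gravity_2d(sl)$coords)
  two <- array(0L, dim = c(2, 12, 12))
  two[1, 4, 4] <- 1L; two[2, 8, 8] <- 1L
  expect_equal(center_of_gravity_3d(two)$coords, c(6, 6))
  expect_false(center_of_gravity_3d(array(0L, c(2, 4, 4)))$valid)
  set.seed(12)
  for (i in 1:100) {
    a <- array(rbinom(3 * 9 * 9, 1L, 0.3), dim = c(3, 9, 9))
    if (sum(a) == 0) next
    expect_identical(center_of_gravity_3d(a)$coords, cog3d_oracle(a))
  }
})

test_that("signed distance map is exact against the all-pairs oracle", {
  one <- matrix(0L, 7, 7); one[4, 4] <- 1L
  s <- signed_distance_map(one)
  expect_equal(s[4, 4], 0)
  expect_equal(s[3, 4], 1); expect_equal(s[4, 5], 1)
  # all-background sentinel: image diagonal
  expect_equal(signed_distance_map(matrix(0L, 3, 4))[1, 1], 5)
  set.seed(13)
  for (i in 1:50) {
    m <- rand_mask(sample(8:32, 1), sample(8:32, 1), runif(1, 0.1, 0.7))
    if (sum(m) == 0 || sum(m) == length(m)) next
    s <- signed_distance_map(m)
    o <- sdf_oracle(m)
    expect_equal(s, o)
    # boundary pixels are exactly zero
    expect_true(all(s[o == 0] == 0))
    # complementing the mask flips the sign off the (shifted) boundary
    sc <- signed_distance_map(1L - m)
    off <- s != 0 & sc != 0
    expect_true(all(sign(s[off]) == -sign(sc[off])))
  }
})

test_that("patch cropping centers, clamps and round-trips", {
  img <- matrix(seq_len(720 * 720) / 1e6, 720, 720)
  r <- crop_patch_2d(img, c(361, 361), c(96, 96))
  expect_equal(r$spec$origin, c(313L, 313L))
  r2 <- crop_patch_2d(img, c(10, 10), c(96, 96))
  expect_equal(r2$spec$origin, c(1L, 1L))
  expect_error(crop_patch_2d(matrix(0, 10, 10), c(5, 5), c(20, 20)),
               "size")
  canvas <- paste_patch_2d(matrix(0, 720, 720), r$patch, r$spec)
  expect_identical(canvas[313:408, 313:408], r$patch)
  r3 <- crop_patch_2d(canvas, c(361, 361), c(96, 96))
  expect_identical(r3$patch, r$patch)
})

test_that("depth chunking follows the stride-and-shift rule", {
  v <- array(stats::runif(64 * 4 * 4), dim = c(64, 4, 4))
  ch <- chunk_volume(v, 32, 0)
  expect_equal(vapply(ch, function(x) x$spec$origin, integer(1)), c(1L, 33L))
  v2 <- array(0, dim = c(40, 4, 4))
  ch2 <- chunk_volume(v2, 32, 16)
  expect_equal(vapply(ch2, function(x) x$spec$origin, integer(1)), c(1L, 9L))
  ch3 <- chunk_volume(v2, 40, 0)
  expect_length(ch3, 1L)
  expect_error(chunk_volume(v2, 8, 8), "overlap")
  # coverage of every slice
  covered <- sort(unique(unlist(lapply(ch2, function(x)
    x$spec$origin:(x$spec$origin + x$spec$size - 1L)))))
  expect_identical(covered, 1:40)
})

test_that("stitching averages overlaps and preserves single coverage", {
  mk <- function(val, o, d) list(
    map = array(val, dim = c(2, d, 3, 3)),
    spec = list(origin = o, size = d, source_depth = 6))
  p1 <- mk(c(0.2, 0.8), 1L, 4L)
  p2 <- mk(c(0.6, 0.4), 3L, 4L)
  out <- stitch_predictions(list(p1, p2), c(2, 6, 3, 3))
  expect_equal(out[1, 1, 1, 1], 0.2)          # covered once
  expect_equal(out[1, 4, 2, 2], 0.4)          # mean of 0.2 and 0.6
  expect_equal(out[1, 6, 1, 1], 0.6)
  expect_equal(apply(out, c(2, 3, 4), sum),
               array(1, dim = c(6, 3, 3)))    # simplex preserved
  expect_error(stitch_predictions(list(p1), c(2, 6, 3, 3)), "uncovered")
  # identical predictions in the overlap stay unchanged
  out2 <- stitch_predictions(list(mk(c(0.3, 0.7), 1L, 4L),
                                  mk(c(0.3, 0.7), 3L, 4L)), c(2, 6, 3, 3))
  expect_equal(out2[2, 4, 1, 1], 0.7)
})

test_that("chunk then stitch is the identity on probability volumes", {
  set.seed(14)
  for (case in list(c(32L, 0L), c(32L, 16L), c(8L, 4L))) {
    p <- rand_cmap(3, 40, 5, 5)
    pieces <- lapply(chunk_volume(p, case[1], case[2]), function(x)
      list(map = x$chunk, spec = x$spec))
    out <- stitch_predictions(pieces, dim(p))
    expect_equal(out, p)
  }
})

test_that("largest connected component matches a flood-fill census", {
  m <- matrix(0L, 20, 20)
  m[3:9, 3:9] <- 1L          # 49-pixel blob
  m[15, 15:17] <- 1L         # 3-pixel fragment
  out <- largest_connected_component(m)
  expect_identical(out[3:9, 3:9], matrix(1L, 7, 7))
  expect_equal(sum(out), 49)
  expect_identical(largest_connected_component(matrix(0L, 5, 5)),
                   matrix(0L, 5, 5))
  set.seed(15)
  for (i in 1:20) {
    m <- rand_mask(15, 15, 0.35)
    if (sum(m) == 0) next
    lab <- flood_components(m)
    sizes <- tabulate(lab[lab > 0])
    expect_identical(largest_connected_component(m),
                     matrix(as.integer(lab == which.max(sizes)), 15, 15))
  }
  # 3D: a 26-connected diagonal chain is one component
  a <- array(0L, dim = c(3, 5, 5))
  a[1, 1, 1] <- 1L; a[2, 2, 2] <- 1L; a[3, 3, 3] <- 1L
  a[1, 5, 5] <- 1L
  out3 <- largest_connected_component(a)
  expect_equal(sum(out3), 3)
  expect_equal(out3[2, 2, 2], 1L)
})

test_that("centroid track repair interpolates, rejects outliers, idempotent", {
  tr <- rbind(c(10, 10), c(NA, NA), c(14, 14))
  expect_equal(repair_centroid_track(tr)[2, ], c(12, 12))
  smooth <- cbind(seq(10, 20, length.out = 11), seq(10, 20, length.out = 11))
  out <- smooth; out[6, ] <- out[6, ] + 100
  rep1 <- repair_centroid_track(out)
  expect_equal(rep1[6, ], smooth[6, ], tolerance = 1e-8)
  expect_equal(rep1[-6, ], smooth[-6, ])
  expect_identical(repair_centroid_track(smooth), smooth)
  expect_error(repair_centroid_track(matrix(NA_real_, 4, 2)),
               "no vessel located")
  set.seed(16)
  for (i in 1:20) {
    tr <- cbind(cumsum(rnorm(15)), cumsum(rnorm(15))) + 30
    tr[sample(15, 3), ] <- NA
    if (sample(2, 1) == 1) tr[8, ] <- c(200, 200)
    r1 <- repair_centroid_track(tr)
    expect_identical(repair_centroid_track(r1), r1)
    expect_false(anyNA(r1))
  }
})
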