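test_that("fixed-radius noise-free phantom rasterises identical disks", {
  cfg <- phantom_config(depth = 8L, height = 40L, width = 40L,
                        lumen_radius_range = c(4, 4),
                        wall_thickness_range = c(2, 2),
                        centerline_wobble = 0, noise_sigma = 0, seed = 2L)
  ph <- generate_phantom(cfg)
  counts <- apply(ph$labels$classes == 1L, 1, sum)
  expect_true(all(counts == counts[1]))
  expect_gt(counts[1], 0)
  # intensities are exact class means without noise
  expect_equal(unique(as.numeric(
    ph$volume$intensities[ph$labels$classes == 1L])), 0.15)
})

test_that("generation is bit-identical under a fixed seed", {
  a <- generate_phantom(phantom_config(depth = 6L, seed = 7L))
  b <- generate_phantom(phantom_config(depth = 6L, seed = 7L))
  expect_identical(a$volume$intensities, b$volume$intensities)
  expect_identical(a$labels$classes, b$labels$classes)
  expect_identical(a$labels$labeled_slices, b$labels$labeled_slices)
})

test_that("stenosis scales the lumen area quadratically", {
  cfg <- phantom_config(depth = 20L, lumen_radius_range = c(8, 8),
                        centerline_wobble = 0, noise_sigma = 0,
                        stenosis = TRUE, stenosis_slices = 10:14,
                        stenosis_scale = 0.5, seed = 3L)
  ph <- generate_phantom(cfg)
  a0 <- sum(ph$labels$classes[1, , ] == 1L)
  a12 <- sum(ph$labels$classes[12, , ] == 1L)
  # disk area scales with radius^2, up to rasterisation error
  expect_lt(abs(a12 / a0 - 0.25), 0.05)
})

test_that("class structure invariants hold on every generated slice", {
  ph <- generate_phantom(phantom_config(seed = 5L))
  cls <- ph$labels$classes
  expect_true(all(cls %in% 0:2))
  for (k in seq_len(dim(cls)[1])) {
    sl <- cls[k, , ]
    lum <- sl == 1L
    # every lumen boundary pixel is 4-adjacent to a wall pixel
    bnd <- which(lum & !(rbind(lum[-1, ], FALSE) &
                           rbind(FALSE, lum[-nrow(lum), ]) &
                           cbind(lum[, -1], FALSE) &
                           cbind(FALSE, lum[, -ncol(lum)])),
                 arr.ind = TRUE)
    for (r in seq_len(nrow(bnd))) {
      i <- bnd[r, 1]; j <- bnd[r, 2]
      nb <- c(sl[max(i - 1, 1), j], sl[min(i + 1, nrow(sl)), j],
              sl[i, max(j - 1, 1)], sl[i, min(j + 1, ncol(sl))])
      expect_true(any(nb == 2L) || all(nb == 1L))
    }
  }
  # black-blood contrast with margin of at least twice the noise level
  cfg <- phantom_config()
  lum_m <- mean(ph$volume$intensities[cls == 1L])
  wall_m <- mean(ph$volume$intensities[cls == 2L])
  expect_gt(wall_m - lum_m, 2 * cfg$noise_sigma)
  # areas vary smoothly outside stenosis/bifurcation
  areas <- apply(cls == 1L, 1, sum)
  expect_true(all(abs(diff(areas)) <= 0.25 * head(areas, -1)))
})

test_that("configuration errors name the offending field", {
  expect_error(phantom_config(label_fraction = 0), "label_fraction")
  expect_error(phantom_config(stenosis_scale = 1.5), "stenosis_scale")
  expect_error(phantom_config(lumen_radius_range = c(20, 30)),
               "lumen_radius_range")
})

test_that("label subsampling has the stated size, is seeded, honors bounds", {
  ph <- generate_phantom(phantom_config(depth = 40L, seed = 1L))
  all_lab <- subsample_labels(ph$labels, 1.0)
  expect_identical(all_lab$labeled_slices, 1:40)
  s1 <- subsample_labels(ph$labels, 0.2, seed = 9L)
  expect_length(s1$labeled_slices, 8L)
  s2 <- subsample_labels(ph$labels, 0.2, seed = 9L)
  expect_identical(s1$labeled_slices, s2$labeled_slices)
  expect_identical(s1$classes, ph$labels$classes)
  expect_error(subsample_labels(ph$labels, 0), "fraction")
  blk <- subsample_labels(ph$labels, 0.2, seed = 2L, contiguous = TRUE)
  expect_identical(diff(blk$labeled_slices), rep(1L, 7L))
})

test_that("fragmented coarse masks corrupt centroids until post-processed", {
  ph <- tiny_phantom(seed = 4L)
  clean <- simulate_fragmented_coarse_mask(ph$labels, 0L)
  expect_identical(clean,
                   array(as.integer(ph$labels$classes == 1L),
                         dim = dim(ph$labels$classes)))
  frag <- simulate_fragmented_coarse_mask(ph$labels, 3L, seed = 8L)
  k <- 5L
  lab <- flood_components(frag[k, , ])
  expect_equal(max(lab), 4L)  # vessel + 3 fragments
  cg_frag <- center_of_gravity_2d(frag[k, , ])
  cg_clean <- cog2d_oracle(clean[k, , ])
  expect_false(isTRUE(all.equal(cg_frag$coords, cg_clean)))
  cg_fixed <- center_of_gravity_2d(largest_connected_component(frag[k, , ]))
  expect_equal(cg_fixed$coords, cg_clean)
})
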