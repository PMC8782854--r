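make_slab_mask <- function(nx = 20, ny = 15, top_k = 10, spacing = 10) {
  a <- array(FALSE, c(nx, ny, top_k + 4))
  a[, , 1:top_k] <- TRUE
  voxel_mask(a, spacing, c(0, 0, 0), "tibia")
}

test_that("height map is the per-column top surface", {
  m <- make_slab_mask(top_k = 10, spacing = 10)
  hm <- height_map(m)
  expect_true(all(abs(hm - 95) < 1e-9))  # top voxel centre at (10 - 0.5) * 10
  # slab with a bump: map adds the bump profile
  a <- m$data; a[8:12, 6:10, 11:13] <- TRUE
  hb <- height_map(voxel_mask(a, 10))
  expect_equal(max(hb), 125)
  expect_true(all(hb[1, ] == 95))
  # internal cavity below the top surface leaves the map unchanged
  a2 <- m$data; a2[5:15, 5:10, 3:5] <- FALSE
  h2 <- height_map(voxel_mask(a2, 10))
  expect_equal(unclass(h2), unclass(hm), ignore_attr = TRUE)
  expect_error(height_map(voxel_mask(array(0, c(3, 3, 3)), 10,
                                     allow_empty = TRUE)), "empty")
})

test_that("coronal profile aggregates the map along y", {
  ph <- tibia_phantom(spacing = 100)
  hm <- height_map(ph$tibia)
  pr <- coronal_profile(hm)
  expect_true(all(diff(pr$x) > 0))
  # twin tubercles: two local maxima near the tubercle positions with an
  # interior minimum between them
  sp <- phantom_spec("rat", spacing = 100)
  near <- function(x0) which.min(abs(pr$x - x0))
  i1 <- near(sp$tub_x[1]); i2 <- near(sp$tub_x[2])
  imid <- near(0)
  expect_gt(pr$h[i1], pr$h[imid])
  expect_gt(pr$h[i2], pr$h[imid])
  # mean aggregator keeps the interior minimum between the tubercles
  prm <- coronal_profile(hm, aggregate = "mean")
  expect_gt(prm$h[near(sp$tub_x[1])], prm$h[near(0)])
  expect_gt(prm$h[near(sp$tub_x[2])], prm$h[near(0)])
  # constant map -> constant profile
  prc <- coronal_profile(height_map(make_slab_mask()))
  expect_equal(diff(range(prc$h)), 0)
})

test_that("cropping restricts to the centre and rescales to [0, 1]", {
  x <- seq(0, 1000, by = 10)
  h <- sin(x / 100) + 2
  p <- structure(list(x = x, h = h, crop_window = NULL, spacing = 10),
                 class = "profile_1d")
  full <- crop_profile(p, 1)
  expect_equal(length(full$h), length(h))
  expect_equal(range(full$h), c(0, 1))
  half <- crop_profile(p, 0.5)
  expect_true(all(half$x >= 250 & half$x <= 750))
  expect_equal(half$crop_window, c(250, 750))
  # degenerate constant profile
  pc <- structure(list(x = x, h = rep(5, length(x)), crop_window = NULL,
                       spacing = 10), class = "profile_1d")
  expect_warning(out <- crop_profile(pc, 1), "constant")
  expect_true(all(out$h == 0))
  expect_error(crop_profile(p, 0), "center_fraction")
})

test_that("an osteophyte-like edge spike is excluded by the crop", {
  ph <- tibia_phantom(spacing = 80,
                      osteophyte = list(height = 700, sigma = 450,
                                        x = 3100, y = 0))
  pr <- coronal_profile(height_map(ph$tibia))
  cropped <- crop_profile(pr, 0.5)
  expect_lt(cropped$crop_window[2], 3100)
})

test_that("persistence pairing matches the worked example and its invariances", {
  pp <- persistence_pairs(c(0, 2, 1, 3, 0))
  expect_equal(nrow(pp), 2)
  # global pair: leftmost tied minimum paired with the global maximum
  expect_equal(pp$min_index[1], 1)
  expect_equal(pp$max_index[1], 4)
  expect_equal(pp$persistence[1], 3)
  expect_equal(pp$min_index[2], 3)
  expect_equal(pp$max_index[2], 2)
  expect_equal(pp$persistence[2], 1)
  # monotone signal: single endpoint pair with persistence = range
  pm <- persistence_pairs(c(1, 2, 5, 9))
  expect_equal(nrow(pm), 1)
  expect_equal(pm$persistence, 8)
  expect_equal(pm$min_index, 1); expect_equal(pm$max_index, 4)
  # shift invariance
  h <- c(2, 5, 1, 4, 0, 3, 2.5)
  expect_equal(persistence_pairs(h + 17), persistence_pairs(h))
  expect_error(persistence_pairs(c(1, 2)), "3 samples")
})

test_that("persistence pairing equals the brute-force filtration oracle", {
  set.seed(77)
  for (i in 1:250) {
    n <- sample(3:200, 1)
    h <- if (i %% 4 == 0) sample(0:8, n, replace = TRUE) else rnorm(n)
    expect_equal(persistence_pairs(h), brute_persistence(h))
  }
})

test_that("the watershed point is the second pair's minimum", {
  p <- structure(list(x = seq(0, 40, by = 10), h = c(0, 2, 1, 3, 0),
                      spacing = 10), class = "profile_1d")
  xd <- watershed_index(p)
  expect_equal(as.numeric(xd), 20)
  expect_equal(attr(xd, "index"), 3)
  # single bump: no interior pair
  pb <- structure(list(x = seq(0, 40, by = 10), h = c(0, 1, 2, 1, 0),
                       spacing = 10), class = "profile_1d")
  expect_error(watershed_index(pb), "no eminence")
})

test_that("the dividing point hits the intercondylar valley on phantoms", {
  ph <- tibia_phantom(spacing = 80)
  pr <- crop_profile(coronal_profile(height_map(ph$tibia)), 0.5)
  xd <- watershed_index(pr)
  expect_lte(abs(as.numeric(xd) - ph$truth$x_star), 80)
  # determinism
  xd2 <- watershed_index(crop_profile(coronal_profile(height_map(ph$tibia)), 0.5))
  expect_identical(as.numeric(xd), as.numeric(xd2))
})

test_that("the dividing point is robust to surface roughness and edge spikes", {
  # roughness up to 15% of the valley's topographic prominence (the
  # operating range where single-voxel accuracy holds; see the vignette)
  ph0 <- tibia_phantom(spacing = 80)
  cp0 <- crop_profile(coronal_profile(height_map(ph0$tibia)), 0.5)
  pp0 <- persistence_pairs(cp0$h)
  prom_topo <- pp0$persistence[2] * diff(cp0$scale)
  for (k in 1:6) {
    ph <- tibia_phantom(spacing = 80,
                        noise_amplitude = (0.15 * prom_topo) * k / 6,
                        seed = 300 + k,
                        osteophyte = if (k %% 2 == 0)
                          list(height = 700, sigma = 450, x = 3100, y = 0))
    pr <- crop_profile(coronal_profile(height_map(ph$tibia)), 0.5)
    xd <- watershed_index(pr)
    expect_lte(abs(as.numeric(xd) - ph$truth$x_star), 80)
  }
})

test_that("splitting partitions every mask at the dividing plane", {
  sp <- phantom_spec("rat", spacing = 120)
  ph <- make_phantom_joint(sp)
  sides <- split_joint(ph$joint, 35)
  for (nm in c("tibia", "femur", "tibial_cartilage", "femoral_cartilage")) {
    med <- sides$medial[[nm]]$data; lat <- sides$lateral[[nm]]$data
    expect_identical(med | lat, ph$joint[[nm]]$data)  # union = original
    expect_false(any(med & lat))                      # disjoint
  }
  # plane shift by +k voxels moves exactly the k-slab
  s2 <- split_joint(ph$joint, 35 + 2 * 120)
  moved <- sum(s2$medial$tibia$data) - sum(sides$medial$tibia$data)
  xs <- ph$joint$tibia$origin[1] +
    (seq_len(dim(ph$joint$tibia$data)[1]) - 0.5) * 120
  slab <- xs >= 35 & xs < 35 + 240
  expect_equal(moved, sum(ph$joint$tibia$data[slab, , ]))
  # x_divide outside the footprint is rejected
  expect_error(split_joint(ph$joint, 1e6), "footprint")
})

test_that("a symmetric phantom splits into near-equal tibial halves", {
  sp <- phantom_spec("rat", spacing = 100, plateau_asym = 0,
                     tub_h = c(800, 800))
  ph <- make_phantom_joint(sp)
  sides <- split_joint(ph$joint, 0)
  vm <- sum(sides$medial$tibia$data); vl <- sum(sides$lateral$tibia$data)
  d <- dim(ph$joint$tibia$data)
  expect_lte(abs(vm - vl), d[2] * d[3])  # within one voxel slab
})
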