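test_that("voxel_mask enforces the binary contract", {
  a <- array(0, c(10, 10, 10))
  expect_error(voxel_mask(a, 10), "empty foreground")
  a[4:6, 4:6, 4:6] <- 255
  m <- voxel_mask(a, 10)
  expect_true(is.logical(m$data))
  expect_equal(sum(m$data), 27)
  expect_error(voxel_mask(a, -1), "spacing")
})

test_that("MetaImage round trip is bit-exact on data, spacing and origin", {
  a <- array(FALSE, c(7, 5, 6)); a[2:4, 2:3, 3:5] <- TRUE
  m <- voxel_mask(a, 12.5, origin = c(100, -40, 7.5))
  p <- file.path(tempdir(), "roundtrip.mha")
  write_mask(m, p)
  m2 <- read_mask(p, label = "tibia")
  expect_identical(m2$data, m$data)
  expect_identical(m2$spacing, m$spacing)
  expect_identical(m2$origin, m$origin)
})

test_that("NIfTI round trip preserves data and spacing", {
  a <- array(FALSE, c(6, 6, 4)); a[2:4, 3:5, 2:3] <- TRUE
  m <- voxel_mask(a, 18)
  p <- file.path(tempdir(), "roundtrip.nii.gz")
  write_mask(m, p)
  m2 <- read_mask(p)
  expect_identical(m2$data, m$data)
  expect_equal(m2$spacing, 18)
})

test_that("read_mask rejects anisotropic headers and grey data is binarised", {
  # hand-written header with anisotropic spacing
  p <- file.path(tempdir(), "aniso.mha")
  con <- file(p, "wb")
  hdr <- c("ObjectType = Image", "NDims = 3", "BinaryData = True",
           "CompressedData = False", "Offset = 0 0 0",
           "ElementSpacing = 10 10 35", "DimSize = 2 2 2",
           "ElementType = MET_UCHAR", "ElementDataFile = LOCAL")
  writeChar(paste0(paste(hdr, collapse = "\n"), "\n"), con, eos = NULL)
  writeBin(as.integer(rep(1, 8)), con, size = 1)
  close(con)
  expect_error(read_mask(p), "anisotropic")
  # grey-valued volume binarised at half max
  p2 <- file.path(tempdir(), "grey.mha")
  con <- file(p2, "wb")
  hdr[6] <- "ElementSpacing = 10 10 10"
  writeChar(paste0(paste(hdr, collapse = "\n"), "\n"), con, eos = NULL)
  writeBin(as.integer(c(0, 60, 128, 255, 0, 0, 200, 10)), con, size = 1)
  close(con)
  m <- read_mask(p2)
  expect_equal(as.vector(m$data), c(0, 0, 1, 1, 0, 0, 1, 0) > 0)
})

test_that("centre of mass follows the voxel-centre convention", {
  a <- array(FALSE, c(8, 8, 8)); a[4, 5, 6] <- TRUE  # 0-based (3, 4, 5)
  m <- voxel_mask(a, 10)
  expect_equal(center_of_mass(m), c(35, 45, 55))
  # symmetric ball: COM at the geometric centre
  b <- make_ball_mask(10, 10)
  ctr <- (dim(b$data) / 2) * 10
  expect_lt(max(abs(center_of_mass(b) - ctr)), 1)  # < 0.1 voxel
  # union of two equal balls: COM at the midpoint
  n <- 41
  b1 <- make_ball_mask(6, 10, centre_vox = c(10, 20, 20))
  a2 <- array(FALSE, c(n, n, n))
  idx <- seq_len(n) - 1
  d1 <- outer(outer((idx - 10)^2, (idx - 20)^2, "+"), (idx - 20)^2, "+") <= 36
  d2 <- outer(outer((idx - 30)^2, (idx - 20)^2, "+"), (idx - 20)^2, "+") <= 36
  mu <- voxel_mask(d1 | d2, 10)
  expect_lt(max(abs(center_of_mass(mu) - c(205, 205, 205))), 1e-9)
})

test_that("rigid_transform validates rigidity and composes correctly", {
  expect_error(rigid_transform(diag(3) * 2), "non-rigid")
  expect_error(rigid_transform(diag(c(1, 1, -1))), "non-rigid")
  R1 <- euler_rotation(c(10, 20, 30)); R2 <- euler_rotation(c(-5, 40, 12))
  a <- rigid_transform(R1, c(1, 2, 3)); b <- rigid_transform(R2, c(-4, 0, 9))
  p <- c(7, -2, 5)
  expect_equal(rt_apply(rt_compose(a, b), p), rt_apply(a, rt_apply(b, p)))
  expect_equal(rt_apply(rt_compose(rt_invert(a), a), p), p)
  expect_equal(rotation_to_euler(euler_rotation(c(11, -24, 37))), c(11, -24, 37))
})

test_that("rigid resampling preserves binary volumes", {
  b <- make_ball_mask(20, 10)
  # identity: voxel-identical
  id <- resample_rigid(b, rigid_transform(), margin = 0)
  expect_identical(id$data, b$data)
  # lattice-exact 90 degree rotation about z: swapped x/y extents
  a <- array(FALSE, c(30, 20, 15)); a[5:25, 5:12, 4:10] <- TRUE
  box <- voxel_mask(a, 10)
  r90 <- resample_rigid(box, rigid_transform(euler_rotation(c(0, 0, 90))),
                        margin = 0)
  expect_equal(sum(r90$data), sum(a))
  fg <- which(r90$data, arr.ind = TRUE)
  expect_equal(diff(range(fg[, 1])), 7)   # was the y extent
  expect_equal(diff(range(fg[, 2])), 20)  # was the x extent
  # random rotation: volume within 2 %
  Tr <- rigid_transform(euler_rotation(c(23, -37, 51)), c(31, -8, 12))
  br <- resample_rigid(b, Tr)
  expect_lt(abs(sum(br$data) - sum(b$data)) / sum(b$data), 0.02)
  expect_error(resample_rigid(b, list(R = diag(3))), "rigid_transform")
})

test_that("resampling round trip and COM equivariance hold", {
  b <- make_ball_mask(28, 10)
  Tr <- rigid_transform(euler_rotation(c(17, 33, -21)), c(25, 3, -14))
  br <- resample_rigid(b, Tr)
  back <- resample_rigid(br, rt_invert(Tr))
  expect_gt(dice_overlap(back, b), 0.98)
  cm_err <- sqrt(sum((center_of_mass(br) - rt_apply(Tr, center_of_mass(b)))^2))
  expect_lt(cm_err, 5)  # half a voxel
})

test_that("joint_image_set requires a shared spacing", {
  a <- array(FALSE, c(5, 5, 5)); a[3, 3, 3] <- TRUE
  t1 <- voxel_mask(a, 10, label = "tibia")
  f1 <- voxel_mask(a, 12, label = "femur")
  expect_error(joint_image_set(tibia = t1, femur = f1), "spacing")
})
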