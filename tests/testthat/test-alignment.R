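test_that("principal axes recover ellipsoid geometry and equivariance", {
  set.seed(21)
  n <- 40000
  # axis-aligned ellipsoidal cloud, semi-axes 4 > 2 > 1 along (y, x, z)
  pts <- cbind(2 * rnorm(n), 4 * rnorm(n), 1 * rnorm(n))
  pa <- principal_axes(pts)
  ang <- function(a, b) acos(pmin(1, abs(sum(a * b)))) * 180 / pi
  expect_lt(ang(pa$axes[, 1], c(0, 1, 0)), 1)  # largest along y
  expect_lt(ang(pa$axes[, 2], c(1, 0, 0)), 1)  # second along x
  expect_lt(ang(pa$axes[, 3], c(0, 0, 1)), 1)  # smallest along z
  expect_true(all(diff(pa$variances) <= 0))
  expect_equal(det(pa$axes), 1, tolerance = 1e-10)
  expect_lt(max(abs(crossprod(pa$axes) - diag(3))), 1e-10)
  # rotating the cloud rotates every axis (up to sign)
  R <- euler_rotation(c(35, -20, 55))
  pa2 <- principal_axes(pts %*% t(R))
  for (k in 1:3)
    expect_lt(ang(pa2$axes[, k], as.vector(R %*% pa$axes[, k])), 1)
})

test_that("isotropic clouds are declared ill-conditioned", {
  set.seed(3)
  pts <- matrix(rnorm(9000), ncol = 3)
  pa <- principal_axes(pts)
  expect_lt(pa$conditioning, 0.05)
  expect_error(alignment_rotation(pa, pts), "ill-conditioned")
  expect_error(principal_axes(cbind(1:10, 2 * (1:10), 3 * (1:10))), "degenerate")
})

test_that("alignment rotation maps the axes to the common orientation", {
  set.seed(22)
  n <- 6000
  # anatomy-like cloud: tail down in z, wider half on -x
  x <- 2 * rnorm(n); y <- 4 * rnorm(n); z <- 1 * rnorm(n) - rexp(n, 1)
  x <- x - 0.5 * rexp(n, 2)
  pts <- cbind(x, y, z)
  pa <- principal_axes(pts)
  rot <- alignment_rotation(pa, pts)
  expect_lt(max(abs(crossprod(rot$R) - diag(3))), 1e-10)
  expect_equal(det(rot$R), 1, tolerance = 1e-10)
  out <- pts %*% t(rot$R)
  pa2 <- principal_axes(out)
  ang <- function(a, b) acos(pmin(1, abs(sum(a * b)))) * 180 / pi
  expect_lt(ang(pa2$axes[, 3], c(0, 0, 1)), 1)
  expect_lt(ang(pa2$axes[, 2], c(1, 0, 0)), 1)
  # sign policy: tail still down, wider half still on -x
  s3 <- out[, 3] - mean(out[, 3])
  expect_lt(mean(s3^3), 0)
  s1 <- out[, 1] - mean(out[, 1])
  expect_lt(mean(s1^3), 0)
  # right limbs mirror the medial-lateral sign
  rotR <- alignment_rotation(pa, pts, limb_side = "right")
  expect_equal(as.vector(rotR$R[1, ]), -as.vector(rot$R[1, ]))
})

test_that("a canonically posed phantom aligns to near identity", {
  sp <- phantom_spec("rat", spacing = 100)
  ph <- make_phantom_joint(sp)
  al <- align_joint(ph$joint, apply = TRUE)
  expect_lt(al$diagnostics$axis_residual_deg, 0.5)
  ang <- acos(pmin(1, (sum(diag(al$transform$R)) - 1) / 2)) * 180 / pi
  expect_lt(ang, 1.5)
  # undo the (intentional) recentring motion before comparing shapes
  back <- resample_rigid(al$joint$tibia, rt_invert(al$transform))
  expect_gt(dice_overlap(back, ph$joint$tibia), 0.98)
  # idempotence: aligning the aligned joint is within 1 degree of identity
  al2 <- align_joint(al$joint, apply = FALSE)
  ang2 <- acos(pmin(1, (sum(diag(al2$transform$R)) - 1) / 2)) * 180 / pi
  expect_lt(ang2, 1)
})

test_that("arbitrary poses are recovered within 2 degrees on both scales", {
  set.seed(33)
  for (preset in c("rat", "rabbit")) {
    spacing <- if (preset == "rat") 80 else 180
    sp <- phantom_spec(preset, spacing = spacing)
    for (k in 1:2) {
      sp$pose$angles_deg <- runif(3, -40, 40)
      sp$pose$translation_um <- runif(3, -400, 400)
      ph <- make_phantom_joint(sp)
      al <- align_joint(ph$joint, apply = FALSE)
      resid <- axis_angles_deg(al$transform$R %*% ph$truth$pose$R)
      expect_lt(max(resid), 2)
    }
  }
})

test_that("relative bone pose is preserved by the shared transform", {
  set.seed(44)
  sp <- phantom_spec("rat", spacing = 100)
  sp$pose$angles_deg <- runif(3, -30, 30)
  ph <- make_phantom_joint(sp)
  al <- align_joint(ph$joint, apply = TRUE)
  # route A: COM vector of the resampled masks
  va <- com_vector(al$joint$femur, al$joint$tibia)
  # route B: analytic transform of the original COM vector
  v0 <- center_of_mass(ph$joint$femur) - center_of_mass(ph$joint$tibia)
  vb <- as.vector(al$transform$R %*% v0)
  cosang <- sum(va$v * vb) / sqrt(sum(va$v^2) * sum(vb^2))
  # agreement limited only by re-binarisation of the masks (sub-voxel COM shifts)
  expect_lt(acos(pmin(1, cosang)) * 180 / pi, 0.5)
})

test_that("the degree-5 form is at least as robust as full-mesh PCA under surface noise", {
  set.seed(55)
  err_sph <- c(); err_full <- c()
  for (k in 1:3) {
    sp <- phantom_spec("rat", spacing = 100,
                       osteophyte = list(height = 700, sigma = 520,
                                         x = 3000, y = 900))
    sp$noise$amplitude <- 60
    sp$noise$seed <- 70 + k
    sp$pose$angles_deg <- runif(3, -30, 30)
    ph <- make_phantom_joint(sp)
    a1 <- align_joint(ph$joint, apply = FALSE)
    a2 <- align_joint(ph$joint, apply = FALSE, use_spharm = FALSE)
    err_sph <- c(err_sph, max(axis_angles_deg(a1$transform$R %*% ph$truth$pose$R)))
    err_full <- c(err_full, max(axis_angles_deg(a2$transform$R %*% ph$truth$pose$R)))
  }
  expect_lte(median(err_sph), median(err_full) + 1e-9)
})
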