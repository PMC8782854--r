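test_that("COM vector angles follow the axis geometry", {
  mk <- function(at) {
    a <- array(FALSE, c(21, 21, 21)); a[at[1], at[2], at[3]] <- TRUE
    voxel_mask(a, 10)
  }
  # vector along +z
  cv <- com_vector(mk(c(11, 11, 16)), mk(c(11, 11, 6)))
  expect_equal(c(cv$alpha, cv$beta, cv$gamma), c(90, 90, 0))
  # symmetric diagonal
  cv2 <- com_vector(mk(c(14, 14, 14)), mk(c(10, 10, 10)))
  expect_equal(cv2$alpha, 54.7356, tolerance = 1e-4)
  expect_equal(cv2$beta, cv2$alpha); expect_equal(cv2$gamma, cv2$alpha)
  expect_equal(cos(cv2$alpha * pi / 180)^2 * 3, 1, tolerance = 1e-9)
  expect_error(com_vector(mk(c(5, 5, 5)), mk(c(5, 5, 5))), "zero-length")
  # rigid rotation of both masks rotates the vector accordingly
  sp <- phantom_spec("rat", spacing = 120)
  ph <- make_phantom_joint(sp)
  v0 <- center_of_mass(ph$joint$femur) - center_of_mass(ph$joint$tibia)
  Tr <- rigid_transform(euler_rotation(c(15, -25, 35)))
  fr <- resample_rigid(ph$joint$femur, Tr)
  tr <- resample_rigid(ph$joint$tibia, Tr)
  v1 <- center_of_mass(fr) - center_of_mass(tr)
  vexp <- as.vector(Tr$R %*% v0)
  expect_lt(acos(sum(v1 * vexp) / sqrt(sum(v1^2) * sum(vexp^2))) * 180 / pi, 0.3)
})

test_that("parallel plates give the closed-form contact curve", {
  g <- 10; s <- 50
  jt <- make_plate_joint(gap_vox = g, foot_vox = c(40, 30), spacing = s)
  cc <- contact_area_curve(jt$tibia, jt$femur)
  A <- 40 * 30 * s^2 / 1e6
  expect_equal(cc$chi_um, g * s)           # chi = gap (+- step/2)
  expect_equal(cc$footprint_mm2, A)
  i <- which(cc$displacement == g * s)
  expect_equal(cc$area[i], A)              # area jumps to the full footprint
  expect_equal(cc$area[i - 1], 0)
  expect_equal(cc$m, A / (s / 1000))       # one-step window slope
  # contact area is monotone non-decreasing
  expect_true(all(diff(cc$area) >= 0))
  # chi decreases when the gap narrows
  jt2 <- make_plate_joint(gap_vox = 6, foot_vox = c(40, 30), spacing = s)
  expect_lt(contact_area_curve(jt2$tibia, jt2$femur)$chi_um, cc$chi_um)
  # already-overlapping inputs
  jt3 <- make_plate_joint(gap_vox = 0, foot_vox = c(10, 10), spacing = s)
  expect_equal(contact_area_curve(jt3$tibia, jt3$femur)$chi_um, 0)
})

test_that("cartilage composites shift contact to the cartilage clearance", {
  jt <- make_plate_joint(gap_vox = 6, foot_vox = c(30, 30), spacing = 50,
                         cart_vox = 2)
  # bone-to-bone distance is 6 + 2*2 voxels, cartilage clearance 6
  cc <- contact_area_curve(jt$tibia, jt$femur, jt$tibial_cartilage,
                           jt$femoral_cartilage)
  expect_equal(cc$chi_um, 6 * 50)
  ccb <- contact_area_curve(jt$tibia, jt$femur)
  expect_equal(ccb$chi_um, 10 * 50)
})

test_that("sphere-on-plate contact slope matches the analytic rate", {
  R <- 60; s <- 50
  jt <- make_sphere_plate_joint(R_vox = R, gap_vox = 6, foot_vox = c(70, 70),
                                thick_vox = 6, spacing = s)
  cc <- contact_area_curve(jt$tibia, jt$femur, max_shift = 14 * s)
  # A(d) ~ pi * 2R * (d - chi), so dA/dd = 2 pi R in mm^2/mm (R in um)
  m_true <- 2 * pi * (R * s) * 1e-3
  expect_lt(abs(cc$m - m_true) / m_true, 0.10)
})

test_that("joint space mask implements the strict between-bones rule", {
  g <- 8; s <- 50
  jt <- make_plate_joint(gap_vox = g, foot_vox = c(20, 15), spacing = s)
  sm <- joint_space_mask(jt$femur, jt$tibia)
  expect_equal(sum(sm$data), 20 * 15 * g)  # volume = A * g exactly
  # touching plates: empty mask
  jt0 <- make_plate_joint(gap_vox = 0, foot_vox = c(10, 10), spacing = s)
  sm0 <- joint_space_mask(jt0$femur, jt0$tibia)
  expect_equal(sum(sm0$data), 0)
  # columns covered by only one bone are excluded
  fem <- jt$femur
  fem$data[1:12, , ] <- FALSE  # femur retreats from some columns
  sm2 <- joint_space_mask(fem, jt$tibia)
  expect_equal(sum(sm2$data[1:12, , ]), 0)
})

test_that("slab joint space yields exact SPECTRA metrics", {
  g <- 8; s <- 50
  jt <- make_plate_joint(gap_vox = g, foot_vox = c(30, 24), spacing = s)
  sm <- joint_space_mask(jt$femur, jt$tibia)
  jm <- jsw_metrics(sm, obstacles = jt$femur$data | jt$tibia$data)
  expect_equal(jm$jsv, 30 * 24 * g * s^3 / 1e9)
  expect_lte(abs(jm$jsw - g * s), s)
  expect_lte(abs(jm$jsw_min - g * s), s)
  expect_lte(abs(jm$jsw_max - g * s), s)
  expect_true(jm$jsw_min <= jm$jsw && jm$jsw <= jm$jsw_max)
})

test_that("wedge gaps bracket the joint space width extremes", {
  g1 <- 4; g2 <- 12; s <- 50
  jt <- make_wedge_joint(gap_vox_1 = g1, gap_vox_2 = g2, spacing = s)
  sm <- joint_space_mask(jt$femur, jt$tibia)
  jm <- jsw_metrics(sm, obstacles = jt$femur$data | jt$tibia$data)
  expect_lte(abs(jm$jsw_min - g1 * s), s)
  expect_lte(abs(jm$jsw_max - g2 * s), s)
  expect_true(jm$jsw > jm$jsw_min && jm$jsw < jm$jsw_max)
})

test_that("joint space metrics are resolution-stable in world units", {
  jm_at <- function(s, scale) {
    jt <- make_plate_joint(gap_vox = round(8 / scale), foot_vox = round(c(24, 20) / scale),
                           thick_vox = round(6 / scale), spacing = s * scale)
    sm <- joint_space_mask(jt$femur, jt$tibia)
    jsw_metrics(sm, obstacles = jt$femur$data | jt$tibia$data)
  }
  fine <- jm_at(50, 1)
  coarse <- jm_at(50, 2)
  expect_lte(abs(fine$jsw - coarse$jsw), 100)       # one coarse voxel
  expect_lte(abs(fine$jsv - coarse$jsv) / fine$jsv, 0.1)
})

test_that("measure_joint degrades gracefully without cartilage", {
  sp <- phantom_spec("rat", spacing = 120)
  ph <- make_phantom_joint(sp)
  jt <- joint_image_set(tibia = ph$joint$tibia, femur = ph$joint$femur)
  sides <- split_joint(jt, 0)
  met <- measure_joint(sides, jt)
  expect_true(all(is.na(met$chi_mm)))
  expect_true(all(is.finite(met$alpha)))
  expect_true(all(is.finite(met$jsw_um)))
})
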