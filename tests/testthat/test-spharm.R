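test_that("basis closed forms and symmetries hold", {
  # Y_0^0 is constant 1/sqrt(4 pi)
  Z <- spharm_basis(0, c(0.3, 1.2, 2.9), c(0, 2, 4))
  expect_equal(as.vector(Z), rep(1 / sqrt(4 * pi), 3))
  # Y_1^0 at the pole
  expect_equal(spharm_basis(1, 0, 0)[1, sh_index(1, 0)], sqrt(3 / (4 * pi)))
  # complex conjugation symmetry Y_l^-m = (-1)^m Conj(Y_l^m)
  th <- c(0.4, 1.1, 2.2); ph <- c(0.5, 2.8, 5.1)
  Zc <- spharm_basis(4, th, ph, type = "complex")
  for (l in 1:4) for (m in 1:l)
    expect_equal(Zc[, sh_index(l, -m)], (-1)^m * Conj(Zc[, sh_index(l, m)]))
  expect_error(sh_index(2, 3), "\\|m\\| > l")
})

test_that("basis columns are orthonormal under exact grid quadrature", {
  nt <- 64; np <- 128
  th <- rep((seq_len(nt) - 0.5) * pi / nt, times = np)
  ph <- rep((seq_len(np) - 1) * 2 * pi / np, each = nt)
  Z <- spharm_basis(10, th, ph)
  w <- rep(theta_quadrature_weights(nt), times = np) * (2 * pi / np)
  G <- crossprod(Z * sqrt(w))
  expect_lt(max(abs(G - diag(ncol(Z)))), 1e-6)
})

test_that("least squares recovers exact coefficients on consistent systems", {
  set.seed(11)
  L <- 5; nc <- (L + 1)^2
  th <- runif(300) * pi; ph <- runif(300) * 2 * pi
  cstar <- matrix(rnorm(nc * 3), nc, 3)
  v <- spharm_basis(L, th, ph) %*% cstar
  pm <- structure(list(mesh = list(vertices = v), theta = th, phi = ph),
                  class = "param_mesh")
  f <- fit_spharm(pm, L)
  expect_lt(max(abs(f$coeffs - cstar)) / max(abs(cstar)), 1e-8)
  expect_lt(f$resid_rms, 1e-8)
  # degree too high for the vertex budget
  expect_error(fit_spharm(pm, 17), "too few vertices")
})

test_that("a centred ball is reconstructed at its radius", {
  b <- make_ball_mask(20, 10)
  s <- extract_surface(b)
  pm <- spherical_parameterize(s)
  # sphere parameterizes to its own spherical coordinates
  ctr <- (dim(b$data) / 2) * 10
  d <- sweep(s$vertices, 2, ctr); d <- d / sqrt(rowSums(d^2))
  expect_lt(max(abs(pm$theta - acos(pmin(1, pmax(-1, d[, 3]))))), 1e-6)
  f <- fit_spharm(pm, 6)
  rec <- reconstruct_surface(f, 6)
  r <- sqrt(rowSums(sweep(rec$vertices, 2, ctr)^2))
  expect_lt(max(abs(r - 200)) / 200, 0.01)
})

test_that("truncation gives the degenerate and hierarchical limits", {
  phantom <- tibia_phantom(spacing = 120)
  s <- extract_surface(phantom$tibia)
  pm <- spherical_parameterize(s)
  f <- fit_spharm(pm, 12, max_vertices = 8000)
  # L = 0: the expansion of each coordinate function is constant
  rec0 <- reconstruct_surface(f, 0)
  expect_lt(max(apply(rec0$vertices, 2, function(x) diff(range(x)))), 1e-6)
  # RMS distance to the mesh is non-increasing in truncation degree
  vv <- pm$mesh$vertices
  rms <- vapply(c(1, 5, 10, 12), function(L) {
    pred <- predict(f, pm$theta, pm$phi, L_trunc = L)
    sqrt(mean(rowSums((pred - vv)^2)))
  }, numeric(1))
  expect_true(all(diff(rms) <= 1e-9))
  # full-degree round trip on the fitted vertices: equals the fit residual
  expect_equal(sqrt(mean(rowSums(residuals(f)^2))), f$resid_rms)
})

test_that("truncated reconstruction is rotation equivariant", {
  phantom <- tibia_phantom(spacing = 120)
  s <- extract_surface(phantom$tibia)
  R <- euler_rotation(c(25, -15, 40))
  s_rot <- s
  s_rot$vertices <- s$vertices %*% t(R)
  attr(s_rot, "euler") <- 2
  rec1 <- reconstruct_surface(fit_spharm(spherical_parameterize(s), 10,
                                         max_vertices = 8000), 5)
  rec2 <- reconstruct_surface(fit_spharm(spherical_parameterize(s_rot), 10,
                                         max_vertices = 8000), 5)
  # the reconstructions describe the same surface up to R; the fixed grid
  # samples different surface points, so compare rotation-covariant shape
  # statistics computed with exact quadrature weights
  w <- attr(rec1, "weights"); w <- w / sum(w)
  diam <- max(dist(rec1$vertices[seq(1, nrow(rec1$vertices), length.out = 200), ]))
  mu1 <- colSums(rec1$vertices * w)
  mu2 <- colSums((rec2$vertices %*% R) * w)
  expect_lt(max(abs(mu1 - mu2)), 0.01 * diam)
  cov_of <- function(v, mu) {
    x <- sweep(v, 2, mu)
    eigen(crossprod(x * sqrt(w)), symmetric = TRUE)
  }
  e1 <- cov_of(rec1$vertices, mu1); e2 <- cov_of(rec2$vertices %*% R, mu2)
  expect_lt(max(abs(sqrt(e1$values) - sqrt(e2$values))), 0.01 * diam)
  # principal directions agree up to sign
  expect_lt(max(1 - abs(colSums(e1$vectors * e2$vectors))), 1e-3)
})

test_that("area relaxation reduces distortion on a prolate ellipsoid", {
  b <- make_ball_mask(14, 10)
  s <- extract_surface(b)
  s$vertices[, 1] <- s$vertices[, 1] * 2  # a = 2b = 2c
  attr(s, "euler") <- 2
  cv_r <- attr(spherical_parameterize(s, "radial"), "distortion")$cv
  cv_a <- attr(spherical_parameterize(s, "area", max_iter = 150), "distortion")$cv
  expect_lt(cv_a, cv_r)
})

test_that("non-spherical or non-star-shaped inputs are rejected", {
  tor <- extract_surface(make_torus_mask())
  expect_error(spherical_parameterize(tor), "genus")
  tube <- extract_surface(make_bent_tube_mask())
  expect_equal(attr(tube, "euler"), 2)
  expect_error(spherical_parameterize(tube, "radial"), "star-shaped")
})

test_that("coefficients serialise to a plain-text l/m table", {
  set.seed(4)
  th <- runif(60) * pi; ph <- runif(60) * 2 * pi
  v <- matrix(rnorm(180), 60, 3)
  pm <- structure(list(mesh = list(vertices = v), theta = th, phi = ph),
                  class = "param_mesh")
  f <- fit_spharm(pm, 3)
  tab <- coef(f)
  expect_equal(nrow(tab), 16)
  expect_equal(tab$l[sh_index(2, -1)], 2)
  expect_equal(tab$m[sh_index(2, -1)], -1)
  p <- file.path(tempdir(), "coefs.tsv")
  write_spharm_table(f, p)
  back <- read.delim(p)
  expect_equal(back$cx, tab$cx)
})
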