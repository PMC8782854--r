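#' Phantom joint specification
#'
#' Parametric description of a synthetic four-component knee joint with
#' known ground truth, used to validate every pipeline stage. Presets pin
#' the published scale of the two animal models (medial-lateral tibial
#' width 8.09 mm at 10 um voxels for the rat, 19.10 mm at 18 um for the
#' rabbit); all other shape parameters are package defaults at anatomically
#' plausible proportions.
#'
#' Geometry (canonical frame, micrometres): the tibial plateau top reference
#' plane is z = 0 with a gentle dome and two conical intercondylar tubercles
#' on top (their flanks cross in a V-shaped valley -- the dividing
#' landmark); the cross-section is a superellipse whose half-widths taper
#' towards a rounded distal cap, so the bone is star-shaped and genus 0 by
#' construction. The femur consists of two condylar lobes whose lower
#' surfaces sit `gap` above the plateau (growing quadratically away from
#' the condyle centre with effective radius `condyle_R`), joined by an
#' intercondylar bridge. Cartilage components are uniform-thickness shells
#' on the apposing surfaces. The anterior-posterior extent exceeds the
#' medial-lateral width (tibial tuberosity), giving the principal-variance
#' ordering the alignment relies on (AP > ML > vertical).
#'
#' @param preset `"rat"` or `"rabbit"`.
#' @param spacing voxel size in micrometres (defaults: 10 rat, 18 rabbit;
#'   coarser values give fast test-size phantoms of identical geometry).
#' @param pose list with `angles_deg` (extrinsic XYZ Euler angles) and
#'   `translation_um`, the acquisition pose of the joint.
#' @param noise list with `amplitude` (RMS bump height, um; 0 = none),
#'   `n_bumps`, `bump_sigma` (correlation scale, um) describing smooth
#'   surface roughness, and `seed`.
#' @param osteophyte `NULL`, or a list with `height`, `sigma`, `x`, `y`
#'   (um) adding a marginal spike at the plateau rim.
#' @param gap_medial,gap_lateral bone-to-bone joint gap at the condyle
#'   centres (um).
#' @param ... overrides for any geometry field (see the function body for
#'   the full list).
#' @return class `phantom_spec` (a list).
#' @export
phantom_spec <- function(preset = c("rat", "rabbit"), spacing = NULL,
                         pose = list(angles_deg = c(0, 0, 0),
                                     translation_um = c(0, 0, 0)),
                         noise = list(amplitude = 0, n_bumps = 30,
                                      bump_sigma = NULL, seed = 1),
                         osteophyte = NULL,
                         gap_medial = NULL, gap_lateral = NULL, ...) {
  preset <- match.arg(preset)
  sc <- if (preset == "rat") 1 else 19100 / 8090
  base <- list(
    preset = preset,
    width = 8090 * sc,            # ML extent (published typical width)
    depth = 9300 * sc,            # AP extent incl. tuberosity
    tibia_height = 3000 * sc,     # epiphyseal crop: flat plate, not long bone
    plateau_thickness = 1500 * sc,
    shaft_frac = 0.62,
    plateau_asym = 0.05,          # medial (-x) half slightly wider
    exponent = 3.5,
    dome_height = 350 * sc,
    tub_x = c(-780, 780) * sc,    # medial tubercle at -x
    tub_w = c(950, 950) * sc,
    tub_h = c(864, 736) * sc,     # slight medial/lateral asymmetry
    gap_medial = 560 * sc,
    gap_lateral = 530 * sc,
    condyle_xc = 2100 * sc,
    condyle_halfwidth = 1500 * sc,
    condyle_depth = 2200 * sc,
    condyle_yc = -400 * sc,
    condyle_exponent = 2.5,
    condyle_R = 4000 * sc,
    notch_halfwidth = 1850 * sc,  # femur cleared of the eminence

    femur_height = 2600 * sc,
    bridge_halfwidth = NULL,      # filled below
    bridge_depth = NULL,
    bridge_clearance = 900 * sc,
    bridge_offset = c(0, 0),
    cart_tibial = 110 * sc,
    cart_femoral = 110 * sc,
    spacing = if (is.null(spacing)) (if (preset == "rat") 10 else 18) else spacing,
    pose = pose, noise = noise, osteophyte = osteophyte)
  base$bridge_halfwidth <- base$condyle_xc + base$condyle_halfwidth / 2
  base$bridge_depth <- base$condyle_depth * 0.8
  if (is.null(base$noise$bump_sigma) || is.null(noise$bump_sigma))
    base$noise$bump_sigma <- base$tub_w[1] / 3
  if (is.null(base$noise$n_bumps)) base$noise$n_bumps <- 30
  if (is.null(base$noise$seed)) base$noise$seed <- 1
  if (!is.null(gap_medial)) base$gap_medial <- gap_medial
  if (!is.null(gap_lateral)) base$gap_lateral <- gap_lateral
  dots <- list(...)
  for (nm in names(dots)) base[[nm]] <- dots[[nm]]
  structure(base, class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec '%s'> ML width %.2f mm, spacing %g um, pose (%s) deg\n",
              x$preset, x$width / 1000, x$spacing,
              paste(signif(x$pose$angles_deg, 3), collapse = ", ")))
  invisible(x)
}

# dense correlated roughness field: white noise on a lattice with step
# bump_sigma, smoothed with a one-cell Gaussian and bilinearly interpolated;
# rescaled to the requested RMS amplitude. Deterministic in the seed.
bump_field <- function(spec) {
  nz <- spec$noise
  if (is.null(nz) || nz$amplitude <= 0) return(function(x, y) 0)
  rs <- local_rng(nz$seed)
  L <- nz$bump_sigma
  x0 <- -spec$width / 2 - 2 * L; x1 <- spec$width / 2 + 2 * L
  y0 <- -spec$depth / 2 - 2 * L; y1 <- spec$depth / 2 + 2 * L
  nxg <- ceiling((x1 - x0) / L) + 1L
  nyg <- ceiling((y1 - y0) / L) + 1L
  g <- matrix(rs$rnorm(nxg * nyg), nxg, nyg)
  k <- exp(-0.5 * (-2:2)^2)
  k <- k / sum(k)
  sm1 <- function(v) {
    n <- length(v)
    as.numeric(stats::filter(c(v[2], v[1], v, v[n], v[n - 1]), k))[3:(n + 2)]
  }
  g <- apply(g, 2, sm1)
  g <- t(apply(g, 1, sm1))
  # normalise the RMS of the *interpolated* field (bilinear interpolation
  # between correlated lattice values loses some variance)
  mid <- (g[-nxg, -nyg] + g[-1, -nyg] + g[-nxg, -1] + g[-1, -1]) / 4
  probe <- c(as.vector(g), as.vector(mid))
  g <- g * nz$amplitude / stats::sd(probe)
  function(x, y) {
    fx <- pmin(pmax((x - x0) / L, 0), nxg - 1.001)
    fy <- pmin(pmax((y - y0) / L, 0), nyg - 1.001)
    i0 <- floor(fx); j0 <- floor(fy)
    tx <- fx - i0; ty <- fy - j0
    i0 <- i0 + 1L; j0 <- j0 + 1L
    g[cbind(i0, j0)] * (1 - tx) * (1 - ty) +
      g[cbind(i0 + 1L, j0)] * tx * (1 - ty) +
      g[cbind(i0, j0 + 1L)] * (1 - tx) * ty +
      g[cbind(i0 + 1L, j0 + 1L)] * tx * ty
  }
}

# seeded RNG stream that does not disturb the global .Random.seed
local_rng <- function(seed) {
  env <- new.env()
  env$state <- {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    st <- get(".Random.seed", globalenv())
    if (!is.null(old)) assign(".Random.seed", old, globalenv()) else rm(".Random.seed", envir = globalenv())
    st
  }
  draw <- function(fun) function(...) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    out <- fun(...)
    env$state <- get(".Random.seed", globalenv())
    if (!is.null(old)) assign(".Random.seed", old, globalenv()) else rm(".Random.seed", envir = globalenv())
    out
  }
  list(runif = draw(stats::runif), rnorm = draw(stats::rnorm))
}

# canonical-frame top surface of the tibia (vectorised over x, y)
tibia_top_surface <- function(spec, x, y, with_noise = TRUE) {
  dome <- spec$dome_height *
    pmax(0, 1 - (x / (spec$width / 2))^2 - (y / (spec$depth / 2))^2)
  r1 <- sqrt((x - spec$tub_x[1])^2 + y^2)
  r2 <- sqrt((x - spec$tub_x[2])^2 + y^2)
  em <- pmax(spec$tub_h[1] * pmax(0, 1 - r1 / spec$tub_w[1]),
             spec$tub_h[2] * pmax(0, 1 - r2 / spec$tub_w[2]))
  z <- dome + em
  if (!is.null(spec$osteophyte)) {
    o <- spec$osteophyte
    z <- z + o$height * exp(-((x - o$x)^2 + (y - o$y)^2) / (2 * o$sigma^2))
  }
  if (with_noise) z <- z + bump_field(spec)(x, y)
  z
}

# femoral lower surface per side over its condyle footprint (list of fns)
femur_surfaces <- function(spec) {
  sides <- list(medial = -spec$condyle_xc, lateral = spec$condyle_xc)
  gaps <- c(medial = spec$gap_medial, lateral = spec$gap_lateral)
  lapply(names(sides), function(s) {
    xc <- sides[[s]]; yc <- spec$condyle_yc
    zref <- tibia_top_surface(spec, xc, yc, with_noise = FALSE)
    list(side = s, xc = xc, yc = yc, gap = gaps[[s]], zref = zref,
         foot = function(x, y)
           ((abs(x - xc) / spec$condyle_halfwidth)^spec$condyle_exponent +
            (abs(y - yc) / spec$condyle_depth)^spec$condyle_exponent <= 1) &
           abs(x) >= spec$notch_halfwidth,
         zf = function(x, y)
           zref + gaps[[s]] + ((x - xc)^2 + (y - yc)^2) / (2 * spec$condyle_R))
  })
}

#' Generate a phantom joint with ground truth
#'
#' Voxelises the four components of the phantom described by `spec` on a
#' common grid in the posed frame (implicit surfaces are evaluated through
#' the inverse pose, so no resampling error enters the ground truth).
#'
#' @param spec a [phantom_spec].
#' @param tibia_only if `TRUE` return just the tibia [voxel_mask] (fast
#'   fixtures for the subdivision tests).
#' @param margin_um extra world margin around the joint bounding box.
#' @return list with `joint` (a [joint_image_set]) and `truth`: pose,
#'   dividing point `x_star` (um, canonical frame), per-side bone gap and
#'   cartilage clearance `chi_um`, analytic contact slope `m_mm2_mm`, and
#'   the canonical-frame centre-of-mass vector.
#' @export
make_phantom_joint <- function(spec, tibia_only = FALSE, margin_um = NULL) {
  s <- spec$spacing
  if (is.null(margin_um)) margin_um <- 6 * s
  R <- euler_rotation(spec$pose$angles_deg)
  tr <- rigid_transform(R, spec$pose$translation_um)
  zmaxgap <- max(spec$gap_medial, spec$gap_lateral)
  zhi <- spec$dome_height + zmaxgap + spec$femur_height + 200
  if (tibia_only) zhi <- spec$dome_height + max(spec$tub_h) +
    (if (is.null(spec$osteophyte)) 0 else spec$osteophyte$height) + 400
  corners <- as.matrix(expand.grid(c(-1, 1) * (spec$width / 2 + margin_um),
                                   c(-1, 1) * (spec$depth / 2 + margin_um),
                                   c(-spec$tibia_height - margin_um, zhi + margin_um)))
  pc <- rt_apply(tr, corners)
  lo <- floor(apply(pc, 2, min) / s) * s
  hi <- apply(pc, 2, max)
  dm <- as.integer(ceiling((hi - lo) / s))
  # world voxel centres -> canonical coordinates
  ii <- (seq_len(dm[1]) - 0.5) * s + lo[1]
  jj <- (seq_len(dm[2]) - 0.5) * s + lo[2]
  kk <- (seq_len(dm[3]) - 0.5) * s + lo[3]
  W <- cbind(rep(ii, times = dm[2] * dm[3]),
             rep(rep(jj, each = dm[1]), times = dm[3]),
             rep(kk, each = dm[1] * dm[2]))
  Cc <- rt_apply(rt_invert(tr), W)
  X <- Cc[, 1]; Y <- Cc[, 2]; Z <- Cc[, 3]
  rm(W, Cc)
  zs <- tibia_top_surface(spec, X, Y)
  zbot <- -spec$tibia_height
  capr <- 0.25 * spec$tibia_height
  taper <- ifelse(Z >= -spec$plateau_thickness, 1,
                  spec$shaft_frac + (1 - spec$shaft_frac) *
                    (Z - zbot) / (-spec$plateau_thickness - zbot))
  cap <- ifelse(Z < zbot + capr,
                sqrt(pmax(0, 1 - ((zbot + capr - Z) / capr)^2)), 1)
  asym <- ifelse(X < 0, 1 + spec$plateau_asym, 1 - spec$plateau_asym)
  ax <- spec$width / 2 * taper * cap * asym
  by <- spec$depth / 2 * taper * cap
  se <- (abs(X) / ax)^spec$exponent + (abs(Y) / by)^spec$exponent
  tib <- Z >= zbot & Z <= zs & se <= 1
  mk <- function(v, label) voxel_mask(array(v, dm), s, lo, label)
  if (tibia_only) {
    return(list(tibia = mk(tib, "tibia"), truth = phantom_truth(spec, tr)))
  }
  fs <- femur_surfaces(spec)
  fm <- fs[[1]]; fl <- fs[[2]]
  footm <- fm$foot(X, Y); footl <- fl$foot(X, Y)
  zfm <- fm$zf(X, Y); zfl <- fl$zf(X, Y)
  zftop <- max(fm$zref + fm$gap, fl$zref + fl$gap) + spec$femur_height
  zbridge <- max(fm$zref + fm$gap, fl$zref + fl$gap) + spec$bridge_clearance
  bx <- spec$bridge_offset[1]; byo <- spec$bridge_offset[2] + spec$condyle_yc
  bridge <- ((X - bx) / spec$bridge_halfwidth)^2 +
    ((Y - byo) / spec$bridge_depth)^2 <= 1
  fem <- ((footm & Z >= zfm) | (footl & Z >= zfl) | (bridge & Z >= zbridge)) &
    Z <= zftop
  # a sheet thinner than one voxel would fragment when voxelised
  ct_t <- max(spec$cart_tibial, s)
  ct_f <- max(spec$cart_femoral, s)
  tcart <- (footm | footl) & Z > zs & Z <= zs + ct_t
  fcart <- (footm & Z < zfm & Z >= zfm - ct_f) |
           (footl & Z < zfl & Z >= zfl - ct_f)
  joint <- joint_image_set(
    tibia = mk(tib, "tibia"), femur = mk(fem, "femur"),
    tibial_cartilage = mk(tcart, "tibial_cartilage"),
    femoral_cartilage = mk(fcart, "femoral_cartilage"),
    provenance = sprintf("%s-phantom", spec$preset))
  truth <- phantom_truth(spec, tr, ct_t, ct_f)
  vposed <- center_of_mass(joint$femur) - center_of_mass(joint$tibia)
  truth$com_canonical <- as.vector(t(R) %*% vposed)
  # canonical-frame tibial COM: align_joint() recentres the tibia COM at the
  # world origin, so canonical coordinates map to aligned ones by
  # subtracting this vector
  truth$tibia_com_canonical <-
    as.vector(t(R) %*% (center_of_mass(joint$tibia) - tr$t))
  list(joint = joint, truth = truth)
}

phantom_truth <- function(spec, tr, ct_t = spec$cart_tibial,
                          ct_f = spec$cart_femoral) {
  xx <- seq(-spec$width / 2, spec$width / 2, by = spec$spacing / 4)
  prof <- tibia_top_surface(spec, xx, rep(0, length(xx)), with_noise = FALSE)
  # valley between the tubercle peaks of the noiseless profile
  inb <- xx > spec$tub_x[1] & xx < spec$tub_x[2]
  x_star <- xx[inb][which.min(prof[inb])]
  list(pose = list(R = tr$R, t = tr$t, angles_deg = spec$pose$angles_deg),
       x_star = x_star,
       gap_um = c(medial = spec$gap_medial, lateral = spec$gap_lateral),
       chi_um = c(medial = spec$gap_medial, lateral = spec$gap_lateral) -
         ct_t - ct_f,
       m_mm2_mm = 2 * pi * spec$condyle_R * 1e-3,
       width = spec$width, spacing = spec$spacing)
}

#' Simulate repeat scans with repositioning jitter
#'
#' Re-poses the same anatomy `n_repeats` times with bounded random rigid
#' jitter (emulating re-positioning between scans) and an independent
#' surface-roughness realisation per repeat.
#'
#' @param spec a [phantom_spec]; its `pose` is the subject's base pose.
#' @param n_repeats number of repeat scans (>= 2).
#' @param jitter_deg,jitter_um uniform bounds of the per-repeat Euler-angle
#'   and translation jitter (defaults 10 degrees / 20 voxels).
#' @param noise_amplitude RMS surface roughness per repeat (um).
#' @param seed RNG seed.
#' @param ... passed on to [make_phantom_joint()] (e.g. `tibia_only`).
#' @return list of `n_repeats` results of [make_phantom_joint()].
#' @export
make_repeat_scans <- function(spec, n_repeats = 4, jitter_deg = 10,
                              jitter_um = NULL, noise_amplitude = NULL,
                              seed = 1, ...) {
  if (n_repeats < 2) stop("n_repeats must be >= 2")
  if (is.null(jitter_um)) jitter_um <- 20 * spec$spacing
  rs <- local_rng(seed)
  lapply(seq_len(n_repeats), function(r) {
    sp <- spec
    sp$pose$angles_deg <- spec$pose$angles_deg +
      rs$runif(3, -jitter_deg, jitter_deg)
    sp$pose$translation_um <- spec$pose$translation_um +
      rs$runif(3, -jitter_um, jitter_um)
    sp$noise$seed <- spec$noise$seed + 1000 * r
    if (!is.null(noise_amplitude)) sp$noise$amplitude <- noise_amplitude
    make_phantom_joint(sp, ...)
  })
}

#' Sample a population of phantom subjects
#'
#' Draws `n` subject specs around a preset with anatomically plausible
#' between-subject variation: ML width SD follows the published cohorts
#' (0.62 mm rat, 0.59 mm rabbit), joint gaps, tubercle geometry, condyle
#' curvature and femoral bridge offset vary proportionally.
#'
#' @param n number of subjects.
#' @param preset `"rat"` or `"rabbit"`.
#' @param spacing voxel size (um).
#' @param seed RNG seed.
#' @return list of [phantom_spec]s.
#' @export
sample_phantom_population <- function(n, preset = "rat", spacing = NULL,
                                      seed = 1) {
  rs <- local_rng(seed)
  base <- phantom_spec(preset, spacing = spacing)
  sdw <- if (preset == "rat") 620 else 590
  lapply(seq_len(n), function(i) {
    f <- function(sd) rs$rnorm(1, 0, sd)
    sc <- 1 + f(sdw / base$width)      # overall size factor
    sp <- phantom_spec(
      preset, spacing = base$spacing,
      width = base$width * sc, depth = base$depth * sc,
      tibia_height = base$tibia_height * sc,
      tub_h = base$tub_h * (1 + f(0.10)),
      tub_x = base$tub_x * (1 + f(0.06)),
      gap_medial = base$gap_medial * (1 + f(0.18)),
      gap_lateral = base$gap_lateral * (1 + f(0.18)),
      condyle_R = base$condyle_R * (1 + f(0.15)),
      condyle_yc = base$condyle_yc + f(0.05 * base$depth),
      bridge_offset = c(f(0.06 * base$width), f(0.06 * base$depth)),
      femur_height = base$femur_height * (1 + f(0.08)))
    sp$noise$seed <- seed + i
    sp
  })
}

# ---------------------------------------------------------------------------
# Closed-form phantoms for the QMA unit tests

#' Parallel-plate, wedge and sphere-on-plate joints
#'
#' Minimal analytic joints for closed-form checks of the contact and joint
#' space metrics. All sizes are given in voxels of the chosen spacing so the
#' expected values are exact in voxel units. The "tibia" is the lower plate
#' (top surface at z = 0 world), the "femur" the upper body.
#'
#' @param gap_vox gap between the plates in voxels.
#' @param foot_vox footprint (x, y) in voxels.
#' @param thick_vox plate thickness in voxels.
#' @param spacing voxel size (um).
#' @param cart_vox optional cartilage sheet thickness (voxels; 0 = none).
#' @return a [joint_image_set].
#' @export
make_plate_joint <- function(gap_vox = 10, foot_vox = c(40, 30),
                             thick_vox = 6, spacing = 50, cart_vox = 0) {
  nx <- foot_vox[1] + 8; ny <- foot_vox[2] + 8
  nz <- 2 * thick_vox + gap_vox + 2 * cart_vox + 8
  inx <- 5:(4 + foot_vox[1]); iny <- 5:(4 + foot_vox[2])
  blank <- function() array(FALSE, c(nx, ny, nz))
  z0 <- thick_vox + 1  # first z index above the lower plate
  tib <- blank(); tib[inx, iny, 1:thick_vox] <- TRUE
  fembot <- z0 + cart_vox + gap_vox + cart_vox
  fem <- blank(); fem[inx, iny, fembot:(fembot + thick_vox - 1)] <- TRUE
  org <- c(0, 0, -thick_vox * spacing)
  out <- list(tibia = voxel_mask(tib, spacing, org, "tibia"),
              femur = voxel_mask(fem, spacing, org, "femur"))
  if (cart_vox > 0) {
    tc <- blank(); tc[inx, iny, z0:(z0 + cart_vox - 1)] <- TRUE
    fc <- blank(); fc[inx, iny, (fembot - cart_vox):(fembot - 1)] <- TRUE
    out$tibial_cartilage <- voxel_mask(tc, spacing, org, "tibial_cartilage")
    out$femoral_cartilage <- voxel_mask(fc, spacing, org, "femoral_cartilage")
  }
  do.call(joint_image_set, c(out, list(provenance = "plate-phantom")))
}

#' @rdname make_plate_joint
#' @param gap_vox_1,gap_vox_2 gap in voxels at the two x ends of the wedge.
#' @export
make_wedge_joint <- function(gap_vox_1 = 4, gap_vox_2 = 12,
                             foot_vox = c(40, 30), thick_vox = 6,
                             spacing = 50) {
  nx <- foot_vox[1] + 8; ny <- foot_vox[2] + 8
  gmax <- max(gap_vox_1, gap_vox_2)
  nz <- 2 * thick_vox + gmax + 8
  inx <- 5:(4 + foot_vox[1]); iny <- 5:(4 + foot_vox[2])
  tib <- array(FALSE, c(nx, ny, nz)); tib[inx, iny, 1:thick_vox] <- TRUE
  fem <- array(FALSE, c(nx, ny, nz))
  g <- round(gap_vox_1 + (gap_vox_2 - gap_vox_1) *
               (seq_along(inx) - 1) / (length(inx) - 1))
  for (q in seq_along(inx)) {
    zlo <- thick_vox + g[q] + 1
    fem[inx[q], iny, zlo:(zlo + thick_vox - 1)] <- TRUE
  }
  org <- c(0, 0, -thick_vox * spacing)
  joint_image_set(tibia = voxel_mask(tib, spacing, org, "tibia"),
                  femur = voxel_mask(fem, spacing, org, "femur"),
                  provenance = "wedge-phantom")
}

#' @rdname make_plate_joint
#' @param R_vox sphere radius in voxels.
#' @export
make_sphere_plate_joint <- function(R_vox = 60, gap_vox = 6,
                                    foot_vox = c(70, 70), thick_vox = 6,
                                    spacing = 50) {
  nx <- foot_vox[1] + 8; ny <- foot_vox[2] + 8
  capz <- 20
  nz <- thick_vox + gap_vox + capz + 8
  inx <- 5:(4 + foot_vox[1]); iny <- 5:(4 + foot_vox[2])
  tib <- array(FALSE, c(nx, ny, nz)); tib[inx, iny, 1:thick_vox] <- TRUE
  # sphere of radius R touching z = gap plane from above, centred over grid
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  xi <- seq_len(nx) - cx; yi <- seq_len(ny) - cy
  r2 <- outer(xi^2, yi^2, "+")
  zbot <- thick_vox + gap_vox + (R_vox - sqrt(pmax(0, R_vox^2 - r2)))
  fem <- array(FALSE, c(nx, ny, nz))
  for (k in (thick_vox + gap_vox + 1):nz)
    fem[, , k] <- r2 <= R_vox^2 & (k - 0.5) > zbot
  org <- c(0, 0, -thick_vox * spacing)
  joint_image_set(tibia = voxel_mask(tib, spacing, org, "tibia"),
                  femur = voxel_mask(fem, spacing, org, "femur"),
                  provenance = "sphere-plate-phantom")
}

#' Digital ball mask (test fixture)
#'
#' @param r_vox radius in voxels.
#' @param spacing voxel size (um).
#' @param centre_vox optional centre in 0-based voxel units (defaults to the
#'   grid centre, on a voxel centre).
#' @return a [voxel_mask].
#' @export
make_ball_mask <- function(r_vox = 20, spacing = 10, centre_vox = NULL) {
  n <- 2 * ceiling(r_vox) + 7
  if (is.null(centre_vox)) centre_vox <- rep((n - 1) / 2, 3)
  idx <- seq_len(n) - 1
  d2 <- outer(outer((idx - centre_vox[1])^2, (idx - centre_vox[2])^2, "+"),
              (idx - centre_vox[3])^2, "+")
  voxel_mask(array(d2 <= r_vox^2, c(n, n, n)), spacing, c(0, 0, 0), "tibia")
}
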