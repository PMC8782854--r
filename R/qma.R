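#' Joint centre-of-mass vector
#'
#' The vector from the tibial to the femoral centre of mass and its angles
#' (degrees) to the three Cartesian axes; `cos2(a) + cos2(b) + cos2(g) = 1`.
#' Measures the relative position of the joint and the quality of the
#' alignment.
#'
#' @param femur,tibia [voxel_mask] objects on a common world frame.
#' @return class `com_vector`: `v` (micrometres), `alpha`, `beta`, `gamma`
#'   (degrees in `[0, 180]`).
#' @export
com_vector <- function(femur, tibia) {
  v <- center_of_mass(femur) - center_of_mass(tibia)
  nv <- sqrt(sum(v^2))
  if (nv == 0) stop("coincident centres of mass: zero-length joint vector")
  ang <- acos(pmin(1, pmax(-1, v / nv))) * 180 / pi
  structure(list(v = v, alpha = ang[1], beta = ang[2], gamma = ang[3]),
            class = "com_vector")
}

#' @export
print.com_vector <- function(x, ...) {
  cat(sprintf("<com_vector> |v| = %.0f um, alpha %.2f, beta %.2f, gamma %.2f deg\n",
              sqrt(sum(x$v^2)), x$alpha, x$beta, x$gamma))
  invisible(x)
}

#' Contact area under virtual loading
#'
#' Incrementally shifts the tibial composite (bone + cartilage) up the
#' vertical z axis onto the femoral composite and records the contact area
#' at each displacement, defined as the area of the xy projection of the
#' overlap between the two shifted composites. `chi` is the displacement at
#' first contact; `m` the least-squares slope of area versus displacement
#' over the post-contact window (from the last zero-area sample up to the
#' displacement at which half of the shared footprint is in contact).
#'
#' @param tibia,femur bone [voxel_mask]s on a common grid.
#' @param tibial_cartilage,femoral_cartilage optional cartilage masks merged
#'   into the respective composite.
#' @param step displacement increment in micrometres; rounded to a whole
#'   number of voxels (minimum 1).
#' @param max_shift largest displacement tried, micrometres.
#' @return class `contact_curve`: `displacement` (um), `area` (mm^2),
#'   `chi_um`, `chi_mm`, `m` (mm^2/mm), `window` (indices used for the
#'   slope fit), `footprint_mm2`.
#' @export
contact_area_curve <- function(tibia, femur, tibial_cartilage = NULL,
                               femoral_cartilage = NULL,
                               step = NULL, max_shift = NULL) {
  s <- tibia$spacing
  same_grid <- function(a, b)
    all(dim(a$data) == dim(b$data)) && max(abs(a$origin - b$origin)) < 1e-6
  if (!same_grid(tibia, femur)) stop("masks must share one grid")
  tcomp <- tibia$data
  if (!is.null(tibial_cartilage)) tcomp <- tcomp | tibial_cartilage$data
  fcomp <- femur$data
  if (!is.null(femoral_cartilage)) fcomp <- fcomp | femoral_cartilage$data
  d <- dim(tcomp)
  if (is.null(step)) step <- s
  kstep <- max(1L, as.integer(round(step / s)))
  step_um <- kstep * s
  if (is.null(max_shift)) max_shift <- d[3] * s / 2
  kmax <- min(d[3] - 2L, as.integer(floor(max_shift / step_um)) * kstep)
  shifts <- seq(0L, kmax, by = kstep)
  # per-column highest tibial and lowest femoral voxel; voxel surfaces touch
  # when the runs become adjacent, i.e. at a displacement of
  # (min_femur - max_tibia - 1) voxels
  nc <- d[1] * d[2]
  tm <- matrix(as.integer(tcomp), nc); fm <- matrix(as.integer(fcomp), nc)
  tmax <- max.col(tm, ties.method = "last")
  tmax[rowSums(tm) == 0] <- NA
  fmin <- max.col(fm[, d[3]:1, drop = FALSE], ties.method = "last")
  fmin <- d[3] + 1L - fmin
  fmin[rowSums(fm) == 0] <- NA
  dmin <- fmin - tmax - 1L
  footprint <- sum(!is.na(dmin))
  area <- vapply(shifts, function(k) sum(dmin <= k, na.rm = TRUE), numeric(1))
  disp <- shifts * s
  area_mm2 <- area * s^2 / 1e6
  first <- which(area > 0)[1]
  chi_um <- if (is.na(first)) NA_real_ else disp[first]
  m <- NA_real_
  window <- NULL
  if (!is.na(first)) {
    i0 <- max(1L, first - 1L)
    iend <- which(area >= 0.5 * footprint)[1]
    if (is.na(iend)) iend <- length(area)
    window <- i0:iend
    if (length(window) >= 2) {
      ft <- stats::lm(area_mm2[window] ~ I(disp[window] / 1000))
      m <- unname(stats::coef(ft)[2])
    }
  } else {
    warning("no contact within max_shift: chi undefined")
  }
  structure(list(displacement = disp, area = area_mm2,
                 chi_um = chi_um, chi_mm = chi_um / 1000, m = m,
                 window = window, footprint_mm2 = footprint * s^2 / 1e6),
            class = "contact_curve")
}

#' @export
print.contact_curve <- function(x, ...) {
  cat(sprintf("<contact_curve> chi = %.3f mm, m = %.2f mm^2/mm (%d displacements)\n",
              x$chi_mm, x$m, length(x$displacement)))
  invisible(x)
}

#' Joint-space mask between two bones
#'
#' Background voxels lying, within each `(x, y)` column where both bones are
#' present, strictly between the highest tibial and the lowest femoral
#' foreground voxel.
#'
#' @param femur,tibia bone [voxel_mask]s on a common grid (aligned,
#'   disjoint).
#' @return a [voxel_mask] of the joint space (possibly empty if the bones
#'   touch everywhere).
#' @export
joint_space_mask <- function(femur, tibia) {
  d <- dim(tibia$data)
  if (!all(dim(femur$data) == d) || max(abs(femur$origin - tibia$origin)) > 1e-6)
    stop("masks must share one grid")
  nz <- d[3]
  ttop <- matrix(-Inf, d[1], d[2])
  fbot <- matrix(Inf, d[1], d[2])
  for (k in seq_len(nz)) {
    st <- tibia$data[, , k]
    if (any(st)) ttop[st] <- k
    sf <- femur$data[, , nz - k + 1]
    if (any(sf)) fbot[sf] <- nz - k + 1
  }
  ok <- is.finite(ttop) & is.finite(fbot)
  if (!any(ok)) stop("empty shared footprint")
  ttop[!ok] <- NA; fbot[!ok] <- NA
  space <- array(FALSE, d)
  kz <- rep(seq_len(nz), each = d[1] * d[2])
  space <- array(kz > as.vector(ttop) & kz < as.vector(fbot), d)
  space[is.na(space)] <- FALSE
  space <- space & !tibia$data & !femur$data
  voxel_mask(space, tibia$spacing, tibia$origin, "joint_space",
             allow_empty = TRUE)
}

#' SPECTRA-style 3D joint space metrics
#'
#' Local thickness of the joint-space mask by the largest-inscribed-sphere
#' (Hildebrand-Rueegsegger) method. JSW is the (volume-weighted) mean
#' thickness over the joint space; JSW.min and JSW.max are taken after
#' discarding the lowest `trim` quantile of the thickness map (guard
#' against single-voxel artefacts); JSV is voxel count times voxel volume.
#'
#' When the bounding bone masks are supplied as `obstacles`, the inscribed
#' spheres are centred in the joint space and bounded only by bone, so the
#' width is the bone-to-bone distance even at the open lateral margins of
#' the compartment (a sphere may overhang into air but not into bone).
#' Without `obstacles`, any non-space voxel (and the volume border) limits
#' the spheres.
#'
#' @param space_mask a non-empty joint-space [voxel_mask] (see
#'   [joint_space_mask()]).
#' @param obstacles optional [voxel_mask] (or logical array on the same
#'   grid) of the structures bounding the space, typically
#'   `femur | tibia`.
#' @param trim lower quantile of the thickness map discarded before the
#'   extremes (default 0.001, i.e. the 0.1 percentile).
#' @return class `joint_space_result`: `jsw`, `jsw_min`, `jsw_max`
#'   (micrometres), `jsv` (mm^3), `n_voxels`, and `thickness` (the voxel
#'   thickness map, micrometres, as a [voxel_mask]-shaped array).
#' @export
jsw_metrics <- function(space_mask, obstacles = NULL, trim = 0.001) {
  if (!any(space_mask$data)) stop("empty joint-space mask")
  d <- dim(space_mask$data)
  if (!is.null(obstacles)) {
    ob <- if (inherits(obstacles, "voxel_mask")) obstacles$data else obstacles
    if (!all(dim(ob) == d)) stop("obstacles must be on the space-mask grid")
    th <- cpp_local_thickness_between(as.logical(space_mask$data),
                                      as.logical(ob), d) * space_mask$spacing
  } else {
    th <- cpp_local_thickness(as.logical(space_mask$data), d) * space_mask$spacing
  }
  vals <- th[as.vector(space_mask$data)]
  lo <- stats::quantile(vals, trim)
  kept <- vals[vals >= lo]
  structure(list(jsw = mean(vals),
                 jsw_min = min(kept), jsw_max = max(kept),
                 jsv = sum(space_mask$data) * space_mask$spacing^3 / 1e9,
                 n_voxels = sum(space_mask$data),
                 thickness = array(th, d)),
            class = "joint_space_result")
}

#' @export
print.joint_space_result <- function(x, ...) {
  cat(sprintf("<joint_space_result> JSW %.1f um [%.1f, %.1f], JSV %.4g mm^3\n",
              x$jsw, x$jsw_min, x$jsw_max, x$jsv))
  invisible(x)
}

#' Measure all joint QMA metrics on an aligned, subdivided joint
#'
#' @param sides list with `medial` and `lateral` [joint_image_set]s (from
#'   [split_joint()]).
#' @param whole the whole aligned [joint_image_set] (for the centre-of-mass
#'   vector).
#' @param step,max_shift passed to [contact_area_curve()].
#' @return one-row data frame per side bound together: columns `side`,
#'   `alpha`, `beta`, `gamma` (degrees, whole joint), `chi_mm`, `m_mm2_mm`,
#'   `jsw_um`, `jsw_min_um`, `jsw_max_um`, `jsv_mm3`.
#' @export
measure_joint <- function(sides, whole, step = NULL, max_shift = NULL) {
  cv <- com_vector(whole$femur, whole$tibia)
  one <- function(side_name) {
    js <- sides[[side_name]]
    chi <- NA_real_; m <- NA_real_
    if (!is.null(js$tibial_cartilage) && !is.null(js$femoral_cartilage) &&
        any(js$tibia$data) && any(js$femur$data)) {
      cc <- contact_area_curve(js$tibia, js$femur, js$tibial_cartilage,
                               js$femoral_cartilage, step = step,
                               max_shift = max_shift)
      chi <- cc$chi_mm; m <- cc$m
    }
    jsw <- jsw_min <- jsw_max <- jsv <- NA_real_
    if (any(js$tibia$data) && any(js$femur$data)) {
      sm <- try(joint_space_mask(js$femur, js$tibia), silent = TRUE)
      if (!inherits(sm, "try-error") && any(sm$data)) {
        jm <- jsw_metrics(sm, obstacles = js$femur$data | js$tibia$data)
        jsw <- jm$jsw; jsw_min <- jm$jsw_min; jsw_max <- jm$jsw_max
        jsv <- jm$jsv
      }
    }
    data.frame(side = side_name, alpha = cv$alpha, beta = cv$beta,
               gamma = cv$gamma, chi_mm = chi, m_mm2_mm = m,
               jsw_um = jsw, jsw_min_um = jsw_min, jsw_max_um = jsw_max,
               jsv_mm3 = jsv, stringsAsFactors = FALSE)
  }
  rbind(one("medial"), one("lateral"))
}
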