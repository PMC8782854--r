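#' Principal axes of a point cloud
#'
#' Eigen-decomposition of the (optionally weighted) covariance of the
#' mean-centred points, ordered by descending explained variance. Used on
#' the vertices of the truncated SPHARM reconstruction (with `sin(theta)`
#' weights undoing polar oversampling of the sampling grid).
#'
#' @param points n x 3 matrix.
#' @param weights optional non-negative per-point weights.
#' @return class `principal_axes`: `axes` (3x3, columns = axes, descending
#'   variance, right-handed), `variances` (um^2), and `conditioning`
#'   (`(lambda2 - lambda3) / lambda1`, the alignment's well-posedness
#'   measure).
#' @export
principal_axes <- function(points, weights = NULL) {
  if (nrow(points) < 4) stop("need at least 4 points")
  if (is.null(weights)) weights <- rep(1, nrow(points))
  w <- weights / sum(weights)
  mu <- colSums(points * w)
  x <- sweep(points, 2, mu)
  cv <- crossprod(x * sqrt(w))
  eg <- eigen(cv, symmetric = TRUE)
  ax <- eg$vectors
  if (det(ax) < 0) ax[, 3] <- -ax[, 3]
  lam <- eg$values
  if (lam[3] < -1e-8 * lam[1] || lam[2] < 1e-12 * lam[1])
    stop("degenerate point cloud (collinear/coplanar)")
  structure(list(axes = ax, variances = lam, center = mu,
                 conditioning = (lam[2] - lam[3]) / lam[1]),
            class = "principal_axes")
}

#' @export
print.principal_axes <- function(x, ...) {
  cat(sprintf("<principal_axes> variances %s um^2, conditioning %.3f\n",
              paste(signif(x$variances, 4), collapse = ", "), x$conditioning))
  invisible(x)
}

#' Rotation aligning principal axes with the common orientation
#'
#' Builds the rotation taking the smallest principal component to the
#' vertical z axis and the second-smallest to the medial-lateral x axis.
#' Eigenvector signs are fixed by an orientation policy based on third
#' moments of the solid bone along the candidate axes: +z is chosen so the
#' bone's long tail (the shaft, below the plateau) points down, i.e. the
#' skewness of the vertical coordinate of the solid is negative; +x is
#' chosen so the wider (medial) half lies on -x, i.e. the skewness of the
#' medial-lateral coordinate of the solid is negative, flipped for right
#' limbs. Extreme-slice area comparisons are not used because the
#' intercondylar tubercles sit above the plateau rim and dominate the top
#' slices.
#'
#' @param axes a [principal_axes].
#' @param points the points the axes were computed from.
#' @param weights optional weights matching `points`.
#' @param solid_points optional n x 3 sample of the solid bone (e.g. voxel
#'   centres); the sign policy uses these, falling back to `points`.
#' @param limb_side `"left"` or `"right"`.
#' @param min_conditioning abort threshold on `(lambda2-lambda3)/lambda1`.
#' @return a [rigid_transform] with zero translation.
#' @export
alignment_rotation <- function(axes, points, weights = NULL,
                               solid_points = NULL,
                               limb_side = c("left", "right"),
                               min_conditioning = 0.02) {
  limb_side <- match.arg(limb_side)
  if (axes$conditioning < min_conditioning)
    stop(sprintf("ill-conditioned principal axes (conditioning %.4f < %.2f): orientation ambiguous",
                 axes$conditioning, min_conditioning))
  if (is.null(solid_points)) solid_points <- points
  a2 <- axes$axes[, 2]; a3 <- axes$axes[, 3]
  skew_along <- function(a) {
    s <- as.vector(solid_points %*% a)
    s <- s - mean(s)
    mean(s^3) / (sqrt(mean(s^2)))^3
  }
  if (skew_along(a3) > 0) a3 <- -a3      # shaft tail points down
  if (skew_along(a2) > 0) a2 <- -a2      # wider (medial) half on -x
  if (limb_side == "right") a2 <- -a2
  zrow <- a3; xrow <- a2
  yrow <- c(zrow[2] * xrow[3] - zrow[3] * xrow[2],
            zrow[3] * xrow[1] - zrow[1] * xrow[3],
            zrow[1] * xrow[2] - zrow[2] * xrow[1])
  rigid_transform(rbind(xrow, yrow, zrow, deparse.level = 0))
}

#' Align a joint to the common orientation
#'
#' The whole-joint alignment stage: the tibia's surface is extracted,
#' spherically parameterized, described by spherical harmonics to degree
#' `L_fit`, truncated to `L_trunc` (its basic form), and the principal axes
#' of that form define one rigid transform (long axis to z, medial-lateral
#' axis to x, tibia centre of mass to the world origin) that is applied
#' identically to every component of the joint, preserving their relative
#' pose.
#'
#' @param joint a [joint_image_set] containing at least the tibia.
#' @param L_trunc truncation degree used for pose estimation (degree 5
#'   retains the basic form the alignment relies on).
#' @param L_fit fitting degree.
#' @param method spherical parameterization method, see
#'   [spherical_parameterize()].
#' @param grid `(theta, phi)` sampling of the truncated reconstruction.
#' @param interpolation passed to [resample_rigid()].
#' @param limb_side `"left"` or `"right"` (sign policy, see
#'   [alignment_rotation()]).
#' @param apply if `FALSE`, compute the transform and diagnostics without
#'   resampling the masks (pose estimation only).
#' @param margin_vox margin around the union bounding box of the transformed
#'   components.
#' @param use_spharm if `FALSE`, run PCA on the full-resolution surface
#'   vertices instead of the truncated SPHARM form (the full-image baseline
#'   the SPHARM route is compared against).
#' @return class `jqma_alignment`: list with `joint` (aligned
#'   [joint_image_set], or `NULL` when `apply = FALSE`), `transform`
#'   ([rigid_transform]), and `diagnostics` (axis residual in degrees, PCA
#'   conditioning, SPHARM condition number and residual RMS).
#' @export
align_joint <- function(joint, L_trunc = 5, L_fit = 10,
                        method = c("radial", "area"), grid = c(64, 128),
                        interpolation = "bspline3",
                        limb_side = c("left", "right"),
                        apply = TRUE, margin_vox = 5, use_spharm = TRUE) {
  method <- match.arg(method)
  limb_side <- match.arg(limb_side)
  if (is.null(joint$tibia)) stop("joint has no tibia mask")
  surf <- extract_surface(joint$tibia)
  solid <- voxel_centres(joint$tibia)
  if (nrow(solid) > 50000)
    solid <- solid[seq(1, nrow(solid), length.out = 50000), ]
  diag_list <- list()
  if (use_spharm) {
    pm <- spherical_parameterize(surf, method = method)
    fit <- fit_spharm(pm, L = L_fit, max_vertices = 20000)
    recon <- reconstruct_surface(fit, L_trunc = L_trunc, grid = grid)
    pts <- recon$vertices
    wts <- attr(recon, "weights")
    diag_list$spharm_condition <- fit$condition
    diag_list$spharm_resid_rms <- fit$resid_rms
    diag_list$distortion_cv <- attr(pm, "distortion")$cv
  } else {
    pts <- surf$vertices
    wts <- NULL
  }
  pa <- principal_axes(pts, wts)
  rot <- alignment_rotation(pa, pts, wts, solid_points = solid,
                            limb_side = limb_side)
  com <- center_of_mass(joint$tibia)
  transform <- rigid_transform(rot$R, -as.vector(rot$R %*% com))
  # residual re-measurement on the transformed form
  rpts <- rt_apply(transform, pts)
  pa2 <- principal_axes(rpts, wts)
  ax3 <- pa2$axes[, 3]
  resid <- acos(pmin(1, abs(ax3[3]))) * 180 / pi
  diag_list$axis_residual_deg <- resid
  diag_list$pca_conditioning <- pa$conditioning
  diag_list$L_trunc <- if (use_spharm) L_trunc else NA_integer_
  out_joint <- NULL
  if (apply) {
    comps <- joint_components(joint)
    s <- joint$spacing
    bbs <- lapply(comps, transformed_bbox, transform = transform)
    lo <- Reduce(pmin, lapply(bbs, `[[`, "min")) - margin_vox * s
    hi <- Reduce(pmax, lapply(bbs, `[[`, "max")) + margin_vox * s
    odim <- as.integer(ceiling((hi - lo) / s - 1e-9))
    og <- list(origin = lo, dim = odim)
    rs <- lapply(comps, resample_rigid, transform = transform,
                 interpolation = interpolation, out_grid = og)
    out_joint <- joint_image_set(tibia = rs$tibia, femur = rs$femur,
                                 tibial_cartilage = rs$tibial_cartilage,
                                 femoral_cartilage = rs$femoral_cartilage,
                                 provenance = joint$provenance)
  }
  structure(list(joint = out_joint, transform = transform,
                 diagnostics = diag_list),
            class = "jqma_alignment")
}

#' @export
print.jqma_alignment <- function(x, ...) {
  cat(sprintf("<jqma_alignment> axis residual %.3f deg, PCA conditioning %.3f%s\n",
              x$diagnostics$axis_residual_deg, x$diagnostics$pca_conditioning,
              if (is.null(x$joint)) " (transform only)" else ""))
  invisible(x)
}
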