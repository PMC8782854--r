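#' Rigid transforms
#'
#' A proper rigid motion `w -> R %*% w + t` acting on world coordinates
#' (micrometres). `R` must be orthonormal with `det(R) = +1`.
#'
#' @param R 3x3 rotation matrix.
#' @param t length-3 translation (micrometres).
#' @return class `rigid_transform`.
#' @export
rigid_transform <- function(R = diag(3), t = c(0, 0, 0)) {
  R <- as.matrix(R)
  if (!all(dim(R) == c(3, 3))) stop("R must be 3x3")
  if (max(abs(crossprod(R) - diag(3))) > 1e-8 || abs(det(R) - 1) > 1e-8)
    stop("non-rigid transform: R must satisfy t(R) %*% R = I, det(R) = +1")
  structure(list(R = R, t = as.numeric(t)), class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- acos(pmin(1, pmax(-1, (sum(diag(x$R)) - 1) / 2))) * 180 / pi
  cat(sprintf("<rigid_transform> rotation %.2f deg, translation (%.1f, %.1f, %.1f) um\n",
              ang, x$t[1], x$t[2], x$t[3]))
  invisible(x)
}

#' @rdname rigid_transform
#' @param a,b transforms to compose (`a` applied after `b`).
#' @export
rt_compose <- function(a, b)
  rigid_transform(a$R %*% b$R, as.vector(a$R %*% b$t) + a$t)

#' @rdname rigid_transform
#' @param x a `rigid_transform`.
#' @export
rt_invert <- function(x) rigid_transform(t(x$R), -as.vector(t(x$R) %*% x$t))

#' @rdname rigid_transform
#' @param points n x 3 matrix (or length-3 vector) of world coordinates.
#' @export
rt_apply <- function(x, points) {
  if (is.null(dim(points))) return(as.vector(x$R %*% points) + x$t)
  sweep(points %*% t(x$R), 2, x$t, "+")
}

#' Rotation from extrinsic XYZ Euler angles (degrees)
#'
#' `R = Rz(c) Ry(b) Rx(a)`: rotate about the world x axis first, z last.
#'
#' @param angles_deg length-3 numeric `(a, b, c)` in degrees.
#' @return 3x3 rotation matrix.
#' @export
euler_rotation <- function(angles_deg) {
  r <- angles_deg * pi / 180
  cx <- cos(r[1]); sx <- sin(r[1])
  cy <- cos(r[2]); sy <- sin(r[2])
  cz <- cos(r[3]); sz <- sin(r[3])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

#' Extrinsic XYZ Euler angles (degrees) of a rotation matrix
#'
#' Inverse of [euler_rotation()] on its principal branch.
#'
#' @param R 3x3 rotation matrix.
#' @return length-3 numeric, degrees.
#' @export
rotation_to_euler <- function(R) {
  sy <- -R[3, 1]
  b <- asin(pmin(1, pmax(-1, sy)))
  if (abs(cos(b)) > 1e-9) {
    a <- atan2(R[3, 2], R[3, 3])
    c <- atan2(R[2, 1], R[1, 1])
  } else { # gimbal lock
    a <- atan2(-R[2, 3], R[2, 2])
    c <- 0
  }
  c(a, b, c) * 180 / pi
}

#' Resample a mask under a rigid transform
#'
#' The mask is interpolated continuously (cubic B-spline by default, matching
#' the pipeline's joint alignment step), sampled on an output grid that
#' encloses the transformed bounding box, and re-binarised at 0.5.
#'
#' @param mask a [voxel_mask].
#' @param transform a [rigid_transform] acting on world coordinates.
#' @param interpolation `"bspline3"` (default), `"linear"` or `"nearest"`.
#' @param out_grid optional list with elements `origin` (length 3, um) and
#'   `dim` (length 3, voxels) fixing the output grid; used to put several
#'   components of one joint on a common frame.
#' @param margin extra voxels added around the transformed bounding box when
#'   `out_grid` is `NULL`.
#' @return a [voxel_mask] on the output grid.
#' @export
resample_rigid <- function(mask, transform,
                           interpolation = c("bspline3", "linear", "nearest"),
                           out_grid = NULL, margin = 2) {
  interpolation <- match.arg(interpolation)
  stopifnot(inherits(transform, "rigid_transform"))
  s <- mask$spacing
  d <- dim(mask$data)
  if (is.null(out_grid)) {
    bb <- transformed_bbox(mask, transform)
    org <- bb$min - margin * s
    odim <- as.integer(ceiling((bb$max + margin * s - org) / s - 1e-9))
  } else {
    org <- out_grid$origin
    odim <- as.integer(out_grid$dim)
  }
  Rt <- t(transform$R)
  M <- Rt
  o <- (as.vector(Rt %*% (org - transform$t)) - mask$origin) / s +
    as.vector(Rt %*% rep(0.5, 3)) - 0.5
  vol <- as.numeric(mask$data)
  method <- switch(interpolation, nearest = 0L, linear = 1L, bspline3 = 3L)
  if (method == 3L) vol <- cpp_bspline_prefilter(vol, d)
  out <- cpp_resample_affine(vol, d, odim, M, o, method)
  arr <- array(out > 0.5, odim)
  voxel_mask(arr, spacing = s, origin = org, label = mask$label,
             allow_empty = TRUE)
}

# world-frame bbox of the full input grid after transform
transformed_bbox <- function(mask, transform) {
  d <- dim(mask$data)
  ext <- d * mask$spacing
  corners <- as.matrix(expand.grid(c(0, ext[1]), c(0, ext[2]), c(0, ext[3])))
  corners <- sweep(corners, 2, mask$origin, "+")
  tc <- rt_apply(transform, corners)
  list(min = apply(tc, 2, min), max = apply(tc, 2, max))
}

#' Dice overlap of two masks defined on compatible world frames
#'
#' Masks are compared voxel-wise on the grid of `a`; `b` must share spacing.
#' @param a,b [voxel_mask] objects on identical grids.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice_overlap <- function(a, b) {
  # resample b's voxel set onto a's grid by integer shift of origins
  shift <- round((b$origin - a$origin) / a$spacing)
  da <- dim(a$data); db <- dim(b$data)
  inter <- 0
  lo_a <- pmax(1, 1 + shift); hi_a <- pmin(da, db + shift)
  if (all(hi_a >= lo_a)) {
    lo_b <- lo_a - shift; hi_b <- hi_a - shift
    inter <- sum(a$data[lo_a[1]:hi_a[1], lo_a[2]:hi_a[2], lo_a[3]:hi_a[3]] &
                   b$data[lo_b[1]:hi_b[1], lo_b[2]:hi_b[2], lo_b[3]:hi_b[3]])
  }
  2 * inter / (sum(a$data) + sum(b$data))
}
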