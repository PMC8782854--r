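#' Spherical-harmonic index
#'
#' Column index of degree/order pair `(l, m)` in a basis matrix:
#' `l^2 + l + m + 1` (1-based).
#' @param l degree(s), `l >= 0`.
#' @param m order(s), `-l <= m <= l`.
#' @export
sh_index <- function(l, m) {
  if (any(abs(m) > l)) stop("|m| > l requested")
  l^2 + l + m + 1L
}

#' Spherical-harmonic basis matrix
#'
#' Evaluates all spherical harmonics up to degree `L` at the given spherical
#' angles, normalised as
#' `sqrt((2l+1)/(4*pi) * (l-m)!/(l+m)!) * P_l^m(cos(theta)) * e(i*m*phi)`
#' (associated Legendre functions with the Condon-Shortley phase). The
#' `"real"` basis folds `+/-m` into cosine (`m > 0`) and sine (`m < 0`)
#' columns and is used throughout the fitting code; the `"complex"` basis is
#' provided for conformance checks of the conjugation symmetry
#' `Y_l^-m = (-1)^m * Conj(Y_l^m)`.
#'
#' @param L maximum degree, `L >= 0`.
#' @param theta polar angles in `[0, pi]`.
#' @param phi azimuthal angles in `[0, 2*pi)`.
#' @param type `"real"` (default) or `"complex"`.
#' @return `length(theta)` x `(L+1)^2` matrix; columns ordered by
#'   [sh_index()].
#' @export
spharm_basis <- function(L, theta, phi, type = c("real", "complex")) {
  type <- match.arg(type)
  if (L < 0) stop("L must be >= 0")
  n <- length(theta)
  if (length(phi) != n) stop("theta and phi must have the same length")
  ct <- cos(theta)
  Z <- matrix(if (type == "real") 0 else 0 + 0i, n, (L + 1)^2)
  for (l in 0:L) {
    P <- if (l == 0) matrix(1, 1, n) else pracma::legendre(l, ct)
    if (is.null(dim(P))) P <- matrix(P, ncol = 1)  # n == 1
    for (m in 0:l) {
      N <- sqrt((2 * l + 1) / (4 * pi) *
                  exp(lgamma(l - m + 1) - lgamma(l + m + 1)))
      base <- N * P[m + 1, ]
      if (type == "real") {
        if (m == 0) {
          Z[, sh_index(l, 0)] <- base
        } else {
          Z[, sh_index(l, m)] <- sqrt(2) * base * cos(m * phi)
          Z[, sh_index(l, -m)] <- sqrt(2) * base * sin(m * phi)
        }
      } else {
        Y <- base * exp(1i * m * phi)
        Z[, sh_index(l, m)] <- Y
        if (m > 0) Z[, sh_index(l, -m)] <- (-1)^m * Conj(Y)
      }
    }
  }
  Z
}

#' Quadrature weights for a uniform cell-centred polar grid
#'
#' Weights `w_j` for the midpoint grid `theta_j = (j - 1/2) * pi / n` such
#' that `sum(w_j * f(theta_j))` equals `integral_0^pi f(theta) sin(theta)
#' dtheta` exactly whenever `f(theta) * sin(theta)` is a trigonometric
#' polynomial of degree below `n` (Driscoll-Healy-type weights). Used for
#' exact Gram matrices of the spherical-harmonic basis on regular grids and
#' for area-unbiased vertex statistics; the leading behaviour is
#' `sin(theta) * pi / n`.
#'
#' @param n number of theta samples.
#' @return numeric vector of length `n` (sums to 2).
#' @export
theta_quadrature_weights <- function(n) {
  th <- (seq_len(n) - 0.5) * pi / n
  ks <- seq_len(n - 1)
  ck <- (1 - (-1)^ks) / ks
  # plain-dtheta Driscoll-Healy weights; sin(theta) is part of the measure
  w_dtheta <- as.vector((2 / n) * (sin(outer(th, ks)) %*% ck))
  w_dtheta * sin(th)
}

#' Spherical parameterization of a closed genus-0 surface
#'
#' Assigns spherical coordinates `(theta, phi)` to each vertex. Method
#' `"radial"` projects along rays from the volumetric centroid and is exact
#' for star-shaped surfaces (checked: the surface must present no
#' back-facing triangles to the centroid). Method `"area"` starts from the
#' radial map and iteratively relaxes vertex positions on the sphere to
#' reduce per-triangle area distortion (spherical triangle area vs surface
#' triangle area, both normalised); only distortion-reducing steps are
#' accepted.
#'
#' @param mesh a `surface_mesh` with Euler characteristic 2.
#' @param method `"radial"` or `"area"`.
#' @param max_iter,tol iteration cap and relative change tolerance of the
#'   distortion coefficient of variation for method `"area"`.
#' @return class `param_mesh`: list with `mesh`, `theta`, `phi`; attribute
#'   `distortion` holds the area-distortion diagnostics (`cv`, `max`,
#'   `iterations`, `method`).
#' @export
spherical_parameterize <- function(mesh, method = c("radial", "area"),
                                   max_iter = 200, tol = 1e-4) {
  method <- match.arg(method)
  chi <- attr(mesh, "euler") %||% mesh_euler(mesh)
  if (chi != 2)
    stop(sprintf("genus != 0 surface (Euler characteristic %d); spherical topology required", chi))
  ctr <- mesh_centroid(mesh)
  v <- sweep(mesh$vertices, 2, ctr)
  r <- sqrt(rowSums(v^2))
  if (any(r == 0)) stop("vertex coincides with the centroid")
  u <- v / r
  # star-shape check: all faces must face the centroid front-on
  f <- mesh$faces
  a <- mesh$vertices[f[, 2], ] - mesh$vertices[f[, 1], ]
  b <- mesh$vertices[f[, 3], ] - mesh$vertices[f[, 1], ]
  nrm <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
               a[, 3] * b[, 1] - a[, 1] * b[, 3],
               a[, 1] * b[, 2] - a[, 2] * b[, 1])
  fc <- (v[f[, 1], ] + v[f[, 2], ] + v[f[, 3], ]) / 3
  back <- rowSums(nrm * fc) <= 0
  if (mean(back) > 0.01)
    stop(sprintf("surface is not star-shaped from its centroid (%.2f%% back-facing triangles); radial parameterization invalid",
                 100 * mean(back)))
  it <- 0L
  if (method == "area") {
    # gradient descent on the squared relative area mismatch, chord-area
    # surrogate (asymptotically equal to spherical areas on fine meshes),
    # with exact triangle-area gradients and a backtracking line search:
    # only distortion-reducing steps are accepted
    surf_a <- triangle_areas(mesh$vertices, mesh$faces)
    sfrac <- surf_a / sum(surf_a)
    cr <- function(a, b) cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                               a[, 3] * b[, 1] - a[, 1] * b[, 3],
                               a[, 1] * b[, 2] - a[, 2] * b[, 1])
    energy <- function(p) {
      A <- triangle_areas(p, f)
      a <- A / sum(A)
      sum((a - sfrac)^2 / sfrac)
    }
    gradient <- function(p) {
      p1 <- p[f[, 1], ]; p2 <- p[f[, 2], ]; p3 <- p[f[, 3], ]
      n <- cr(p2 - p1, p3 - p1)
      nn <- sqrt(rowSums(n^2))
      nh <- n / nn
      A <- nn / 2
      S <- sum(A)
      coefs <- 2 * (A / S - sfrac) / sfrac / S
      dl <- list(0.5 * cr(nh, p3 - p2) * coefs,
                 0.5 * cr(nh, p1 - p3) * coefs,
                 0.5 * cr(nh, p2 - p1) * coefs)
      g <- matrix(0, nrow(p), 3)
      for (cc in 1:3) {
        for (ax in 1:3) {
          acc <- rowsum(dl[[cc]][, ax], f[, cc], reorder = FALSE)
          g[as.integer(rownames(acc)), ax] <-
            g[as.integer(rownames(acc)), ax] + acc
        }
      }
      g - p * rowSums(g * p)  # tangent to the sphere
    }
    E <- energy(u)
    lam <- 0.005
    while (it < max_iter) {
      it <- it + 1L
      g <- gradient(u)
      g <- g / sqrt(mean(rowSums(g^2)))
      accepted <- FALSE
      while (lam >= 1e-7) {
        cand <- u - lam * g
        cand <- cand / sqrt(rowSums(cand^2))
        Ec <- energy(cand)
        if (is.finite(Ec) && Ec < E) {
          rel <- (E - Ec) / E
          u <- cand; E <- Ec
          lam <- min(lam * 1.5, 0.1)
          accepted <- TRUE
          if (rel < tol) it <- max_iter
          break
        }
        lam <- lam / 2
      }
      if (!accepted) break
    }
  }
  theta <- acos(pmin(1, pmax(-1, u[, 3])))
  phi <- atan2(u[, 2], u[, 1]) %% (2 * pi)
  sa <- spherical_triangle_areas(u, f)
  surf_a <- triangle_areas(mesh$vertices, mesh$faces)
  ratio <- (sa / sum(sa)) / (surf_a / sum(surf_a))
  structure(list(mesh = mesh, theta = theta, phi = phi),
            class = "param_mesh",
            distortion = list(cv = stats::sd(ratio) / mean(ratio),
                              max = max(ratio), iterations = it,
                              method = method))
}

# spherical triangle areas (unit sphere) by l'Huilier's formula
spherical_triangle_areas <- function(u, f) {
  dotc <- function(a, b) pmin(1, pmax(-1, rowSums(a * b)))
  p1 <- u[f[, 1], ]; p2 <- u[f[, 2], ]; p3 <- u[f[, 3], ]
  a <- acos(dotc(p2, p3)); b <- acos(dotc(p1, p3)); cc <- acos(dotc(p1, p2))
  s <- (a + b + cc) / 2
  t <- tan(s / 2) * tan((s - a) / 2) * tan((s - b) / 2) * tan((s - cc) / 2)
  4 * atan(sqrt(pmax(t, 0)))
}

#' @export
print.param_mesh <- function(x, ...) {
  d <- attr(x, "distortion")
  cat(sprintf("<param_mesh> %d vertices, method '%s', area-distortion CV %.3f\n",
              length(x$theta), d$method, d$cv))
  invisible(x)
}

#' Fit spherical-harmonic coefficients to a parameterized surface
#'
#' Solves, per coordinate function, the least-squares system relating the
#' basis values at the vertex angles to the vertex positions, via a QR
#' decomposition (numerically equivalent to the normal-equation solution on
#' well-conditioned systems, and stable on ill-conditioned ones).
#'
#' @param pm a [param_mesh].
#' @param L maximum degree; requires `n_vert >= (L+1)^2`.
#' @param max_vertices cap on the number of vertices entering the
#'   least-squares system (a deterministic regular subsample is used above
#'   it; the fit is heavily overdetermined either way).
#' @return class `spharm_fit`: `L`, `coeffs` ((L+1)^2 x 3 matrix, real
#'   basis), `resid_rms` (micrometres), `condition` (condition number of the
#'   basis matrix), plus the vertex angles for residual computation.
#' @export
fit_spharm <- function(pm, L = 10, max_vertices = Inf) {
  if (is.finite(max_vertices) && length(pm$theta) > max_vertices) {
    keep <- unique(round(seq(1, length(pm$theta), length.out = max_vertices)))
    pm <- structure(list(mesh = list(vertices = pm$mesh$vertices[keep, , drop = FALSE]),
                         theta = pm$theta[keep], phi = pm$phi[keep]),
                    class = "param_mesh")
  }
  n <- length(pm$theta)
  nc <- (L + 1)^2
  if (n < nc)
    stop(sprintf("n_vert = %d < (L+1)^2 = %d: too few vertices for degree %d", n, nc, L))
  Z <- spharm_basis(L, pm$theta, pm$phi)
  qz <- qr(Z)
  if (qz$rank < nc)
    stop(sprintf("rank-deficient basis (rank %d < %d): degenerate parameterization; try a lower L", qz$rank, nc))
  cf <- qr.coef(qz, pm$mesh$vertices)
  fitted <- Z %*% cf
  res <- pm$mesh$vertices - fitted
  dg <- abs(diag(qr.R(qz)))
  structure(list(L = L, coeffs = cf,
                 resid_rms = sqrt(mean(rowSums(res^2))),
                 condition = max(dg) / min(dg),
                 theta = pm$theta, phi = pm$phi,
                 vertices = pm$mesh$vertices),
            class = "spharm_fit")
}

#' @export
print.spharm_fit <- function(x, ...) {
  cat(sprintf("<spharm_fit> degree %d (%d basis functions), residual RMS %.3g um, cond %.3g\n",
              x$L, (x$L + 1)^2, x$resid_rms, x$condition))
  invisible(x)
}

#' @export
coef.spharm_fit <- function(object, ...) {
  l <- rep(0:object$L, times = 2 * (0:object$L) + 1)
  m <- unlist(lapply(0:object$L, function(ll) -ll:ll))
  data.frame(l = l, m = m,
             cx = object$coeffs[, 1], cy = object$coeffs[, 2],
             cz = object$coeffs[, 3], row.names = NULL)
}

#' @export
predict.spharm_fit <- function(object, theta, phi, L_trunc = object$L, ...) {
  if (L_trunc > object$L) stop("L_trunc exceeds the fitted degree")
  nc <- (L_trunc + 1)^2
  spharm_basis(L_trunc, theta, phi) %*% object$coeffs[seq_len(nc), , drop = FALSE]
}

#' @export
residuals.spharm_fit <- function(object, ...) {
  object$vertices - predict(object, object$theta, object$phi)
}

#' Write SPHARM coefficients to a plain-text table
#' @param fit a [fit_spharm] result.
#' @param path output file (TSV with columns l, m, cx, cy, cz).
#' @export
write_spharm_table <- function(fit, path) {
  utils::write.table(coef(fit), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Reconstruct a surface from (possibly truncated) SPHARM coefficients
#'
#' Evaluates the expansion on a regular `(theta, phi)` grid (cell-centred in
#' theta so the poles are sampled separately) and triangulates it into a
#' closed mesh. Truncating to a low degree yields the object's basic form
#' used for pose estimation.
#'
#' @param fit a `spharm_fit`.
#' @param L_trunc truncation degree, `<= fit$L`.
#' @param grid `c(n_theta, n_phi)` sampling density.
#' @return a `surface_mesh`; attribute `weights` holds per-vertex
#'   `sin(theta)` quadrature weights (poles get 0) for area-unbiased
#'   statistics on the grid vertices, attribute `grid` the sampling used.
#' @export
reconstruct_surface <- function(fit, L_trunc = fit$L, grid = c(64, 128)) {
  if (L_trunc > fit$L) stop("L_trunc exceeds the fitted degree")
  nt <- grid[1]; np <- grid[2]
  th <- (seq_len(nt) - 0.5) * pi / nt
  ph <- (seq_len(np) - 1) * 2 * pi / np
  ang <- expand.grid(theta = th, phi = ph)
  verts <- predict(fit, ang$theta, ang$phi, L_trunc = L_trunc)
  w <- rep(theta_quadrature_weights(nt), times = np)
  # pole vertices
  poles <- predict(fit, c(0, pi), c(0, 0), L_trunc = L_trunc)
  verts <- rbind(verts, poles)
  w <- c(w, 0, 0)
  idx <- function(i, j) (j - 1L) * nt + i  # i: theta row, j: phi col
  jn <- c(2:np, 1L)
  faces <- NULL
  i <- rep(seq_len(nt - 1L), np)
  j <- rep(seq_len(np), each = nt - 1L)
  q11 <- idx(i, j); q21 <- idx(i + 1L, j)
  q12 <- idx(i, jn[j]); q22 <- idx(i + 1L, jn[j])
  faces <- rbind(cbind(q11, q21, q22), cbind(q11, q22, q12))
  npole <- nrow(verts) - 1L; spole <- nrow(verts)
  top <- cbind(npole, idx(1L, seq_len(np)), idx(1L, jn))
  bot <- cbind(spole, idx(nt, jn), idx(nt, seq_len(np)))
  faces <- rbind(faces, top, bot)
  mesh <- structure(list(vertices = verts, faces = faces),
                    class = "surface_mesh")
  if (mesh_volume(mesh) < 0) mesh$faces <- mesh$faces[, c(1, 3, 2)]
  attr(mesh, "euler") <- mesh_euler(mesh)
  attr(mesh, "genus") <- as.integer(round((2 - attr(mesh, "euler")) / 2))
  attr(mesh, "weights") <- w
  attr(mesh, "grid") <- grid
  mesh
}
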