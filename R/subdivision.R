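#' Topographic height map of an aligned tibia
#'
#' For each `(x, y)` column of the mask, the world z coordinate of the
#' highest foreground voxel centre; columns without foreground are `NA`.
#' Assumes the tibia is aligned (long axis on z, plateau facing +z).
#'
#' @param mask an aligned tibia [voxel_mask].
#' @return class `height_map`: numeric `nx x ny` matrix (micrometres) with
#'   attributes `x`, `y` (column-centre world coordinates) and `spacing`.
#' @export
height_map <- function(mask) {
  if (!any(mask$data)) stop("empty mask")
  d <- dim(mask$data)
  s <- mask$spacing
  zc <- mask$origin[3] + (seq_len(d[3]) - 0.5) * s
  hm <- matrix(-Inf, d[1], d[2])
  for (k in seq_len(d[3])) {
    sl <- mask$data[, , k]
    if (any(sl)) hm[sl] <- zc[k]  # slices visited bottom-up: overwrite keeps max
  }
  hm[!is.finite(hm)] <- NA_real_
  structure(hm,
            x = mask$origin[1] + (seq_len(d[1]) - 0.5) * s,
            y = mask$origin[2] + (seq_len(d[2]) - 0.5) * s,
            spacing = s, class = "height_map")
}

#' Coronal 1D projection of a height map
#'
#' Collapses the topographic map along y, giving the height profile of the
#' tibial plateau along the medial-lateral axis. The default aggregator
#' (`max`) preserves the intercondylar tubercle peaks.
#'
#' @param hm a [height_map].
#' @param aggregate `"max"` (default) or `"mean"` over y.
#' @return class `profile_1d`: list with `x` (micrometres, strictly
#'   increasing), `h` (micrometres), `crop_window` (`NULL` until cropped).
#' @export
coronal_profile <- function(hm, aggregate = c("max", "mean")) {
  aggregate <- match.arg(aggregate)
  fun <- if (aggregate == "max") function(v) if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)
         else function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  h <- apply(unclass(hm), 1, fun)
  x <- attr(hm, "x")
  keep <- !is.na(h)
  structure(list(x = x[keep], h = h[keep], crop_window = NULL,
                 spacing = attr(hm, "spacing")),
            class = "profile_1d")
}

#' @export
print.profile_1d <- function(x, ...) {
  cat(sprintf("<profile_1d> %d samples, x in [%.0f, %.0f] um%s\n",
              length(x$x), min(x$x), max(x$x),
              if (!is.null(x$crop_window))
                sprintf(", cropped to [%.0f, %.0f]", x$crop_window[1], x$crop_window[2])
              else ""))
  invisible(x)
}

#' QC plot of a coronal height profile
#'
#' Draws the height profile (and, when present, the crop window and a
#' dividing point) for visual checking of the subdivision stage.
#'
#' @param x a [profile_1d].
#' @param x_divide optional dividing x coordinate (um) to mark.
#' @param ... passed to [graphics::plot()].
#' @export
plot.profile_1d <- function(x, ..., x_divide = NULL) {
  graphics::plot(x$x / 1000, x$h, type = "l", col = "steelblue", lwd = 2,
                 xlab = "medial-lateral position (mm)",
                 ylab = if (is.null(x$crop_window)) "top-surface height (um)"
                        else "boosted height",
                 main = "coronal height profile", ...)
  if (!is.null(x$crop_window))
    graphics::abline(v = x$crop_window / 1000, lty = 3, col = "grey40")
  if (!is.null(x_divide))
    graphics::abline(v = x_divide / 1000, col = "firebrick", lwd = 2)
  invisible(x)
}

#' Crop a profile to the centre of the object and rescale
#'
#' Restricts the profile to the central `center_fraction` of its footprint
#' extent (about the footprint midpoint), excluding peripheral features such
#' as osteophytes from the dividing-point search, and affinely rescales the
#' heights to `[0, 1]` (the "boosted" profile). Persistence ranking is
#' invariant to the rescale; it only conditions the numbers.
#'
#' @param profile a [profile_1d].
#' @param center_fraction fraction of the footprint extent kept, in `(0, 1]`.
#' @return the cropped [profile_1d] with `crop_window` recorded.
#' @export
crop_profile <- function(profile, center_fraction = 0.5) {
  if (center_fraction <= 0 || center_fraction > 1)
    stop("center_fraction must be in (0, 1]")
  x <- profile$x; h <- profile$h
  mid <- (min(x) + max(x)) / 2
  half <- (max(x) - min(x)) * center_fraction / 2
  win <- c(mid - half, mid + half)
  keep <- x >= win[1] & x <= win[2]
  if (!any(keep)) stop("crop removes all samples")
  x <- x[keep]; h <- h[keep]
  rng <- range(h)
  if (diff(rng) == 0) {
    warning("constant profile: degenerate rescale, heights set to 0")
    h <- rep(0, length(h))
  } else {
    h <- (h - rng[1]) / diff(rng)
  }
  structure(list(x = x, h = h, crop_window = win, spacing = profile$spacing,
                 scale = rng), class = "profile_1d")
}

#' 1D persistence pairs of a signal
#'
#' Sublevel-set persistence of the piecewise-linear signal: components are
#' born at local minima (in increasing value order) and die where they merge
#' into an older component; the sample domain is treated as a closed path
#' (both endpoints adjacent to the background), so the surviving global
#' minimum pairs with the global maximum and persistences are shift
#' invariant. Equal values are ordered by leftmost index.
#'
#' @param h numeric vector (>= 3 samples) or a [profile_1d].
#' @return `data.frame(min_index, max_index, persistence)` sorted by
#'   descending persistence (1-based indices into `h`).
#' @export
persistence_pairs <- function(h) {
  if (inherits(h, "profile_1d")) h <- h$h
  n <- length(h)
  if (n < 3) stop("need at least 3 samples")
  if (any(!is.finite(h))) stop("non-finite samples")
  ord <- order(h, seq_len(n))
  parent <- integer(n)        # union-find, 0 = not yet added
  birth <- integer(n)         # root -> index of its minimum
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  mins <- integer(0); maxs <- integer(0); pers <- numeric(0)
  added <- logical(n)
  left <- function(i) if (i == 1L) n else i - 1L
  right <- function(i) if (i == n) 1L else i + 1L
  for (i in ord) {
    nb <- c(left(i), right(i))
    nb <- nb[added[nb]]
    added[i] <- TRUE
    if (length(nb) == 0L) {
      parent[i] <- i
      birth[i] <- i
    } else if (length(nb) == 1L) {
      parent[i] <- find(nb[1])
    } else {
      r1 <- find(nb[1]); r2 <- find(nb[2])
      if (r1 == r2) { parent[i] <- r1; next }
      b1 <- birth[r1]; b2 <- birth[r2]
      # older component: lower birth value, leftmost on ties
      older_is_1 <- (h[b1] < h[b2]) || (h[b1] == h[b2] && b1 < b2)
      older <- if (older_is_1) r1 else r2
      younger <- if (older_is_1) r2 else r1
      mins <- c(mins, birth[younger])
      maxs <- c(maxs, i)
      pers <- c(pers, h[i] - h[birth[younger]])
      parent[younger] <- older
      parent[i] <- older
    }
  }
  # surviving component: global minimum pairs with the global maximum
  gmin <- ord[1]
  gmax <- ord[n]
  mins <- c(mins, gmin)
  maxs <- c(maxs, gmax)
  pers <- c(pers, h[gmax] - h[gmin])
  o <- order(-pers, mins)
  data.frame(min_index = mins[o], max_index = maxs[o], persistence = pers[o])
}

#' Locate the intercondylar dividing point
#'
#' Runs 1D persistence on the cropped coronal profile and returns the x
#' coordinate of the minimum belonging to the second-most-persistent pair:
#' the valley between the intercondylar tubercles (the most persistent
#' interior extremum; the global pair always belongs to the background).
#'
#' The two most persistent pairs carry the two tubercle peaks as their
#' maxima; the dividing point is the minimum among those pairs that lies
#' *between* the two peaks. Generically that is the second pair's minimum
#' (the global pair's minimum sits at the object margin), but the rule also
#' stays anchored to the intercondylar valley when surface roughness pushes
#' the valley below the cropped margins and it becomes the global minimum.
#' Because heights are voxel-quantized, the valley bottom is typically a
#' run of exactly tied samples; the reported coordinate is the centre of
#' the contiguous tied run containing the selected minimum.
#'
#' @param profile a cropped [profile_1d] (see [crop_profile()]).
#' @return dividing x coordinate in micrometres; attributes `index` (sample
#'   index) and `pairs` (the persistence table).
#' @export
watershed_index <- function(profile) {
  pp <- persistence_pairs(profile$h)
  if (nrow(pp) < 2)
    stop("no eminence detected: profile has no interior persistence pair")
  peaks <- range(pp$max_index[1:2])
  between <- pp$min_index[1:2] > peaks[1] & pp$min_index[1:2] < peaks[2]
  idx <- if (between[2]) pp$min_index[2]
         else if (between[1]) pp$min_index[1]
         else stop("no eminence detected: no interior minimum between the peaks")
  h <- profile$h
  lo <- idx; while (lo > 1L && h[lo - 1L] == h[idx]) lo <- lo - 1L
  hi <- idx; while (hi < length(h) && h[hi + 1L] == h[idx]) hi <- hi + 1L
  structure(mean(profile$x[lo:hi]), index = idx, pairs = pp)
}

#' Split a joint into medial and lateral volumes of interest
#'
#' Partitions every mask of an aligned joint by the plane `x = x_divide`; a
#' voxel belongs to the side containing its centre. After [align_joint()]
#' the medial side is always on -x (the limb-side flag is resolved during
#' alignment), so voxels with centre `x < x_divide` are labelled medial by
#' default.
#'
#' @param joint an aligned [joint_image_set].
#' @param x_divide dividing x coordinate (micrometres, world frame); must
#'   lie inside the tibial footprint.
#' @param medial which half-space is the medial compartment,
#'   `"negative-x"` (default, the aligned convention) or `"positive-x"`.
#' @return list with elements `medial` and `lateral`, each a
#'   [joint_image_set] on the original grid with the other side zeroed.
#' @export
split_joint <- function(joint, x_divide, medial = c("negative-x", "positive-x")) {
  medial <- match.arg(medial)
  tib <- joint$tibia
  xc <- tib$origin[1] + (seq_len(dim(tib$data)[1]) - 0.5) * tib$spacing
  foot <- range(xc[apply(tib$data, 1, any)])
  if (x_divide < foot[1] || x_divide > foot[2])
    stop("x_divide lies outside the tibial footprint")
  take_side <- function(mask, lower) {
    xs <- mask$origin[1] + (seq_len(dim(mask$data)[1]) - 0.5) * mask$spacing
    keep <- if (lower) xs < x_divide else xs >= x_divide
    dat <- mask$data
    dat[!keep, , ] <- FALSE
    voxel_mask(dat, mask$spacing, mask$origin, mask$label, allow_empty = TRUE)
  }
  side_set <- function(lower) {
    comps <- lapply(joint_components(joint), take_side, lower = lower)
    joint_image_set(tibia = comps$tibia, femur = comps$femur,
                    tibial_cartilage = comps$tibial_cartilage,
                    femoral_cartilage = comps$femoral_cartilage,
                    provenance = joint$provenance)
  }
  lower_is_medial <- medial == "negative-x"
  list(medial = side_set(lower_is_medial),
       lateral = side_set(!lower_is_medial))
}
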