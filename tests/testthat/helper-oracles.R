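# Shared fixtures and independent oracles, all built in code at test time.

# O(n^2) brute-force sublevel-set filtration on the closed sample path:
# labels are propagated by full relabelling (no union-find structure).
brute_persistence <- function(h) {
  n <- length(h)
  ord <- order(h, seq_len(n))
  lab <- integer(n)
  birth <- list()
  nextl <- 0L
  mins <- integer(0); maxs <- integer(0); pers <- numeric(0)
  for (i in ord) {
    nb <- c(if (i == 1L) n else i - 1L, if (i == n) 1L else i + 1L)
    labs <- unique(lab[nb[lab[nb] != 0L]])
    if (length(labs) == 0L) {
      nextl <- nextl + 1L
      lab[i] <- nextl
      birth[[nextl]] <- i
    } else if (length(labs) == 1L) {
      lab[i] <- labs
    } else {
      b1 <- birth[[labs[1]]]; b2 <- birth[[labs[2]]]
      older_is_1 <- (h[b1] < h[b2]) || (h[b1] == h[b2] && b1 < b2)
      older <- if (older_is_1) labs[1] else labs[2]
      younger <- if (older_is_1) labs[2] else labs[1]
      mins <- c(mins, birth[[younger]])
      maxs <- c(maxs, i)
      pers <- c(pers, h[i] - h[birth[[younger]]])
      lab[lab == younger] <- older
      lab[i] <- older
    }
  }
  gmin <- ord[1]; gmax <- ord[n]
  mins <- c(mins, gmin); maxs <- c(maxs, gmax)
  pers <- c(pers, h[gmax] - h[gmin])
  o <- order(-pers, mins)
  data.frame(min_index = mins[o], max_index = maxs[o], persistence = pers[o])
}

# small digital torus (genus 1) mask
make_torus_mask <- function(R_vox = 9, r_vox = 3, spacing = 10) {
  n <- 2 * (R_vox + r_vox) + 7
  c0 <- (n - 1) / 2
  idx <- seq_len(n) - 1
  g <- expand.grid(x = idx, y = idx, z = idx)
  rad <- sqrt((g$x - c0)^2 + (g$y - c0)^2)
  inside <- (rad - R_vox)^2 + (g$z - c0)^2 <= r_vox^2
  voxel_mask(array(inside, c(n, n, n)), spacing, c(0, 0, 0), "tibia")
}

# bent tube (3/4 arc), genus 0 but clearly not star-shaped
make_bent_tube_mask <- function(R_vox = 10, r_vox = 3, spacing = 10) {
  n <- 2 * (R_vox + r_vox) + 7
  c0 <- (n - 1) / 2
  idx <- seq_len(n) - 1
  g <- expand.grid(x = idx, y = idx, z = idx)
  ang <- atan2(g$y - c0, g$x - c0)
  rad <- sqrt((g$x - c0)^2 + (g$y - c0)^2)
  inside <- (rad - R_vox)^2 + (g$z - c0)^2 <= r_vox^2 & ang > -3 * pi / 4
  voxel_mask(array(inside, c(n, n, n)), spacing, c(0, 0, 0), "tibia")
}

# angles (deg) of a rotation matrix product from the identity, per axis
axis_angles_deg <- function(R) abs(rotation_to_euler(R))

# aligned tibia-only phantom helper for the subdivision tests
tibia_phantom <- function(spacing = 80, noise_amplitude = 0, seed = 1,
                          osteophyte = NULL, ...) {
  sp <- phantom_spec("rat", spacing = spacing, osteophyte = osteophyte, ...)
  sp$noise$amplitude <- noise_amplitude
  sp$noise$seed <- seed
  make_phantom_joint(sp, tibia_only = TRUE)
}
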