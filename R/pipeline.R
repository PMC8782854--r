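#' Pipeline configuration
#'
#' Collects every tunable of the align - subdivide - measure - repro chain
#' with its default. Precedence when merging: defaults < `file` (YAML,
#' optional) < `...` overrides.
#'
#' @param file optional YAML file of overrides.
#' @param ... named overrides.
#' @return class `jqma_config` (a list): `spharm_L` (fit degree, 10),
#'   `spharm_truncation` (pose degree, 5), `spharm_method`
#'   (`"radial"`), `spharm_grid` (`c(64, 128)`), `center_fraction` (0.5),
#'   `limb_side` (`"left"`), `interpolation` (`"bspline3"`), `step_um`
#'   (`NULL` = 1 voxel), `max_shift_um` (`NULL` = half the stack),
#'   `profile_aggregate` (`"max"`), `jsw_trim` (0.001), `seed` (1).
#' @export
jqma_config <- function(file = NULL, ...) {
  cfg <- list(spharm_L = 10, spharm_truncation = 5, spharm_method = "radial",
              spharm_grid = c(64, 128), center_fraction = 0.5,
              limb_side = "left", interpolation = "bspline3",
              step_um = NULL, max_shift_um = NULL,
              profile_aggregate = "max", jsw_trim = 0.001, seed = 1)
  if (!is.null(file)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading a config file requires the 'yaml' package")
    ov <- yaml::read_yaml(file)
    for (nm in names(ov)) cfg[[nm]] <- ov[[nm]]
  }
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  structure(cfg, class = "jqma_config")
}

#' Process one joint through the full pipeline
#'
#' Align, locate the dividing point, split, and measure a single joint.
#'
#' @param joint a [joint_image_set].
#' @param config a [jqma_config].
#' @return list with `alignment` (transform + diagnostics), `x_divide`
#'   (um), `profile` (the cropped coronal profile), `sides` (medial/lateral
#'   sets), and `metrics` (two-row data frame from [measure_joint()]).
#' @export
process_joint <- function(joint, config = jqma_config()) {
  al <- align_joint(joint, L_trunc = config$spharm_truncation,
                    L_fit = config$spharm_L, method = config$spharm_method,
                    grid = config$spharm_grid,
                    interpolation = config$interpolation,
                    limb_side = config$limb_side, apply = TRUE)
  hm <- height_map(al$joint$tibia)
  prof <- coronal_profile(hm, aggregate = config$profile_aggregate)
  cropped <- crop_profile(prof, config$center_fraction)
  xd <- watershed_index(cropped)
  sides <- split_joint(al$joint, as.numeric(xd))
  met <- measure_joint(sides, al$joint, step = config$step_um,
                       max_shift = config$max_shift_um)
  list(alignment = al[c("transform", "diagnostics")], x_divide = as.numeric(xd),
       profile = cropped, sides = sides, metrics = met)
}

#' Run the pipeline over a manifest of scans
#'
#' The manifest lists one row per scan: columns `sample_id`, `repeat_id`,
#' `limb_side`, and the four mask paths (`tibia`, `femur`,
#' `tibial_cartilage`, `femoral_cartilage`; the cartilage columns may be
#' empty, in which case contact metrics are skipped for that scan).
#' Alternatively `joints` may carry in-memory [joint_image_set]s matching
#' the manifest rows. Failures are isolated per sample and collected.
#'
#' @param manifest data frame or CSV path.
#' @param config a [jqma_config].
#' @param out_dir optional directory for `results.csv`, `repro.csv` and
#'   per-sample JSON sidecars.
#' @param joints optional list of in-memory joints, parallel to the
#'   manifest rows.
#' @return class `jqma_run`: list with `results` (long data frame, one row
#'   per scan x side), `repro` (reproducibility report over repeats),
#'   `errors` (named list of failed rows), `config`.
#' @export
run_pipeline <- function(manifest, config = jqma_config(), out_dir = NULL,
                         joints = NULL) {
  if (is.character(manifest)) manifest <- utils::read.csv(manifest)
  need <- c("sample_id", "repeat_id")
  if (!all(need %in% names(manifest)))
    stop("manifest must have columns sample_id, repeat_id and mask paths")
  rows <- list()
  errors <- list()
  sidecars <- list()
  for (i in seq_len(nrow(manifest))) {
    id <- sprintf("%s/%s", manifest$sample_id[i], manifest$repeat_id[i])
    res <- tryCatch({
      jt <- if (!is.null(joints)) joints[[i]] else load_manifest_row(manifest[i, ])
      cfg <- config
      if ("limb_side" %in% names(manifest) && nzchar(manifest$limb_side[i] %||% ""))
        cfg$limb_side <- as.character(manifest$limb_side[i])
      pr <- process_joint(jt, cfg)
      met <- pr$metrics
      met <- cbind(data.frame(sample_id = manifest$sample_id[i],
                              repeat_id = manifest$repeat_id[i],
                              stringsAsFactors = FALSE), met)
      sidecars[[id]] <- list(
        x_divide_um = pr$x_divide,
        crop_window_um = pr$profile$crop_window,
        axis_residual_deg = pr$alignment$diagnostics$axis_residual_deg,
        pca_conditioning = pr$alignment$diagnostics$pca_conditioning,
        spharm_condition = pr$alignment$diagnostics$spharm_condition)
      met
    }, error = function(e) e)
    if (inherits(res, "error")) errors[[id]] <- conditionMessage(res)
    else rows[[id]] <- res
  }
  results <- if (length(rows)) do.call(rbind, c(rows, list(make.row.names = FALSE))) else NULL
  repro <- NULL
  if (!is.null(results)) {
    long <- reshape_side_metrics(results)
    metcols <- setdiff(names(long), c("sample_id", "repeat_id"))
    if (length(unique(long$repeat_id)) >= 2)
      repro <- repro_report(long, metcols)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(results))
      utils::write.csv(results, file.path(out_dir, "results.csv"),
                       row.names = FALSE)
    if (!is.null(repro))
      utils::write.csv(repro, file.path(out_dir, "repro.csv"),
                       row.names = FALSE)
    if (requireNamespace("jsonlite", quietly = TRUE) && length(sidecars)) {
      payload <- list(config = unclass(config), scans = sidecars)
      jsonlite::write_json(payload, file.path(out_dir, "diagnostics.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
  }
  structure(list(results = results, repro = repro, errors = errors,
                 config = config),
            class = "jqma_run")
}

#' @export
print.jqma_run <- function(x, ...) {
  cat(sprintf("<jqma_run> %d scans measured, %d failed\n",
              if (is.null(x$results)) 0 else nrow(x$results) / 2,
              length(x$errors)))
  if (!is.null(x$repro)) {
    cat("reproducibility report:\n")
    print(x$repro, digits = 3)
  }
  invisible(x)
}

load_manifest_row <- function(row) {
  rd <- function(col, label) {
    p <- row[[col]]
    if (is.null(p) || is.na(p) || !nzchar(p)) return(NULL)
    read_mask(p, label)
  }
  joint_image_set(tibia = rd("tibia", "tibia"), femur = rd("femur", "femur"),
                  tibial_cartilage = rd("tibial_cartilage", "tibial_cartilage"),
                  femoral_cartilage = rd("femoral_cartilage", "femoral_cartilage"),
                  provenance = as.character(row[["repeat_id"]] %||% ""))
}

# wide per-side metrics -> one row per scan with side-suffixed columns
reshape_side_metrics <- function(results) {
  med <- results[results$side == "medial", ]
  lat <- results[results$side == "lateral", ]
  key <- c("sample_id", "repeat_id")
  side_cols <- c("chi_mm", "m_mm2_mm", "jsw_um", "jsw_min_um", "jsw_max_um",
                 "jsv_mm3")
  out <- med[, c(key, "alpha", "beta", "gamma")]
  for (cc in side_cols) {
    out[[paste0(cc, "_medial")]] <- med[[cc]]
    out[[paste0(cc, "_lateral")]] <- lat[[cc]][match(
      interaction(med$sample_id, med$repeat_id),
      interaction(lat$sample_id, lat$repeat_id))]
  }
  out
}

#' Parametric sweep of the SPHARM truncation degree
#'
#' Re-runs pose estimation at each truncation degree over a set of repeat
#' scans and reports the ICC of the centre-of-mass vector angles per
#' degree -- the mechanism used to select the working degree (degree 5).
#'
#' @param joints list of [joint_image_set]s.
#' @param sample_ids,repeat_ids vectors parallel to `joints`.
#' @param degrees integer vector of truncation degrees.
#' @param config a [jqma_config].
#' @return data frame with columns `degree`, `icc_alpha`, `icc_beta`,
#'   `icc_gamma`.
#' @export
sweep_degree <- function(joints, sample_ids, repeat_ids, degrees = c(1, 5, 10),
                         config = jqma_config()) {
  if (length(unique(repeat_ids)) < 2)
    stop("degree sweep needs at least 2 repeats per sample")
  rows <- lapply(degrees, function(dg) {
    angs <- lapply(joints, function(jt) {
      al <- align_joint(jt, L_trunc = dg, L_fit = max(dg, config$spharm_L),
                        method = config$spharm_method,
                        grid = config$spharm_grid,
                        limb_side = config$limb_side, apply = FALSE)
      vf <- rt_apply(al$transform, center_of_mass(jt$femur))
      vt <- rt_apply(al$transform, center_of_mass(jt$tibia))
      v <- vf - vt
      acos(pmin(1, pmax(-1, v / sqrt(sum(v^2))))) * 180 / pi
    })
    am <- do.call(rbind, angs)
    icc_of <- function(col) {
      tab <- tapply(am[, col], list(sample_ids, repeat_ids), mean)
      icc_consistency(tab[stats::complete.cases(tab), , drop = FALSE])$icc
    }
    data.frame(degree = dg, icc_alpha = icc_of(1), icc_beta = icc_of(2),
               icc_gamma = icc_of(3))
  })
  do.call(rbind, rows)
}

#' Write a 4x4 homogeneous transform matrix to a text file
#' @param transform a [rigid_transform].
#' @param path output file.
#' @export
write_transform <- function(transform, path) {
  m <- rbind(cbind(transform$R, transform$t), c(0, 0, 0, 1))
  utils::write.table(format(m, digits = 17), path, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}
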