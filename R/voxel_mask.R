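#' Binary voxel masks
#'
#' A `voxel_mask` is the unit of image data in the package: a binary 3D
#' array indexed `[x, y, z]` with isotropic voxel spacing in micrometres and
#' a world-frame origin. The world coordinate of the *centre* of the voxel
#' with 0-based index `(i, j, k)` is `origin + (c(i, j, k) + 0.5) * spacing`.
#'
#' @param data 3D array coercible to binary (values are thresholded at
#'   `0.5 * max` when not already in `{0, 1}`).
#' @param spacing isotropic voxel size in micrometres (single positive number).
#' @param origin world coordinate (micrometres) of the corner of voxel
#'   `(0, 0, 0)`; length-3 numeric.
#' @param label component name, one of `"femur"`, `"tibia"`,
#'   `"femoral_cartilage"`, `"tibial_cartilage"` (free labels are allowed but
#'   the pipeline expects these four).
#' @param allow_empty keep masks with no foreground (internal use: split
#'   compartments may legitimately be empty for one component).
#' @return An object of class `voxel_mask`: a list with elements `data`
#'   (logical 3D array), `spacing`, `origin`, `label`.
#' @examples
#' a <- array(0L, c(4, 4, 4)); a[2:3, 2:3, 2:3] <- 1L
#' m <- voxel_mask(a, spacing = 10)
#' center_of_mass(m)
#' @export
voxel_mask <- function(data, spacing, origin = c(0, 0, 0), label = "tibia",
                       allow_empty = FALSE) {
  if (length(dim(data)) != 3L) stop("`data` must be a 3D array")
  if (length(spacing) != 1L || !is.finite(spacing) || spacing <= 0)
    stop("`spacing` must be a single positive number (micrometres)")
  if (length(origin) != 3L) stop("`origin` must be length 3")
  if (!is.logical(data)) {
    u <- unique(as.vector(data))
    if (!all(u %in% c(0, 1))) {
      mx <- max(data)
      data <- data > 0.5 * mx
    } else {
      data <- data > 0.5
    }
    dim(data) <- dim(data) %||% NULL
  }
  if (!allow_empty && !any(data)) stop("empty foreground")
  structure(list(data = data, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), label = label),
            class = "voxel_mask")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.voxel_mask <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<voxel_mask '%s'> %d x %d x %d voxels @ %g um, %s foreground voxels\n",
              x$label, d[1], d[2], d[3], x$spacing,
              format(sum(x$data), big.mark = ",")))
  invisible(x)
}

#' @export
dim.voxel_mask <- function(x) dim(x$data)

#' Foreground voxel-centre world coordinates
#'
#' @param mask a [voxel_mask].
#' @return n x 3 matrix of world coordinates (micrometres) of foreground
#'   voxel centres.
#' @export
voxel_centres <- function(mask) {
  idx <- which(mask$data, arr.ind = TRUE)  # 1-based
  sweep((idx - 0.5) * mask$spacing, 2, mask$origin, "+")
}

#' Centre of mass of a binary mask
#'
#' Unweighted mean of the foreground voxel-centre world coordinates.
#'
#' @param mask a [voxel_mask].
#' @return length-3 numeric, micrometres, world frame.
#' @export
center_of_mass <- function(mask) {
  if (!any(mask$data)) stop("empty mask")
  unname(colMeans(voxel_centres(mask)))
}

#' A set of joint component masks on a common grid
#'
#' @param tibia,femur [voxel_mask] objects (required).
#' @param tibial_cartilage,femoral_cartilage optional [voxel_mask] objects;
#'   contact-area metrics are skipped when absent.
#' @param provenance free-text scan label (e.g. "PRE", "HEX2").
#' @return class `joint_image_set`: list of the masks plus `spacing` and
#'   `provenance`.
#' @export
joint_image_set <- function(tibia, femur, tibial_cartilage = NULL,
                            femoral_cartilage = NULL, provenance = "") {
  comps <- list(tibia = tibia, femur = femur,
                tibial_cartilage = tibial_cartilage,
                femoral_cartilage = femoral_cartilage)
  comps <- comps[!vapply(comps, is.null, logical(1))]
  sp <- vapply(comps, function(m) m$spacing, numeric(1))
  if (max(sp) - min(sp) > 1e-9 * max(sp))
    stop("all components of one joint must share the same voxel spacing")
  structure(c(comps, list(spacing = sp[[1]], provenance = provenance)),
            class = "joint_image_set")
}

#' @export
print.joint_image_set <- function(x, ...) {
  nm <- intersect(c("tibia", "femur", "tibial_cartilage", "femoral_cartilage"),
                  names(x))
  cat(sprintf("<joint_image_set> [%s] components: %s @ %g um\n",
              x$provenance, paste(nm, collapse = ", "), x$spacing))
  invisible(x)
}

joint_components <- function(joint) {
  nm <- intersect(c("tibia", "femur", "tibial_cartilage", "femoral_cartilage"),
                  names(joint))
  joint[nm]
}

# ---------------------------------------------------------------------------
# I/O: MetaImage (.mha/.mhd) and NIfTI (.nii/.nii.gz)

#' Read a segmented component mask
#'
#' Reads MetaImage (`.mha`, `.mhd` + `.raw`) or NIfTI-1 (`.nii`, `.nii.gz`)
#' volumes and binarises them at half the maximum value. Header spacing is
#' interpreted in micrometres (NIfTI headers declaring `mm` pixel units are
#' converted).
#'
#' @param path file path.
#' @param label component label stored on the mask.
#' @return a [voxel_mask].
#' @export
read_mask <- function(path, label = "tibia") {
  if (!file.exists(path)) stop("file not found: ", path)
  lower <- tolower(path)
  if (grepl("\\.mhd?a?$", lower)) {
    vol <- read_metaimage(path)
  } else if (grepl("\\.nii(\\.gz)?$", lower)) {
    img <- RNifti::readNifti(path)
    sp <- RNifti::pixdim(img)[1:3]
    un <- tryCatch(RNifti::pixunits(img)[1], error = function(e) "Unknown")
    if (identical(un, "mm")) sp <- sp * 1000
    orig <- attr(img, "origin") %||% c(0, 0, 0)
    vol <- list(data = array(as.numeric(img), dim(img)[1:3]),
                spacing = sp, origin = rep(0, 3))
  } else stop("unsupported mask format: ", path)
  sp <- vol$spacing
  if (max(sp) - min(sp) > 1e-6 * max(sp))
    stop("anisotropic spacing (", paste(signif(sp, 6), collapse = " x "),
         "): the pipeline requires isotropic voxels")
  voxel_mask(vol$data, spacing = sp[1], origin = vol$origin, label = label)
}

#' Write a mask to MetaImage or NIfTI
#'
#' @param mask a [voxel_mask].
#' @param path output path; format chosen from the extension (`.mha`
#'   uncompressed MetaImage with embedded data, or `.nii`/`.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  lower <- tolower(path)
  if (grepl("\\.mha$", lower)) {
    write_metaimage(mask, path)
  } else if (grepl("\\.nii(\\.gz)?$", lower)) {
    img <- array(as.integer(mask$data), dim(mask$data))
    nim <- RNifti::asNifti(img)
    RNifti::pixdim(nim) <- rep(mask$spacing, 3)
    RNifti::writeNifti(nim, path)
  } else stop("unsupported mask format: ", path)
  invisible(path)
}

read_metaimage <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  datafile <- NULL
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0) stop("truncated MetaImage header")
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    key <- trimws(kv[1]); val <- trimws(paste(kv[-1], collapse = "="))
    hdr[[key]] <- val
    if (key == "ElementDataFile") { datafile <- val; break }
  }
  dm <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1]])
  sp <- as.numeric(strsplit(hdr$ElementSpacing %||% "1 1 1", "\\s+")[[1]])
  off <- as.numeric(strsplit(hdr$Offset %||% "0 0 0", "\\s+")[[1]])
  type <- hdr$ElementType %||% "MET_UCHAR"
  if (!is.null(hdr$CompressedData) && toupper(hdr$CompressedData) == "TRUE")
    stop("compressed MetaImage not supported")
  n <- prod(dm)
  if (identical(datafile, "LOCAL")) {
    raw_con <- con
  } else {
    close(con); on.exit()
    raw_con <- file(file.path(dirname(path), datafile), "rb")
    on.exit(close(raw_con))
  }
  vals <- switch(type,
    MET_UCHAR = as.numeric(readBin(raw_con, "integer", n, size = 1, signed = FALSE)),
    MET_CHAR = as.numeric(readBin(raw_con, "integer", n, size = 1, signed = TRUE)),
    MET_SHORT = as.numeric(readBin(raw_con, "integer", n, size = 2, signed = TRUE)),
    MET_USHORT = as.numeric(readBin(raw_con, "integer", n, size = 2, signed = FALSE)),
    MET_FLOAT = as.numeric(readBin(raw_con, "numeric", n, size = 4)),
    MET_DOUBLE = readBin(raw_con, "numeric", n, size = 8),
    stop("unsupported MetaImage ElementType: ", type))
  if (length(vals) < n) stop("truncated MetaImage data")
  list(data = array(vals, dm), spacing = sp, origin = off)
}

write_metaimage <- function(mask, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  d <- dim(mask$data)
  hdr <- c("ObjectType = Image",
           "NDims = 3",
           "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           "CompressedData = False",
           "TransformMatrix = 1 0 0 0 1 0 0 0 1",
           paste("Offset =", paste(format(mask$origin, scientific = FALSE), collapse = " ")),
           paste("ElementSpacing =", paste(rep(format(mask$spacing, scientific = FALSE), 3), collapse = " ")),
           paste("DimSize =", paste(d, collapse = " ")),
           "ElementType = MET_UCHAR",
           "ElementDataFile = LOCAL")
  writeChar(paste0(paste(hdr, collapse = "\n"), "\n"), con, eos = NULL)
  writeBin(as.integer(mask$data), con, size = 1)
  invisible(path)
}
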