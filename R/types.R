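#' Construct a 3D ultrasound stack
#'
#' An `us_stack` holds a tracker-aligned stack of 2D B-mode frames as a
#' 3D array (rows = axial depth, columns = lateral, third dimension = sweep
#' frames) together with its voxel spacing in millimetres and scan identity.
#' Intensities are stored on the 8-bit export scale, 0--255.
#'
#' @param voxels numeric 3D array (H x W x Z) with values in [0, 255].
#' @param spacing numeric length-3 voxel spacing (dx, dy, dz) in mm, all
#'   strictly positive.
#' @param patient_id character scalar.
#' @param side `"left"` or `"right"`.
#' @param scan_index integer 1, 2 or 3; each kidney is swept three times.
#' @return An object of class `us_stack`.
#' @export
us_stack <- function(voxels, spacing, patient_id = "unknown",
                     side = c("left", "right"), scan_index = 1L) {
  side <- match.arg(side)
  if (length(dim(voxels)) != 3L) stopf("voxels must be a 3D array")
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stopf("spacing must be three strictly positive values (mm)")
  if (!scan_index %in% 1:3) stopf("scan_index must be 1, 2 or 3")
  structure(list(voxels = voxels, spacing = as.numeric(spacing),
                 patient_id = as.character(patient_id), side = side,
                 scan_index = as.integer(scan_index)),
            class = "us_stack")
}

#' Construct a binary segmentation mask
#'
#' A `seg_mask` is a voxel-for-voxel binary companion to an [us_stack()];
#' foreground (1) marks kidney.
#'
#' @param voxels integer/numeric 3D array containing only 0 and 1.
#' @param spacing voxel spacing (dx, dy, dz) in mm.
#' @return An object of class `seg_mask`.
#' @export
seg_mask <- function(voxels, spacing) {
  if (length(dim(voxels)) != 3L) stopf("voxels must be a 3D array")
  assert_binary(voxels)
  if (length(spacing) != 3L || any(spacing <= 0))
    stopf("spacing must be three strictly positive values (mm)")
  storage.mode(voxels) <- "integer"
  structure(list(voxels = voxels, spacing = as.numeric(spacing)),
            class = "seg_mask")
}

#' @export
print.us_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("us_stack %s/%s scan %d: %d x %d x %d, spacing %.2f x %.2f x %.2f mm\n",
              x$patient_id, x$side, x$scan_index, d[1], d[2], d[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' @export
print.seg_mask <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("seg_mask: %d x %d x %d, %d foreground voxels\n",
              d[1], d[2], d[3], sum(x$voxels)))
  invisible(x)
}

check_aligned <- function(a, b) {
  if (!identical(dim(a$voxels), dim(b$voxels)))
    stopf("volumes are not aligned: dims %s vs %s",
          paste(dim(a$voxels), collapse = "x"),
          paste(dim(b$voxels), collapse = "x"))
  invisible(TRUE)
}

#' Write a stack or mask to NIfTI
#'
#' Voxel spacing is carried in the NIfTI header; image and mask written from
#' the same geometry share identical affines.
#'
#' @param x an [us_stack()] or [seg_mask()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_nifti_volume <- function(x, path) {
  img <- RNifti::asNifti(x$voxels)
  RNifti::pixdim(img) <- x$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume as a stack or mask
#'
#' @param path NIfTI file.
#' @param as `"stack"` or `"mask"`.
#' @param ... passed to the corresponding constructor (scan identity fields).
#' @return An [us_stack()] or [seg_mask()].
#' @export
read_nifti_volume <- function(path, as = c("stack", "mask"), ...) {
  as <- match.arg(as)
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1:3]
  vox <- array(as.numeric(img), dim = dim(img)[1:3])
  if (as == "stack") us_stack(vox, sp, ...)
  else seg_mask(round(vox), sp)
}
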