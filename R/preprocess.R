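#' Preprocessing configuration
#'
#' Controls the standardization geometry, the blank-frame filter and the
#' slab construction used to feed the segmentation network.  Full-scale
#' clinical defaults standardize frames to 320 x 320 and feed the model
#' 256 x 256 slabs; desk-scale experiments shrink both.
#'
#' @param target_inplane analysis frame size in px after zero-padding or
#'   center-cropping (default 320).
#' @param slab_size model input size in px reached by bilinear resampling
#'   from `target_inplane` (default 256).
#' @param nonzero_frame_threshold minimum fraction of non-zero pixels for a
#'   frame to be kept; inclusive at the threshold (default 0.20).
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(target_inplane = 320L, slab_size = 256L,
                              nonzero_frame_threshold = 0.20) {
  if (nonzero_frame_threshold < 0 || nonzero_frame_threshold > 1)
    stopf("nonzero_frame_threshold must lie in [0, 1]")
  if (slab_size > target_inplane)
    stopf("slab_size must not exceed target_inplane")
  structure(list(target_inplane = as.integer(target_inplane),
                 slab_size = as.integer(slab_size),
                 nonzero_frame_threshold = nonzero_frame_threshold,
                 slab_channels = 3L),
            class = "preprocess_config")
}

pad_crop_plane <- function(vox, target) {
  d <- dim(vox)
  H <- d[1]; W <- d[2]
  out <- array(0, c(target, target, d[3]))
  # rows
  if (H <= target) {
    r_src <- seq_len(H); r_dst <- floor((target - H) / 2) + seq_len(H)
  } else {
    r_src <- floor((H - target) / 2) + seq_len(target); r_dst <- seq_len(target)
  }
  if (W <= target) {
    c_src <- seq_len(W); c_dst <- floor((target - W) / 2) + seq_len(W)
  } else {
    c_src <- floor((W - target) / 2) + seq_len(target); c_dst <- seq_len(target)
  }
  out[r_dst, c_dst, ] <- vox[r_src, c_src, ]
  list(out = out, r_src = r_src, c_src = c_src)
}

#' Standardize a stack to the analysis geometry
#'
#' Frames smaller than `target_inplane` are centred inside a zero border;
#' larger frames are centre-cropped.  The sweep (Z) dimension is untouched.
#' A paired mask is transformed identically; if the centre crop would remove
#' any foreground voxel of the mask the call is rejected, because the whole
#' kidney must remain inside the standardized frame.
#'
#' @param stack an [us_stack()].
#' @param cfg a [preprocess_config()].
#' @param mask optional paired [seg_mask()].
#' @return list with `stack` and (if given) `mask`, both standardized.
#' @export
standardize_stack <- function(stack, cfg = preprocess_config(), mask = NULL) {
  d <- dim(stack$voxels)
  if (d[1] < 1 || d[2] < 1) stopf("stack has empty in-plane dimensions")
  t <- cfg$target_inplane
  if (!is.null(mask)) {
    check_aligned(stack, mask)
    if (d[1] > t || d[2] > t) {
      pc <- pad_crop_plane(mask$voxels, t)
      if (sum(pc$out) != sum(mask$voxels))
        stopf(paste("center crop to %d px would remove foreground voxels;",
                    "the kidney must be fully included"), t)
    }
  }
  ps <- pad_crop_plane(stack$voxels, t)
  out_stack <- us_stack(ps$out, stack$spacing, stack$patient_id, stack$side,
                        stack$scan_index)
  out_mask <- if (!is.null(mask))
    seg_mask(pad_crop_plane(mask$voxels, t)$out, mask$spacing) else NULL
  list(stack = out_stack, mask = out_mask)
}

#' Indices of informative (non-blank) frames
#'
#' A frame is kept when its fraction of non-zero pixels is at least
#' `nonzero_frame_threshold` (inclusive); sweeps begin and end with blank
#' frames that would otherwise dominate training with empty targets.
#'
#' @param stack a standardized [us_stack()].
#' @param cfg a [preprocess_config()].
#' @return integer vector of kept frame indices, in order.
#' @export
filter_blank_frames <- function(stack, cfg = preprocess_config()) {
  d <- dim(stack$voxels)
  if (any(d == 0)) stopf("cannot filter an empty stack")
  npix <- d[1] * d[2]
  frac <- vapply(seq_len(d[3]),
                 function(k) sum(stack$voxels[, , k] != 0) / npix,
                 numeric(1))
  which(frac >= cfg$nonzero_frame_threshold)
}

#' Build the 3-channel slab for one frame
#'
#' The model consumes a 2.5D slab: channels are the frames (z-1, z, z+1),
#' clamped at the ends of the sweep, each bilinearly resampled from the
#' analysis geometry to `slab_size`.  A paired mask slice is resampled
#' nearest-neighbour.  The `from`/`to` sizes needed to invert the resampling
#' for volumetry are returned alongside.
#'
#' @param stack a standardized [us_stack()].
#' @param z frame index (1-based).
#' @param cfg a [preprocess_config()].
#' @param mask optional paired [seg_mask()]; only the central slice is used.
#' @return list with `image` (slab_size x slab_size x 3, original intensity
#'   scale), optional `mask` (slab_size x slab_size binary matrix), and
#'   `resample` (list `from`, `to`).
#' @export
make_slab <- function(stack, z, cfg = preprocess_config(), mask = NULL) {
  d <- dim(stack$voxels)
  if (z < 1 || z > d[3]) stopf("frame index %d outside the stack (Z = %d)",
                               z, d[3])
  s <- cfg$slab_size
  zz <- pmin(pmax(c(z - 1, z, z + 1), 1), d[3])
  img <- array(0, c(s, s, 3))
  for (i in 1:3)
    img[, , i] <- cpp_resize_bilinear(stack$voxels[, , zz[i]], s, s)
  out <- list(image = img,
              resample = list(from = d[1:2], to = c(s, s)))
  if (!is.null(mask)) {
    check_aligned(stack, mask)
    out$mask <- cpp_resize_nearest(mask$voxels[, , z] + 0, s, s)
  }
  out
}

# Map a slab_size probability map back to the analysis geometry.
unresample_prob <- function(prob, from) {
  cpp_resize_bilinear(prob, from[1], from[2])
}
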