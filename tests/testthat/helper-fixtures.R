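# Shared fixtures: tiny deterministic volumes and random mask generators.

make_stack <- function(vox, spacing = c(1, 1, 1), ...) {
  sonotkv::us_stack(vox, spacing, ...)
}

make_mask <- function(vox, spacing = c(1, 1, 1)) {
  sonotkv::seg_mask(vox, spacing)
}

# Random binary 3D mask with roughly `p` foreground.
random_mask_array <- function(dims, p = 0.3) {
  array(stats::rbinom(prod(dims), 1, p), dims)
}

# A small blob mask: ball of radius r centred at ctr inside dims.
ball_mask <- function(dims, ctr, r) {
  idx <- expand.grid(i = seq_len(dims[1]), j = seq_len(dims[2]),
                     k = seq_len(dims[3]))
  inside <- (idx$i - ctr[1])^2 + (idx$j - ctr[2])^2 + (idx$k - ctr[3])^2 <= r^2
  array(as.integer(inside), dims)
}

# Cached tiny phantom render shared by several test files.
tiny_phantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- sonotkv::sample_spec(3, "centered", in_plane_size = 64L,
                                   n_frames = 24L,
                                   spacing_mm = c(3, 3, 4))
      cache <<- sonotkv::render_phantom(spec)
    }
    cache
  }
})
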