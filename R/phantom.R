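#' Phantom specification for a synthetic 3D-ultrasound kidney sweep
#'
#' A `phantom_spec` fully determines one synthetic tracker-aligned sweep of a
#' cystic kidney: an ellipsoidal kidney (semi-axes `axes_mm`) carrying
#' internal spherical cysts, imaged through a curved-array sector field of
#' view with depth attenuation, per-exam gain and multiplicative speckle.
#' Rendering a spec is fully deterministic given its `seed`.
#'
#' Geometry conventions: rows of a frame run along the axial (depth)
#' direction away from the probe face, columns are lateral, and the third
#' array dimension is the sweep (Z).  `center_mm` places the kidney centre as
#' (depth from the probe face, lateral offset from mid-frame, sweep offset
#' from mid-stack).  Cyst centres are expressed in the kidney's local frame
#' so they rotate with the organ.
#'
#' @param axes_mm kidney semi-axes (a, b, c) in mm, strictly positive.
#' @param center_mm kidney centre (depth, lateral, sweep) in mm.
#' @param orientation_deg Euler angles (x, y, z) in degrees.
#' @param cysts list of `list(center = c(x, y, z) mm in kidney frame,
#'   radius = mm)`.
#' @param sector_fov list with `apex_mm` (apex depth; negative = above the
#'   probe face), `width_deg` (angular aperture) and `depth_mm` (radial
#'   imaging depth from the apex).
#' @param gain fraction in [0, 1]; clinically exported gains range 0.54-0.68.
#' @param speckle_scale speckle contrast in [0, 1]; 0 disables speckle.
#' @param attenuation_coeff per-mm intensity decay with radial depth.
#' @param in_plane_size frame size in pixels; one of 64, 128, 256, 512.
#' @param n_frames number of sweep frames (>= 3).
#' @param n_blank_edge blank lead-in/lead-out frames at each end of the
#'   sweep, emulating probe contact before and after the organ.
#' @param spacing_mm voxel spacing (dx, dy, dz) in mm.
#' @param seed integer RNG seed for texture and speckle.
#' @return An object of class `phantom_spec`.
#' @seealso [sample_spec()], [render_phantom()], [render_scan_triple()]
#' @export
phantom_spec <- function(axes_mm = c(38, 28, 25),
                         center_mm = c(85, 0, 0),
                         orientation_deg = c(0, 0, 0),
                         cysts = list(),
                         sector_fov = list(apex_mm = -15, width_deg = 68,
                                           depth_mm = 175),
                         gain = 0.62,
                         speckle_scale = 0.5,
                         attenuation_coeff = 0.002,
                         in_plane_size = 128L,
                         n_frames = 48L,
                         n_blank_edge = 4L,
                         spacing_mm = c(1.5, 1.5, 2.0),
                         seed = 1L) {
  spec <- structure(list(axes_mm = as.numeric(axes_mm),
                         center_mm = as.numeric(center_mm),
                         orientation_deg = as.numeric(orientation_deg),
                         cysts = cysts, sector_fov = sector_fov,
                         gain = gain, speckle_scale = speckle_scale,
                         attenuation_coeff = attenuation_coeff,
                         in_plane_size = as.integer(in_plane_size),
                         n_frames = as.integer(n_frames),
                         n_blank_edge = as.integer(n_blank_edge),
                         spacing_mm = as.numeric(spacing_mm),
                         seed = as.integer(seed)),
                    class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  if (length(spec$axes_mm) != 3L || any(spec$axes_mm <= 0))
    stopf("kidney semi-axes must be three strictly positive lengths (mm)")
  for (cy in spec$cysts)
    if (is.null(cy$radius) || cy$radius <= 0)
      stopf("every cyst needs a strictly positive radius")
  if (spec$n_frames < 3L) stopf("n_frames must be at least 3")
  if (!spec$in_plane_size %in% c(64L, 128L, 256L, 512L))
    stopf("in_plane_size must be one of 64, 128, 256, 512")
  if (spec$gain < 0 || spec$gain > 1) stopf("gain must lie in [0, 1]")
  if (any(spec$spacing_mm <= 0)) stopf("spacing must be strictly positive")
  if (spec$sector_fov$depth_mm <= 0 || spec$sector_fov$width_deg <= 0)
    stopf("sector FOV depth and width must be positive")
  invisible(spec)
}

#' Draw a randomized phantom spec for a named acquisition challenge
#'
#' The four difficulty labels mirror the acquisition conditions commonly seen
#' in freehand renal sweeps: a well-centred kidney, a sector too small for
#' the organ, a low-gain speckle-heavy exam, and an enlarged kidney whose
#' long axis exceeds the sector depth so the ground-truth mask is clipped by
#' the field of view.  Sampled gains always stay inside the clinical export
#' range 0.54--0.68.
#'
#' @param seed non-negative integer; the draw is deterministic in
#'   (`seed`, `difficulty`).
#' @param difficulty one of `"centered"`, `"small_fov"`, `"low_contrast"`,
#'   `"oversized"`.
#' @param in_plane_size,n_frames,spacing_mm stack geometry overrides; the
#'   defaults are the desk-scale fleet geometry.
#' @return A [phantom_spec()].
#' @export
sample_spec <- function(seed,
                        difficulty = c("centered", "small_fov",
                                       "low_contrast", "oversized"),
                        in_plane_size = 128L, n_frames = 48L,
                        spacing_mm = c(1.5, 1.5, 2.0)) {
  if (length(difficulty) == 1L &&
      !difficulty %in% c("centered", "small_fov", "low_contrast", "oversized"))
    stopf("unknown difficulty label '%s'", difficulty)
  difficulty <- match.arg(difficulty)
  with_seed(child_seed(seed, difficulty), {
    axes <- c(runif(1, 32, 45), runif(1, 24, 32), runif(1, 20, 28))
    sector <- list(apex_mm = -15,
                   width_deg = runif(1, 62, 72),
                   depth_mm = runif(1, 165, 185))
    gain <- runif(1, 0.58, 0.66)
    speckle <- runif(1, 0.40, 0.55)
    # Sector apertures keep the in-frame occupancy well above the 20%
    # blank-frame threshold, as clinical sectors do; the difficulty labels
    # differ in how much of the kidney the sector can contain.
    if (difficulty == "small_fov") {
      sector$width_deg <- runif(1, 52, 60)
      sector$depth_mm <- runif(1, 145, 160)
      axes[1] <- runif(1, 42, 50)
    } else if (difficulty == "low_contrast") {
      gain <- runif(1, 0.54, 0.56)
      speckle <- runif(1, 0.65, 0.80)
    } else if (difficulty == "oversized") {
      axes <- c(runif(1, 68, 78), runif(1, 32, 38), runif(1, 22, 28))
      sector$width_deg <- runif(1, 66, 72)
      sector$depth_mm <- runif(1, 125, 135)
    }
    depth_extent <- in_plane_size * spacing_mm[1]
    center <- c(runif(1, 0.40, 0.50) * depth_extent,
                runif(1, -8, 8), runif(1, -4, 4))
    n_cysts <- sample(2:5, 1)
    cysts <- vector("list", n_cysts)
    for (i in seq_len(n_cysts)) {
      r <- runif(1, 4, 9)
      repeat {
        u <- runif(3, -1, 1)
        margin <- axes - r - 1
        if (all(margin > 0) && sum((u * axes / margin)^2) <= 1) break
      }
      cysts[[i]] <- list(center = u * axes, radius = r)
    }
    phantom_spec(axes_mm = axes, center_mm = center,
                 orientation_deg = c(runif(1, -8, 8), runif(1, -8, 8),
                                     runif(1, -25, 25)),
                 cysts = cysts, sector_fov = sector, gain = gain,
                 speckle_scale = speckle,
                 in_plane_size = in_plane_size, n_frames = n_frames,
                 spacing_mm = spacing_mm,
                 seed = child_seed(seed, difficulty, 17L))
  })
}

euler_matrix <- function(deg) {
  a <- deg * pi / 180
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

# Physical coordinates of voxel centres for a spec's grid.
phantom_grid <- function(spec) {
  H <- spec$in_plane_size; W <- spec$in_plane_size; Z <- spec$n_frames
  sp <- spec$spacing_mm
  list(r = (seq_len(H) - 1) * sp[1],
       c = (seq_len(W) - (W + 1) / 2) * sp[2],
       z = (seq_len(Z) - (Z + 1) / 2) * sp[3])
}

# Squared ellipsoid form q(p) over the full grid; q <= 1 is inside.
ellipsoid_form <- function(spec, grid) {
  Rm <- euler_matrix(spec$orientation_deg)
  Rt <- t(Rm)
  d1 <- grid$r - spec$center_mm[1]
  d2 <- grid$c - spec$center_mm[2]
  d3 <- grid$z - spec$center_mm[3]
  q <- 0
  for (i in 1:3) {
    u <- outer_sum3(Rt[i, 1] * d1, Rt[i, 2] * d2, Rt[i, 3] * d3)
    q <- q + (u / spec$axes_mm[i])^2
  }
  q
}

cyst_world_centers <- function(spec) {
  Rm <- euler_matrix(spec$orientation_deg)
  lapply(spec$cysts, function(cy)
    list(center = as.numeric(spec$center_mm + Rm %*% cy$center),
         radius = cy$radius))
}

# In-plane sector membership (H x W logical) and radial depth map (mm).
sector_geometry <- function(spec, grid) {
  dr <- grid$r - spec$sector_fov$apex_mm
  rho <- sqrt(outer(dr^2, grid$c^2, "+"))
  ang <- atan2(matrix(grid$c, nrow = length(grid$r), ncol = length(grid$c),
                      byrow = TRUE),
               matrix(dr, nrow = length(grid$r), ncol = length(grid$c)))
  inside <- rho <= spec$sector_fov$depth_mm &
    abs(ang) <= (spec$sector_fov$width_deg / 2) * pi / 180
  list(inside = inside, rho = rho)
}

# Frames actually recorded by the sweep (blank lead-in/out removed).
recorded_frames <- function(spec) {
  nb <- spec$n_blank_edge
  if (nb <= 0) return(seq_len(spec$n_frames))
  seq.int(nb + 1L, spec$n_frames - nb)
}

# Exact kidney volume before voxelization and before FOV clipping: ellipsoid
# volume plus any cyst material protruding beyond the capsule (fine fixed
# quadrature; cysts sampled by sample_spec() never protrude, in which case
# the value is closed-form).
analytic_kidney_volume_mL <- function(spec, quad_mm = 0.3) {
  v <- 4 / 3 * pi * prod(spec$axes_mm)
  Rt <- t(euler_matrix(spec$orientation_deg))
  for (cy in cyst_world_centers(spec)) {
    # conservative containment check in the kidney frame
    u <- Rt %*% (cy$center - spec$center_mm)
    if (sqrt(sum(((abs(u) + cy$radius) / spec$axes_mm)^2)) <= 1) next
    g <- lapply(1:3, function(i)
      seq(cy$center[i] - cy$radius, cy$center[i] + cy$radius, by = quad_mm))
    d1 <- g[[1]] - spec$center_mm[1]
    d2 <- g[[2]] - spec$center_mm[2]
    d3 <- g[[3]] - spec$center_mm[3]
    q <- 0
    for (i in 1:3) {
      uu <- outer_sum3(Rt[i, 1] * d1, Rt[i, 2] * d2, Rt[i, 3] * d3)
      q <- q + (uu / spec$axes_mm[i])^2
    }
    s <- outer_sum3((g[[1]] - cy$center[1])^2, (g[[2]] - cy$center[2])^2,
                    (g[[3]] - cy$center[3])^2)
    v <- v + sum(s <= cy$radius^2 & q > 1) * quad_mm^3
  }
  v / 1000
}

#' Render a phantom sweep with analytic ground truth
#'
#' Voxelizes the kidney (ellipsoid plus cysts) clipped by the sector field of
#' view, then synthesizes the B-mode image as a Gaussian-smoothed tissue
#' template (bright capsule rim, darker parenchyma, hypoechoic cysts)
#' multiplied by radial depth attenuation, exam gain and Rayleigh speckle,
#' quantized to 8 bits.  Cysts render hypoechoic but remain part of the
#' kidney mask.  Blank lead-in/out frames are zeroed in both image and mask.
#'
#' @param spec a valid [phantom_spec()].
#' @param patient_id,side,scan_index identity stamped on the outputs.
#' @return list with `stack` ([us_stack()]), `mask` ([seg_mask()]) and
#'   `analytic_volume_mL`, the exact (FOV-unclipped) kidney volume.
#' @export
render_phantom <- function(spec, patient_id = "phantom", side = "left",
                           scan_index = 1L) {
  validate_phantom_spec(spec)
  grid <- phantom_grid(spec)
  H <- spec$in_plane_size; W <- spec$in_plane_size; Z <- spec$n_frames
  q <- ellipsoid_form(spec, grid)
  kidney <- q <= 1
  cyst <- array(FALSE, dim(kidney))
  for (cy in cyst_world_centers(spec)) {
    s <- outer_sum3((grid$r - cy$center[1])^2, (grid$c - cy$center[2])^2,
                    (grid$z - cy$center[3])^2)
    cyst <- cyst | (s <= cy$radius^2)
  }
  sec <- sector_geometry(spec, grid)
  rec <- recorded_frames(spec)
  fov <- array(FALSE, c(H, W, Z))
  fov[, , rec] <- sec$inside
  mask <- (kidney | cyst) & fov

  # tissue template in [0, 1]
  tmpl <- array(0.60, c(H, W, Z))
  tmpl[kidney] <- 0.32
  rim <- q >= 0.82 & q <= 1.18
  tmpl[rim] <- 0.88
  tmpl[cyst] <- 0.07

  img <- with_seed(spec$seed, {
    # smooth low-frequency background variation, constant across the sweep
    bgv <- cpp_gauss_blur2d(matrix(runif(H * W, -1, 1), H, W), 12)
    bgv <- bgv / max(abs(bgv)) * 0.12
    atten <- exp(-spec$attenuation_coeff * sec$rho)
    gf <- spec$gain / 0.68
    s <- spec$speckle_scale
    out <- array(0, c(H, W, Z))
    for (k in seq_len(Z)) {
      if (!(k %in% rec)) next
      sl <- cpp_gauss_blur2d(tmpl[, , k] + bgv, 1.0)
      if (s > 0) {
        ray <- sqrt(-2 * log(runif(H * W))) / sqrt(pi / 2)
        sl <- sl * ((1 - s) + s * matrix(ray, H, W))
      }
      sl <- sl * atten * gf
      sl[!sec$inside] <- 0
      out[, , k] <- sl
    }
    out
  })
  img <- round(pmin(pmax(img, 0), 1) * 255)
  list(stack = us_stack(img, spec$spacing_mm, patient_id, side,
                        scan_index),
       mask = seg_mask(mask * 1L, spec$spacing_mm),
       analytic_volume_mL = analytic_kidney_volume_mL(spec))
}

#' Render the three repeated sweeps of one kidney
#'
#' Emulates the acquisition protocol in which every kidney is scanned three
#' times: orientation, gain, kidney placement and sector aperture are jittered
#' independently per sweep, so ground-truth masks differ only through
#' re-voxelization and FOV clipping.  With `jitter = 0` the three renders are
#' identical.
#'
#' @param spec base [phantom_spec()].
#' @param jitter_seed integer seed for the perturbation draws.
#' @param jitter non-negative multiplier on the perturbation amplitudes
#'   (1 = default protocol variability).
#' @param patient_id,side identity stamped on the outputs.
#' @return list of 3 elements, each `list(stack, mask, analytic_volume_mL,
#'   spec)`.
#' @export
render_scan_triple <- function(spec, jitter_seed, jitter = 1,
                               patient_id = "phantom", side = "left") {
  validate_phantom_spec(spec)
  if (jitter < 0) stopf("jitter must be non-negative")
  perturbed <- with_seed(jitter_seed, {
    lapply(1:3, function(s) {
      p <- spec
      p$orientation_deg <- p$orientation_deg + jitter * runif(3, -6, 6)
      p$gain <- min(max(p$gain + jitter * runif(1, -0.02, 0.02), 0.54), 0.68)
      p$center_mm <- p$center_mm + jitter * c(runif(1, -2, 2),
                                              runif(1, -3, 3),
                                              runif(1, -2, 2))
      p$sector_fov$width_deg <- p$sector_fov$width_deg +
        jitter * runif(1, -2, 2)
      p$seed <- if (jitter > 0) child_seed(spec$seed, jitter_seed, s)
                else spec$seed
      p
    })
  })
  lapply(1:3, function(s) {
    r <- render_phantom(perturbed[[s]], patient_id = patient_id, side = side,
                        scan_index = s)
    r$spec <- perturbed[[s]]
    r
  })
}
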