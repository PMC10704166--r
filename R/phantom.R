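#' Specify a head phantom
#'
#' Builds the parameter set for one voxelized head phantom: concentric
#' (optionally ellipsoidal) tissue shells emulating skin, skull, CSF and
#' brain, with a parameterized degree of brain atrophy. Atrophy shrinks the
#' brain (gray + white matter) outer surface while skull and scalp stay
#' fixed, so cerebrospinal fluid fills the widening gap — the same geometry
#' change that drives dose loss in atrophied heads.
#'
#' @param grid_shape Integer vector of 3 voxel counts per axis.
#' @param voxel_size_mm Isotropic voxel edge length in mm.
#' @param shell_radii_mm Named numeric vector with outer radii (mm) for
#'   `scalp`, `skull`, `csf` (inner skull) and `brain`; must be strictly
#'   decreasing.
#' @param atrophy_scale Fraction in (0, 1] multiplying the brain outer
#'   radius; 1 means no atrophy.
#' @param gm_thickness_mm Gray-matter shell thickness in mm.
#' @param ventricle_radius_mm Radius (mm) of an interior CSF sphere standing
#'   in for the lateral ventricles; scaled by `1/atrophy_scale` so atrophied
#'   brains get larger ventricles. 0 disables it.
#' @param axis_scales Per-axis ellipsoid stretch factors (x right, y
#'   anterior, z superior).
#' @param seed RNG seed recorded with the spec (used by cohort jitter).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(96L, 96L, 96L),
                         voxel_size_mm = 2,
                         shell_radii_mm = c(scalp = 77, skull = 70,
                                            csf = 64, brain = 58),
                         atrophy_scale = 1,
                         gm_thickness_mm = 4,
                         ventricle_radius_mm = 12,
                         axis_scales = c(1, 1, 1),
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3 || any(grid_shape < 8)) {
    stop_validation("grid_shape must be 3 dimensions of at least 8 voxels")
  }
  if (!is.numeric(voxel_size_mm) || voxel_size_mm <= 0) {
    stop_validation("voxel_size_mm must be > 0")
  }
  need <- c("scalp", "skull", "csf", "brain")
  if (!all(need %in% names(shell_radii_mm))) {
    stop_validation("shell_radii_mm needs named entries scalp, skull, csf, brain")
  }
  r <- shell_radii_mm[need]
  if (any(diff(r) >= 0)) {
    stop_validation("shell radii must be strictly decreasing scalp > skull > csf > brain")
  }
  if (atrophy_scale <= 0 || atrophy_scale > 1) {
    stop_validation("atrophy_scale must be in (0, 1]")
  }
  if (gm_thickness_mm <= 0 || gm_thickness_mm >= r["brain"]) {
    stop_validation("gm_thickness_mm must be in (0, brain radius)")
  }
  if (length(axis_scales) != 3 || any(axis_scales <= 0)) {
    stop_validation("axis_scales must be 3 positive factors")
  }
  structure(
    list(
      grid_shape = grid_shape, voxel_size_mm = voxel_size_mm,
      shell_radii_mm = r, atrophy_scale = atrophy_scale,
      gm_thickness_mm = gm_thickness_mm,
      ventricle_radius_mm = ventricle_radius_mm,
      axis_scales = as.numeric(axis_scales), seed = as.integer(seed)
    ),
    class = "phantom_spec"
  )
}

#' Construct a labeled head volume
#'
#' Low-level container for a 3D integer tissue-label grid. Most users get
#' one from [generate_phantom()] or [read_labeled_volume()].
#'
#' @param labels 3D integer array of tissue codes (see [tissue_labels()]).
#' @param voxel_size_mm Isotropic voxel spacing in mm.
#' @param origin World coordinate (mm) of the center of voxel (1,1,1).
#' @return An object of class `head_volume`.
#' @export
head_volume <- function(labels, voxel_size_mm, origin = NULL) {
  if (length(dim(labels)) != 3) stop_validation("labels must be a 3D array")
  if (!is.integer(labels)) {
    if (any(labels != round(labels))) {
      stop_validation("labels must be integer-valued")
    }
    storage.mode(labels) <- "integer"
  }
  if (is.null(origin)) origin <- -(dim(labels) - 1) / 2 * voxel_size_mm
  structure(
    list(labels = labels, voxel_size_mm = voxel_size_mm,
         origin = as.numeric(origin)),
    class = "head_volume"
  )
}

#' @export
print.head_volume <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<head_volume> %d x %d x %d voxels @ %g mm\n",
              d[1], d[2], d[3], x$voxel_size_mm))
  tab <- table(factor(x$labels, levels = LABELS,
                      labels = names(LABELS)))
  print(tab)
  invisible(x)
}

# Normalized ellipsoidal radius (mm) of every voxel center relative to the
# grid center, after removing the per-axis stretch.
.phantom_radius_grid <- function(spec) {
  d <- spec$grid_shape
  origin <- -(d - 1) / 2 * spec$voxel_size_mm
  cx <- axis_coords(d[1], spec$voxel_size_mm, origin[1]) / spec$axis_scales[1]
  cy <- axis_coords(d[2], spec$voxel_size_mm, origin[2]) / spec$axis_scales[2]
  cz <- axis_coords(d[3], spec$voxel_size_mm, origin[3]) / spec$axis_scales[3]
  r2 <- outer(outer(cx^2, cy^2, `+`), cz^2, `+`)
  sqrt(r2)
}

#' Generate a voxelized head phantom
#'
#' Rasterizes the concentric shells of a [phantom_spec()] center-out: white
#' matter core, gray matter shell, CSF, bone, skin. A voxel belongs to the
#' innermost shell containing its center. The optional ventricle is carved
#' as CSF out of the white-matter core.
#'
#' @param spec A [phantom_spec()].
#' @return A [head_volume()] with labels in 0..5 (no electrodes yet).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  half_extent <- (spec$grid_shape - 1) / 2 * spec$voxel_size_mm
  if (any(spec$shell_radii_mm["scalp"] * spec$axis_scales > half_extent)) {
    stop_geometry("scalp shell exceeds the grid; enlarge grid_shape or shrink radii")
  }
  r <- .phantom_radius_grid(spec)
  rad <- spec$shell_radii_mm
  brain_r <- rad[["brain"]] * spec$atrophy_scale
  wm_r <- brain_r - spec$gm_thickness_mm
  lab <- array(LABELS[["background"]], dim = spec$grid_shape)
  lab[r <= rad[["scalp"]]] <- LABELS[["skin"]]
  lab[r <= rad[["skull"]]] <- LABELS[["bone"]]
  lab[r <= rad[["csf"]]] <- LABELS[["csf"]]
  lab[r <= brain_r] <- LABELS[["gm"]]
  lab[r <= wm_r] <- LABELS[["wm"]]
  if (spec$ventricle_radius_mm > 0) {
    vent_r <- spec$ventricle_radius_mm / spec$atrophy_scale
    lab[r <= vent_r & lab == LABELS[["wm"]]] <- LABELS[["csf"]]
  }
  storage.mode(lab) <- "integer"
  head_volume(lab, spec$voxel_size_mm)
}

#' Generate a phantom cohort with graded atrophy
#'
#' Emulates a cohort of older-adult heads: atrophy scales are spread evenly
#' across `atrophy_range` with seeded jitter, and shell radii / axis scales
#' receive small per-subject perturbations so no two heads are identical.
#'
#' @param n Number of subjects (>= 2).
#' @param atrophy_range Interval of atrophy scales, within (0, 1].
#' @param jitter Non-negative multiplier on the built-in inter-individual
#'   variability (0 disables all jitter; 1 is the default calibration:
#'   atrophy SD 0.1 of the grid step between subjects, radii SD 1.5%, axis
#'   scale SD 2%).
#' @param seed Master seed for the cohort.
#' @param base_spec Template [phantom_spec()] supplying grid and nominal
#'   radii.
#' @return List with one element per subject, each a list of `spec`
#'   (the jittered [phantom_spec()]) and `volume` (the [head_volume()]).
#' @export
generate_cohort <- function(n, atrophy_range = c(0.86, 1.0), jitter = 1,
                            seed = 1L, base_spec = phantom_spec()) {
  if (n < 2) stop_validation("cohort needs n >= 2")
  if (length(atrophy_range) != 2 || diff(atrophy_range) <= 0 ||
      atrophy_range[1] <= 0 || atrophy_range[2] > 1) {
    stop_validation("atrophy_range must be a non-empty interval within (0, 1]")
  }
  if (jitter < 0) stop_validation("jitter must be >= 0")
  scales <- seq(atrophy_range[1], atrophy_range[2], length.out = n)
  step <- diff(atrophy_range) / max(n - 1, 1)
  with_seed(seed, {
    scales <- scales + stats::rnorm(n, 0, jitter * 0.1 * step)
    scales <- pmin(pmax(scales, atrophy_range[1]), atrophy_range[2])
    lapply(seq_len(n), function(i) {
      radii <- base_spec$shell_radii_mm *
        exp(stats::rnorm(1, 0, jitter * 0.015))
      axes <- base_spec$axis_scales * exp(stats::rnorm(3, 0, jitter * 0.02))
      sp <- phantom_spec(
        grid_shape = base_spec$grid_shape,
        voxel_size_mm = base_spec$voxel_size_mm,
        shell_radii_mm = radii,
        atrophy_scale = scales[i],
        gm_thickness_mm = base_spec$gm_thickness_mm,
        ventricle_radius_mm = base_spec$ventricle_radius_mm,
        axis_scales = axes,
        seed = as.integer(derive_seed(seed, i))
      )
      list(spec = sp, volume = generate_phantom(sp))
    })
  })
}

#' Brain volume ratio
#'
#' Ratio of brain tissue volume to intracranial volume, the study's proxy
#' for atrophy (lower ratio = more atrophy). For `numerator = "brain"` this
#' is (GM + WM) / (GM + WM + CSF); `"gm"` and `"wm"` restrict the numerator
#' to one tissue, with the same intracranial denominator.
#'
#' @param vol A [head_volume()].
#' @param numerator One of `"brain"`, `"gm"`, `"wm"`.
#' @return Ratio in (0, 1].
#' @export
compute_volume_ratio <- function(vol, numerator = c("brain", "gm", "wm")) {
  numerator <- match.arg(numerator)
  lab <- vol$labels
  n_gm <- sum(lab == LABELS[["gm"]])
  n_wm <- sum(lab == LABELS[["wm"]])
  n_csf <- sum(lab == LABELS[["csf"]])
  icv <- n_gm + n_wm + n_csf
  if (icv == 0) stop_validation("volume has no intracranial voxels")
  if (numerator != "wm" && n_gm == 0) {
    stop_validation("volume has no gray-matter voxels")
  }
  num <- switch(numerator, brain = n_gm + n_wm, gm = n_gm, wm = n_wm)
  num / icv
}

#' Default ROI sector bounds
#'
#' Angular windows (degrees) defining the ROI analogs on the brain
#' compartment: polar angle is measured from the superior axis, azimuth from
#' the anterior inter-electrode midline. The three frontal sectors stack
#' superior-to-inferior between the electrodes; the temporal sector sits
#' lateral and posterior-inferior to them.
#'
#' @return Named list of sector bounds, each
#'   `list(polar = c(lo, hi), azimuth = c(lo, hi))` with azimuth applied to
#'   `abs(azimuth)` (both hemispheres).
#' @export
roi_sector_defaults <- function() {
  list(
    sfg_analog = list(polar = c(0, 35), azimuth = c(0, 52)),
    mfg_analog = list(polar = c(35, 55), azimuth = c(0, 52)),
    ifg_analog = list(polar = c(55, 75), azimuth = c(0, 52)),
    temporal_analog = list(polar = c(60, 100), azimuth = c(80, 140))
  )
}

#' Define ROI analog masks on a phantom
#'
#' Splits the brain compartment into angular sectors relative to the
#' inter-electrode midline: analogs of the superior, middle and inferior
#' frontal gyri (stimulation targets of a frontal bilateral montage) and a
#' temporal-lobe analog as a non-target control region. Also returns the
#' standard tissue masks.
#'
#' @param vol A [head_volume()].
#' @param anode_anchor,cathode_anchor Unit direction vectors (head frame,
#'   from the head center) of the two electrode anchors.
#' @param sectors Sector bounds as from [roi_sector_defaults()].
#' @return Named list of logical 3D masks: the four ROI analogs plus
#'   `brain`, `gm`, `wm`, `whole_head`.
#' @export
define_roi_masks <- function(vol, anode_anchor, cathode_anchor,
                             sectors = roi_sector_defaults()) {
  u_a <- unit(anode_anchor)
  u_c <- unit(cathode_anchor)
  if (sum((u_a - u_c)^2) < 1e-12) {
    stop_validation("anode and cathode anchors coincide")
  }
  lab <- vol$labels
  d <- dim(lab)
  gm <- lab == LABELS[["gm"]]
  wm <- lab == LABELS[["wm"]]
  brain <- gm | wm
  if (!any(brain)) stop_validation("volume has no brain voxels")

  cx <- axis_coords(d[1], vol$voxel_size_mm, vol$origin[1])
  cy <- axis_coords(d[2], vol$voxel_size_mm, vol$origin[2])
  cz <- axis_coords(d[3], vol$voxel_size_mm, vol$origin[3])
  # Brain centroid as the angular origin.
  idx <- which(brain, arr.ind = TRUE)
  ctr <- c(mean(cx[idx[, 1]]), mean(cy[idx[, 2]]), mean(cz[idx[, 3]]))
  x <- cx[idx[, 1]] - ctr[1]
  y <- cy[idx[, 2]] - ctr[2]
  z <- cz[idx[, 3]] - ctr[3]
  r <- sqrt(x^2 + y^2 + z^2)
  r[r == 0] <- .Machine$double.eps
  polar <- acos(pmin(pmax(z / r, -1), 1)) * 180 / pi
  # Anterior reference: in-plane direction of the inter-electrode midline.
  mid <- u_a + u_c
  mid[3] <- 0
  if (sqrt(sum(mid^2)) < 1e-9) mid <- c(0, 1, 0) # degenerate: use +y
  mid <- unit(mid)
  az <- abs(atan2(x * mid[2] - y * mid[1], x * mid[1] + y * mid[2])) * 180 / pi

  lin <- which(brain)
  mask_of <- function(b) {
    keep <- polar >= b$polar[1] & polar < b$polar[2] &
      az >= b$azimuth[1] & az < b$azimuth[2]
    m <- array(FALSE, dim = d)
    m[lin[keep]] <- TRUE
    m
  }
  rois <- lapply(sectors, mask_of)
  c(rois, list(
    brain = brain, gm = gm, wm = wm,
    whole_head = lab != LABELS[["background"]]
  ))
}
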