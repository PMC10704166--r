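#' Default montage anchor directions
#'
#' Unit direction vectors (head frame: x right, y anterior, z superior) for
#' the planned frontal bilateral montage analog: anode over the right
#' frontal scalp, cathode mirrored on the left. The default polar/azimuth
#' angles place the pads so that, on the default spherical phantom, the
#' short-edge separation distance of idealized electrodes is close to the
#' 4.7 cm scale typical of a frontal bilateral pad montage.
#'
#' @param polar_deg Polar angle from the superior axis, degrees.
#' @param azimuth_deg Azimuth from the anterior midline, degrees (applied
#'   with opposite signs to the two electrodes).
#' @return List with unit vectors `anode` and `cathode`.
#' @export
montage_anchors <- function(polar_deg = 55, azimuth_deg = 52.8) {
  th <- polar_deg * pi / 180
  az <- azimuth_deg * pi / 180
  mk <- function(side) {
    unit(c(sin(th) * sin(az) * side, sin(th) * cos(az), cos(th)))
  }
  list(anode = mk(1), cathode = mk(-1))
}

#' Default perturbation model for as-placed electrodes
#'
#' Generative stand-in for the deviations observed between planned and
#' as-placed pads: a systematic tangential slip away from the partner
#' electrode (head-coil pressure and operator error push pads outward,
#' widening the montage), an isotropic tangential Gaussian jitter, a
#' rotation jitter about the pad normal, and a gel coverage-area multiplier
#' drawn uniformly (hair and coil contact make the paste footprint deviate
#' from the pad footprint in either direction).
#'
#' @param systematic_shift_mm Mean outward slip along the inter-electrode
#'   axis, mm.
#' @param tangential_shift_sd_mm SD of the random tangential shift, mm.
#' @param rotation_sd_deg SD of the rotation jitter about the pad normal,
#'   degrees.
#' @param coverage_fraction_range Uniform range of the gel footprint area
#'   multiplier.
#' @return Named list of perturbation parameters.
#' @export
perturbation_defaults <- function(systematic_shift_mm = 11,
                                  tangential_shift_sd_mm = 4,
                                  rotation_sd_deg = 10,
                                  coverage_fraction_range = c(0.85, 1.35)) {
  if (any(coverage_fraction_range <= 0)) {
    stop_validation("coverage_fraction_range must be positive")
  }
  list(systematic_shift_mm = systematic_shift_mm,
       tangential_shift_sd_mm = tangential_shift_sd_mm,
       rotation_sd_deg = rotation_sd_deg,
       coverage_fraction_range = coverage_fraction_range)
}

#' Specify one electrode
#'
#' @param role `"anode"` or `"cathode"`.
#' @param anchor Either a unit direction vector from the head center
#'   (curved-scalp placement) or a list `list(point=, normal=, long_axis=)`
#'   of world coordinates for planar placement on a test slab.
#' @param partner_anchor Anchor direction of the other electrode; orients
#'   the pad long axis along the inter-electrode direction.
#' @param pad_length_mm,pad_width_mm,pad_thickness_mm Pad dimensions, mm
#'   (defaults 70 x 50 x 3).
#' @param gel_max_thickness_mm Gel standoff, mm: the pad underside is held
#'   this far above the scalp's highest point under the footprint and the
#'   full gap down to the skin is filled with gel, so no gap remains between
#'   electrode assembly and scalp.
#' @param mode `"artificial"` (idealized placement) or `"real"`
#'   (perturbed as-placed placement).
#' @param perturbation Parameters from [perturbation_defaults()]; only used
#'   in real mode.
#' @param seed RNG seed for real-mode perturbations.
#' @return Object of class `electrode_spec`.
#' @export
electrode_spec <- function(role = c("anode", "cathode"), anchor,
                           partner_anchor = NULL,
                           pad_length_mm = 70, pad_width_mm = 50,
                           pad_thickness_mm = 3, gel_max_thickness_mm = 3,
                           mode = c("artificial", "real"),
                           perturbation = perturbation_defaults(),
                           seed = 1L) {
  role <- match.arg(role)
  mode <- match.arg(mode)
  if (pad_length_mm < pad_width_mm || pad_width_mm <= 0) {
    stop_validation("pad dimensions must satisfy length >= width > 0")
  }
  if (pad_thickness_mm <= 0 || gel_max_thickness_mm <= 0) {
    stop_validation("pad and gel thickness must be > 0")
  }
  structure(
    list(role = role, anchor = anchor, partner_anchor = partner_anchor,
         pad_length_mm = pad_length_mm, pad_width_mm = pad_width_mm,
         pad_thickness_mm = pad_thickness_mm,
         gel_max_thickness_mm = gel_max_thickness_mm,
         mode = mode, perturbation = perturbation, seed = as.integer(seed)),
    class = "electrode_spec"
  )
}

# Rotate vector v about unit axis k by angle (radians), Rodrigues formula.
rotate_about <- function(v, k, angle) {
  v * cos(angle) + pracma_cross(k, v) * sin(angle) +
    k * sum(k * v) * (1 - cos(angle))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Centroid (world mm) of all non-background voxels.
head_centroid <- function(vol) {
  idx <- which(vol$labels != LABELS[["background"]], arr.ind = TRUE)
  if (nrow(idx) == 0) stop_validation("volume is empty")
  d <- dim(vol$labels)
  c(mean(axis_coords(d[1], vol$voxel_size_mm, vol$origin[1])[idx[, 1]]),
    mean(axis_coords(d[2], vol$voxel_size_mm, vol$origin[2])[idx[, 2]]),
    mean(axis_coords(d[3], vol$voxel_size_mm, vol$origin[3])[idx[, 3]]))
}

# Outermost skin-surface radius along direction u from ctr, by ray
# sampling; NA if the ray misses the scalp.
surface_radius <- function(vol, ctr, u) {
  d <- dim(vol$labels)
  h <- vol$voxel_size_mm
  rmax <- sqrt(sum(((d - 1) * h / 2)^2)) + h
  ts <- seq(rmax, h / 4, by = -h / 4)
  for (t in ts) {
    p <- ctr + t * u
    v <- round((p - vol$origin) / h) + 1
    if (any(v < 1) || any(v > d)) next
    if (vol$labels[v[1], v[2], v[3]] == LABELS[["skin"]]) return(t)
  }
  NA_real_
}

#' Place an electrode pad and gel on a head volume
#'
#' Snaps an oriented rigid pad box tangent to the local scalp surface at the
#' anchor, held off by the gel standoff, and fills the full gap between pad
#' underside and skin with gel so that no gap remains. In `"real"` mode the
#' anchor is first slipped tangentially (systematic outward component plus
#' Gaussian jitter), the pad is rotated about its normal, and the gel
#' footprint is eroded or dilated to a sampled coverage fraction — all
#' seeded and reproducible.
#'
#' @param vol A [head_volume()].
#' @param spec An [electrode_spec()].
#' @return List with `volume` (labels updated with gel 6 and pad 7) and
#'   `geometry` (class `electrode_geometry`): voxel sets, frame vectors,
#'   short-edge midpoints and terminal voxels.
#' @export
place_electrode <- function(vol, spec) {
  stopifnot(inherits(spec, "electrode_spec"))
  h <- vol$voxel_size_mm
  d <- dim(vol$labels)
  planar <- is.list(spec$anchor)

  cover <- 1
  rot <- 0
  shift2 <- c(0, 0)
  if (spec$mode == "real") {
    pert <- spec$perturbation
    draws <- with_seed(spec$seed, list(
      shift = stats::rnorm(2, 0, pert$tangential_shift_sd_mm),
      rot = stats::rnorm(1, 0, pert$rotation_sd_deg) * pi / 180,
      cover = stats::runif(1, pert$coverage_fraction_range[1],
                           pert$coverage_fraction_range[2])
    ))
    shift2 <- draws$shift
    rot <- draws$rot
    cover <- draws$cover
  }

  if (planar) {
    p_surf <- spec$anchor$point
    n <- unit(spec$anchor$normal)
    l <- unit(spec$anchor$long_axis - sum(spec$anchor$long_axis * n) * n)
  } else {
    ctr <- head_centroid(vol)
    u <- unit(spec$anchor)
    t_long <- .tangent_toward(u, spec$partner_anchor)
    if (spec$mode == "real") {
      r0 <- surface_radius(vol, ctr, u)
      if (is.na(r0)) stop_validation("anchor does not resolve to a scalp voxel")
      t_perp <- unit(pracma_cross(u, t_long))
      shift_vec <- (-spec$perturbation$systematic_shift_mm + shift2[1]) * t_long +
        shift2[2] * t_perp
      u <- unit(ctr + r0 * u + shift_vec - ctr)
      t_long <- .tangent_toward(u, spec$partner_anchor)
    }
    r_surf <- surface_radius(vol, ctr, u)
    if (is.na(r_surf)) stop_validation("anchor does not resolve to a scalp voxel")
    p_surf <- ctr + r_surf * u
    n <- u
    l <- t_long
  }
  if (rot != 0) l <- unit(rotate_about(l, n, rot))
  w_axis <- unit(pracma_cross(n, l))

  L2 <- spec$pad_length_mm / 2
  W2 <- spec$pad_width_mm / 2
  gL2 <- L2 * sqrt(cover)
  gW2 <- W2 * sqrt(cover)
  rad <- sqrt(max(L2, gL2)^2 + max(W2, gW2)^2) +
    spec$pad_thickness_mm + spec$gel_max_thickness_mm + 6 * h

  # Candidate voxels in a bounding box around the anchor.
  ext <- ceiling(rad / h)
  vc <- round((p_surf - vol$origin) / h) + 1
  if (any(vc + ext < 1) || any(vc - ext > d)) {
    stop_validation("pad footprint does not overlap the scalp")
  }
  rng <- lapply(1:3, function(a) {
    max(1, vc[a] - ext):min(d[a], vc[a] + ext)
  })
  xs <- axis_coords(d[1], h, vol$origin[1])[rng[[1]]]
  ys <- axis_coords(d[2], h, vol$origin[2])[rng[[2]]]
  zs <- axis_coords(d[3], h, vol$origin[3])[rng[[3]]]
  nx <- length(xs); ny <- length(ys); nz <- length(zs)
  rel_x <- rep(xs - p_surf[1], times = ny * nz)
  rel_y <- rep(rep(ys - p_surf[2], each = nx), times = nz)
  rel_z <- rep(zs - p_surf[3], each = nx * ny)
  uu <- rel_x * l[1] + rel_y * l[2] + rel_z * l[3]
  vv <- rel_x * w_axis[1] + rel_y * w_axis[2] + rel_z * w_axis[3]
  ww <- rel_x * n[1] + rel_y * n[2] + rel_z * n[3]
  lin <- as.vector(outer(outer(rng[[1]], (rng[[2]] - 1) * d[1], `+`),
                         (rng[[3]] - 1) * d[1] * d[2], `+`))
  lab_here <- vol$labels[lin]

  # half-open footprint so centers exactly on an edge are not double-counted
  in_pad_fp <- uu > -L2 & uu <= L2 & vv > -W2 & vv <= W2
  in_gel_fp <- uu > -gL2 & uu <= gL2 & vv > -gW2 & vv <= gW2
  skin_fp <- lab_here == LABELS[["skin"]] & (in_pad_fp | in_gel_fp)
  if (!any(skin_fp)) stop_validation("pad footprint does not overlap the scalp")
  w0 <- max(ww[skin_fp])
  w_pad <- w0 + spec$gel_max_thickness_mm

  pad_rng <- in_pad_fp & ww > w_pad & ww <= w_pad + spec$pad_thickness_mm
  gel_rng <- in_gel_fp & ww <= w_pad &
    ww > w_pad - (spec$gel_max_thickness_mm + 25)
  if (any(lab_here[pad_rng | gel_rng] %in%
          c(LABELS[["gel"]], LABELS[["pad"]]))) {
    stop_geometry("electrode would overlap an existing electrode")
  }
  is_bg <- lab_here == LABELS[["background"]]
  pad_sel <- is_bg & pad_rng
  gel_sel <- is_bg & gel_rng
  pad_voxels <- lin[pad_sel]
  gel_voxels <- lin[gel_sel]
  if (length(pad_voxels) == 0) {
    stop_geometry("pad does not rasterize to any voxel; check grid margins")
  }

  labels <- vol$labels
  labels[gel_voxels] <- LABELS[["gel"]]
  labels[pad_voxels] <- LABELS[["pad"]]

  top <- max(ww[pad_sel])
  term_sel <- pad_sel & ww > top - h * 0.75
  terminal <- lin[term_sel]

  face_c <- p_surf + w_pad * n
  midpoints <- rbind(face_c + L2 * l, face_c - L2 * l)
  geometry <- structure(
    list(pad_voxels = pad_voxels, gel_voxels = gel_voxels,
         terminal_voxels = terminal,
         center = p_surf + (w_pad + spec$pad_thickness_mm / 2) * n,
         long_axis = l, normal = n,
         short_edge_midpoints = midpoints,
         role = spec$role, mode = spec$mode, coverage = cover),
    class = "electrode_geometry"
  )
  list(volume = head_volume(labels, h, vol$origin), geometry = geometry)
}

# Unit tangent at anchor direction u pointing toward the partner anchor;
# falls back to the anterior tangent when no partner is given.
.tangent_toward <- function(u, partner) {
  ref <- if (is.null(partner)) c(0, 1, 0) else unit(partner)
  t <- ref - sum(ref * u) * u
  if (sqrt(sum(t^2)) < 1e-9) {
    ref <- c(0, 0, 1)
    t <- ref - sum(ref * u) * u
  }
  unit(t)
}

#' Gel-scalp contact area
#'
#' Measures the gel-skin interface of one placed electrode from the
#' 6-connectivity adjacency faces between gel and skin voxels. Each face is
#' weighted by the cosine between its normal and the pad normal, which
#' projects the voxel staircase onto the pad plane: the raw staircase face
#' count overestimates a curved interface and does not converge under grid
#' refinement, while the projected count converges to the footprint of the
#' contact patch.
#'
#' @param vol A [head_volume()] containing the placed electrode.
#' @param geom The `electrode_geometry` from [place_electrode()].
#' @return Contact area in cm^2.
#' @export
compute_contact_area <- function(vol, geom) {
  gel <- geom$gel_voxels
  if (length(gel) == 0) stop_validation("electrode has no gel voxels")
  d <- dim(vol$labels)
  idx <- arrayInd(gel, d)
  area <- 0
  for (axis in 1:3) {
    w <- abs(geom$normal[axis])
    for (s in c(-1L, 1L)) {
      nb <- idx
      nb[, axis] <- nb[, axis] + s
      ok <- nb[, axis] >= 1 & nb[, axis] <= d[axis]
      nb_lin <- nb[ok, 1] + (nb[ok, 2] - 1) * d[1] +
        (nb[ok, 3] - 1) * d[1] * d[2]
      area <- area + w * sum(vol$labels[nb_lin] == LABELS[["skin"]])
    }
  }
  if (area == 0) {
    stop_geometry("gel has no contact with the scalp (zero-contact)")
  }
  area * vol$voxel_size_mm^2 / 100
}

#' Normalize contact areas against the idealized-model mean
#'
#' Every contact area (both electrode models) is divided by the mean contact
#' area of the idealized ("artificial") model, and each subject's value is
#' the mean of their normalized anode and cathode areas. By construction the
#' mean normalized artificial value is exactly 1.
#'
#' @param areas_artificial,areas_real n x 2 matrices (columns anode,
#'   cathode) of contact areas in cm^2.
#' @return List: `mean_artificial_cm2`, per-electrode normalized matrices
#'   `artificial` and `real`, and per-subject vectors `subject_artificial`,
#'   `subject_real`.
#' @export
normalize_contact_areas <- function(areas_artificial, areas_real) {
  aa <- as.matrix(areas_artificial)
  ar <- as.matrix(areas_real)
  if (length(aa) == 0) stop_validation("artificial area set is empty")
  if (any(aa <= 0) || any(ar <= 0)) {
    stop_validation("contact areas must be positive")
  }
  m <- mean(aa)
  na <- aa / m
  nr <- ar / m
  list(mean_artificial_cm2 = m,
       artificial = na, real = nr,
       subject_artificial = rowMeans(na),
       subject_real = rowMeans(nr))
}

#' Electrode separation distance
#'
#' For each electrode, the short-edge midpoint nearest the other electrode's
#' center is selected; the separation is the Euclidean distance between the
#' two selected midpoints, in cm. Ties are broken toward the more anterior
#' midpoint.
#'
#' @param geom_anode,geom_cathode `electrode_geometry` objects.
#' @return Separation distance in cm.
#' @export
compute_separation_distance <- function(geom_anode, geom_cathode) {
  pick <- function(geom, other_center) {
    mp <- geom$short_edge_midpoints
    dd <- sqrt(rowSums(sweep(mp, 2, other_center)^2))
    if (abs(dd[1] - dd[2]) < 1e-9) {
      mp[which.max(mp[, 2]), ] # anterior tie-break
    } else {
      mp[which.min(dd), ]
    }
  }
  m_a <- pick(geom_anode, geom_cathode$center)
  m_c <- pick(geom_cathode, geom_anode$center)
  sqrt(sum((m_a - m_c)^2)) / 10
}
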