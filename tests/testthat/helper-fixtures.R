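# Shared fixtures, all built in code at test time.

# Homogeneous skin slab filling the lower z half of the grid; large enough
# to carry a full 70 x 50 mm pad with margin.
slab_volume <- function(dims = c(44, 32, 26), voxel = 2, top = 13) {
  lab <- array(tissue_labels()[["background"]], dims)
  lab[, , seq_len(top)] <- tissue_labels()[["skin"]]
  head_volume(lab, voxel)
}

# Planar anchor at the center of the slab's top surface, normal +z.
slab_anchor <- function(vol, top = 13, long_axis = c(1, 0, 0)) {
  d <- dim(vol$labels)
  ctr_xy <- vol$origin[1:2] + (d[1:2] - 1) / 2 * vol$voxel_size_mm
  z_top <- vol$origin[3] + (top - 1) * vol$voxel_size_mm
  list(point = c(ctr_xy, z_top), normal = c(0, 0, 1), long_axis = long_axis)
}

zero_perturbation <- function() {
  perturbation_defaults(systematic_shift_mm = 0, tangential_shift_sd_mm = 0,
                        rotation_sd_deg = 0,
                        coverage_fraction_range = c(1, 1))
}

# Half-scale head and electrodes: fast plumbing tests (solves < 1 s).
small_base_spec <- function() {
  phantom_spec(grid_shape = c(48, 48, 48), voxel_size_mm = 2,
               shell_radii_mm = c(scalp = 38.5, skull = 35, csf = 32,
                                  brain = 29),
               gm_thickness_mm = 3, ventricle_radius_mm = 6)
}

small_electrode_args <- function() {
  list(pad_length_mm = 36, pad_width_mm = 26, pad_thickness_mm = 3,
       gel_max_thickness_mm = 3)
}

# Default-geometry phantom, built once per test run.
default_phantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_phantom(phantom_spec())
    cache
  }
})

# Homogeneous cuboid solve with full-face terminals at the z ends;
# returns fields plus the system for conservation checks.
solve_slab_column <- function(dims, voxel, sigma_value = 0.465,
                              current = 0.002, tol = 1e-10) {
  lab <- array(tissue_labels()[["skin"]], dims)
  vol <- head_volume(lab, voxel)
  sigma <- build_conductivity_volume(vol)
  sigma[] <- ifelse(sigma > 0, sigma_value, 0)
  sys <- assemble_laplace_system(sigma, voxel)
  lin <- array(seq_len(prod(dims)), dims)
  geom_a <- structure(list(terminal_voxels = as.vector(lin[, , dims[3]])),
                      class = "electrode_geometry")
  geom_c <- structure(list(terminal_voxels = as.vector(lin[, , 1])),
                      class = "electrode_geometry")
  cfg <- simulation_config(input_current_A = current,
                           solver_tolerance = tol)
  b <- apply_current_boundary(sys, geom_a, geom_c, cfg)
  phi <- solve_potential(sys, b, cfg)
  E <- compute_electric_field(phi, voxel)
  J <- compute_current_density(E, sigma)
  list(vol = vol, sigma = sigma, sys = sys, b = b, phi = phi, E = E, J = J)
}
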