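test_that("conductivity assignment maps labels to the configured values", {
  gm <- head_volume(array(tissue_labels()[["gm"]], c(3, 3, 3)), 1)
  expect_true(all(build_conductivity_volume(gm) == 0.276))
  bg <- head_volume(array(0L, c(3, 3, 3)), 1)
  expect_true(all(build_conductivity_volume(bg) == 0))
  two <- head_volume(array(c(tissue_labels()[["csf"]],
                             tissue_labels()[["bone"]]), c(2, 1, 1)), 1)
  expect_equal(as.vector(build_conductivity_volume(two)), c(1.65, 0.01))
  bad <- head_volume(array(9L, c(2, 2, 2)), 1)
  expect_error(build_conductivity_volume(bad),
               class = "tdcsflow_validation_error")
})

test_that("face conductances use the harmonic mean and conserve by row", {
  # two equal-sigma neighbors at 1 mm: face conductance sigma * 1e-3 S
  sig <- array(0, c(2, 1, 1))
  sig[] <- 0.465
  sys <- assemble_laplace_system(sig, 1)
  expect_equal(sys$A[1, 2], -0.465e-3)
  # harmonic mean for a bone/CSF face
  sig2 <- array(c(0.01, 1.65), c(2, 1, 1))
  sys2 <- assemble_laplace_system(sig2, 1)
  h <- 2 / (1 / 0.01 + 1 / 1.65)
  expect_equal(sys2$A[1, 2], -h * 1e-3)
  # zero row sums on a random heterogeneous grid
  set.seed(2)
  sig3 <- array(sample(c(0, 0.01, 0.276, 1.65), 10^3, replace = TRUE),
                c(10, 10, 10))
  sig3[5, 5, 5] <- 0.3 # ensure some conductive voxel
  sys3 <- assemble_laplace_system(sig3, 2)
  rs <- Matrix::rowSums(sys3$A)
  expect_lt(max(abs(rs)), 1e-12 * max(Matrix::diag(sys3$A)))
})

test_that("current sources split uniformly, balance, and flip with roles", {
  sl <- solve_slab_column(c(6, 6, 8), 2)
  dims <- dim(sl$sigma)
  lin <- array(seq_len(prod(dims)), dims)
  geom_a <- structure(list(terminal_voxels = as.vector(lin[, , dims[3]])),
                      class = "electrode_geometry")
  geom_c <- structure(list(terminal_voxels = as.vector(lin[, , 1])),
                      class = "electrode_geometry")
  cfg <- simulation_config(input_current_A = 0.002)
  b <- apply_current_boundary(sl$sys, geom_a, geom_c, cfg)
  n_term <- length(geom_a$terminal_voxels)
  expect_equal(max(b), 0.002 / n_term)
  expect_equal(sum(b[b > 0]), 0.002)
  expect_equal(sum(b), 0)
  b_swapped <- apply_current_boundary(sl$sys, geom_c, geom_a, cfg)
  expect_equal(b_swapped, -b)
})

test_that("disconnected terminal components are detected", {
  sig <- array(0, c(7, 3, 3))
  sig[1:3, , ] <- 0.465
  sig[5:7, , ] <- 0.465 # gap at x = 4
  sys <- assemble_laplace_system(sig, 2)
  lin <- array(seq_len(prod(dim(sig))), dim(sig))
  ga <- structure(list(terminal_voxels = as.vector(lin[1, , ])),
                  class = "electrode_geometry")
  gc <- structure(list(terminal_voxels = as.vector(lin[7, , ])),
                  class = "electrode_geometry")
  expect_error(apply_current_boundary(sys, ga, gc),
               class = "tdcsflow_geometry_error")
})

test_that("zero source yields zero potential after gauge fixing", {
  sig <- array(0.465, c(5, 5, 5))
  sys <- assemble_laplace_system(sig, 2)
  phi <- solve_potential(sys, numeric(nrow(sys$A)))
  expect_true(all(abs(phi[sys$index]) < 1e-14))
})

test_that("a three-voxel chain reproduces series-resistor potential drops", {
  sig <- array(c(0.465, 0.01, 1.65), c(3, 1, 1))
  h <- 1
  sys <- assemble_laplace_system(sig, h)
  I <- 0.002
  b <- c(I, 0, -I)
  phi <- solve_potential(sys, b, simulation_config(solver_tolerance = 1e-10))
  x <- phi[sys$index]
  g12 <- 2 / (1 / 0.465 + 1 / 0.01) * h * 1e-3
  g23 <- 2 / (1 / 0.01 + 1 / 1.65) * h * 1e-3
  expect_equal(x[1] - x[2], I / g12, tolerance = 1e-8)
  expect_equal(x[2] - x[3], I / g23, tolerance = 1e-8)
})

test_that("iterative solve matches a dense direct solve on small grids", {
  set.seed(11)
  for (rep in 1:3) {
    dims <- c(10, 11, 12)
    sig <- array(sample(c(0.01, 0.126, 0.276, 0.465, 1.65),
                        prod(dims), replace = TRUE), dims)
    sig[sample(prod(dims), 100)] <- 0 # air pockets
    # keep a single connected conductive component
    ctr_lin <- which(sig > 0)[1]
    comp <- tdcsflow:::reachable_voxels(as.vector(sig > 0),
                                        as.integer(dims),
                                        as.integer(ctr_lin))
    sig[!array(comp, dims)] <- 0
    sys <- assemble_laplace_system(sig, 2)
    n <- nrow(sys$A)
    b <- numeric(n)
    src <- sample(n, 20)
    b[src[1:10]] <- 1e-4
    b[src[11:20]] <- -1e-4
    b <- b - mean(b)
    phi <- solve_potential(sys, b,
                           simulation_config(solver_tolerance = 1e-12))
    x_cg <- phi[sys$index]
    # dense oracle: pin one unknown, solve the reduced system
    Ad <- as.matrix(sys$A)
    x_dense <- c(0, solve(Ad[-1, -1, drop = FALSE], b[-1]))
    x_dense <- x_dense - mean(x_dense)
    denom <- max(abs(x_dense))
    expect_lt(max(abs(x_cg - x_dense)) / denom, 1e-8)
  }
})

test_that("field derivation is exact for linear and constant potentials", {
  dims <- c(8, 8, 8)
  h <- 2
  sig <- array(0.276, dims)
  xcoord <- array(rep(seq_len(dims[1]), times = prod(dims[2:3])), dims)
  phi <- -1 * (xcoord - 1) * h * 1e-3 # slope -1 V/m along x
  E <- compute_electric_field(phi, h)
  expect_true(all(abs(E$Ex - 1) < 1e-12))
  expect_true(all(abs(E$Ey) < 1e-12))
  expect_true(all(abs(E$Ez) < 1e-12))
  E0 <- compute_electric_field(array(3.3, dims), h)
  expect_true(all(abs(E0$Ex) < 1e-12))
  J <- compute_current_density(E, sig)
  expect_equal(J$Jmag[2, 2, 2], 0.276)
  # background voxels carry zero current density
  sig[1, , ] <- 0
  J2 <- compute_current_density(E, sig)
  expect_true(all(J2$Jmag[1, , ] == 0))
})

test_that("uniform slab carries I/A everywhere away from terminals", {
  dims <- c(35, 25, 30) # 70 x 50 mm cross-section at 2 mm
  sl <- solve_slab_column(dims, 2)
  target <- 0.002 / 35e-4 # 0.5714 A/m^2
  interior <- array(FALSE, dims)
  interior[, , 5:(dims[3] - 4)] <- TRUE
  expect_lt(max(abs(sl$J$Jmag[interior] - target)) / target, 0.01)
  # |E| = |J| / sigma uniform
  expect_lt(max(abs(sl$E$Ez[interior] + target / 0.465)) /
              (target / 0.465), 0.01)
})

test_that("discrete current is conserved through planes and the surface", {
  dims <- c(12, 10, 16)
  sl <- solve_slab_column(dims, 2)
  rep1 <- check_current_conservation(sl$sys, sl$phi, sl$b)
  # every interior cross-section passes the full -2 mA (flux out of the
  # cathode-side half-space)
  expect_true(all(abs(abs(rep1$plane_flux) - 0.002) / 0.002 < 0.005))
  expect_lt(abs(rep1$surface_leakage), 0.005 * 0.002)
  expect_equal(rep1$net_source, 0)
  # zero-source solve: all fluxes vanish
  phi0 <- solve_potential(sl$sys, numeric(nrow(sl$sys$A)))
  rep0 <- check_current_conservation(sl$sys, phi0,
                                     numeric(nrow(sl$sys$A)))
  expect_true(all(abs(rep0$plane_flux) < 1e-15))
})

test_that("solution is linear in the input current and reciprocal", {
  dims <- c(10, 10, 12)
  sl1 <- solve_slab_column(dims, 2, current = 0.002, tol = 1e-12)
  sl2 <- solve_slab_column(dims, 2, current = 0.004, tol = 1e-12)
  x1 <- sl1$phi[sl1$sys$index]
  x2 <- sl2$phi[sl2$sys$index]
  expect_lt(max(abs(x2 - 2 * x1)) / max(abs(x1)), 1e-8)
  # reciprocity: swapping terminals negates the potential
  phi_swapped <- solve_potential(sl1$sys, -sl1$b,
                                 simulation_config(solver_tolerance = 1e-12))
  expect_lt(max(abs(phi_swapped[sl1$sys$index] + x1)) / max(abs(x1)), 1e-8)
})

test_that("layered slab reproduces the series-resistor closed form", {
  # skin / bone / CSF stack at 1 mm voxels
  dims <- c(20, 20, 30)
  h <- 1
  lab <- array(tissue_labels()[["skin"]], dims)
  lab[, , 11:20] <- tissue_labels()[["bone"]]
  lab[, , 21:30] <- tissue_labels()[["csf"]]
  vol <- head_volume(lab, h)
  sigma <- build_conductivity_volume(vol)
  sys <- assemble_laplace_system(sigma, h)
  lin <- array(seq_len(prod(dims)), dims)
  cfg <- simulation_config(input_current_A = 0.002,
                           solver_tolerance = 1e-12)
  ga <- structure(list(terminal_voxels = as.vector(lin[, , dims[3]])),
                  class = "electrode_geometry")
  gc <- structure(list(terminal_voxels = as.vector(lin[, , 1])),
                  class = "electrode_geometry")
  b <- apply_current_boundary(sys, ga, gc, cfg)
  phi <- solve_potential(sys, b, cfg)
  # series-resistor form measured between the end voxel-center planes:
  # effective per-layer thicknesses 9.5 / 10 / 9.5 mm
  A_m2 <- prod(dims[1:2]) * (h * 1e-3)^2
  drop_expected <- 0.002 / A_m2 * h * 1e-3 *
    (9.5 / 0.465 + 10 / 0.01 + 9.5 / 1.65)
  got <- mean(phi[, , dims[3]]) - mean(phi[, , 1])
  expect_lt(abs(got - drop_expected) / drop_expected, 0.01)
})

test_that("thicker CSF shunts current away from the brain", {
  an <- montage_anchors()
  med <- vapply(c(1.0, 0.9), function(a) {
    vol <- generate_phantom(phantom_spec(atrophy_scale = a))
    masks <- define_roi_masks(vol, an$anode, an$cathode)
    pa <- place_electrode(vol, electrode_spec(
      "anode", an$anode, partner_anchor = an$cathode))
    pc <- place_electrode(pa$volume, electrode_spec(
      "cathode", an$cathode, partner_anchor = an$anode))
    sigma <- build_conductivity_volume(pc$volume)
    sys <- assemble_laplace_system(sigma, vol$voxel_size_mm)
    b <- apply_current_boundary(sys, pa$geometry, pc$geometry)
    phi <- solve_potential(sys, b)
    E <- compute_electric_field(phi, vol$voxel_size_mm)
    J <- compute_current_density(E, sigma)
    median_current_density(J$Jmag, masks$brain)$median
  }, numeric(1))
  expect_lt(med[2], med[1])
})

test_that("non-convergence raises a solver error with residual report", {
  sig <- array(0.465, c(8, 8, 8))
  sys <- assemble_laplace_system(sig, 2)
  b <- numeric(nrow(sys$A))
  b[1] <- 1e-3
  b[length(b)] <- -1e-3
  expect_error(
    solve_potential(sys, b, simulation_config(solver_tolerance = 1e-10,
                                              max_iterations = 2L)),
    class = "tdcsflow_solver_error")
})
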