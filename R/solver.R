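#' Default tissue conductivities
#'
#' Isotropic conductivities in S/m: white matter 0.126, gray matter 0.276,
#' CSF 1.65, bone 0.01, skin 0.465, conductive paste/gel 0.3178, rubber
#' electrode pad 0.59, background/air 0 (excluded from the conductive
#' domain). All values are configurable.
#'
#' @return Named numeric vector keyed by tissue name (see
#'   [tissue_labels()]).
#' @export
conductivity_defaults <- function() {
  c(background = 0, wm = 0.126, gm = 0.276, csf = 1.65,
    bone = 0.01, skin = 0.465, gel = 0.3178, pad = 0.59)
}

#' Simulation configuration
#'
#' @param input_current_A Total injected current in amperes (default 2 mA).
#' @param solver_tolerance Relative residual for the iterative solve.
#' @param max_iterations Iteration cap for the conjugate-gradient solve.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(input_current_A = 0.002,
                              solver_tolerance = 1e-10,
                              max_iterations = 50000L) {
  if (input_current_A <= 0) stop_validation("input_current_A must be > 0")
  if (solver_tolerance <= 0 || solver_tolerance > 1e-4) {
    stop_validation("solver_tolerance must be in (0, 1e-4]")
  }
  structure(
    list(input_current_A = input_current_A,
         solver_tolerance = solver_tolerance,
         max_iterations = as.integer(max_iterations)),
    class = "simulation_config"
  )
}

#' Map tissue labels to a conductivity grid
#'
#' @param vol A [head_volume()].
#' @param cmap Named conductivities (S/m) as from [conductivity_defaults()];
#'   every label present in `vol` must have an entry.
#' @return 3D numeric array of conductivities (S/m), background 0.
#' @export
build_conductivity_volume <- function(vol, cmap = conductivity_defaults()) {
  lab <- vol$labels
  present <- sort(unique(as.vector(lab)))
  codes <- LABELS[names(cmap)]
  if (any(is.na(codes))) {
    stop_validation("unknown tissue names in conductivity map: ",
                    paste(setdiff(names(cmap), names(LABELS)), collapse = ", "))
  }
  missing <- setdiff(present, codes)
  if (length(missing) > 0) {
    stop_validation("labels without a conductivity entry: ",
                    paste(missing, collapse = ", "))
  }
  lut <- numeric(max(codes) + 1)
  lut[codes + 1] <- cmap
  sigma <- array(lut[as.vector(lab) + 1], dim = dim(lab))
  sigma
}

#' Assemble the finite-volume Laplace operator
#'
#' Discretizes div(sigma grad phi) = 0 on the voxel grid with a 7-point
#' finite-volume stencil. The conductance of the face between neighboring
#' voxels i and j is `H(sigma_i, sigma_j) * A_face / d` with H the harmonic
#' mean (exact for layered media), `A_face` the voxel face area and `d` the
#' center spacing; faces touching a non-conductive voxel carry zero flux
#' (natural Neumann boundary). Only voxels with sigma > 0 become unknowns.
#'
#' @param sigma 3D conductivity array (S/m) from
#'   [build_conductivity_volume()].
#' @param voxel_size_mm Isotropic voxel spacing in mm.
#' @return Object of class `laplace_system`: sparse symmetric operator `A`
#'   (entries in siemens), 1-based linear `index` of the unknown voxels,
#'   inverse `map` grid, `dims`, `voxel_size_mm`.
#' @export
assemble_laplace_system <- function(sigma, voxel_size_mm) {
  d <- dim(sigma)
  cond <- sigma > 0
  idx <- which(cond)
  nun <- length(idx)
  if (nun == 0) stop_validation("no conductive voxels")
  map <- integer(prod(d))
  map[idx] <- seq_len(nun)

  lin <- array(seq_len(prod(d)), dim = d)
  pair_i <- vector("list", 3)
  pair_j <- vector("list", 3)
  pair_i[[1]] <- as.vector(lin[-d[1], , , drop = FALSE])
  pair_j[[1]] <- as.vector(lin[-1, , , drop = FALSE])
  pair_i[[2]] <- as.vector(lin[, -d[2], , drop = FALSE])
  pair_j[[2]] <- as.vector(lin[, -1, , drop = FALSE])
  pair_i[[3]] <- as.vector(lin[, , -d[3], drop = FALSE])
  pair_j[[3]] <- as.vector(lin[, , -1, drop = FALSE])
  ii <- unlist(pair_i, use.names = FALSE)
  jj <- unlist(pair_j, use.names = FALSE)
  keep <- cond[ii] & cond[jj]
  ii <- ii[keep]
  jj <- jj[keep]
  # Face conductance in S: harmonic mean (S/m) * face area / spacing
  # = H * voxel_size (mm) * 1e-3 (m/mm) for an isotropic grid.
  g <- 2 / (1 / sigma[ii] + 1 / sigma[jj]) * voxel_size_mm * 1e-3
  # Isolated conductive voxels (no conductive face neighbor) carry no
  # current and would make the operator singular voxelwise; exclude them
  # from the unknowns like the non-conductive background.
  deg <- tabulate(c(map[ii], map[jj]), nbins = nun)
  if (any(deg == 0)) {
    idx <- idx[deg > 0]
    nun <- length(idx)
    map <- integer(prod(d))
    map[idx] <- seq_len(nun)
  }
  ri <- map[ii]
  rj <- map[jj]
  A <- Matrix::sparseMatrix(
    i = c(ri, rj, ri, rj),
    j = c(rj, ri, ri, rj),
    x = c(-g, -g, g, g),
    dims = c(nun, nun)
  )
  structure(
    list(A = A, index = idx, map = map, dims = d,
         voxel_size_mm = voxel_size_mm),
    class = "laplace_system"
  )
}

# Terminal voxels of a placed electrode: the outer-face layer of the pad.
terminal_voxels <- function(geom) {
  tv <- geom$terminal_voxels
  if (is.null(tv) || length(tv) == 0) {
    stop_validation("electrode geometry has no terminal voxels")
  }
  tv
}

#' Build the Neumann current source vector
#'
#' Distributes the input current +I uniformly over the anode pad's
#' outer-face terminal voxels and -I over the cathode's, so the source sums
#' to zero exactly (compatibility condition of the pure-Neumann problem) and
#' no current leaves anywhere else on the head surface.
#'
#' @param system A `laplace_system` from [assemble_laplace_system()].
#' @param anode,cathode `electrode_geometry` objects from
#'   [place_electrode()].
#' @param config A [simulation_config()].
#' @return Numeric source vector (amperes) over the system unknowns.
#' @export
apply_current_boundary <- function(system, anode, cathode,
                                   config = simulation_config()) {
  ta <- terminal_voxels(anode)
  tc <- terminal_voxels(cathode)
  ua <- system$map[ta]
  uc <- system$map[tc]
  if (any(ua == 0) || any(uc == 0)) {
    # isolated pad voxels excluded at assembly cannot carry current
    if (all(ua == 0) || all(uc == 0)) {
      stop_validation("all terminal voxels fall outside the conductive domain")
    }
    ta <- ta[ua > 0]
    tc <- tc[uc > 0]
    ua <- ua[ua > 0]
    uc <- uc[uc > 0]
  }
  cond_flag <- as.vector(system$map > 0)
  seen <- reachable_voxels(cond_flag, as.integer(system$dims),
                           as.integer(ta))
  if (!all(seen[tc])) {
    stop_geometry("anode and cathode terminals lie in disconnected conductive components")
  }
  b <- numeric(nrow(system$A))
  b[ua] <- b[ua] + config$input_current_A / length(ua)
  b[uc] <- b[uc] - config$input_current_A / length(uc)
  b
}

#' Solve for the electric potential
#'
#' Jacobi-preconditioned conjugate gradients on the singular pure-Neumann
#' system, iterated to the configured relative residual. The gauge is fixed
#' by subtracting the mean potential over the conductive domain.
#'
#' @param system A `laplace_system`.
#' @param source Source vector from [apply_current_boundary()] (amperes;
#'   must sum to zero).
#' @param config A [simulation_config()].
#' @return 3D array of potentials (volts); `NA` outside the conductive
#'   domain. Attribute `solve_info` carries iterations and residual.
#' @export
solve_potential <- function(system, source, config = simulation_config()) {
  if (length(source) != nrow(system$A)) {
    stop_validation("source length does not match system unknowns")
  }
  tot <- sum(source)
  if (abs(tot) > 1e-9 * max(abs(source), 1e-300)) {
    stop_validation("source is not compatible (does not sum to zero)")
  }
  A <- methods::as(system$A, "CsparseMatrix")
  res <- cg_neumann(A@p, A@i, A@x, source,
                    config$solver_tolerance, config$max_iterations)
  if (!res$converged && any(source != 0)) {
    stop_solver(sprintf(
      "CG did not converge: relative residual %.3e after %d iterations",
      res$relres, res$iterations))
  }
  x <- res$x - mean(res$x)
  phi <- array(NA_real_, dim = system$dims)
  phi[system$index] <- x
  attr(phi, "solve_info") <- list(iterations = res$iterations,
                                  relres = res$relres)
  phi
}

# Shift an array by one voxel along an axis, padding with NA.
shift_array <- function(a, axis, by) {
  d <- dim(a)
  out <- array(NA_real_, dim = d)
  src <- lapply(d, seq_len)
  dst <- src
  if (by == 1) {
    src[[axis]] <- seq_len(d[axis] - 1)
    dst[[axis]] <- 2:d[axis]
  } else {
    src[[axis]] <- 2:d[axis]
    dst[[axis]] <- seq_len(d[axis] - 1)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

#' Electric field from the potential
#'
#' E = -grad(phi), central differences inside the conductive domain and
#' one-sided differences where a neighbor is missing (domain boundary).
#'
#' @param phi Potential grid (V) from [solve_potential()].
#' @param voxel_size_mm Voxel spacing in mm.
#' @return List of 3D arrays `Ex`, `Ey`, `Ez` in V/m; `NA` outside the
#'   domain.
#' @export
compute_electric_field <- function(phi, voxel_size_mm) {
  h_m <- voxel_size_mm * 1e-3
  inside <- is.finite(phi)
  comp <- function(axis) {
    pm <- shift_array(phi, axis, 1)  # value at i-1
    pp <- shift_array(phi, axis, -1) # value at i+1
    hm <- is.finite(pm)
    hp <- is.finite(pp)
    g <- array(0, dim = dim(phi))
    both <- hm & hp
    g[both] <- (pp[both] - pm[both]) / (2 * h_m)
    fwd <- !hm & hp
    g[fwd] <- (pp[fwd] - phi[fwd]) / h_m
    bwd <- hm & !hp
    g[bwd] <- (phi[bwd] - pm[bwd]) / h_m
    g[!inside] <- NA_real_
    -g
  }
  list(Ex = comp(1), Ey = comp(2), Ez = comp(3))
}

#' Current density from field and conductivity
#'
#' J = sigma * E voxelwise; the magnitude is the Euclidean norm of the
#' components. Non-conductive voxels carry zero current density.
#'
#' @param E Field component list from [compute_electric_field()].
#' @param sigma Conductivity grid (S/m).
#' @return List with components `Jx`, `Jy`, `Jz` and magnitude `Jmag`, all
#'   in A/m^2.
#' @export
compute_current_density <- function(E, sigma) {
  if (!all(dim(E$Ex) == dim(sigma))) stop_validation("shape mismatch")
  jc <- function(e) {
    j <- sigma * e
    j[sigma == 0] <- 0
    j
  }
  Jx <- jc(E$Ex)
  Jy <- jc(E$Ey)
  Jz <- jc(E$Ez)
  list(Jx = Jx, Jy = Jy, Jz = Jz,
       Jmag = sqrt(Jx^2 + Jy^2 + Jz^2))
}

#' Check discrete current conservation
#'
#' Integrates the discrete flux over axis-aligned cut planes (every face
#' crossed by the plane contributes its face conductance times the potential
#' drop) and over the closed head surface, reporting the net fluxes and
#' their deviation from the injected current. Under the zero-flux Neumann
#' boundary the surface leakage is zero up to the solver residual.
#'
#' @param system A `laplace_system`.
#' @param phi Solved potential grid.
#' @param source Source vector used for the solve (amperes).
#' @param plane_axis Axis (1, 2 or 3) normal to the cut planes.
#' @param plane_after Integer slice indices k; each plane cuts between
#'   slices k and k+1. Default: every interior plane.
#' @return List: `plane_flux` (A, signed, one per plane), `surface_leakage`
#'   (A), `net_source` (A), `max_voxel_imbalance` (A).
#' @export
check_current_conservation <- function(system, phi, source,
                                       plane_axis = 3, plane_after = NULL) {
  x <- phi[system$index]
  Ax <- as.numeric(system$A %*% x)
  resid <- source - Ax
  d <- system$dims
  if (is.null(plane_after)) plane_after <- seq_len(d[plane_axis] - 1)
  ax_index <- arrayInd(system$index, d)[, plane_axis]
  plane_flux <- vapply(plane_after, function(k) {
    s_side <- ax_index <= k
    # Net flux out of the half-space = sum over it of (A phi) = source - resid.
    sum(Ax[s_side])
  }, numeric(1))
  list(
    plane_flux = plane_flux,
    surface_leakage = sum(Ax),
    net_source = sum(source),
    max_voxel_imbalance = max(abs(resid))
  )
}
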