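# Region keys summarized for every subject and model.
REGION_KEYS <- c("whole_head", "brain", "gm", "wm",
                 "sfg_analog", "mfg_analog", "ifg_analog", "temporal_analog")

# Apply a small seeded tangential perturbation (degrees) to a unit anchor
# direction; used for per-subject planned-montage jitter.
jitter_anchor <- function(u, sd_deg) {
  if (sd_deg == 0) return(u)
  ref <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
  t1 <- unit(pracma_cross(u, ref))
  t2 <- unit(pracma_cross(u, t1))
  a <- stats::rnorm(2, 0, sd_deg * pi / 180)
  unit(u + a[1] * t1 + a[2] * t2)
}

# Place both electrodes of one model, solve, and summarize.
.simulate_one_model <- function(vol, anchors, mode, seed_a, seed_c,
                                config, perturbation, cmap, masks,
                                electrode_args = list()) {
  sp_a <- do.call(electrode_spec, c(
    list(role = "anode", anchor = anchors$anode,
         partner_anchor = anchors$cathode, mode = mode,
         perturbation = perturbation, seed = seed_a),
    electrode_args))
  sp_c <- do.call(electrode_spec, c(
    list(role = "cathode", anchor = anchors$cathode,
         partner_anchor = anchors$anode, mode = mode,
         perturbation = perturbation, seed = seed_c),
    electrode_args))
  p1 <- place_electrode(vol, sp_a)
  p2 <- place_electrode(p1$volume, sp_c)
  vol_e <- p2$volume
  sigma <- build_conductivity_volume(vol_e, cmap)
  system <- assemble_laplace_system(sigma, vol_e$voxel_size_mm)
  b <- apply_current_boundary(system, p1$geometry, p2$geometry, config)
  phi <- solve_potential(system, b, config)
  E <- compute_electric_field(phi, vol_e$voxel_size_mm)
  J <- compute_current_density(E, sigma)
  medians <- vapply(REGION_KEYS, function(k) {
    median_current_density(J$Jmag, masks[[k]], region = k, model = mode)$median
  }, numeric(1))
  list(
    geom_anode = p1$geometry, geom_cathode = p2$geometry,
    volume = vol_e,
    area_anode = compute_contact_area(vol_e, p1$geometry),
    area_cathode = compute_contact_area(vol_e, p2$geometry),
    separation_cm = compute_separation_distance(p1$geometry, p2$geometry),
    medians = medians, jmag = J$Jmag,
    solve_info = attr(phi, "solve_info")
  )
}

#' Run the paired artificial/real simulation for one subject
#'
#' Places the idealized and the perturbed as-placed electrode montage on
#' copies of the same tissue volume (tissue labels are bit-identical across
#' the two solves, so every difference in the fields originates from the
#' electrode model), solves both, and reduces to the per-subject comparison
#' row: regional median current densities, electrode properties, and percent
#' differences.
#'
#' @param vol A [head_volume()] without electrodes.
#' @param anchors List with unit vectors `anode` and `cathode` (the planned
#'   montage for this subject).
#' @param subject_seed Seed governing the real-mode perturbations.
#' @param config A [simulation_config()].
#' @param perturbation Real-mode perturbation parameters.
#' @param cmap Conductivity map.
#' @param sectors ROI sector bounds.
#' @param keep_fields Keep the two current-density magnitude grids.
#' @param electrode_args Extra arguments for [electrode_spec()] (pad and gel
#'   dimensions).
#' @return List: `row` (named list of scalars), `masks`, and if requested
#'   `jmag_artificial`, `jmag_real`.
#' @export
run_paired_simulation <- function(vol, anchors, subject_seed = 1L,
                                  config = simulation_config(),
                                  perturbation = perturbation_defaults(),
                                  cmap = conductivity_defaults(),
                                  sectors = roi_sector_defaults(),
                                  keep_fields = FALSE,
                                  electrode_args = list()) {
  masks <- define_roi_masks(vol, anchors$anode, anchors$cathode, sectors)
  art <- .simulate_one_model(vol, anchors, "artificial",
                             derive_seed(subject_seed, 1),
                             derive_seed(subject_seed, 2),
                             config, perturbation, cmap, masks,
                             electrode_args)
  rea <- .simulate_one_model(vol, anchors, "real",
                             derive_seed(subject_seed, 3),
                             derive_seed(subject_seed, 4),
                             config, perturbation, cmap, masks,
                             electrode_args)
  tissue_identical <- identical(
    art$volume$labels * (art$volume$labels <= 5L),
    rea$volume$labels * (rea$volume$labels <= 5L)
  )
  row <- list(
    ratio_brain = compute_volume_ratio(vol, "brain"),
    ratio_gm = compute_volume_ratio(vol, "gm"),
    ratio_wm = compute_volume_ratio(vol, "wm"),
    area_anode_artificial = art$area_anode,
    area_cathode_artificial = art$area_cathode,
    area_anode_real = rea$area_anode,
    area_cathode_real = rea$area_cathode,
    separation_artificial_cm = art$separation_cm,
    separation_real_cm = rea$separation_cm,
    pd_separation = percent_difference(art$separation_cm, rea$separation_cm),
    pd_area = percent_difference(
      (art$area_anode + art$area_cathode) / 2,
      (rea$area_anode + rea$area_cathode) / 2
    ),
    tissue_identical = tissue_identical
  )
  for (k in REGION_KEYS) {
    row[[paste0("med_", k, "_artificial")]] <- art$medians[[k]]
    row[[paste0("med_", k, "_real")]] <- rea$medians[[k]]
    row[[paste0("pd_", k)]] <-
      percent_difference(art$medians[[k]], rea$medians[[k]])
  }
  out <- list(row = row, masks = masks)
  if (keep_fields) {
    out$jmag_artificial <- art$jmag
    out$jmag_real <- rea$jmag
  }
  out
}

#' Run the full cohort comparison experiment
#'
#' Generates a phantom cohort with graded atrophy, jitters the planned
#' montage anchors per subject (identically for both electrode models, so
#' the as-placed deviation is relative to each subject's planned montage),
#' runs the paired simulation for every subject (two solves per subject),
#' and assembles the comparison table with normalized contact areas.
#' Per-subject failures are recorded and the run continues.
#'
#' @param n Cohort size.
#' @param atrophy_range Atrophy scale interval.
#' @param master_seed Single seed fixing the entire experiment.
#' @param base_spec Template [phantom_spec()].
#' @param anchors Planned montage from [montage_anchors()].
#' @param anchor_jitter_sd_deg Per-subject tangential jitter (degrees) of
#'   the planned anchors.
#' @param config,perturbation,cmap,sectors Passed to
#'   [run_paired_simulation()].
#' @param keep_fields Keep per-subject current-density grids (needed for
#'   voxelwise t-maps).
#' @param cohort_jitter Phantom jitter multiplier (see [generate_cohort()]).
#' @param electrode_args Extra arguments for [electrode_spec()].
#' @param verbose Print per-subject progress.
#' @return List: `table` (one row per subject), `masks` (shared-grid masks
#'   of the first subject), and if requested `jmag_artificial`, `jmag_real`
#'   (lists of grids).
#' @export
run_cohort_experiment <- function(n = 16, atrophy_range = c(0.86, 1.0),
                                  master_seed = 1L,
                                  base_spec = phantom_spec(),
                                  anchors = montage_anchors(),
                                  anchor_jitter_sd_deg = 5,
                                  config = simulation_config(),
                                  perturbation = perturbation_defaults(),
                                  cmap = conductivity_defaults(),
                                  sectors = roi_sector_defaults(),
                                  keep_fields = FALSE,
                                  cohort_jitter = 1,
                                  electrode_args = list(),
                                  verbose = FALSE) {
  cohort <- generate_cohort(n, atrophy_range, jitter = cohort_jitter,
                            seed = derive_seed(master_seed, 0),
                            base_spec = base_spec)
  rows <- vector("list", n)
  jm_a <- vector("list", n)
  jm_r <- vector("list", n)
  masks1 <- NULL
  for (i in seq_len(n)) {
    subj_anchors <- with_seed(derive_seed(master_seed, 100 + i), list(
      anode = jitter_anchor(anchors$anode, anchor_jitter_sd_deg),
      cathode = jitter_anchor(anchors$cathode, anchor_jitter_sd_deg)
    ))
    res <- tryCatch(
      run_paired_simulation(
        cohort[[i]]$volume, subj_anchors,
        subject_seed = derive_seed(master_seed, 200 + i),
        config = config, perturbation = perturbation, cmap = cmap,
        sectors = sectors, keep_fields = keep_fields,
        electrode_args = electrode_args
      ),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      warning(sprintf("subject %d failed: %s", i, conditionMessage(res)))
      rows[[i]] <- list(complete = FALSE)
    } else {
      rows[[i]] <- c(list(subject = i,
                          atrophy_scale = cohort[[i]]$spec$atrophy_scale,
                          complete = TRUE), res$row)
      if (keep_fields) {
        jm_a[[i]] <- res$jmag_artificial
        jm_r[[i]] <- res$jmag_real
      }
      if (is.null(masks1)) masks1 <- res$masks
      if (verbose) {
        message(sprintf(
          "subject %2d: sep %4.2f/%4.2f cm, med J brain %.4f/%.4f A/m^2",
          i, rows[[i]]$separation_artificial_cm,
          rows[[i]]$separation_real_cm,
          rows[[i]]$med_brain_artificial, rows[[i]]$med_brain_real))
      }
    }
  }
  complete <- vapply(rows, function(r) isTRUE(r$complete), logical(1))
  all_names <- unique(unlist(lapply(rows[complete], names)))
  table <- do.call(rbind, lapply(seq_len(n), function(i) {
    r <- rows[[i]]
    vals <- lapply(all_names, function(nm) r[[nm]] %||% NA)
    names(vals) <- all_names
    vals$subject <- i
    as.data.frame(vals)
  }))
  table$norm_area_artificial <- NA_real_
  table$norm_area_real <- NA_real_
  if (sum(complete) > 0) {
    tc <- table[complete, ]
    norm <- normalize_contact_areas(
      cbind(tc$area_anode_artificial, tc$area_cathode_artificial),
      cbind(tc$area_anode_real, tc$area_cathode_real)
    )
    table$norm_area_artificial[complete] <- norm$subject_artificial
    table$norm_area_real[complete] <- norm$subject_real
  }
  out <- list(table = table, masks = masks1)
  if (keep_fields) {
    out$jmag_artificial <- jm_a[complete]
    out$jmag_real <- jm_r[complete]
  }
  out
}

#' Correlate electrode-property differences with dose differences
#'
#' Regresses the per-subject percent difference of regional median current
#' density on the percent differences of electrode separation distance and
#' of contact area, one regression per (predictor, region) pair.
#'
#' @param table Comparison table from [run_cohort_experiment()].
#' @param regions Region keys to include.
#' @return data.frame: predictor, region, slope, r_squared, p, n. Pairs
#'   with a constant predictor are skipped with a warning.
#' @export
correlate_electrode_properties <- function(table, regions = REGION_KEYS) {
  tab <- table[!is.na(table$pd_separation), ]
  if (nrow(tab) < 3) stop_validation("need at least 3 complete rows")
  out <- list()
  for (pred in c("pd_separation", "pd_area")) {
    x <- tab[[pred]]
    if (stats::var(x) == 0) {
      warning("constant predictor skipped: ", pred)
      next
    }
    for (rg in regions) {
      y <- tab[[paste0("pd_", rg)]]
      fit <- linear_regression(x, y)
      out[[length(out) + 1]] <- data.frame(
        predictor = pred, region = rg, slope = fit$slope,
        r_squared = fit$r_squared, p = fit$p, n = fit$n
      )
    }
  }
  do.call(rbind, out)
}

#' Correlate brain volume ratio with median current density
#'
#' Regresses regional median current density on the matching volume ratio
#' (brain, gray matter, white matter) separately for the idealized and the
#' as-placed electrode model; the sign of the slope is the headline result
#' (lower ratio = more atrophy = less current reaching the brain).
#'
#' @param table Comparison table from [run_cohort_experiment()].
#' @return data.frame: region, model, slope, r_squared, p, n.
#' @export
correlate_atrophy <- function(table) {
  tab <- table[!is.na(table$med_brain_artificial), ]
  if (nrow(tab) < 3) stop_validation("need at least 3 complete rows")
  out <- list()
  for (rg in c("brain", "gm", "wm")) {
    x <- tab[[paste0("ratio_", rg)]]
    if (stats::var(x) == 0) {
      warning("constant volume ratio skipped: ", rg)
      next
    }
    for (model in c("artificial", "real")) {
      y <- tab[[paste0("med_", rg, "_", model)]]
      fit <- linear_regression(x, y)
      out[[length(out) + 1]] <- data.frame(
        region = rg, model = model, slope = fit$slope,
        r_squared = fit$r_squared, p = fit$p, n = fit$n
      )
    }
  }
  do.call(rbind, out)
}
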