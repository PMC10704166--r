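nifti_affine <- function(voxel_size_mm, origin) {
  aff <- diag(c(rep(voxel_size_mm, 3), 1))
  aff[1:3, 4] <- origin
  aff
}

#' Write a labeled head volume as NIfTI-1
#'
#' Integer tissue labels with the voxel size on the affine diagonal and the
#' world coordinate of the first voxel center in the translation column.
#'
#' @param vol A [head_volume()].
#' @param path Output `.nii` / `.nii.gz` path.
#' @return The path, invisibly.
#' @export
write_labeled_volume <- function(vol, path) {
  x <- vol$labels
  attr(x, "pixdim") <- rep(vol$voxel_size_mm, 3)
  img <- RNifti::asNifti(x, datatype = "int32")
  aff <- nifti_affine(vol$voxel_size_mm, vol$origin)
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a labeled head volume from NIfTI-1
#'
#' @param path NIfTI file with integer-valued data.
#' @return A [head_volume()]. Non-integer data raises a format error; an
#'   anisotropic affine raises a warning and uses the first axis spacing.
#' @export
read_labeled_volume <- function(path) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3) stop_validation("expected a 3D label volume")
  arr <- array(as.vector(img), dim = dim(img))
  if (any(arr != round(arr))) {
    stop_validation("label volume contains non-integer data")
  }
  aff <- RNifti::xform(img)
  sp <- sqrt(colSums(aff[1:3, 1:3]^2))
  if (diff(range(sp)) > 1e-6 * sp[1]) {
    warning("anisotropic voxel spacing; using the first axis spacing")
  }
  origin <- aff[1:3, 4]
  storage.mode(arr) <- "integer"
  head_volume(arr, sp[1], origin)
}

#' Write a field volume as float32 NIfTI-1
#'
#' @param grid 3D numeric grid (NA/NaN allowed outside the conductive
#'   domain).
#' @param vol The [head_volume()] supplying the affine.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_field_volume <- function(grid, vol, path) {
  x <- grid
  attributes(x) <- list(dim = dim(grid),
                        pixdim = rep(vol$voxel_size_mm, 3))
  img <- RNifti::asNifti(x, datatype = "float")
  aff <- nifti_affine(vol$voxel_size_mm, vol$origin)
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a field volume
#'
#' @param path NIfTI file.
#' @return List with `grid` (3D numeric array), `voxel_size_mm`, `origin`.
#' @export
read_field_volume <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  sp <- sqrt(colSums(aff[1:3, 1:3]^2))
  list(grid = array(as.vector(img), dim = dim(img)),
       voxel_size_mm = sp[1], origin = aff[1:3, 4])
}

#' Write a comparison or statistics table as CSV
#'
#' Fixed column order, header row, locale-independent decimal point.
#'
#' @param table A data.frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Read a run configuration file
#'
#' YAML configuration with blocks `cohort`, `electrodes`, `conductivities`,
#' `solver`, plus `output_dir` and `master_seed`. Unknown top-level keys are
#' rejected so typos do not silently fall back to defaults.
#'
#' @param path YAML file path.
#' @return Named list of configuration blocks merged over defaults.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("cohort", "electrodes", "conductivities", "solver",
             "output_dir", "master_seed", "verbosity")
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    stop_validation("unknown configuration keys: ",
                    paste(unknown, collapse = ", "))
  }
  if (is.null(raw$master_seed)) {
    stop_validation("configuration must set master_seed explicitly")
  }
  # "n_subjects" rather than "n": bare n/y are YAML 1.1 booleans and would
  # silently turn into logical keys
  defaults <- list(
    cohort = list(n_subjects = 16, atrophy_range = c(0.86, 1.0), jitter = 1),
    electrodes = list(anchor_jitter_sd_deg = 5),
    conductivities = as.list(conductivity_defaults()),
    solver = list(input_current_A = 0.002, solver_tolerance = 1e-10,
                  max_iterations = 50000),
    output_dir = "results",
    verbosity = 1
  )
  for (k in names(defaults)) {
    if (is.list(defaults[[k]])) {
      raw[[k]] <- utils::modifyList(defaults[[k]], raw[[k]] %||% list())
    } else if (is.null(raw[[k]])) {
      raw[[k]] <- defaults[[k]]
    }
  }
  raw
}
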