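#' @useDynLib tdcsflow, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Tissue label codes shared by every module. Gel (6) and pad (7) only appear
# after electrode placement.
LABELS <- c(
  background = 0L, wm = 1L, gm = 2L, csf = 3L,
  bone = 4L, skin = 5L, gel = 6L, pad = 7L
)

#' Tissue label codes
#'
#' Integer codes used in labeled head volumes: 0 background/air, 1 white
#' matter, 2 gray matter, 3 CSF, 4 bone, 5 skin, 6 gel/paste, 7 electrode
#' pad.
#'
#' @return Named integer vector of label codes.
#' @export
tissue_labels <- function() LABELS

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(expr)
}

# Derive a child seed from a master seed and a stream index; keeps every
# random operation traceable to one master seed while avoiding overlapping
# streams. Result is kept inside the 32-bit integer range.
derive_seed <- function(master, stream) {
  (as.double(master) * 48271 + as.double(stream) * 16807) %% 2147483629
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_validation <- function(...) {
  stop(errorCondition(paste0(...), class = c("tdcsflow_validation_error", "error")))
}

stop_geometry <- function(...) {
  stop(errorCondition(paste0(...), class = c("tdcsflow_geometry_error", "error")))
}

stop_solver <- function(...) {
  stop(errorCondition(paste0(...), class = c("tdcsflow_solver_error", "error")))
}

unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stop_validation("cannot normalize a zero vector")
  v / n
}

# World coordinates (mm) of every voxel center along one axis.
axis_coords <- function(dim, voxel_size_mm, origin_axis) {
  origin_axis + (seq_len(dim) - 1) * voxel_size_mm
}

# World coordinate (mm) of a voxel index triple (1-based).
voxel_to_world <- function(idx, voxel_size_mm, origin) {
  sweep((idx - 1) * voxel_size_mm, 2, origin, `+`)
}

# Nearest voxel index triple (1-based) for world points (rows of `p`).
world_to_voxel <- function(p, voxel_size_mm, origin) {
  round(sweep(p, 2, origin, `-`) / voxel_size_mm) + 1
}
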