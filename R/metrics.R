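#' Median current density over a region
#'
#' Sample median (mean of the two central order statistics for even counts)
#' of the current-density magnitude over the masked voxels. Medians rather
#' than means summarize each region so hotspot outliers near the electrodes
#' do not skew the regional dose.
#'
#' @param jmag 3D current-density magnitude grid (A/m^2).
#' @param mask Logical 3D mask.
#' @param region,model Optional tags carried into the summary.
#' @return Object of class `median_summary`: `region`, `median`
#'   (A/m^2), `n_voxels`, `model`.
#' @export
median_current_density <- function(jmag, mask, region = "", model = "") {
  if (!any(mask)) stop_validation("mask is empty")
  vals <- jmag[mask]
  if (any(!is.finite(vals))) {
    stop_validation("non-finite current density inside mask")
  }
  structure(
    list(region = region, median = stats::median(vals),
         n_voxels = length(vals), model = model),
    class = "median_summary"
  )
}

#' Percent difference relative to the as-placed model
#'
#' `100 * |artificial - real| / real`: the absolute difference between the
#' two electrode models' values, relative to the as-placed ("real") model.
#' Vectorized over paired inputs.
#'
#' @param artificial_value,real_value Paired metric values; `real_value`
#'   must be nonzero.
#' @return Percent difference(s).
#' @export
percent_difference <- function(artificial_value, real_value) {
  if (any(real_value == 0)) {
    stop_validation("real_value must be nonzero for a percent difference")
  }
  100 * abs(artificial_value - real_value) / real_value
}

# Moving-average box filter of full width `w` (odd) along every axis, with
# truncated windows at the borders (normalized by the in-window count).
box_mean3 <- function(a, w = 11L) {
  half <- (w - 1L) %/% 2L
  sm1 <- function(m) {
    # column-wise moving mean over a matrix, truncated at edges
    n <- nrow(m)
    cs <- rbind(0, apply(m, 2, cumsum))
    hi <- pmin(seq_len(n) + half, n)
    lo <- pmax(seq_len(n) - half, 1L)
    (cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]) / (hi - lo + 1)
  }
  d <- dim(a)
  x <- sm1(matrix(a, d[1], d[2] * d[3]))
  x <- aperm(array(x, d), c(2, 1, 3))
  x <- sm1(matrix(x, d[2], d[1] * d[3]))
  x <- aperm(array(x, d[c(2, 1, 3)]), c(2, 1, 3))
  x <- aperm(x, c(3, 2, 1))
  x <- sm1(matrix(x, d[3], d[2] * d[1]))
  aperm(array(x, d[c(3, 2, 1)]), c(3, 2, 1))
}

#' Structural similarity and Dice overlap of two field volumes
#'
#' SSIM with the standard constants (11-voxel cubic window, K1 = 0.01,
#' K2 = 0.03, dynamic range = max over both masked volumes), averaged over
#' the mask. Dice is computed between the suprathreshold sets of the two
#' volumes, thresholding each at a configurable percentile of its own
#' masked values.
#'
#' @param vol_a,vol_b 3D grids on the same lattice.
#' @param mask Logical mask over which both metrics are evaluated.
#' @param dice_percentile Percentile (0-1) defining the suprathreshold
#'   sets; default 0.99.
#' @param window SSIM window width (odd).
#' @return List with `ssim` and `dice`.
#' @export
volume_similarity <- function(vol_a, vol_b, mask, dice_percentile = 0.99,
                              window = 11L) {
  if (!all(dim(vol_a) == dim(vol_b)) || !all(dim(vol_a) == dim(mask))) {
    stop_validation("volume and mask shapes must match")
  }
  if (!any(mask)) stop_validation("mask is empty")
  a <- vol_a
  b <- vol_b
  a[!mask | !is.finite(a)] <- 0
  b[!mask | !is.finite(b)] <- 0
  L <- max(max(a[mask]), max(b[mask]))
  if (L <= 0) stop_validation("volumes are non-positive everywhere in mask")
  c1 <- (0.01 * L)^2
  c2 <- (0.03 * L)^2
  mu_a <- box_mean3(a, window)
  mu_b <- box_mean3(b, window)
  var_a <- box_mean3(a * a, window) - mu_a^2
  var_b <- box_mean3(b * b, window) - mu_b^2
  cov_ab <- box_mean3(a * b, window) - mu_a * mu_b
  ssim_map <- ((2 * mu_a * mu_b + c1) * (2 * cov_ab + c2)) /
    ((mu_a^2 + mu_b^2 + c1) * (var_a + var_b + c2))
  ssim <- mean(ssim_map[mask])

  ta <- stats::quantile(vol_a[mask], dice_percentile, names = FALSE)
  tb <- stats::quantile(vol_b[mask], dice_percentile, names = FALSE)
  sa <- mask & vol_a > ta
  sb <- mask & vol_b > tb
  denom <- sum(sa) + sum(sb)
  if (denom == 0) {
    stop_validation("Dice undefined: both suprathreshold sets are empty")
  }
  dice <- 2 * sum(sa & sb) / denom
  list(ssim = ssim, dice = dice)
}

#' Voxelwise paired t-map between two model stacks
#'
#' Per-voxel paired t-test across subjects between the as-placed and
#' idealized current-density stacks (all phantoms share one grid, so no
#' template registration is needed). Voxels with zero difference variance
#' are excluded and counted. Significance is thresholded at `alpha`,
#' uncorrected.
#'
#' @param stack_artificial,stack_real Lists of n 3D grids (same order of
#'   subjects).
#' @param alpha Uncorrected two-sided significance level (default 0.001).
#' @param mask Optional logical mask restricting the comparison (default:
#'   all voxels finite in every subject).
#' @return Object of class `paired_map_comparison`: `t` grid,
#'   `significant` mask, `difference` grid (mean real - artificial inside
#'   the significant mask, A/m^2), `df`, `alpha`, `n_excluded`.
#' @export
voxelwise_paired_tmap <- function(stack_artificial, stack_real,
                                  alpha = 0.001, mask = NULL) {
  n <- length(stack_artificial)
  if (length(stack_real) != n) stop_validation("stacks differ in length")
  if (n < 3) stop_validation("paired t-map needs n >= 3 subjects")
  d <- dim(stack_artificial[[1]])
  A <- vapply(stack_artificial, as.vector, numeric(prod(d)))
  B <- vapply(stack_real, as.vector, numeric(prod(d)))
  if (is.null(mask)) {
    mask <- array(rowSums(!is.finite(A)) + rowSums(!is.finite(B)) == 0,
                  dim = d)
  }
  m <- as.vector(mask)
  D <- B[m, , drop = FALSE] - A[m, , drop = FALSE]
  mu <- rowMeans(D)
  sdv <- sqrt(rowSums((D - mu)^2) / (n - 1))
  zero_var <- sdv == 0
  tval <- rep(NA_real_, length(mu))
  tval[!zero_var] <- mu[!zero_var] / (sdv[!zero_var] / sqrt(n))
  df <- n - 1
  pval <- rep(NA_real_, length(mu))
  pval[!zero_var] <- 2 * stats::pt(-abs(tval[!zero_var]), df)
  tg <- array(NA_real_, d)
  tg[m] <- tval
  sig <- array(FALSE, d)
  sig[which(m)[!zero_var & pval < alpha]] <- TRUE
  diffg <- array(NA_real_, d)
  diffg[sig] <- mu[sig[m]]
  structure(
    list(t = tg, significant = sig, difference = diffg, df = df,
         alpha = alpha, n_excluded = sum(zero_var)),
    class = "paired_map_comparison"
  )
}
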