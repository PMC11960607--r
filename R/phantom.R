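#' Phantom specification
#'
#' Describes a single synthetic scan: the designed mean intensity of each
#' cortical region-side as a multiple of the cerebellar mean, plus noise
#' and smoothing. Before noise and smoothing, every voxel of region `r`
#' equals `multipliers[[r]] * cerebellar_mean`, cerebellar voxels equal
#' `cerebellar_mean`, and background voxels 0.5x the cerebellar mean (so
#' the 1.65x threshold never fires on background). The volume is then
#' Gaussian-smoothed at the stated FWHM and i.i.d. Gaussian noise of
#' standard deviation `noise_sd` (in cerebellar-mean units) is added.
#'
#' @param multipliers named list/vector of nonnegative multipliers for the
#'   12 region-sides of [cortical_region_sides()]; missing entries default
#'   to 1.0.
#' @param cerebellar_mean positive reference mean (default 1.0).
#' @param noise_sd nonnegative additive Gaussian noise sd (default 0.05).
#' @param smoothing_fwhm_mm nonnegative Gaussian FWHM in mm (default 4).
#' @param seed integer RNG seed.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(multipliers = list(), cerebellar_mean = 1,
                         noise_sd = 0.05, smoothing_fwhm_mm = 4,
                         seed = 1L) {
  multipliers <- as.list(multipliers)
  unknown <- setdiff(names(multipliers), cortical_region_sides())
  if (length(unknown) > 0L)
    stop("unknown region name(s) in multipliers: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  full <- stats::setNames(rep(1.0, 12L), cortical_region_sides())
  full[names(multipliers)] <- as.numeric(multipliers)
  if (any(full < 0) || any(!is.finite(full)))
    stop("multipliers must be finite and nonnegative", call. = FALSE)
  stopifnot(cerebellar_mean > 0, noise_sd >= 0, smoothing_fwhm_mm >= 0)
  structure(list(multipliers = full,
                 cerebellar_mean = cerebellar_mean,
                 noise_sd = noise_sd,
                 smoothing_fwhm_mm = smoothing_fwhm_mm,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Cohort specification
#'
#' Describes a synthetic study-like scan mix: `n_high_tau` AD-pattern scans
#' designed as high tau (frontal multipliers drawn above the 2.80x
#' threshold), `n_non_high_ad` AD-pattern scans that are not high tau
#' (frontal multipliers strictly inside (1.0, 2.80)), and `n_negative`
#' scans with no AD-pattern posterior elevation. A fraction
#' `fraction_tau_ad_plus` of AD-pattern scans carries the moderate
#' (tau_ad_plus) pattern; because a high-tau design forces an advanced
#' pattern, those moderate scans are drawn from the non-high pool. The
#' defaults mirror the validation study mix of 70 high-tau, 70 non-high,
#' 20 negative scans with ~5% moderate patterns.
#'
#' @param n_high_tau,n_non_high_ad,n_negative nonnegative scan counts.
#' @param fraction_tau_ad_plus proportion of AD-pattern scans designed as
#'   moderate pattern (default 0.05).
#' @param noise_sd,smoothing_fwhm_mm,seed as in [phantom_spec()].
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_high_tau = 70L, n_non_high_ad = 70L,
                        n_negative = 20L, fraction_tau_ad_plus = 0.05,
                        noise_sd = 0.05, smoothing_fwhm_mm = 4,
                        seed = 1L) {
  stopifnot(n_high_tau >= 0, n_non_high_ad >= 0, n_negative >= 0,
            fraction_tau_ad_plus >= 0, fraction_tau_ad_plus <= 1,
            noise_sd >= 0, smoothing_fwhm_mm >= 0)
  structure(list(n_high_tau = as.integer(n_high_tau),
                 n_non_high_ad = as.integer(n_non_high_ad),
                 n_negative = as.integer(n_negative),
                 fraction_tau_ad_plus = fraction_tau_ad_plus,
                 noise_sd = noise_sd,
                 smoothing_fwhm_mm = smoothing_fwhm_mm,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# Fractional box bounds (inclusive, 1-based) along one dimension.
.frac_range <- function(n, lo, hi) {
  (round(lo * (n - 1)) + 1L):(round(hi * (n - 1)) + 1L)
}

#' Build a deterministic synthetic atlas
#'
#' Produces a geometric parcellation hosting the cerebellar reference
#' region (an inferior central block) and the 12 cortical region-sides as
#' disjoint boxes whose left/right members mirror across the mid-sagittal
#' plane (first array axis). Axes are interpreted as x = left-right,
#' y = posterior-anterior, z = inferior-superior. Every region occupies at
#' least 50 voxels, or construction fails.
#'
#' @param shape integer triple, each dimension >= 16.
#' @param voxel_size_mm positive real triple (default 2 mm isotropic).
#' @return A [region_atlas()].
#' @export
#' @examples
#' atlas <- build_synthetic_atlas(c(48, 48, 48), c(2, 2, 2))
#' table(atlas$labels)[1:3]
build_synthetic_atlas <- function(shape = c(48L, 48L, 48L),
                                  voxel_size_mm = c(2, 2, 2)) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 16L))
    stop("shape too small to host 14 disjoint regions: each dimension ",
         "must be >= 16", call. = FALSE)
  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
  labs <- array(0L, dim = shape)
  tab <- default_label_table()

  # left-hemisphere x band; right side mirrors across the mid-sagittal plane
  xl <- .frac_range(nx, 0.08, 0.44)
  xr <- rev(nx + 1L - xl)
  # per-region (y, z) fractional bands; y runs posterior -> anterior
  bands <- list(
    frontal                    = list(y = c(0.62, 0.90), z = c(0.58, 0.80)),
    parietal                   = list(y = c(0.36, 0.56), z = c(0.58, 0.80)),
    precuneus                  = list(y = c(0.14, 0.30), z = c(0.58, 0.80)),
    lateral_anterior_temporal  = list(y = c(0.52, 0.70), z = c(0.28, 0.44)),
    lateral_posterior_temporal = list(y = c(0.28, 0.46), z = c(0.28, 0.44)),
    occipital                  = list(y = c(0.04, 0.22), z = c(0.32, 0.50)))
  for (base in names(bands)) {
    ys <- .frac_range(ny, bands[[base]]$y[1], bands[[base]]$y[2])
    zs <- .frac_range(nz, bands[[base]]$z[1], bands[[base]]$z[2])
    labs[xl, ys, zs] <- tab[[paste0(base, "_L")]]
    labs[xr, ys, zs] <- tab[[paste0(base, "_R")]]
  }
  # cerebellum: inferior central block, symmetric about the midline
  cx_lo <- round(0.34 * (nx - 1)) + 1L
  cx <- cx_lo:(nx + 1L - cx_lo)
  cy <- .frac_range(ny, 0.32, 0.62)
  cz <- .frac_range(nz, 0.04, 0.20)
  if (any(labs[cx, cy, cz] != 0L))
    stop("internal error: cerebellum block overlaps a cortical region")
  labs[cx, cy, cz] <- tab[["cerebellum"]]

  counts <- table(factor(labs[labs != 0L],
                         levels = tab[setdiff(names(tab), "background")]))
  if (any(counts < 50L))
    stop("shape too small to host 14 disjoint regions: smallest region has ",
         min(counts), " voxels (< 50)", call. = FALSE)
  region_atlas(labs, label_table = tab, voxel_size_mm = voxel_size_mm)
}

# Separable Gaussian smoothing with edge replication. sigma in voxels per
# axis; kernels truncated at 3 sigma and renormalized.
.gaussian_smooth <- function(values, fwhm_mm, voxel_size_mm) {
  if (fwhm_mm <= 0) return(values)
  sigma_vox <- (fwhm_mm / (2 * sqrt(2 * log(2)))) / voxel_size_mm
  d <- dim(values)
  out <- values
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    r <- ceiling(3 * s)
    if (r < 1L) next
    k <- stats::dnorm(-r:r, sd = s)
    k <- k / sum(k)
    acc <- array(0, d)
    n <- d[ax]
    for (j in seq_along(k)) {
      off <- j - r - 1L
      idx <- pmin(pmax(seq_len(n) + off, 1L), n)  # replicate edges
      shifted <- switch(ax,
                        out[idx, , , drop = FALSE],
                        out[, idx, , drop = FALSE],
                        out[, , idx, drop = FALSE])
      acc <- acc + k[j] * shifted
    }
    out <- acc
  }
  out
}

# Phantom voxel values using the *current* RNG state (callers seed).
.phantom_values <- function(atlas, multipliers, cerebellar_mean, noise_sd,
                            smoothing_fwhm_mm) {
  tab <- atlas$label_table
  vals <- array(0.5 * cerebellar_mean, dim = atlas$shape)
  vals[atlas$labels == tab[["cerebellum"]]] <- cerebellar_mean
  for (r in cortical_region_sides())
    vals[atlas$labels == tab[[r]]] <- multipliers[[r]] * cerebellar_mean
  vals <- .gaussian_smooth(vals, smoothing_fwhm_mm, atlas$voxel_size_mm)
  if (noise_sd > 0)
    vals <- vals + array(stats::rnorm(length(vals), sd = noise_sd),
                         dim = dim(vals))
  vals
}

#' Generate a single synthetic phantom scan
#'
#' Realizes a [phantom_spec()] on an atlas grid: piecewise-constant
#' designed uptake, optional Gaussian smoothing, then seeded additive
#' Gaussian noise. Identical spec and seed yield identical volumes.
#'
#' @param atlas a [region_atlas()].
#' @param spec a [phantom_spec()].
#' @return A [voxel_grid()] sharing the atlas grid.
#' @export
generate_phantom <- function(atlas, spec) {
  stopifnot(inherits(atlas, "region_atlas"), inherits(spec, "phantom_spec"))
  vals <- withr::with_seed(spec$seed,
    .phantom_values(atlas, spec$multipliers, spec$cerebellar_mean,
                    spec$noise_sd, spec$smoothing_fwhm_mm))
  voxel_grid(vals, voxel_size_mm = atlas$voxel_size_mm,
             affine = atlas$affine)
}

# Designed multiplier draw ranges. High-tau frontal draws sit well above
# the 2.80 threshold and non-high frontal draws well below it so that the
# designed truth stays unambiguous after smoothing.
.cohort_draw <- function(kind) {
  u <- function(lo, hi) stats::runif(1, lo, hi)
  m <- stats::setNames(rep(1.0, 12L), cortical_region_sides())
  post_ad <- c("lateral_posterior_temporal", "occipital", "parietal",
               "precuneus")
  sides <- function(base) paste0(base, c("_L", "_R"))
  if (kind == "high") {
    for (b in post_ad) for (s in sides(b)) m[[s]] <- u(1.8, 3.0)
    for (s in sides("lateral_anterior_temporal")) m[[s]] <- u(1.2, 2.6)
    for (s in sides("frontal")) m[[s]] <- u(2.9, 3.6)
  } else if (kind == "nonhigh_pp") {
    for (b in post_ad) for (s in sides(b)) m[[s]] <- u(1.8, 3.0)
    for (s in sides("lateral_anterior_temporal")) m[[s]] <- u(1.2, 2.6)
    for (s in sides("frontal")) m[[s]] <- u(1.1, 2.6)
  } else if (kind == "nonhigh_plus") {
    # moderate pattern: posterior-lateral temporal/occipital elevated only
    for (b in c("lateral_posterior_temporal", "occipital"))
      for (s in sides(b)) m[[s]] <- u(1.8, 3.0)
    for (b in c("parietal", "precuneus"))
      for (s in sides(b)) m[[s]] <- u(0.9, 1.3)
    for (s in sides("lateral_anterior_temporal")) m[[s]] <- u(0.9, 1.3)
    for (s in sides("frontal")) m[[s]] <- u(1.1, 1.5)
  } else {  # negative
    for (s in cortical_region_sides()) m[[s]] <- u(0.9, 1.3)
  }
  m
}

#' Generate a study-like synthetic cohort
#'
#' Draws per-scan regional multipliers from documented ranges, realizes
#' each scan as a phantom, and records the designed ground truth (tier and
#' high-tau flag). All randomness flows from the single seed in the
#' [cohort_spec()].
#'
#' @param atlas a [region_atlas()].
#' @param spec a [cohort_spec()].
#' @return A list of class `phantom_cohort` with elements `scans` (list of
#'   [voxel_grid()]), `truth` (data.frame with `scan_id`, `tier`,
#'   `high_tau`), and `multipliers` (matrix of the designed draws).
#' @export
generate_cohort <- function(atlas, spec) {
  stopifnot(inherits(atlas, "region_atlas"), inherits(spec, "cohort_spec"))
  n_ad <- spec$n_high_tau + spec$n_non_high_ad
  n_plus <- min(round(spec$fraction_tau_ad_plus * n_ad), spec$n_non_high_ad)
  kinds <- c(rep("high", spec$n_high_tau),
             rep("nonhigh_pp", spec$n_non_high_ad - n_plus),
             rep("nonhigh_plus", n_plus),
             rep("negative", spec$n_negative))
  tiers <- c(high = "tau_ad_plusplus", nonhigh_pp = "tau_ad_plusplus",
             nonhigh_plus = "tau_ad_plus", negative = "tau_ad_negative")
  n <- length(kinds)
  out <- withr::with_seed(spec$seed, {
    scans <- vector("list", n)
    mults <- matrix(NA_real_, n, 12L,
                    dimnames = list(NULL, cortical_region_sides()))
    for (i in seq_len(n)) {
      m <- .cohort_draw(kinds[i])
      mults[i, ] <- m
      vals <- .phantom_values(atlas, as.list(m), 1.0, spec$noise_sd,
                              spec$smoothing_fwhm_mm)
      scans[[i]] <- voxel_grid(vals, voxel_size_mm = atlas$voxel_size_mm,
                               affine = atlas$affine)
    }
    list(scans = scans, mults = mults)
  })
  truth <- data.frame(
    scan_id = sprintf("scan_%03d", seq_len(n)),
    tier = unname(tiers[kinds]),
    high_tau = kinds == "high",
    stringsAsFactors = FALSE)
  structure(list(scans = out$scans, truth = truth,
                 multipliers = out$mults, spec = spec),
            class = "phantom_cohort")
}

#' @export
print.phantom_cohort <- function(x, ...) {
  cat(sprintf("<phantom_cohort> %d scans (%d high-tau, %d AD non-high, %d negative)\n",
              nrow(x$truth), sum(x$truth$high_tau),
              sum(!x$truth$high_tau & x$truth$tier != "tau_ad_negative"),
              sum(x$truth$tier == "tau_ad_negative")))
  invisible(x)
}
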