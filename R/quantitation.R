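#' Quantitation configuration
#'
#' Configures the simplified AD-signature weighted SUVr: a voxel weight
#' map over the neocortical target (normalized to sum 1), a reference
#' region whose arithmetic mean forms the denominator, and the two
#' decision cuts -- trial eligibility at SUVr >= 1.10 and high tau at
#' SUVr > 1.46 (both strict as printed: "less than 1.10" is excluded,
#' "more than 1.46" is high tau).
#'
#' The reference statistic is deliberately the plain arithmetic mean of
#' the named region: the histogram-mode white-matter reference estimation
#' used with the published AD-signature target is a separate algorithm and
#' is not part of this package; results record the simplification. The
#' default weight map is likewise a labeled stand-in: posterior cortical
#' region-sides carry weight 2 and frontal sides weight 1 (renormalized),
#' honoring the published target's heavier posterior weighting without its
#' unpublished voxel weights. Supply `target_weights` to replace it.
#'
#' @param target_weights optional 3-D nonnegative array of voxel weights
#'   on the scan grid; renormalized to sum 1.
#' @param reference_region region name for the denominator (default
#'   `"cerebellum"`).
#' @param eligibility_cut eligibility SUVr cut (default 1.10).
#' @param high_tau_cut high-tau SUVr cut (default 1.46).
#' @return An object of class `quant_config`.
#' @export
quant_config <- function(target_weights = NULL,
                         reference_region = "cerebellum",
                         eligibility_cut = 1.10, high_tau_cut = 1.46) {
  stopifnot(eligibility_cut < high_tau_cut)
  if (!is.null(target_weights)) {
    if (!is.array(target_weights) || length(dim(target_weights)) != 3L)
      stop("target_weights must be a 3-D array", call. = FALSE)
    if (any(!is.finite(target_weights)) || any(target_weights < 0))
      stop("target_weights must be finite and nonnegative", call. = FALSE)
    s <- sum(target_weights)
    if (s <= 0)
      stop("target_weights sum to zero", call. = FALSE)
    target_weights <- target_weights / s
  }
  structure(list(target_weights = target_weights,
                 reference_region = reference_region,
                 eligibility_cut = eligibility_cut,
                 high_tau_cut = high_tau_cut),
            class = "quant_config")
}

#' Default AD-signature stand-in weight map
#'
#' Posterior cortical region-sides (both temporals, occipital, parietal,
#' precuneus) weight 2, frontal sides weight 1, zero elsewhere,
#' renormalized to sum 1 over the nonzero support.
#'
#' @param atlas a [region_atlas()].
#' @return 3-D numeric array of voxel weights summing to 1.
#' @export
default_weight_map <- function(atlas) {
  stopifnot(inherits(atlas, "region_atlas"))
  w <- array(0, dim = atlas$shape)
  tab <- atlas$label_table
  for (r in cortical_region_sides()) {
    wt <- if (grepl("^frontal", r)) 1 else 2
    w[atlas$labels == tab[[r]]] <- wt
  }
  s <- sum(w)
  if (s <= 0) stop("atlas has no cortical voxels", call. = FALSE)
  w / s
}

#' Compute the simplified weighted SUVr
#'
#' `suvr = sum(weights * intensity) / mean(reference-region intensity)`.
#' Scale-invariant under global intensity scaling; increasing any weighted
#' cortical voxel weakly increases the SUVr, increasing reference voxels
#' weakly decreases it.
#'
#' @param grid a [voxel_grid()].
#' @param atlas a [region_atlas()] on the same grid.
#' @param config a [quant_config()].
#' @param tier optional tier label; a `"tau_ad_plusplus"` tier makes a
#'   below-cut scan eligible (the advanced-pattern eligibility exception).
#'   The override never affects high-tau status.
#' @return An object of class `suvr_result` with fields `suvr`,
#'   `eligible`, `high_tau_quant`, `reference_mean`, and metadata on the
#'   simplifications in force.
#' @export
compute_suvr <- function(grid, atlas, config = quant_config(),
                         tier = NULL) {
  stopifnot(inherits(config, "quant_config"))
  validate_grid_match(grid, atlas)
  w <- config$target_weights
  weight_source <- "user"
  if (is.null(w)) {
    w <- default_weight_map(atlas)
    weight_source <- "default_posterior2_frontal1"
  } else if (!identical(as.integer(dim(w)), as.integer(atlas$shape))) {
    stop("weight grid shape does not match the scan grid", call. = FALSE)
  }
  ref_name <- config$reference_region
  if (!ref_name %in% names(atlas$label_table))
    stop("unknown reference region: ", ref_name, call. = FALSE)
  ref_mask <- atlas$labels == atlas$label_table[[ref_name]]
  if (!any(ref_mask))
    stop("reference region is empty: ", ref_name, call. = FALSE)
  ref_mean <- mean(grid$values[ref_mask])
  if (!is.finite(ref_mean) || abs(ref_mean) < .Machine$double.eps * 100 ||
      ref_mean <= 0)
    stop("nonpositive or zero reference mean (", format(ref_mean), ")",
         call. = FALSE)
  suvr <- sum(w * grid$values) / ref_mean
  cls <- classify_quant(suvr, tier = tier, config = config)
  structure(list(suvr = suvr,
                 eligible = cls$eligible,
                 high_tau_quant = cls$high_tau_quant,
                 reference_mean = ref_mean,
                 reference_statistic = "arithmetic_mean",
                 weight_map = weight_source),
            class = "suvr_result")
}

#' @export
print.suvr_result <- function(x, ...) {
  cat(sprintf("<suvr_result> suvr=%.4f eligible=%s high_tau_quant=%s (ref mean %.4g)\n",
              x$suvr, x$eligible, x$high_tau_quant, x$reference_mean))
  invisible(x)
}

#' Quantitation-based eligibility and high-tau classification
#'
#' `high_tau_quant` is `suvr > high_tau_cut` (strict). `eligible` is
#' `suvr >= eligibility_cut`, or unconditionally `TRUE` for an advanced
#' (`tau_ad_plusplus`) pattern -- the tier override applies only to
#' eligibility, never to high-tau status.
#'
#' @param suvr positive SUVr value.
#' @param tier optional tier label (`NULL` means no override).
#' @param config a [quant_config()].
#' @return List with logical elements `eligible` and `high_tau_quant`.
#' @export
classify_quant <- function(suvr, tier = NULL, config = quant_config()) {
  stopifnot(is.numeric(suvr), length(suvr) == 1L, suvr > 0)
  override <- !is.null(tier) && identical(tier, "tau_ad_plusplus")
  list(eligible = suvr >= config$eligibility_cut || override,
       high_tau_quant = suvr > config$high_tau_cut)
}
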