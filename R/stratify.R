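#' Estimate the mean cerebellar count (MCC)
#'
#' The MCC anchors every visual threshold: suprathreshold signal is defined
#' relative to multiples of it. Two estimators are provided: `mask3d`
#' (arithmetic mean over every cerebellar voxel; reproducible default) and
#' `slice2d` (mean over the cerebellar voxels of the single axial slice --
#' third array axis -- holding the most cerebellar voxels, mimicking a
#' manually drawn 2-D region of interest; ties resolve to the lowest slice
#' index).
#'
#' @param grid a [voxel_grid()].
#' @param atlas a [region_atlas()] sharing the grid.
#' @param method `"mask3d"` or `"slice2d"`.
#' @return An object of class `mcc_estimate` with fields `value`,
#'   `n_voxels`, `method`.
#' @export
estimate_mcc <- function(grid, atlas, method = c("mask3d", "slice2d")) {
  method <- match.arg(method)
  validate_grid_match(grid, atlas)
  mask <- atlas$labels == atlas$label_table[["cerebellum"]]
  if (!any(mask))
    stop("cerebellum region is empty", call. = FALSE)
  if (method == "mask3d") {
    v <- grid$values[mask]
  } else {
    per_slice <- apply(mask, 3, sum)
    z <- which.max(per_slice)  # ties -> lowest index
    v <- grid$values[, , z][mask[, , z]]
  }
  value <- mean(v)
  if (!is.finite(value) || value <= 0)
    stop("nonpositive MCC (", format(value),
         "): scan appears corrupt or mis-registered", call. = FALSE)
  structure(list(value = value, n_voxels = length(v), method = method),
            class = "mcc_estimate")
}

#' @export
print.mcc_estimate <- function(x, ...) {
  cat(sprintf("<mcc_estimate> %.6g over %d voxels (%s)\n",
              x$value, x$n_voxels, x$method))
  invisible(x)
}

#' Voxelwise suprathreshold map
#'
#' Marks voxels with intensity strictly greater than
#' `multiplier * mcc$value` -- the automated analogue of adjusting the
#' color scale so that only signal above the visual threshold lights up.
#' Both thresholds of the read (1.65x and 2.80x MCC) use strict
#' inequality.
#'
#' @param grid a [voxel_grid()].
#' @param mcc an `mcc_estimate` (or a positive scalar).
#' @param multiplier positive threshold multiplier.
#' @return A logical 3-D array.
#' @export
suprathreshold_map <- function(grid, mcc, multiplier) {
  stopifnot(multiplier > 0)
  m <- if (inherits(mcc, "mcc_estimate")) mcc$value else as.numeric(mcc)
  array(grid$values > multiplier * m, dim = grid$shape)
}

# 26-connected component labeling by iterative minimum-label propagation,
# restricted to the bounding box of the foreground. Returns an integer
# array with components numbered 1..k and 0 elsewhere.
label_components_26 <- function(mask) {
  d <- dim(mask)
  out <- array(0L, d)
  if (!any(mask)) return(out)
  ai <- which(mask, arr.ind = TRUE)
  r <- apply(ai, 2, range)
  xs <- r[1, 1]:r[2, 1]; ys <- r[1, 2]:r[2, 2]; zs <- r[1, 3]:r[2, 3]
  sub <- mask[xs, ys, zs, drop = FALSE]
  ds <- dim(sub)
  cur <- array(Inf, ds)
  cur[sub] <- which(as.vector(sub))
  # One propagation step is a 3x3x3 minimum filter (separable: a 3-window
  # minimum along each axis in turn), masked back to the foreground.
  # Labels can only enter a foreground voxel from within its 26-neighbour
  # cube, so the fixed point is the 26-connected component labeling.
  repeat {
    nxt <- cur
    for (ax in 1:3) {
      n <- ds[ax]
      if (n == 1L) next
      im <- c(1L, seq_len(n - 1L))
      ip <- c(seq_len(n - 1L) + 1L, n)
      nxt <- switch(ax,
        pmin(nxt, nxt[im, , , drop = FALSE], nxt[ip, , , drop = FALSE]),
        pmin(nxt, nxt[, im, , drop = FALSE], nxt[, ip, , drop = FALSE]),
        pmin(nxt, nxt[, , im, drop = FALSE], nxt[, , ip, drop = FALSE]))
      dim(nxt) <- ds
    }
    nxt[!sub] <- Inf
    if (all(nxt[sub] == cur[sub])) break
    cur <- nxt
  }
  ids <- cur[sub]
  relab <- match(ids, sort(unique(ids)))
  labs_sub <- array(0L, ds)
  labs_sub[sub] <- relab
  out[xs, ys, zs] <- labs_sub
  out
}

#' Score regions for suprathreshold positivity
#'
#' A region-side is scored positive when it contains at least
#' `min_cluster_voxels` voxels of a single 26-connected suprathreshold
#' component (components are formed on the whole map and then intersected
#' with the region mask). `min_cluster_voxels = 1` realizes the literal
#' "regardless of signal intensity or extent" reading; the default of 5
#' mirrors a human reader's implicit dismissal of single-voxel speckle.
#'
#' @param binary_map logical 3-D array (e.g. from [suprathreshold_map()]).
#' @param atlas a [region_atlas()].
#' @param regions character vector of region-side names to score.
#' @param min_cluster_voxels minimum intersected component size (>= 1).
#' @param scheme region-name resolution scheme, see [region_mask()].
#' @param multiplier,threshold_value optional metadata recorded on the
#'   result (filled in by [stratify_scan()]).
#' @return An object of class `regional_score_set` with fields
#'   `multiplier`, `threshold_value`, `scores` (named logical), and
#'   `max_cluster_voxels` (named integer).
#' @export
score_regions <- function(binary_map, atlas, regions,
                          min_cluster_voxels = 5L,
                          scheme = c("step1", "step2"),
                          multiplier = NA_real_,
                          threshold_value = NA_real_) {
  scheme <- match.arg(scheme)
  stopifnot(length(regions) >= 1L, min_cluster_voxels >= 1L)
  if (!identical(dim(binary_map), as.integer(atlas$shape)) &&
      !identical(as.integer(dim(binary_map)), as.integer(atlas$shape)))
    stop("binary map shape does not match atlas", call. = FALSE)
  comp <- label_components_26(binary_map)
  scores <- stats::setNames(logical(length(regions)), regions)
  maxclust <- stats::setNames(integer(length(regions)), regions)
  for (r in regions) {
    rmask <- region_mask(atlas, r, scheme = scheme)
    ids <- comp[rmask & binary_map]
    maxclust[[r]] <- if (length(ids) == 0L) 0L else max(tabulate(ids))
    scores[[r]] <- maxclust[[r]] >= min_cluster_voxels
  }
  structure(list(multiplier = multiplier,
                 threshold_value = threshold_value,
                 scores = scores,
                 max_cluster_voxels = maxclust,
                 min_cluster_voxels = as.integer(min_cluster_voxels),
                 scheme = scheme),
            class = "regional_score_set")
}

#' Decision tables for the three-tier pattern read
#'
#' A decision table is an ordered list of rules mapping step-1 regional
#' score patterns to a tier label (`tau_ad_negative`, `tau_ad_plus`,
#' `tau_ad_plusplus`). Construction verifies totality by exhaustive
#' enumeration of all 2^12 score patterns: every pattern must match at
#' least one rule (first match wins).
#'
#' The default table encodes the narrative rules of the three-tier read:
#' a scan is AD-pattern-positive iff any of lateral posterior temporal,
#' occipital, parietal, or precuneus is positive on either side; among
#' AD-pattern-positive scans, the pattern is advanced (`tau_ad_plusplus`)
#' iff any of parietal, precuneus, or frontal is positive on either side,
#' else moderate (`tau_ad_plus`). The exact supplemental rule text of the
#' original three-tier method is not reproduced here, so the table is a
#' named, swappable configuration object.
#'
#' @param rules list of `list(condition = function(scores) ..., tier =
#'   <label>)`; `scores` is a named logical vector over the 12
#'   region-sides.
#' @param name identifier recorded in config fingerprints.
#' @return An object of class `decision_table`.
#' @export
decision_table <- function(rules, name = "custom") {
  tiers <- c("tau_ad_negative", "tau_ad_plus", "tau_ad_plusplus")
  stopifnot(length(rules) >= 1L)
  for (r in rules) {
    stopifnot(is.function(r$condition), r$tier %in% tiers)
  }
  sides <- cortical_region_sides()
  pat <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), 12L)))
  colnames(pat) <- sides
  for (i in seq_len(nrow(pat))) {
    s <- pat[i, ]
    hit <- FALSE
    for (r in rules) if (isTRUE(r$condition(s))) { hit <- TRUE; break }
    if (!hit)
      stop("decision table is not total: pattern {",
           paste(sides[s], collapse = ", "), "} matches no rule",
           call. = FALSE)
  }
  structure(list(rules = rules, name = name), class = "decision_table")
}

#' @rdname decision_table
#' @export
default_decision_table <- function() {
  post <- .posterior_sides()
  adv <- .advanced_sides()
  decision_table(list(
    list(condition = function(s) !any(s[post]), tier = "tau_ad_negative"),
    list(condition = function(s) any(s[adv]),   tier = "tau_ad_plusplus"),
    list(condition = function(s) TRUE,          tier = "tau_ad_plus")),
    name = "default_3tier")
}

#' Classify the AD-pattern tier from step-1 scores
#'
#' @param step1 a `regional_score_set` covering all 12 region-sides.
#' @param table a [decision_table()].
#' @return One of `"tau_ad_negative"`, `"tau_ad_plus"`,
#'   `"tau_ad_plusplus"`.
#' @export
classify_tier <- function(step1, table = default_decision_table()) {
  stopifnot(inherits(step1, "regional_score_set"),
            inherits(table, "decision_table"))
  s <- step1$scores
  missing_sides <- setdiff(cortical_region_sides(), names(s))
  if (length(missing_sides) > 0L)
    stop("step-1 scores must cover all 12 region-sides; missing: ",
         paste(missing_sides, collapse = ", "), call. = FALSE)
  for (r in table$rules) if (isTRUE(r$condition(s))) return(r$tier)
  stop("internal error: non-total decision table")  # unreachable
}

#' Stratification configuration
#'
#' @param step1_multiplier threshold multiplier for the tier read
#'   (default 1.65).
#' @param step2_multiplier threshold multiplier for the high-tau read
#'   (default 2.80).
#' @param min_cluster_voxels minimum 26-connected cluster size for
#'   regional positivity (default 5; 1 gives the literal any-voxel rule).
#' @param mcc_method `"mask3d"` or `"slice2d"`, see [estimate_mcc()].
#' @param table a [decision_table()].
#' @param step2_scheme `"step2"` scores the coarse 4-region bilateral
#'   scheme (temporal and parietal+precuneus unions; default), `"step1"`
#'   re-uses the 12 atomic region-sides.
#' @return An object of class `stratify_config` carrying a deterministic
#'   `fingerprint` string.
#' @export
stratify_config <- function(step1_multiplier = 1.65,
                            step2_multiplier = 2.80,
                            min_cluster_voxels = 5L,
                            mcc_method = c("mask3d", "slice2d"),
                            table = default_decision_table(),
                            step2_scheme = c("step2", "step1")) {
  mcc_method <- match.arg(mcc_method)
  step2_scheme <- match.arg(step2_scheme)
  stopifnot(step1_multiplier > 0, step2_multiplier > 0,
            min_cluster_voxels >= 1L, inherits(table, "decision_table"))
  fp <- sprintf("m1=%g;m2=%g;k=%d;mcc=%s;table=%s;s2=%s",
                step1_multiplier, step2_multiplier,
                as.integer(min_cluster_voxels), mcc_method, table$name,
                step2_scheme)
  structure(list(step1_multiplier = step1_multiplier,
                 step2_multiplier = step2_multiplier,
                 min_cluster_voxels = as.integer(min_cluster_voxels),
                 mcc_method = mcc_method,
                 table = table,
                 step2_scheme = step2_scheme,
                 fingerprint = fp),
            class = "stratify_config")
}

#' Stratify a scan: two-step tier and high-tau read
#'
#' Step 1 scores all 12 region-sides at `step1_multiplier` x MCC and
#' assigns the tier via the decision table. Scans not consistent with AD
#' (`tau_ad_negative`) stop there with `high_tau = FALSE`. Otherwise step
#' 2 re-thresholds at `step2_multiplier` x MCC and scores the step-2
#' regions bilaterally; the scan is high tau iff either frontal side is
#' positive in step 2. Non-frontal step-2 scores are recorded but play no
#' role in the stratification. The visual path has no quantitation
#' dependency, so scans with failed or absent quantitation remain
#' stratifiable.
#'
#' @param grid a [voxel_grid()].
#' @param atlas a [region_atlas()] on the same grid.
#' @param config a [stratify_config()].
#' @return An object of class `stratification_result` with fields `tier`,
#'   `high_tau`, `step1`, `step2` (NULL for negative scans), `mcc`,
#'   `config_fingerprint`.
#' @export
#' @examples
#' atlas <- build_synthetic_atlas(c(24, 24, 24))
#' spec <- phantom_spec(list(frontal_L = 3.2, parietal_L = 2.2,
#'                           lateral_posterior_temporal_L = 2.2),
#'                      noise_sd = 0, smoothing_fwhm_mm = 0)
#' res <- stratify_scan(generate_phantom(atlas, spec), atlas)
#' res$tier; res$high_tau
stratify_scan <- function(grid, atlas, config = stratify_config()) {
  stopifnot(inherits(config, "stratify_config"))
  validate_grid_match(grid, atlas)
  mcc <- estimate_mcc(grid, atlas, method = config$mcc_method)

  map1 <- suprathreshold_map(grid, mcc, config$step1_multiplier)
  step1 <- score_regions(map1, atlas, cortical_region_sides(),
                         min_cluster_voxels = config$min_cluster_voxels,
                         scheme = "step1",
                         multiplier = config$step1_multiplier,
                         threshold_value = config$step1_multiplier * mcc$value)
  tier <- classify_tier(step1, config$table)

  step2 <- NULL
  high_tau <- FALSE
  if (tier != "tau_ad_negative") {
    map2 <- suprathreshold_map(grid, mcc, config$step2_multiplier)
    step2 <- score_regions(map2, atlas,
                           step2_region_sides(config$step2_scheme),
                           min_cluster_voxels = config$min_cluster_voxels,
                           scheme = config$step2_scheme,
                           multiplier = config$step2_multiplier,
                           threshold_value = config$step2_multiplier * mcc$value)
    high_tau <- isTRUE(step2$scores[["frontal_L"]]) ||
      isTRUE(step2$scores[["frontal_R"]])
  }
  structure(list(tier = tier,
                 high_tau = high_tau,
                 step1 = step1,
                 step2 = step2,
                 mcc = mcc,
                 config_fingerprint = config$fingerprint),
            class = "stratification_result")
}

#' @export
print.stratification_result <- function(x, ...) {
  cat(sprintf("<stratification_result> tier=%s high_tau=%s mcc=%.4g\n",
              x$tier, x$high_tau, x$mcc$value))
  if (!is.null(x$step2)) {
    pos <- names(x$step2$scores)[x$step2$scores]
    cat("  step-2 positive:",
        if (length(pos)) paste(pos, collapse = ", ") else "(none)", "\n")
  }
  invisible(x)
}
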