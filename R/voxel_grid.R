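#' Voxel grid container
#'
#' A `voxel_grid` is a 3-D array of finite intensities (tracer counts or
#' SUVr units, unitless) together with its voxel geometry: the voxel size in
#' millimetres and the 4x4 voxel-to-world affine. All regional logic in the
#' package operates in voxel space; the affine is carried only so that scans
#' and atlases can be checked for grid compatibility.
#'
#' @param values 3-D numeric array; all values must be finite.
#' @param voxel_size_mm positive numeric triple, voxel edge lengths in mm.
#' @param affine 4x4 voxel-to-world transform; defaults to a diagonal
#'   scaling by `voxel_size_mm` with the origin at the first voxel.
#' @return An object of class `voxel_grid` with fields `values`, `shape`,
#'   `voxel_size_mm`, `affine`.
#' @export
#' @examples
#' g <- voxel_grid(array(1, dim = c(8, 8, 8)), voxel_size_mm = c(2, 2, 2))
#' g$shape
voxel_grid <- function(values, voxel_size_mm = c(1, 1, 1), affine = NULL) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("expected 3-D volume, got ", length(dim(values)), " dimension(s)",
         call. = FALSE)
  n_bad <- sum(!is.finite(values))
  if (n_bad > 0L)
    stop("volume contains ", n_bad, " non-finite voxel(s) (NaN/Inf)",
         call. = FALSE)
  voxel_size_mm <- as.numeric(voxel_size_mm)
  if (length(voxel_size_mm) != 3L || any(!is.finite(voxel_size_mm)) ||
      any(voxel_size_mm <= 0))
    stop("voxel_size_mm must be a positive real triple", call. = FALSE)
  if (is.null(affine)) {
    affine <- diag(c(voxel_size_mm, 1))
  }
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)))
    stop("affine must be a 4x4 matrix", call. = FALSE)
  structure(list(values = values,
                 shape = dim(values),
                 voxel_size_mm = voxel_size_mm,
                 affine = unname(affine)),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %s voxels, %s mm; range [%.4g, %.4g]\n",
              paste(x$shape, collapse = "x"),
              paste(format(x$voxel_size_mm), collapse = "x"),
              min(x$values), max(x$values)))
  invisible(x)
}

#' Region atlas container
#'
#' A `region_atlas` pairs an integer label grid (same shape as the scan it
#' annotates) with a label table drawn from the fixed region vocabulary:
#' `cerebellum`, `background`, and the 12 cortical region-sides of
#' [cortical_region_sides()]. The cerebellum anchors all intensity
#' thresholds; the cortical region-sides are scored for suprathreshold
#' signal.
#'
#' @param labels 3-D integer array of region labels (0 = background).
#' @param label_table named integer vector mapping region names to label
#'   values; defaults to [default_label_table()].
#' @param voxel_size_mm,affine voxel geometry, as in [voxel_grid()].
#' @return An object of class `region_atlas`.
#' @export
region_atlas <- function(labels, label_table = default_label_table(),
                         voxel_size_mm = c(1, 1, 1), affine = NULL) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("expected 3-D label volume", call. = FALSE)
  if (any(!is.finite(labels)) || any(labels != round(labels)))
    stop("atlas labels must be finite integers", call. = FALSE)
  storage.mode(labels) <- "integer"
  if (is.null(names(label_table)) || anyNA(names(label_table)))
    stop("label_table must be a named integer vector", call. = FALSE)
  if (anyDuplicated(names(label_table)))
    stop("duplicated region name(s) in label_table: ",
         paste(unique(names(label_table)[duplicated(names(label_table))]),
               collapse = ", "), call. = FALSE)
  known <- c("background", "cerebellum", cortical_region_sides())
  unknown <- setdiff(names(label_table), known)
  if (length(unknown) > 0L)
    stop("unknown region name(s) in label_table: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  if (!"cerebellum" %in% names(label_table))
    stop("label_table must name a cerebellum label", call. = FALSE)
  present <- unique(as.vector(labels))
  allowed <- c(0L, unname(as.integer(label_table)))
  stray <- setdiff(present, allowed)
  if (length(stray) > 0L)
    stop("label grid contains values absent from label_table: ",
         paste(stray, collapse = ", "), call. = FALSE)
  if (sum(labels == label_table[["cerebellum"]]) < 1L)
    stop("cerebellum label maps to no voxels", call. = FALSE)
  voxel_size_mm <- as.numeric(voxel_size_mm)
  if (length(voxel_size_mm) != 3L || any(voxel_size_mm <= 0))
    stop("voxel_size_mm must be a positive real triple", call. = FALSE)
  if (is.null(affine)) affine <- diag(c(voxel_size_mm, 1))
  structure(list(labels = labels,
                 label_table = stats::setNames(as.integer(label_table),
                                               names(label_table)),
                 shape = dim(labels),
                 voxel_size_mm = voxel_size_mm,
                 affine = unname(as.matrix(affine))),
            class = "region_atlas")
}

#' @export
print.region_atlas <- function(x, ...) {
  cat(sprintf("<region_atlas> %s voxels, %d named labels\n",
              paste(x$shape, collapse = "x"), length(x$label_table)))
  invisible(x)
}

#' Binary mask of a named region
#'
#' Resolves a region name against an atlas. Under the `step1` scheme names
#' must be atomic label-table entries (the 12 region-sides or
#' `cerebellum`). Under the `step2` scheme, which mirrors the coarser
#' 4-region bilateral scoring of the second read step, `temporal_L/R`
#' resolves to the union of the lateral anterior and posterior temporal
#' sides and `parietal_L/R` to the union of parietal and precuneus;
#' `occipital` and `frontal` stay atomic.
#'
#' @param atlas a [region_atlas()].
#' @param region region or region-side name.
#' @param scheme `"step1"` (atomic names) or `"step2"` (coarse unions).
#' @return logical 3-D array.
#' @export
region_mask <- function(atlas, region, scheme = c("step1", "step2")) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(atlas, "region_atlas"))
  tab <- atlas$label_table
  atomic_of <- function(nm) {
    if (!nm %in% names(tab))
      stop("unknown region name: ", nm, call. = FALSE)
    tab[[nm]]
  }
  ids <- if (scheme == "step2" && grepl("^(temporal|parietal)_(L|R)$", region)) {
    side <- sub("^.*_", "", region)
    base <- sub("_(L|R)$", "", region)
    parts <- if (base == "temporal") {
      paste0(c("lateral_anterior_temporal", "lateral_posterior_temporal"),
             "_", side)
    } else {
      paste0(c("parietal", "precuneus"), "_", side)
    }
    vapply(parts, atomic_of, integer(1))
  } else {
    atomic_of(region)
  }
  array(atlas$labels %in% ids, dim = atlas$shape)
}

# Step-2 region-side names under each granularity scheme.
step2_region_sides <- function(scheme = c("step2", "step1")) {
  scheme <- match.arg(scheme)
  if (scheme == "step1") return(cortical_region_sides())
  as.vector(t(outer(c("temporal", "occipital", "parietal", "frontal"),
                    c("_L", "_R"), paste0)))
}
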