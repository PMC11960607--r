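#' Read a 3-D volume from NIfTI-1
#'
#' Loads a NIfTI-1 file into a [voxel_grid()]. The format's stored
#' slope/intercept scaling is applied on read (by RNifti); no other
#' normalization is performed -- the stratification method is
#' scale-invariant by construction, so absolute units never matter
#' downstream. Orientation is taken from the affine; there is no implicit
#' reorientation, and a scan and its atlas are required to share a grid
#' (see [validate_grid_match()]).
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return A [voxel_grid()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  im <- RNifti::readNifti(path)
  d <- dim(im)
  if (length(d) != 3L)
    stop("expected 3-D volume, got ", length(d), "-D image: ", path,
         call. = FALSE)
  vals <- as.array(im)
  attributes(vals) <- list(dim = d)
  n_bad <- sum(!is.finite(vals))
  if (n_bad > 0L)
    stop("volume contains ", n_bad, " non-finite voxel(s) (NaN/Inf): ",
         path, call. = FALSE)
  voxel_grid(vals,
             voxel_size_mm = abs(RNifti::pixdim(im))[1:3],
             affine = unclass(RNifti::xform(im))[1:4, 1:4])
}

#' Write a 3-D volume to NIfTI-1
#'
#' Writes a [voxel_grid()] so that [read_volume()] round-trips it
#' value-identically. Double-precision data are stored as float64 and
#' integer data as int32, so round-trips are exact in both cases.
#'
#' @param grid a [voxel_grid()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return Invisibly, `path`.
#' @export
write_volume <- function(grid, path) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (!dir.exists(dirname(path)) || file.access(dirname(path), 2L) != 0L)
    stop("cannot write to directory: ", dirname(path), call. = FALSE)
  .write_nifti(grid$values, grid$voxel_size_mm, grid$affine, path,
               datatype = if (is.integer(grid$values)) "int32" else "double")
  invisible(path)
}

.write_nifti <- function(values, voxel_size_mm, affine, path, datatype) {
  im <- RNifti::asNifti(values)
  RNifti::pixdim(im) <- voxel_size_mm
  im <- RNifti::`sform<-`(im, structure(affine, code = 2L))
  im <- RNifti::`qform<-`(im, structure(affine, code = 2L))
  RNifti::writeNifti(im, path, datatype = datatype)
}

#' Read/write a region atlas as NIfTI-1
#'
#' The label grid is stored as an integer NIfTI volume; the label table is
#' not embedded in the image and defaults to the package's canonical
#' coding ([default_label_table()]). Integer labels round-trip bit-exactly.
#'
#' @param path path to the label image.
#' @param label_table named integer vector mapping region names to labels.
#' @return `read_atlas()` returns a [region_atlas()].
#' @export
read_atlas <- function(path, label_table = default_label_table()) {
  g <- read_volume(path)
  labs <- g$values
  if (any(labs != round(labs)))
    stop("atlas volume contains non-integer labels: ", path, call. = FALSE)
  storage.mode(labs) <- "integer"
  region_atlas(labs, label_table = label_table,
               voxel_size_mm = g$voxel_size_mm, affine = g$affine)
}

#' @rdname read_atlas
#' @param atlas a [region_atlas()].
#' @export
write_atlas <- function(atlas, path) {
  stopifnot(inherits(atlas, "region_atlas"))
  if (!dir.exists(dirname(path)) || file.access(dirname(path), 2L) != 0L)
    stop("cannot write to directory: ", dirname(path), call. = FALSE)
  .write_nifti(atlas$labels, atlas$voxel_size_mm, atlas$affine, path,
               datatype = "int32")
  invisible(path)
}

#' Check that a scan and an atlas share a voxel grid
#'
#' The stratification method operates on a single co-registered scan;
#' resampling is out of scope, so shape and affine must agree (affine to
#' an absolute tolerance of 1e-4).
#'
#' @param grid a [voxel_grid()].
#' @param atlas a [region_atlas()] (or another `voxel_grid`).
#' @param tol absolute affine tolerance.
#' @return Invisibly `TRUE`; raises an error describing the differing
#'   components otherwise.
#' @export
validate_grid_match <- function(grid, atlas, tol = 1e-4) {
  s1 <- grid$shape
  s2 <- atlas$shape
  if (!identical(as.integer(s1), as.integer(s2)))
    stop(sprintf("shape mismatch: scan %s vs atlas %s",
                 paste(s1, collapse = "x"), paste(s2, collapse = "x")),
         call. = FALSE)
  da <- abs(grid$affine - atlas$affine)
  if (any(da > tol)) {
    ij <- which(da > tol, arr.ind = TRUE)[1, ]
    stop(sprintf(paste0("affine mismatch at [%d,%d]: %.6g vs %.6g ",
                        "(|diff| %.3g > tol %.3g)"),
                 ij[1], ij[2], grid$affine[ij[1], ij[2]],
                 atlas$affine[ij[1], ij[2]], da[ij[1], ij[2]], tol),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Read and write reader-call tables
#'
#' The reads CSV schema has columns `scan_id`, `reader_id`,
#' `call` (one of `high_tau`, `non_high_tau`) and an optional `truth`
#' column with the same vocabulary (the quantitation-based label). Scans
#' without a truth value (e.g. quantitation failures) are kept in the
#' matrix with `NA` truth; agreement endpoints exclude them while kappa
#' statistics retain them.
#'
#' @param path CSV file path.
#' @return `read_reads_csv()` returns a [read_matrix()].
#' @export
read_reads_csv <- function(path) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("scan_id", "reader_id", "call")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L)
    stop("reads CSV missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  lev <- c("high_tau", "non_high_tau")
  if (!all(df$call %in% lev))
    stop("call values must be one of: ", paste(lev, collapse = ", "),
         call. = FALSE)
  scan_ids <- unique(df$scan_id)
  reader_ids <- unique(df$reader_id)
  calls <- matrix(NA, length(scan_ids), length(reader_ids),
                  dimnames = list(scan_ids, reader_ids))
  calls[cbind(match(df$scan_id, scan_ids),
              match(df$reader_id, reader_ids))] <- df$call == "high_tau"
  truth <- NULL
  if ("truth" %in% names(df)) {
    tvals <- df$truth
    ok <- is.na(tvals) | tvals %in% c(lev, "")
    if (!all(ok))
      stop("truth values must be one of: ", paste(lev, collapse = ", "),
           call. = FALSE)
    truth <- rep(NA, length(scan_ids))
    has <- !is.na(tvals) & tvals != ""
    truth[match(df$scan_id[has], scan_ids)] <- tvals[has] == "high_tau"
  }
  read_matrix(calls, scan_ids = scan_ids, reader_ids = reader_ids,
              truth = truth)
}

#' @rdname read_reads_csv
#' @param matrix a [read_matrix()].
#' @export
write_reads_csv <- function(matrix, path) {
  stopifnot(inherits(matrix, "read_matrix"))
  lev <- function(x) ifelse(x, "high_tau", "non_high_tau")
  n_s <- length(matrix$scan_ids)
  n_r <- length(matrix$reader_ids)
  df <- data.frame(
    scan_id = rep(matrix$scan_ids, times = n_r),
    reader_id = rep(matrix$reader_ids, each = n_s),
    call = lev(as.vector(matrix$calls)),
    stringsAsFactors = FALSE)
  if (!is.null(matrix$truth)) {
    tr <- rep(ifelse(is.na(matrix$truth), "", lev(matrix$truth)),
              times = n_r)
    df$truth <- tr
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
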