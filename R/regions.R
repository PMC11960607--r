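#' Region vocabulary
#'
#' The stratification method examines six cortical regions bilaterally
#' (lateral anterior temporal, lateral posterior temporal, occipital,
#' parietal, precuneus, frontal) against a cerebellar reference region.
#' These helpers return the canonical region names used throughout the
#' package.
#'
#' @return `cortical_regions()` returns the 6 base region names;
#'   `cortical_region_sides()` the 12 left/right region-side names
#'   (suffixes `_L`, `_R`); `default_label_table()` a named integer vector
#'   mapping region names (plus `background` and `cerebellum`) to the
#'   canonical atlas label coding.
#' @export
#' @examples
#' cortical_region_sides()
cortical_regions <- function() {
  c("lateral_anterior_temporal", "lateral_posterior_temporal",
    "occipital", "parietal", "precuneus", "frontal")
}

#' @rdname cortical_regions
#' @export
cortical_region_sides <- function() {
  as.vector(t(outer(cortical_regions(), c("_L", "_R"), paste0)))
}

#' @rdname cortical_regions
#' @export
default_label_table <- function() {
  nm <- c("background", "cerebellum", cortical_region_sides())
  stats::setNames(seq_along(nm) - 1L, nm)
}

# Region-side groups used by the default decision rules.
.posterior_sides <- function() {
  as.vector(outer(c("lateral_posterior_temporal", "occipital",
                    "parietal", "precuneus"), c("_L", "_R"), paste0))
}

.advanced_sides <- function() {
  as.vector(outer(c("parietal", "precuneus", "frontal"),
                  c("_L", "_R"), paste0))
}
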