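Package: tauvisread
Title: Automated Visual Stratification of Tau PET Scans with Reader-Agreement Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements an automated, deterministic analogue of the
    flortaucipir tau PET visual stratification read: mean cerebellar count
    (MCC) estimation from a co-registered label atlas, voxelwise
    thresholding at configurable multiples of the MCC (1.65x and 2.80x by
    default), connected-component regional positivity scoring, and a
    two-step decision algorithm yielding a three-tier AD-pattern label and
    a high-tau/non-high-tau stratum. Includes a simplified AD-signature
    weighted SUVr quantitation, a synthetic 3-D phantom and cohort
    generator with known ground truth, and the reader-study agreement
    statistics used to validate the method: positive/negative percent
    agreement with Wilson score confidence intervals, Fleiss and Cohen
    kappa, majority reads, and protocol success criteria.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
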