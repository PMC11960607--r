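#' Serialize results to plain lists for JSON output
#'
#' `as_report_list()` turns package result objects into nested lists of
#' bare scalars suitable for `jsonlite::write_json(..., auto_unbox =
#' TRUE, digits = NA)`. Percentages are kept at full precision; rounded
#' display (1 decimal for percentages, 4 for kappa) is a print-time
#' concern only.
#'
#' @param x a `stratification_result`, `suvr_result`, `kappa_estimate`,
#'   `proportion_estimate`, or `agreement_report`.
#' @return A plain nested list.
#' @export
as_report_list <- function(x) UseMethod("as_report_list")

#' @export
as_report_list.proportion_estimate <- function(x) {
  list(numerator = x$numerator, denominator = x$denominator,
       point_pct = x$point_pct, ci_low_pct = x$ci_low_pct,
       ci_high_pct = x$ci_high_pct, level = x$level)
}

#' @export
as_report_list.kappa_estimate <- function(x) {
  list(statistic = x$statistic, se = x$se, ci_low = x$ci_low,
       ci_high = x$ci_high, method = x$method, level = x$level)
}

#' @export
as_report_list.regional_score_set <- function(x) {
  list(multiplier = x$multiplier, threshold_value = x$threshold_value,
       min_cluster_voxels = x$min_cluster_voxels, scheme = x$scheme,
       scores = as.list(x$scores),
       max_cluster_voxels = as.list(x$max_cluster_voxels))
}

#' @export
as_report_list.stratification_result <- function(x) {
  list(tier = x$tier, high_tau = x$high_tau,
       mcc = list(value = x$mcc$value, n_voxels = x$mcc$n_voxels,
                  method = x$mcc$method),
       step1 = as_report_list(x$step1),
       step2 = if (is.null(x$step2)) NULL else as_report_list(x$step2),
       config_fingerprint = x$config_fingerprint)
}

#' @export
as_report_list.suvr_result <- function(x) {
  list(suvr = x$suvr, eligible = x$eligible,
       high_tau_quant = x$high_tau_quant,
       reference_mean = x$reference_mean,
       reference_statistic = x$reference_statistic,
       weight_map = x$weight_map)
}

#' @export
as_report_list.agreement_report <- function(x) {
  list(per_reader = lapply(x$per_reader, function(pr)
         list(reader = pr$reader,
              tp = pr$counts$tp, fp = pr$counts$fp,
              tn = pr$counts$tn, fn = pr$counts$fn,
              ppa = as_report_list(pr$ppa),
              npa = as_report_list(pr$npa),
              overall = as_report_list(pr$overall))),
       pooled = list(tp = x$pooled_counts$tp, fp = x$pooled_counts$fp,
                     tn = x$pooled_counts$tn, fn = x$pooled_counts$fn,
                     ppa = as_report_list(x$pooled$ppa),
                     npa = as_report_list(x$pooled$npa),
                     overall = as_report_list(x$pooled$overall)),
       medians = x$medians,
       fleiss = as_report_list(x$fleiss),
       success_ppa_npa = x$success_ppa_npa,
       success_fleiss = x$success_fleiss,
       level = x$level)
}

#' Run an end-to-end synthetic reader study
#'
#' Realizes the study schema on synthetic data: build an atlas, generate
#' a cohort with designed ground truth, stratify every scan with the
#' automated classifier, compute the simplified SUVr per scan, assemble a
#' read matrix (either `n_readers` copies of the classifier's own calls
#' -- the deterministic reader -- or a simulated panel with the given
#' operating point), and assemble the agreement report against the
#' designed truth. Every artifact carries the configuration fingerprint
#' and seed.
#'
#' @param cohort a [cohort_spec()].
#' @param shape,voxel_size_mm atlas geometry (defaults 48^3 at 2 mm).
#' @param config a [stratify_config()].
#' @param reader_mode `"classifier"` (deterministic) or `"simulated"`.
#' @param n_readers panel size.
#' @param sensitivity,specificity simulated-reader operating point.
#' @param out_dir optional directory; when given, writes
#'   `truth.csv`, `reads.csv`, `stratifications.json`, `report.json`.
#' @return A list of class `study_sim` with `truth`, `results`
#'   (stratifications), `suvr`, `reads` ([read_matrix()]), `report`
#'   ([agreement_report()]), `accuracy` (fraction of scans whose tier and
#'   high-tau flag match the designed truth), `fingerprint`, `seed`.
#' @export
run_study_sim <- function(cohort = cohort_spec(),
                          shape = c(48L, 48L, 48L),
                          voxel_size_mm = c(2, 2, 2),
                          config = stratify_config(),
                          reader_mode = c("classifier", "simulated"),
                          n_readers = 5L,
                          sensitivity = 0.85, specificity = 0.9,
                          out_dir = NULL) {
  reader_mode <- match.arg(reader_mode)
  atlas <- build_synthetic_atlas(shape, voxel_size_mm)
  coh <- generate_cohort(atlas, cohort)
  results <- lapply(coh$scans, stratify_scan, atlas = atlas,
                    config = config)
  suvr <- vapply(seq_along(coh$scans), function(i)
    compute_suvr(coh$scans[[i]], atlas, tier = results[[i]]$tier)$suvr,
    numeric(1))
  got_high <- vapply(results, function(r) r$high_tau, logical(1))
  got_tier <- vapply(results, function(r) r$tier, character(1))
  accuracy <- mean(got_high == coh$truth$high_tau &
                     got_tier == coh$truth$tier)
  reads <- if (reader_mode == "classifier") {
    read_matrix(matrix(rep(got_high, n_readers), ncol = n_readers),
                scan_ids = coh$truth$scan_id,
                reader_ids = paste0("reader_", seq_len(n_readers)),
                truth = coh$truth$high_tau)
  } else {
    m <- simulate_reader_panel(coh$truth$high_tau, sensitivity,
                               specificity, n_readers,
                               seed = cohort$seed + 1L)
    read_matrix(m$calls, scan_ids = coh$truth$scan_id,
                reader_ids = m$reader_ids, truth = m$truth)
  }
  report <- agreement_report(reads)
  out <- structure(list(truth = coh$truth, results = results,
                        suvr = suvr, reads = reads, report = report,
                        accuracy = accuracy,
                        fingerprint = config$fingerprint,
                        seed = cohort$seed),
                   class = "study_sim")
  if (!is.null(out_dir)) write_study_sim(out, out_dir)
  out
}

#' @export
print.study_sim <- function(x, ...) {
  cat(sprintf("<study_sim> %d scans; truth-recovery accuracy %.1f%%; seed %d\n",
              nrow(x$truth), 100 * x$accuracy, x$seed))
  print(x$report)
  invisible(x)
}

#' @rdname run_study_sim
#' @param x a `study_sim` result.
#' @export
write_study_sim <- function(x, out_dir) {
  stopifnot(inherits(x, "study_sim"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(x$truth, file.path(out_dir, "truth.csv"),
                   row.names = FALSE, quote = FALSE)
  write_reads_csv(x$reads, file.path(out_dir, "reads.csv"))
  strat <- lapply(seq_along(x$results), function(i)
    c(list(scan_id = x$truth$scan_id[i]),
      as_report_list(x$results[[i]]),
      list(suvr = x$suvr[i])))
  jsonlite::write_json(
    list(fingerprint = x$fingerprint, seed = x$seed, scans = strat),
    file.path(out_dir, "stratifications.json"),
    auto_unbox = TRUE, digits = NA, null = "null")
  jsonlite::write_json(
    c(list(fingerprint = x$fingerprint, seed = x$seed,
           accuracy = x$accuracy),
      as_report_list(x$report)),
    file.path(out_dir, "report.json"),
    auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}
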