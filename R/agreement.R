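#' Reader-call matrix
#'
#' Scans x readers binary high-tau calls, optionally paired with a
#' per-scan quantitation truth label. Truth may be `NA` for scans without
#' a usable quantitation (those are excluded from agreement endpoints but
#' retained for kappa statistics).
#'
#' @param calls logical matrix (scans in rows, readers in columns); no
#'   missing calls.
#' @param scan_ids,reader_ids identifiers; default to row/column names or
#'   generated labels.
#' @param truth optional logical vector of per-scan truth (NA = masked).
#' @return An object of class `read_matrix`.
#' @export
read_matrix <- function(calls, scan_ids = NULL, reader_ids = NULL,
                        truth = NULL) {
  calls <- as.matrix(calls)
  if (!is.logical(calls))
    stop("calls must be a logical matrix", call. = FALSE)
  if (anyNA(calls))
    stop("missing reader calls are not supported", call. = FALSE)
  if (is.null(scan_ids))
    scan_ids <- rownames(calls) %||% sprintf("scan_%03d", seq_len(nrow(calls)))
  if (is.null(reader_ids))
    reader_ids <- colnames(calls) %||% sprintf("reader_%d", seq_len(ncol(calls)))
  stopifnot(length(scan_ids) == nrow(calls),
            length(reader_ids) == ncol(calls))
  if (!is.null(truth)) {
    truth <- as.logical(truth)
    stopifnot(length(truth) == nrow(calls))
  }
  dimnames(calls) <- list(scan_ids, reader_ids)
  structure(list(calls = calls, scan_ids = as.character(scan_ids),
                 reader_ids = as.character(reader_ids), truth = truth),
            class = "read_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.read_matrix <- function(x, ...) {
  cat(sprintf("<read_matrix> %d scans x %d readers; truth: %s\n",
              nrow(x$calls), ncol(x$calls),
              if (is.null(x$truth)) "absent" else
                sprintf("%d labeled, %d masked", sum(!is.na(x$truth)),
                        sum(is.na(x$truth)))))
  invisible(x)
}

#' Wilson score confidence interval for a binomial proportion
#'
#' Inverts the score test at `z = qnorm((1 + level) / 2)`. The interval
#' always contains the point estimate; at 0 (or n) successes the lower
#' (upper) bound is exactly 0 (1).
#'
#' @param successes,n counts with `0 <= successes <= n`, `n >= 1`.
#' @param level confidence level in (0, 1); default 0.95.
#' @return Numeric vector `c(low, high)` on the proportion scale.
#' @export
#' @examples
#' round(100 * wilson_interval(58, 70), 1)
wilson_interval <- function(successes, n, level = 0.95) {
  stopifnot(length(successes) == 1L, length(n) == 1L,
            n >= 1, successes >= 0, successes <= n,
            level > 0, level < 1)
  z <- stats::qnorm((1 + level) / 2)
  p <- successes / n
  den <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  low <- if (successes == 0) 0 else max(0, centre - hw)
  high <- if (successes == n) 1 else min(1, centre + hw)
  c(low = low, high = high)
}

#' Proportion estimate with Wilson interval, on the percent scale
#'
#' @param numerator,denominator counts.
#' @param level confidence level.
#' @return An object of class `proportion_estimate` with `point_pct`,
#'   `ci_low_pct`, `ci_high_pct`, `numerator`, `denominator`, `level`.
#' @export
proportion_estimate <- function(numerator, denominator, level = 0.95) {
  if (denominator < 1)
    stop("zero denominator for a requested endpoint", call. = FALSE)
  ci <- wilson_interval(numerator, denominator, level)
  structure(list(numerator = numerator, denominator = denominator,
                 point_pct = 100 * numerator / denominator,
                 ci_low_pct = 100 * ci[["low"]],
                 ci_high_pct = 100 * ci[["high"]],
                 level = level),
            class = "proportion_estimate")
}

#' @export
print.proportion_estimate <- function(x, ...) {
  cat(sprintf("%.1f%% (%.1f%%-%.1f%%) [%d/%d]\n", x$point_pct,
              x$ci_low_pct, x$ci_high_pct, x$numerator, x$denominator))
  invisible(x)
}

#' Contingency counts for one reader against truth
#'
#' Scans without a truth label (e.g. quantitation failures) are excluded
#' from the counts; the number excluded is recorded in `n_excluded`.
#'
#' @param matrix a [read_matrix()] with truth.
#' @param reader reader id or column index.
#' @return An object of class `contingency_counts` with fields `tp`,
#'   `fp`, `tn`, `fn`, `n_excluded`.
#' @export
contingency_from_reads <- function(matrix, reader) {
  stopifnot(inherits(matrix, "read_matrix"))
  if (is.null(matrix$truth))
    stop("read matrix carries no truth labels", call. = FALSE)
  if (is.character(reader)) {
    if (!reader %in% matrix$reader_ids)
      stop("unknown reader: ", reader, call. = FALSE)
    j <- match(reader, matrix$reader_ids)
  } else {
    j <- as.integer(reader)
    if (j < 1L || j > ncol(matrix$calls))
      stop("unknown reader index: ", reader, call. = FALSE)
  }
  keep <- !is.na(matrix$truth)
  calls <- matrix$calls[keep, j]
  truth <- matrix$truth[keep]
  contingency_counts(tp = sum(calls & truth), fp = sum(calls & !truth),
                     tn = sum(!calls & !truth), fn = sum(!calls & truth),
                     n_excluded = sum(!keep))
}

#' @rdname contingency_from_reads
#' @param tp,fp,tn,fn nonnegative counts.
#' @param n_excluded scans dropped for missing truth.
#' @export
contingency_counts <- function(tp, fp, tn, fn, n_excluded = 0L) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 tn = as.integer(tn), fn = as.integer(fn),
                 n_excluded = as.integer(n_excluded)),
            class = "contingency_counts")
}

#' Agreement endpoints from contingency counts
#'
#' `PPA = 100 * TP / (TP + FN)`, `NPA = 100 * TN / (TN + FP)`, overall
#' agreement `100 * (TP + TN) / total`, each with a Wilson score interval.
#' PPA and NPA are the sensitivity/specificity analogues used when the
#' reference is another measurement (here quantitation) rather than
#' ground truth.
#'
#' @param counts a [contingency_counts()].
#' @param level confidence level.
#' @return List with `proportion_estimate` elements `ppa`, `npa`,
#'   `overall`.
#' @export
ppa_npa <- function(counts, level = 0.95) {
  stopifnot(inherits(counts, "contingency_counts"))
  with(counts, {
    if (tp + fn < 1) stop("no truth-positive scans: PPA undefined",
                          call. = FALSE)
    if (tn + fp < 1) stop("no truth-negative scans: NPA undefined",
                          call. = FALSE)
    list(ppa = proportion_estimate(tp, tp + fn, level),
         npa = proportion_estimate(tn, tn + fp, level),
         overall = proportion_estimate(tp + tn, tp + fp + tn + fn, level))
  })
}

# Shared two-category Fleiss kappa computation from
#   Po (mean per-scan pairwise agreement), total positive calls.
.fleiss_core <- function(p_o, n_pos_total, n_scans, n_readers,
                         level = 0.95) {
  p <- n_pos_total / (n_scans * n_readers)
  q <- 1 - p
  p_e <- p^2 + q^2
  if (p_e >= 1 - .Machine$double.eps * 8)
    stop("degenerate input: all calls in a single category, ",
         "Fleiss kappa undefined", call. = FALSE)
  kappa <- (p_o - p_e) / (1 - p_e)
  # Fleiss-Nee-Landis large-sample se under the null structure
  pj <- c(p, q)
  qj <- 1 - pj
  spq <- sum(pj * qj)
  se <- sqrt(2 / (n_scans * n_readers * (n_readers - 1))) *
    sqrt(spq^2 - sum(pj * qj * (qj - pj))) / spq
  z <- stats::qnorm((1 + level) / 2)
  kappa_estimate(kappa, se, kappa - z * se, kappa + z * se,
                 method = "fleiss", level = level)
}

kappa_estimate <- function(statistic, se, ci_low, ci_high, method,
                           level = 0.95) {
  structure(list(statistic = statistic, se = se,
                 ci_low = ci_low, ci_high = min(ci_high, 1.0),
                 method = method, level = level),
            class = "kappa_estimate")
}

#' @export
print.kappa_estimate <- function(x, ...) {
  cat(sprintf("<kappa_estimate> %s kappa = %.4f (%.0f%% CI, %.4f-%.4f)\n",
              x$method, x$statistic, 100 * x$level, x$ci_low, x$ci_high))
  invisible(x)
}

#' Fleiss kappa for multi-reader binary calls
#'
#' Two-category Fleiss kappa: `Po` is the mean per-scan pairwise
#' agreement, `Pe = p^2 + q^2` over category marginals pooled across
#' readers, and `kappa = (Po - Pe) / (1 - Pe)`. The standard error uses
#' the Fleiss-Nee-Landis large-sample formula; the CI is
#' `kappa +- z * se` with the upper bound capped at 1.000 for reporting.
#'
#' @param matrix a [read_matrix()] with >= 2 readers and >= 2 scans.
#' @param level confidence level.
#' @return A `kappa_estimate`.
#' @export
fleiss_kappa <- function(matrix, level = 0.95) {
  stopifnot(inherits(matrix, "read_matrix"))
  calls <- matrix$calls
  n_scans <- nrow(calls)
  n_readers <- ncol(calls)
  if (n_readers < 2L || n_scans < 2L)
    stop("Fleiss kappa requires >= 2 readers and >= 2 scans",
         call. = FALSE)
  k <- rowSums(calls)
  splits <- table(paste0(pmax(k, n_readers - k), "-",
                         pmin(k, n_readers - k)))
  fleiss_kappa_from_summary(
    stats::setNames(as.numeric(splits), names(splits)),
    colSums(calls), n_scans, level)
}

#' Fleiss kappa from a printed agreement summary
#'
#' Computes the identical statistic as [fleiss_kappa()] from the summary
#' a study report typically prints: per-scan split counts (how many scans
#' were called positive by a-of-n readers, keyed as `"a-b"` unordered
#' splits) and per-reader positive-call totals.
#'
#' @param split_counts named numeric vector; names are unordered splits
#'   like `"5-0"`, `"4-1"`, `"3-2"`, values are scan counts.
#' @param positive_totals integer vector of positive calls per reader.
#' @param n_scans total scan count.
#' @param level confidence level.
#' @return A `kappa_estimate`, exactly equal to [fleiss_kappa()] on any
#'   matrix realizing the summary.
#' @export
#' @examples
#' fleiss_kappa_from_summary(c("5-0" = 124, "4-1" = 9, "3-2" = 7),
#'                           c(65, 67, 72, 69, 58), 140)
fleiss_kappa_from_summary <- function(split_counts, positive_totals,
                                      n_scans, level = 0.95) {
  if (is.null(names(split_counts)))
    stop("split_counts must be named like '5-0', '4-1', ...",
         call. = FALSE)
  parts <- strsplit(names(split_counts), "-", fixed = TRUE)
  ab <- vapply(parts, function(p) sort(as.integer(p), decreasing = TRUE),
               integer(2))
  n_readers <- unique(colSums(ab))
  if (length(n_readers) != 1L || any(is.na(ab)))
    stop("inconsistent summary: split names must all sum to the same ",
         "reader count", call. = FALSE)
  n_readers <- as.integer(n_readers)
  if (length(positive_totals) != n_readers)
    stop("inconsistent summary: expected ", n_readers,
         " per-reader positive totals", call. = FALSE)
  if (sum(split_counts) != n_scans)
    stop("inconsistent summary: split counts sum to ", sum(split_counts),
         ", not n_scans = ", n_scans, call. = FALSE)
  if (any(positive_totals < 0) || any(positive_totals > n_scans))
    stop("inconsistent summary: positive totals outside [0, n_scans]",
         call. = FALSE)
  # canonical summation order so that any realization of the same summary
  # yields a bit-identical statistic
  ord <- order(ab[1, ], ab[2, ], decreasing = TRUE)
  a <- ab[1, ord]
  b <- ab[2, ord]
  cnt <- as.numeric(split_counts)[ord]
  agree <- (a * (a - 1) + b * (b - 1)) / (n_readers * (n_readers - 1))
  p_o <- sum(cnt * agree) / n_scans
  .fleiss_core(p_o, sum(positive_totals), n_scans, n_readers, level)
}

#' Cohen kappa for two rating vectors
#'
#' Standard two-rater Cohen kappa with per-rater marginals and the
#' asymptotic (Fleiss-Cohen-Everitt) standard error. Used for test-retest
#' (intrareader) reliability: the two vectors are a reader's first and
#' second calls on the same scans. If both vectors are identical and
#' constant, kappa is defined as 1 with se 0; other degenerate marginals
#' raise an error. The CI upper bound is capped at 1.000 for reporting.
#'
#' @param calls_a,calls_b logical vectors of equal length >= 2.
#' @param level confidence level.
#' @return A `kappa_estimate`.
#' @export
cohen_kappa <- function(calls_a, calls_b, level = 0.95) {
  calls_a <- as.logical(calls_a)
  calls_b <- as.logical(calls_b)
  stopifnot(length(calls_a) == length(calls_b), length(calls_a) >= 2L,
            !anyNA(calls_a), !anyNA(calls_b))
  n <- length(calls_a)
  if (identical(calls_a, calls_b) &&
      (all(calls_a) || !any(calls_a)))
    return(kappa_estimate(1.0, 0.0, 1.0, 1.0, method = "cohen",
                          level = level))
  # observed proportions over the 2x2 table (TRUE first)
  p <- matrix(0, 2, 2)
  p[1, 1] <- sum(calls_a & calls_b) / n
  p[1, 2] <- sum(calls_a & !calls_b) / n
  p[2, 1] <- sum(!calls_a & calls_b) / n
  p[2, 2] <- sum(!calls_a & !calls_b) / n
  pr <- rowSums(p)
  pc <- colSums(p)
  po <- sum(diag(p))
  pe <- sum(pr * pc)
  if (abs(1 - pe) < .Machine$double.eps * 8)
    stop("degenerate marginals: Cohen kappa undefined", call. = FALSE)
  kappa <- (po - pe) / (1 - pe)
  # asymptotic variance of kappa-hat (Fleiss, Cohen & Everitt 1969)
  t1 <- sum(vapply(1:2, function(i)
    p[i, i] * ((1 - pe) - (pc[i] + pr[i]) * (1 - po))^2, numeric(1)))
  t2 <- (1 - po)^2 * sum(vapply(1:2, function(i)
    sum(vapply(setdiff(1:2, i), function(j)
      p[i, j] * (pc[i] + pr[j])^2, numeric(1))), numeric(1)))
  t3 <- (po * pe - 2 * pe + po)^2
  var_k <- (t1 + t2 - t3) / (n * (1 - pe)^4)
  se <- sqrt(max(var_k, 0))
  z <- stats::qnorm((1 + level) / 2)
  kappa_estimate(kappa, se, kappa - z * se, kappa + z * se,
                 method = "cohen", level = level)
}

#' Majority read across a reader panel
#'
#' Per-scan consensus: the category with strictly more votes. Even panels
#' need a `tie_rule`.
#'
#' @param matrix a [read_matrix()].
#' @param tie_rule `"error"` (default), `"positive"`, or `"negative"`.
#' @return Logical vector of per-scan majority calls.
#' @export
majority_read <- function(matrix, tie_rule = c("error", "positive",
                                               "negative")) {
  tie_rule <- match.arg(tie_rule)
  stopifnot(inherits(matrix, "read_matrix"))
  n_readers <- ncol(matrix$calls)
  votes <- rowSums(matrix$calls)
  if (n_readers %% 2L == 0L && any(votes == n_readers / 2)) {
    if (tie_rule == "error")
      stop("tied majority vote with tie_rule = 'error' (scans: ",
           paste(matrix$scan_ids[votes == n_readers / 2], collapse = ", "),
           ")", call. = FALSE)
    ties <- votes == n_readers / 2
    out <- votes > n_readers / 2
    out[ties] <- tie_rule == "positive"
    return(stats::setNames(out, matrix$scan_ids))
  }
  stats::setNames(votes > n_readers / 2, matrix$scan_ids)
}

#' Full agreement report for a reader study
#'
#' Builds, for a [read_matrix()] with truth: per-reader contingency
#' counts, PPA/NPA/overall-agreement with Wilson CIs; a pooled row
#' (endpoints of the summed per-reader contingencies, the convention
#' matching the published overall row); per-reader medians of the point
#' estimates; Fleiss kappa over all scans (masked-truth scans included);
#' and the protocol success-criterion verdicts.
#'
#' @param matrix a [read_matrix()] with truth labels.
#' @param level confidence level.
#' @param ... passed to [evaluate_success_criteria()].
#' @return An object of class `agreement_report`.
#' @export
agreement_report <- function(matrix, level = 0.95, ...) {
  stopifnot(inherits(matrix, "read_matrix"))
  if (is.null(matrix$truth))
    stop("agreement report requires truth labels", call. = FALSE)
  readers <- matrix$reader_ids
  per_reader <- lapply(readers, function(r) {
    cc <- contingency_from_reads(matrix, r)
    c(list(reader = r, counts = cc), ppa_npa(cc, level))
  })
  names(per_reader) <- readers
  pooled_counts <- contingency_counts(
    tp = sum(vapply(per_reader, function(x) x$counts$tp, integer(1))),
    fp = sum(vapply(per_reader, function(x) x$counts$fp, integer(1))),
    tn = sum(vapply(per_reader, function(x) x$counts$tn, integer(1))),
    fn = sum(vapply(per_reader, function(x) x$counts$fn, integer(1))))
  pooled <- ppa_npa(pooled_counts, level)
  medians <- list(
    ppa_pct = stats::median(vapply(per_reader,
                                   function(x) x$ppa$point_pct, numeric(1))),
    npa_pct = stats::median(vapply(per_reader,
                                   function(x) x$npa$point_pct, numeric(1))),
    overall_pct = stats::median(vapply(per_reader,
                                       function(x) x$overall$point_pct,
                                       numeric(1))))
  fleiss <- fleiss_kappa(matrix, level)
  report <- structure(list(per_reader = per_reader,
                           pooled = pooled,
                           pooled_counts = pooled_counts,
                           medians = medians,
                           fleiss = fleiss,
                           level = level),
                      class = "agreement_report")
  succ <- evaluate_success_criteria(report, ...)
  report$success_ppa_npa <- succ$success_ppa_npa
  report$success_fleiss <- succ$success_fleiss
  report
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("<agreement_report>\n")
  for (r in names(x$per_reader)) {
    pr <- x$per_reader[[r]]
    cat(sprintf("  %-10s PPA %5.1f%% (%.1f-%.1f)  NPA %5.1f%% (%.1f-%.1f)  overall %5.1f%%\n",
                r, pr$ppa$point_pct, pr$ppa$ci_low_pct, pr$ppa$ci_high_pct,
                pr$npa$point_pct, pr$npa$ci_low_pct, pr$npa$ci_high_pct,
                pr$overall$point_pct))
  }
  cat(sprintf("  %-10s PPA %5.1f%% (%.1f-%.1f)  NPA %5.1f%% (%.1f-%.1f)  overall %5.1f%%\n",
              "pooled", x$pooled$ppa$point_pct, x$pooled$ppa$ci_low_pct,
              x$pooled$ppa$ci_high_pct, x$pooled$npa$point_pct,
              x$pooled$npa$ci_low_pct, x$pooled$npa$ci_high_pct,
              x$pooled$overall$point_pct))
  cat(sprintf("  Fleiss kappa %.4f (%.4f-%.4f); success: endpoints=%s, kappa=%s\n",
              x$fleiss$statistic, x$fleiss$ci_low, x$fleiss$ci_high,
              x$success_ppa_npa, x$success_fleiss))
  invisible(x)
}

#' Protocol success criteria
#'
#' Endpoint criterion: the PPA and NPA 95% CI lower bounds are both
#' `bound_pct` or greater for at least `n_required_readers` readers.
#' Reliability criterion: Fleiss kappa at least `fleiss_min` and its CI
#' lower bound at least `fleiss_ci_min`. All comparisons are inclusive
#' (`>=`), per the protocol wording "50% or greater" / "at least".
#'
#' @param report an [agreement_report()].
#' @param n_required_readers minimum qualifying readers (default 3).
#' @param bound_pct endpoint CI lower-bound threshold in percent
#'   (default 50).
#' @param fleiss_min,fleiss_ci_min Fleiss point and CI-lower thresholds
#'   (defaults 0.64 and 0.55).
#' @return List with logicals `success_ppa_npa`, `success_fleiss`.
#' @export
evaluate_success_criteria <- function(report, n_required_readers = 3L,
                                      bound_pct = 50,
                                      fleiss_min = 0.64,
                                      fleiss_ci_min = 0.55) {
  stopifnot(inherits(report, "agreement_report") ||
              is.list(report))
  per <- report$per_reader
  if (length(per) < n_required_readers)
    stop("report has fewer readers than n_required_readers",
         call. = FALSE)
  ok <- vapply(per, function(x)
    x$ppa$ci_low_pct >= bound_pct && x$npa$ci_low_pct >= bound_pct,
    logical(1))
  list(success_ppa_npa = sum(ok) >= n_required_readers,
       success_fleiss = report$fleiss$statistic >= fleiss_min &&
         report$fleiss$ci_low >= fleiss_ci_min)
}

#' Simulate an independent reader panel
#'
#' Each reader independently calls each truth-positive scan positive with
#' probability `sensitivity` and each truth-negative scan positive with
#' probability `1 - specificity`. A deterministic harness for the kappa
#' and endpoint estimators.
#'
#' @param truth logical vector of scan truth labels.
#' @param sensitivity,specificity per-reader operating point in [0, 1].
#' @param n_readers panel size.
#' @param seed integer RNG seed.
#' @return A [read_matrix()] carrying `truth`.
#' @export
simulate_reader_panel <- function(truth, sensitivity, specificity,
                                  n_readers = 5L, seed = 1L) {
  truth <- as.logical(truth)
  stopifnot(!anyNA(truth), sensitivity >= 0, sensitivity <= 1,
            specificity >= 0, specificity <= 1, n_readers >= 1L)
  p_pos <- ifelse(truth, sensitivity, 1 - specificity)
  calls <- withr::with_seed(as.integer(seed), {
    matrix(stats::runif(length(truth) * n_readers) <
             rep(p_pos, times = n_readers),
           nrow = length(truth), ncol = n_readers)
  })
  read_matrix(calls, truth = truth)
}
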