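#' Published validation-study summary counts
#'
#' The five-reader flortaucipir stratification validation study reported
#' its agreement results only as summary counts; this function returns
#' them as structured inputs for the statistics in this package:
#' per-reader true-positive/true-negative counts against the
#' quantitation standard (70 truth-positive and 70 truth-negative scans
#' per reader), per-scan agreement splits (how many of the 140 scans were
#' called identically by 5, 4, or 3 of the 5 readers), per-reader
#' positive-call totals, and the majority-read contingency.
#'
#' @return A list with elements `tp`, `tn` (integer vectors, one per
#'   reader), `n_pos`, `n_neg` (truth group sizes), `splits` (named
#'   vector of per-scan split counts), `positive_totals`, `n_scans`, and
#'   `majority` (named vector with `tp`, `fn`, `tn`, `fp`).
#' @export
#' @examples
#' s <- reader_study_summary()
#' fleiss_kappa_from_summary(s$splits, s$positive_totals, s$n_scans)
reader_study_summary <- function() {
  list(tp = c(58L, 59L, 63L, 60L, 52L),
       tn = c(63L, 62L, 61L, 61L, 64L),
       n_pos = 70L,
       n_neg = 70L,
       splits = c("5-0" = 124, "4-1" = 9, "3-2" = 7),
       positive_totals = c(65L, 67L, 72L, 69L, 58L),
       n_scans = 140L,
       majority = c(tp = 60L, fn = 10L, tn = 62L, fp = 8L))
}

#' Synthetic realization of the validation-study read matrix
#'
#' Constructs one 140-scan by 5-reader call matrix with truth labels that
#' jointly reproduces every summary count of [reader_study_summary()]:
#' the per-scan agreement splits, the per-reader positive totals, every
#' per-reader contingency (TP/FP/TN/FN), and the majority-read
#' contingency. The scan-level data of the study were never published, so
#' this is a synthetic realization consistent with all printed marginals,
#' not the study's actual reads; any statistic that depends only on those
#' marginals (the agreement endpoints, Fleiss kappa, majority read) is
#' nevertheless exactly reproduced.
#'
#' The construction concatenates scan groups (T = high-tau call):
#' \itemize{
#'  \item 52 unanimous-positive, truth-positive; 5 unanimous-positive,
#'    truth-negative;
#'  \item 3 scans 4-1 with reader 5 dissenting negative, truth-positive;
#'    3 alike but truth-negative (dissenters: readers 1, 5, 5);
#'  \item 5 scans 3-2 positive-by \{3, and pairs 12/14/14/24/24\},
#'    truth-positive;
#'  \item 2 scans 2-3 (positives \{2,3\} and \{3,4\}), truth-positive;
#'  \item 3 scans 1-4 (single positives: readers 3, 3, 4), the first
#'    truth-positive, the others truth-negative;
#'  \item 7 unanimous-negative truth-positive; 60 unanimous-negative
#'    truth-negative.
#' }
#'
#' @return A [read_matrix()] with 140 scans, 5 readers, and truth.
#' @export
reader_study_matrix <- function() {
  row5 <- function(pos) { x <- rep(FALSE, 5L); x[pos] <- TRUE; x }
  rows <- list()
  truth <- logical(0)
  add <- function(n, pos, tr) {
    for (i in seq_len(n)) rows[[length(rows) + 1L]] <<- row5(pos)
    truth <<- c(truth, rep(tr, n))
  }
  add(52L, 1:5, TRUE)               # unanimous positive, truth+
  add(5L, 1:5, FALSE)               # unanimous positive, truth-
  add(3L, c(1, 2, 3, 4), TRUE)      # 4-1, reader 5 negative, truth+
  add(1L, c(2, 3, 4, 5), FALSE)     # 4-1, reader 1 negative, truth-
  add(2L, c(1, 2, 3, 4), FALSE)     # 4-1, reader 5 negative, truth-
  add(1L, c(1, 2, 3), TRUE)         # 3-2 positives {r1,r2,r3}, truth+
  add(2L, c(1, 3, 4), TRUE)         # 3-2 positives {r1,r3,r4}, truth+
  add(2L, c(2, 3, 4), TRUE)         # 3-2 positives {r2,r3,r4}, truth+
  add(1L, c(2, 3), TRUE)            # 2-3 positives {r2,r3}, truth+
  add(1L, c(3, 4), TRUE)            # 2-3 positives {r3,r4}, truth+
  add(1L, 3, TRUE)                  # 1-4 positive r3 only, truth+
  add(1L, 3, FALSE)                 # 1-4 positive r3 only, truth-
  add(1L, 4, FALSE)                 # 1-4 positive r4 only, truth-
  add(7L, integer(0), TRUE)         # unanimous negative, truth+ (FN)
  add(60L, integer(0), FALSE)       # unanimous negative, truth-
  calls <- do.call(rbind, rows)
  read_matrix(calls,
              scan_ids = sprintf("scan_%03d", seq_len(nrow(calls))),
              reader_ids = paste0("reader_", 1:5),
              truth = truth)
}
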