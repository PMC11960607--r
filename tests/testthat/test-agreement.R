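test_that("Wilson intervals contain the point estimate and hit exact boundaries", {
  ci <- wilson_interval(58, 70)
  expect_true(ci[["low"]] <= 58 / 70 && 58 / 70 <= ci[["high"]])
  expect_identical(wilson_interval(0, 50)[["low"]], 0)
  expect_identical(wilson_interval(50, 50)[["high"]], 1)
  # width is non-increasing in n at a fixed proportion
  widths <- vapply(c(10, 40, 160, 640), function(n)
    diff(wilson_interval(round(0.3 * n), n)), numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("Wilson bounds solve the score equation (root-finding oracle)", {
  # at each Wilson bound p*, |phat - p*| = z * sqrt(p*(1-p*)/n)
  score_gap <- function(p, phat, n, z)
    (phat - p)^2 - z^2 * p * (1 - p) / n
  z <- qnorm(0.975)
  set.seed(14)
  for (i in 1:100) {
    n <- sample(5:500, 1)
    x <- sample(0:n, 1)
    ci <- wilson_interval(x, n)
    for (b in ci) expect_lt(abs(score_gap(b, x / n, n, z)), 1e-10)
  }
})

test_that("contingency counting excludes masked-truth scans and matches hand counts", {
  calls <- matrix(c(TRUE, TRUE, FALSE), ncol = 1)
  m <- read_matrix(calls, scan_ids = c("a", "b", "c"), reader_ids = "r1",
                   truth = c(TRUE, FALSE, FALSE))
  cc <- contingency_from_reads(m, "r1")
  expect_equal(unlist(cc[c("tp", "fp", "tn", "fn")]),
               c(tp = 1L, fp = 1L, tn = 1L, fn = 0L))
  # masking one scan reduces the denominators
  m2 <- read_matrix(calls, scan_ids = c("a", "b", "c"), reader_ids = "r1",
                    truth = c(TRUE, NA, FALSE))
  cc2 <- contingency_from_reads(m2, "r1")
  expect_equal(unlist(cc2[c("tp", "fp", "tn", "fn", "n_excluded")]),
               c(tp = 1L, fp = 0L, tn = 1L, fn = 0L, n_excluded = 1L))
  expect_error(contingency_from_reads(m, "r9"), "unknown reader")
})

test_that("PPA/NPA/overall reproduce published per-reader endpoint examples", {
  e <- ppa_npa(contingency_counts(tp = 60, fp = 0, tn = 1, fn = 10))
  expect_equal(e$ppa$point_pct, 100 * 60 / 70)
  e0 <- ppa_npa(contingency_counts(tp = 0, fp = 1, tn = 1, fn = 10))
  expect_equal(e0$ppa$point_pct, 0)
  r1 <- ppa_npa(contingency_counts(tp = 58, fn = 12, tn = 63, fp = 7))
  expect_equal(round(r1$overall$point_pct, 1), 86.4)
  expect_equal(round(c(r1$overall$ci_low_pct, r1$overall$ci_high_pct), 1),
               c(79.8, 91.1))
  expect_error(ppa_npa(contingency_counts(tp = 0, fp = 2, tn = 1, fn = 0)),
               "PPA undefined")
})

test_that("Fleiss kappa equals 1 for unanimous mixed-category calls and errors when degenerate", {
  calls <- rbind(matrix(TRUE, 4, 3), matrix(FALSE, 4, 3))
  expect_equal(fleiss_kappa(read_matrix(calls))$statistic, 1.0)
  all_pos <- matrix(TRUE, 5, 3)
  expect_error(fleiss_kappa(read_matrix(all_pos)), "degenerate")
})

test_that("Fleiss kappa matches a direct pairwise hand computation for 2 readers", {
  set.seed(7)
  calls <- matrix(runif(40) < 0.5, ncol = 2)
  k <- fleiss_kappa(read_matrix(calls))
  p_o <- mean(calls[, 1] == calls[, 2])
  p <- mean(calls)
  p_e <- p^2 + (1 - p)^2
  expect_equal(k$statistic, (p_o - p_e) / (1 - p_e))
})

test_that("matrix and summary Fleiss kappa agree exactly on random panels", {
  set.seed(23)
  for (i in 1:100) {
    n_scans <- sample(5:40, 1)
    n_readers <- sample(2:6, 1)
    calls <- matrix(runif(n_scans * n_readers) < runif(1, 0.2, 0.8),
                    n_scans, n_readers)
    if (all(calls) || !any(calls)) next
    pos <- rowSums(calls)
    splits <- table(paste0(pmax(pos, n_readers - pos), "-",
                           pmin(pos, n_readers - pos)))
    k1 <- fleiss_kappa(read_matrix(calls))
    k2 <- fleiss_kappa_from_summary(
      stats::setNames(as.numeric(splits), names(splits)),
      colSums(calls), n_scans)
    expect_identical(k1$statistic, k2$statistic)
    expect_identical(k1$se, k2$se)
  }
})

test_that("summary kappa validates its inputs", {
  expect_error(fleiss_kappa_from_summary(c("5-0" = 10, "4-1" = 2),
                                         c(5, 5, 5, 5, 5), 13),
               "split counts sum")
  expect_error(fleiss_kappa_from_summary(c("5-0" = 10, "3-1" = 2),
                                         c(5, 5, 5, 5, 5), 12),
               "same\n* reader count|same reader count")
  expect_error(fleiss_kappa_from_summary(c("3-0" = 10), c(2, 2), 10),
               "per-reader positive totals")
})

test_that("Cohen kappa handles perfect, maximal-disagreement, and hand-computed cases", {
  a <- c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE)
  expect_equal(cohen_kappa(a, a)$statistic, 1.0)
  expect_equal(cohen_kappa(a, !a)$statistic, -1.0)
  # 20-scan test-retest, 1 discordant pair, 12/8 marginals on first read
  x <- rep(c(TRUE, FALSE), c(12, 8))
  y <- x; y[12] <- FALSE  # one positive flips on retest
  k <- cohen_kappa(x, y)
  po <- 19 / 20
  pe <- (12 / 20) * (11 / 20) + (8 / 20) * (9 / 20)
  expect_equal(k$statistic, (po - pe) / (1 - pe))
  expect_lte(k$ci_high, 1.0)
  # symmetric in its arguments
  k2 <- cohen_kappa(y, x)
  expect_equal(k2$statistic, k$statistic)
  expect_equal(k2$se, k$se)
  # identical constant vectors define kappa = 1; se 0
  kc <- cohen_kappa(rep(TRUE, 5), rep(TRUE, 5))
  expect_equal(kc$statistic, 1.0)
  expect_equal(kc$se, 0.0)
})

test_that("majority read takes the strict majority and respects tie rules", {
  calls <- rbind(c(TRUE, TRUE, TRUE, FALSE, FALSE),
                 c(FALSE, FALSE, TRUE, TRUE, FALSE))
  m <- read_matrix(calls)
  expect_equal(unname(majority_read(m)), c(TRUE, FALSE))
  # invariant to reader order
  perm <- read_matrix(calls[, c(4, 2, 5, 1, 3)])
  expect_equal(unname(majority_read(perm)), c(TRUE, FALSE))
  # even panel ties
  even <- read_matrix(rbind(c(TRUE, TRUE, FALSE, FALSE)))
  expect_error(majority_read(even), "tied majority")
  expect_true(majority_read(even, tie_rule = "positive"))
  expect_false(majority_read(even, tie_rule = "negative"))
})

test_that("success criteria use inclusive bounds", {
  m <- reader_study_matrix()
  rep <- agreement_report(m)
  expect_true(rep$success_ppa_npa)
  expect_true(rep$success_fleiss)
  # all lower bounds at 49% -> endpoint failure
  fake <- rep
  for (r in names(fake$per_reader)) {
    fake$per_reader[[r]]$ppa$ci_low_pct <- 49
    fake$per_reader[[r]]$npa$ci_low_pct <- 49
  }
  expect_false(evaluate_success_criteria(fake)$success_ppa_npa)
  # kappa exactly at the inclusive thresholds passes
  fake$fleiss$statistic <- 0.64
  fake$fleiss$ci_low <- 0.55
  expect_true(evaluate_success_criteria(fake)$success_fleiss)
})

test_that("pooled endpoints equal endpoints of summed per-reader contingencies", {
  m <- simulate_reader_panel(rep(c(TRUE, FALSE), c(30, 30)), 0.8, 0.85,
                             n_readers = 5, seed = 9)
  rep <- agreement_report(m)
  tps <- vapply(rep$per_reader, function(x) x$counts$tp, integer(1))
  expect_equal(rep$pooled_counts$tp, sum(tps))
  expect_equal(rep$pooled$ppa$point_pct,
               100 * sum(tps) / (5 * 30))
})

test_that("simulated panels are seed-deterministic and recover the operating point", {
  truth <- rep(c(TRUE, FALSE), c(70, 70))
  m1 <- simulate_reader_panel(truth, 0.85, 0.9, 5, seed = 4)
  m2 <- simulate_reader_panel(truth, 0.85, 0.9, 5, seed = 4)
  expect_identical(m1$calls, m2$calls)
  expect_false(identical(
    m1$calls, simulate_reader_panel(truth, 0.85, 0.9, 5, seed = 5)$calls))
  # perfect readers agree with truth and with each other
  mp <- simulate_reader_panel(truth, 1, 1, 5, seed = 1)
  expect_true(all(mp$calls == truth))
  expect_equal(fleiss_kappa(mp)$statistic, 1.0)
  # pooled PPA over many replicates concentrates on the sensitivity
  ppa <- vapply(1:60, function(s) {
    m <- simulate_reader_panel(truth, 0.85, 0.9, 5, seed = 100 + s)
    rep <- agreement_report(m)
    rep$pooled$ppa$point_pct
  }, numeric(1))
  mc_se <- sd(ppa) / sqrt(length(ppa))
  expect_lt(abs(mean(ppa) - 85), 3 * mc_se + 1e-9)
})
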