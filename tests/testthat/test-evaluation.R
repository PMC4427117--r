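gi <- function(starts, ends, id = "x", label = "predicted") {
  if (!length(starts)) return(genomic_intervals(label = label))
  genomic_intervals(rep(id, length(starts)), starts, ends, label = label)
}

test_that("segment confusion counts exons and noncoding units", {
  truth <- gi(c(0, 200, 400, 600, 800), c(100, 300, 500, 700, 900),
              label = "exon")
  # all five hit, two spurious calls, five noncoding units
  pred <- gi(c(0, 200, 400, 600, 800, 1000, 1200),
             c(100, 300, 500, 700, 900, 1050, 1250))
  cc <- segment_confusion(pred, truth, noncoding_units = 5)
  expect_equal(as.integer(cc[1, c("tp", "fp", "fn", "tn")]), c(5L, 2L, 0L, 3L))

  none <- segment_confusion(gi(integer(), integer()), truth,
                            noncoding_units = 5)
  expect_equal(as.integer(none[1, c("tp", "fp", "fn", "tn")]),
               c(0L, 0L, 5L, 5L))

  exact <- segment_confusion(gi(truth$start, truth$end), truth)
  expect_equal(exact$fp, 0L)
  expect_equal(exact$fn, 0L)
  expect_equal(exact$tn, 6L)   # default: n_exons + 1 flanking/intervening units
})

test_that("segment confusion applies the overlap rule and ignores interval order", {
  truth <- gi(c(100, 500), c(300, 700), label = "exon")
  half <- gi(200, 300)     # covers exactly 50% of exon 1
  cc <- segment_confusion(half, truth)
  expect_equal(cc$tp, 1L)
  under <- gi(201, 300)    # 49.5%
  expect_equal(segment_confusion(under, truth)$tp, 0L)

  shuffled <- genomic_intervals(c("x", "x"), c(500, 100), c(700, 300),
                                label = "exon")
  pred <- gi(c(520, 110), c(700, 290))
  expect_equal(segment_confusion(pred, truth), segment_confusion(pred, shuffled))
  expect_error(segment_confusion(gi(0, 10, id = "a"), gi(0, 10, id = "b",
                                                         label = "exon")),
               "different sequences")
})

test_that("nucleotide confusion classifies every position", {
  cc <- nucleotide_confusion(gi(0, 10), gi(0, 10, label = "exon"), 20)
  expect_equal(as.integer(cc[1, c("tp", "fp", "fn", "tn")]),
               c(10L, 0L, 0L, 10L))

  cc2 <- nucleotide_confusion(gi(0, 10), gi(5, 15, label = "exon"), 20)
  expect_equal(as.integer(cc2[1, c("tp", "fp", "fn", "tn")]),
               c(5L, 5L, 5L, 5L))

  cc3 <- nucleotide_confusion(gi(integer(), integer()),
                              gi(integer(), integer(), label = "exon"), 7)
  expect_equal(cc3$tn, 7L)
  expect_equal(cc3$tp + cc3$fp + cc3$fn + cc3$tn, 7L)
  expect_error(nucleotide_confusion(gi(0, 30), gi(0, 10, label = "exon"), 20),
               "out of bounds")
})

test_that("metrics reproduce the worked threshold rows from counts", {
  m25 <- compute_metrics(confusion_counts(5, 2, 0, 3, "segment"))
  expect_equal(m25$sensitivity, 1.00)
  expect_equal(m25$specificity, 0.60)
  expect_equal(m25$accuracy, 0.80)
  expect_equal(m25$positive_precision, 5 / 7, tolerance = 1e-12)
  expect_equal(round(100 * m25$positive_precision, 2), 71.43)
  expect_equal(m25$negative_precision, 1.00)
  expect_equal(m25$error_rate, 0.20)
  expect_equal(m25$false_discovery_rate, 2 / 7, tolerance = 1e-12)
  expect_equal(round(100 * m25$false_discovery_rate, 2), 28.57)
  expect_equal(m25$false_omission_rate, 0.00)

  m55 <- compute_metrics(confusion_counts(4, 0, 1, 5, "segment"))
  expect_equal(m55$sensitivity, 0.80)
  expect_equal(m55$specificity, 1.00)
  expect_equal(m55$accuracy, 0.90)
  expect_equal(m55$positive_precision, 1.00)
  expect_equal(m55$error_rate, 0.10)
  expect_equal(m55$false_discovery_rate, 0.00)
  expect_equal(m55$false_omission_rate, 1 / 6, tolerance = 1e-12)
  expect_equal(round(100 * m55$false_omission_rate, 2), 16.67)
  # literal ratio TN/(TN+FN) = 5/6; complementary to the false omission rate
  expect_equal(m55$negative_precision, 5 / 6, tolerance = 1e-12)
})

test_that("zero denominators yield NA, never 0 or 1; all-zero counts abort", {
  m <- compute_metrics(confusion_counts(0, 0, 0, 8, "segment"))
  expect_true(is.na(m$sensitivity))
  expect_true(is.na(m$false_discovery_rate))
  expect_true(is.na(m$positive_precision))
  expect_equal(m$specificity, 1.00)
  expect_error(compute_metrics(confusion_counts(0, 0, 0, 0, "segment")),
               "degenerate")
})

test_that("complementarity identities hold on random counts", {
  set.seed(51)
  for (rep in 1:25) {
    cnt <- confusion_counts(sample(0:20, 1), sample(0:20, 1),
                            sample(0:20, 1), sample(1:20, 1), "nucleotide")
    m <- compute_metrics(cnt)
    expect_equal(m$error_rate, 1 - m$accuracy, tolerance = 1e-12)
    if (!is.na(m$positive_precision)) {
      expect_equal(m$false_discovery_rate, 1 - m$positive_precision,
                   tolerance = 1e-12)
    }
    if (!is.na(m$negative_precision)) {
      expect_equal(m$false_omission_rate, 1 - m$negative_precision,
                   tolerance = 1e-12)
    }
    td <- tidy(m)
    expect_equal(nrow(td), 8L)
  }
})

test_that("ROC: perfect separation, symmetry, and label-independent profiles", {
  truth <- gi(c(20, 60), c(40, 80), label = "exon")
  v <- numeric(100)
  v[c(21:40, 61:80)] <- 1
  roc <- roc_curve(norm_profile(v), truth, thresholds = c(0.25, 0.5, 0.75))
  expect_equal(roc$auc, 1.0)

  set.seed(52)
  vr <- runif(10000)
  truth_r <- gi(seq(0, 9000, by = 1000), seq(500, 9500, by = 1000),
                label = "exon")
  roc_r <- roc_curve(norm_profile(vr), truth_r)
  expect_lt(abs(roc_r$auc - 0.5), 0.05)

  v2 <- runif(400)
  tr <- gi(c(50, 250), c(150, 330), label = "exon")
  a1 <- roc_curve(norm_profile(v2), tr, thresholds = sort(unique(v2)))$auc
  a2 <- roc_curve(norm_profile(1 - v2), tr,
                  thresholds = sort(unique(1 - v2)))$auc
  expect_equal(a1, 1 - a2, tolerance = 1e-9)

  expect_error(roc_curve(norm_profile(v2), tr, thresholds = 0.5),
               "at least two")
  full <- gi(0, 400, label = "exon")
  expect_error(roc_curve(norm_profile(v2), full), "degenerate")
})

test_that("trapezoidal AUC equals the brute-force Mann-Whitney statistic", {
  set.seed(53)
  for (n in c(200, 1000)) {
    v <- sample(seq(0.001, 0.999, length.out = n))  # all distinct
    truth <- gi(c(0, floor(n / 2)), c(floor(n / 4), floor(0.7 * n)),
                label = "exon")
    positive <- logical(n)
    positive[c(1:floor(n / 4), (floor(n / 2) + 1):floor(0.7 * n))] <- TRUE
    roc <- roc_curve(norm_profile(v), truth, thresholds = sort(unique(v)))
    expect_equal(roc$auc, mw_auc(v, positive), tolerance = 1e-9)
  }
})

test_that("segment-level ROC runs and stays within [0, 1]", {
  v <- numeric(500)
  v[101:200] <- seq(0.5, 1, length.out = 100)
  roc <- roc_curve(norm_profile(v), gi(100, 200, label = "exon"),
                   thresholds = c(0.3, 0.6, 0.9), level = "segment")
  expect_true(all(roc$points$tpr >= 0 & roc$points$tpr <= 1))
  expect_true(roc$auc >= 0 && roc$auc <= 1)
})

test_that("SNR in dB follows the closed form", {
  truth <- gi(10, 20, label = "exon")
  v <- rep(1, 50)
  expect_equal(snr_db(norm_profile(v), truth), 0)

  v2 <- rep(0.01, 50); v2[11:20] <- 1
  expect_equal(snr_db(numeric_signal("x", v2, "energy"), truth), 20)

  v3 <- rep(1, 50); v3[11:20] <- 256.06
  expect_equal(snr_db(numeric_signal("x", v3, "energy"), truth),
               10 * log10(256.06), tolerance = 1e-9)
  expect_equal(round(10 * log10(256.06), 4), 24.0834)

  v4 <- numeric(50); v4[11:20] <- 1
  expect_warning(inf <- snr_db(numeric_signal("x", v4, "energy"), truth),
                 "infinite")
  expect_identical(inf, Inf)
  expect_error(snr_db(norm_profile(v), gi(integer(), integer())), "empty")
  expect_error(snr_db(norm_profile(v), gi(0, 50, label = "exon")),
               "whole sequence")
})
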