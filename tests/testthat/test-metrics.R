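test_that("AUC matches the pairwise definition and handles ties", {
  expect_equal(compute_auc(c(0.9, 0.8), c(0.2, 0.1)), 1.0)
  expect_equal(compute_auc(rep(0.5, 4), rep(0.5, 3)), 0.5)
  expect_equal(compute_auc(c(0.9, 0.4), c(0.6, 0.1)), 0.75)  # 3 of 4 pairs
  expect_error(compute_auc(numeric(0), 1), "empty")

  set.seed(101)
  for (i in 1:200) {
    n1 <- sample(1:50, 1); n0 <- sample(1:50, 1)
    pos <- round(runif(n1), 2)   # rounding forces ties
    neg <- round(runif(n0), 2)
    expect_equal(compute_auc(pos, neg), auc_brute(pos, neg))
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(303)
  for (i in 1:20) {
    pos <- runif(sample(5:80, 1))
    neg <- runif(sample(5:80, 1))
    ref <- as.numeric(pROC::auc(
      response = c(rep(1, length(pos)), rep(0, length(neg))),
      predictor = c(pos, neg), quiet = TRUE, direction = "<"
    ))
    expect_equal(compute_auc(pos, neg), ref, tolerance = 1e-10)
  }
})

test_that("TSS and Kappa follow their confusion-matrix formulas", {
  expect_equal(compute_tss(tp = 5, fp = 0, tn = 5, fn = 0), 1.0)
  expect_equal(compute_tss(tp = 0, fp = 5, tn = 0, fn = 5), -1.0)
  expect_equal(compute_tss(tp = 3, fp = 2, tn = 2, fn = 1), 0.25)
  expect_error(compute_tss(tp = 0, fp = 1, tn = 1, fn = 0), "margin")

  expect_equal(compute_kappa(tp = 50, fp = 0, tn = 50, fn = 0), 1.0)
  expect_equal(compute_kappa(tp = 50, fp = 50, tn = 0, fn = 0), 0.0)
  expect_equal(compute_kappa(tp = 40, fp = 10, tn = 40, fn = 10), 0.6)
  expect_warning(k <- compute_kappa(tp = 5, fp = 0, tn = 0, fn = 0), "p_e")
  expect_equal(k, 0)
  expect_error(compute_kappa(0, 0, 0, 0), "empty")
})

test_that("kappa never exceeds 1 and equals TSS for balanced margins", {
  set.seed(77)
  for (i in 1:100) {
    cc <- sample(0:30, 4, replace = TRUE)
    if (cc[1] + cc[4] == 0 || cc[3] + cc[2] == 0) next
    k <- suppressWarnings(compute_kappa(cc[1], cc[2], cc[3], cc[4]))
    expect_lte(k, 1)
  }
  # balanced class margins: tp + fn = tn + fp
  for (i in 1:50) {
    m <- sample(1:30, 1)
    tp <- sample(0:m, 1); fp <- sample(0:m, 1)
    expect_equal(
      compute_kappa(tp, fp, m - fp, m - tp),
      compute_tss(tp, fp, m - fp, m - tp)
    )
  }
})

test_that("TSS-max threshold selection equals an exhaustive scan", {
  sel <- select_tss_threshold(c(0.8, 0.6), c(0.4, 0.2))
  expect_equal(sel$threshold, 0.5)
  expect_equal(sel$tss, 1.0)

  tie <- select_tss_threshold(0.7, 0.7)
  expect_equal(tie$threshold, 0)
  expect_equal(tie$tss, 0)

  mid <- select_tss_threshold(c(0.9, 0.2), c(0.8, 0.1))
  expect_equal(mid$tss, 0.5)
  expect_equal(mid$threshold, 0.15)   # smallest argmax midpoint

  set.seed(55)
  for (i in 1:50) {
    pos <- round(runif(sample(2:30, 1)), 2)
    neg <- round(runif(sample(2:30, 1)), 2)
    sel <- select_tss_threshold(pos, neg)
    scan <- tss_scan(pos, neg)
    expect_equal(sel$tss, scan$tss, tolerance = 1e-9)
    # argmax property: selected TSS >= TSS at every dense-grid point
    expect_gte(sel$tss + 1e-12, scan$tss)
  }
})

test_that("AUC performance classes follow the printed bins", {
  expect_identical(classify_performance(1.000), "Perfect")
  expect_identical(classify_performance(0.913), "Excellent")
  expect_identical(classify_performance(0.462), "Random")
  expect_identical(
    classify_performance(c(0.999, 0.99, 0.989, 0.9, 0.899, 0.8, 0.7, 0.6, 0.5, 0.499)),
    c("Near-perfect", "Near-perfect", "Excellent", "Excellent", "Very Good",
      "Very Good", "Good", "Fair", "Poor", "Random")
  )
  expect_error(classify_performance(1.2), "\\[0, 1\\]")
})

test_that("cohort summaries reproduce count-derived percentages", {
  # 69-species cohort with class counts 3/14/28/16/5/1/1/1
  auc <- c(rep(1.000, 3), rep(0.995, 14), rep(0.95, 28), rep(0.85, 16),
           rep(0.75, 5), 0.65, 0.55, 0.45)
  sm <- tibble::tibble(species_id = sprintf("s%02d", seq_along(auc)),
                       auc = auc, tss = auc - 0.1, kappa = auc - 0.3)
  out <- summarize_performance(sm)
  expect_identical(out$class_table$n, c(3L, 14L, 28L, 16L, 5L, 1L, 1L, 1L))
  expect_equal(out$class_table$pct,
               c(4.3, 20.3, 40.6, 23.2, 7.2, 1.4, 1.4, 1.4))
  expect_equal(out$share_auc_ge_0.8, 88.4)
  expect_equal(sum(out$class_table$pct), 100, tolerance = 0.3)

  single <- summarize_performance(tibble::tibble(species_id = "x", auc = 0.91))
  expect_equal(single$class_table$pct[single$class_table$class == "Excellent"], 100)

  # 27 of 69 in one bucket is 39.1%
  mix <- tibble::tibble(species_id = sprintf("s%02d", 1:69),
                        auc = c(rep(0.95, 27), rep(0.85, 42)))
  out2 <- summarize_performance(mix)
  expect_equal(out2$class_table$pct[out2$class_table$class == "Excellent"], 39.1)
})
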