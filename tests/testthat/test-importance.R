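vars6 <- c("BIO1", "BIO2", "BIO3", "BIO12", "BIO13", "BIO14")

test_that("permutation importance finds the driving variable", {
  g <- tiny_grid(16, seed = 21)
  x <- extract_predictors(g, mask_cells(g))
  cut <- median(x$BIO1)
  set.seed(13)
  idx <- sample(nrow(x), 240)
  d <- dplyr::mutate(x[idx, ], label = as.integer(BIO1 > cut))
  split <- sample(nrow(d), 160)
  model <- stacksdm:::fit_rf(d[split, ], vars6, rf_config(), seed = 3)
  mda <- permutation_importance(model, d[-split, ], vars6,
                                n_shuffles = 10, seed = 4)
  expect_named(mda, vars6)
  expect_identical(names(which.max(mda)), "BIO1")
  expect_gt(mda["BIO1"], max(mda[setdiff(vars6, "BIO1")]))

  # constant column: permutation is the identity, MDA exactly zero
  d0 <- dplyr::mutate(d, BIO3 = 7)
  m0 <- stacksdm:::fit_rf(d0[split, ], vars6, rf_config(), seed = 3)
  mda0 <- permutation_importance(m0, d0[-split, ], vars6, seed = 4)
  expect_identical(unname(mda0["BIO3"]), 0)

  expect_error(
    permutation_importance(model, dplyr::mutate(d[-split, ], label = 1), vars6),
    "both classes"
  )
})

test_that("pure-noise labels give near-zero importance everywhere", {
  g <- tiny_grid(16, seed = 23)
  x <- extract_predictors(g, mask_cells(g)[1:200, ])
  set.seed(13)
  d <- dplyr::mutate(x, label = sample(rep(0:1, 100)))
  split <- sample(200, 140)
  model <- stacksdm:::fit_rf(d[split, ], vars6, rf_config(), seed = 13)
  mda <- permutation_importance(model, d[-split, ], vars6,
                                n_shuffles = 10, seed = 13)
  expect_true(all(abs(mda) <= 0.1))
})

test_that("normalisation clips negatives and ranks deterministically", {
  raw <- c(BIO1 = 0.3, BIO2 = -0.1, BIO3 = 0.05,
           BIO12 = 0, BIO13 = 0, BIO14 = 0)
  prof <- normalize_and_rank(raw, "a")
  expect_equal(prof$normalized,
               c(0.3, 0, 0.05, 0, 0, 0) / 0.35, tolerance = 1e-12)
  expect_equal(sum(prof$normalized), 1, tolerance = 1e-9)
  expect_identical(prof$rank[prof$variable == "BIO1"], 1L)
  expect_true("negative_mda_clipped" %in% attr(prof, "flags"))

  zero <- normalize_and_rank(setNames(rep(0, 6), vars6), "z")
  expect_equal(zero$normalized, rep(1 / 6, 6))
  expect_true("uninformative" %in% attr(zero, "flags"))
  expect_identical(zero$rank, 1:6)   # tie-break follows the fixed order

  equal <- normalize_and_rank(setNames(rep(0.2, 6), vars6), "e")
  expect_identical(equal$rank, 1:6)

  set.seed(5)
  for (i in 1:25) {
    p <- normalize_and_rank(setNames(rnorm(6), vars6), "r")
    expect_setequal(p$rank, 1:6)
    expect_equal(sum(p$normalized), 1, tolerance = 1e-9)
  }
})

test_that("top-three patterns partition into the three types", {
  expect_identical(classify_pattern(c("BIO1", "BIO2", "BIO3")),
                   "Temperature-centered")
  expect_identical(classify_pattern(c("BIO12", "BIO13", "BIO14")),
                   "Precipitation-centered")
  expect_identical(classify_pattern(c("BIO14", "BIO3", "BIO2")), "Mixed")
  expect_error(classify_pattern(c("BIO1", "BIO2")), "length")
})

test_that("cohort importance summaries reproduce count arithmetic", {
  # engineer 69 profiles: 27 led by BIO1, the rest led by BIO14
  mk <- function(id, first) {
    raw <- setNames(rep(0.01, 6), vars6)
    raw[first] <- 1
    normalize_and_rank(raw, id)
  }
  profs <- c(
    lapply(1:27, \(i) mk(sprintf("a%02d", i), "BIO1")),
    lapply(1:42, \(i) mk(sprintf("b%02d", i), "BIO14"))
  )
  s <- summarize_importance(profs)
  expect_identical(s$n_species, 69L)
  fr <- s$first_rank
  expect_equal(fr$pct[fr$variable == "BIO1"], 39.1)
  expect_identical(fr$n[fr$variable == "BIO14"], 42L)
  expect_equal(sum(fr$n), 69L)
  gs <- s$group_split
  expect_equal(gs$pct[gs$group == "temperature"], 39.1)
  expect_equal(gs$pct[gs$group == "precipitation"], 60.9)
  # mean ranks across the six variables always average to 3.5
  expect_equal(mean(s$mean_rank$mean_rank), 3.5)
  expect_equal(sum(s$patterns$n), 69L)

  one <- summarize_importance(list(mk("solo", "BIO2")))
  expect_equal(one$first_rank$pct[one$first_rank$variable == "BIO2"], 100)
  expect_identical(one$mean_rank$mean_rank,
                   as.numeric(mk("solo", "BIO2")$rank))

  # BIO14 ranks (1, 2, 6) across three species average to 3
  p1 <- mk("x1", "BIO14")
  raw2 <- setNames(c(1, 0.5, 0.4, 0.3, 0.2, 0.6), vars6)   # BIO14 second
  p2 <- normalize_and_rank(raw2, "x2")
  raw3 <- setNames(c(1, 0.5, 0.4, 0.3, 0.2, 0.01), vars6)  # BIO14 last
  p3 <- normalize_and_rank(raw3, "x3")
  expect_identical(p2$rank[p2$variable == "BIO14"], 2L)
  expect_identical(p3$rank[p3$variable == "BIO14"], 6L)
  s3 <- summarize_importance(list(p1, p2, p3))
  expect_equal(s3$mean_rank$mean_rank[s3$mean_rank$variable == "BIO14"], 3)
})
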