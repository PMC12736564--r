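test_that("pseudo-absence sampling is matched, disjoint, and seeded", {
  g <- tiny_grid(12, seed = 2, mask_fraction = 0.9)
  occ <- mask_cells(g)[1:10, ]
  pa <- sample_pseudo_absences(g, occ, seed = 3)
  expect_identical(nrow(pa), 10L)
  expect_identical(nrow(dplyr::distinct(pa)), 10L)
  expect_identical(nrow(dplyr::inner_join(pa, occ, by = c("row", "col"))), 0L)
  expect_identical(sample_pseudo_absences(g, occ, seed = 3), pa)

  # a pool of exactly n candidates is returned whole
  pool <- mask_cells(g)
  occ_all <- pool[-(1:5), ]
  got <- sample_pseudo_absences(g, occ_all, n = 5, seed = 1)
  expect_identical(dplyr::arrange(got, row, col),
                   dplyr::arrange(pool[1:5, ], row, col))
  expect_error(sample_pseudo_absences(g, occ_all, n = 6, seed = 1),
               "candidate cells")
})

test_that("the forest separates a perfectly separable rule in-sample", {
  g <- tiny_grid(16, seed = 5)
  cells <- mask_cells(g)
  x <- extract_predictors(g, cells)
  cut <- median(x$BIO1)
  set.seed(9)
  idx <- sample(nrow(x), 120)
  train <- dplyr::mutate(x[idx, ], label = as.integer(BIO1 > cut))
  surf <- fit_predict(train, g, rf_config(seed = 4))
  expect_s3_class(surf, "suitability_surface")
  p <- surf$values[cbind(train$row, train$col)]
  expect_gt(min(p[train$label == 1]), max(p[train$label == 0]))
  expect_true(all(surf$values >= 0 & surf$values <= 1, na.rm = TRUE))

  expect_error(fit_predict(dplyr::mutate(train, label = 1), g), "single class")
})

test_that("permuted labels and constant predictors give chance-level output", {
  g <- tiny_grid(16, seed = 11)
  cells <- mask_cells(g)[1:200, ]
  x <- extract_predictors(g, cells)
  set.seed(11)
  train <- dplyr::mutate(x, label = sample(rep(0:1, 100)))
  test_idx <- sample(nrow(train), 60)
  model <- stacksdm:::fit_rf(train[-test_idx, ],
                             c("BIO1", "BIO2", "BIO3", "BIO12", "BIO13", "BIO14"),
                             rf_config(), seed = 11)
  p_train <- stacksdm:::predict_prob(model, train[-test_idx, ])
  p_test <- stacksdm:::predict_prob(model, train[test_idx, ])
  auc_in <- compute_auc(p_train[train$label[-test_idx] == 1],
                        p_train[train$label[-test_idx] == 0])
  auc_out <- compute_auc(p_test[train$label[test_idx] == 1],
                         p_test[train$label[test_idx] == 0])
  expect_lt(auc_out, 0.7)
  expect_gt(auc_out, 0.3)

  const <- dplyr::mutate(train,
                         dplyr::across(dplyr::starts_with("BIO"), \(v) 1))
  surf <- fit_predict(const, g, rf_config(seed = 2))
  p <- surf$values[!is.na(surf$values)]
  expect_true(all(abs(p - 0.5) <= 0.05 + 1e-9))
})

test_that("cross-validation is reproducible and flags tiny species", {
  g <- tiny_grid(20, seed = 3)
  sp <- narrow_species(g, "BIO1", seed = 4, n = 30, id = "cv")
  cfg <- rf_config(n_repetitions = 2, seed = 8)
  a <- cross_validate(sp$presence_cells, g, cfg, species_id = "cv")
  b <- cross_validate(sp$presence_cells, g, cfg, species_id = "cv")
  expect_identical(a$records, b$records)
  expect_identical(a$threshold, b$threshold)
  expect_identical(a$importance_raw, b$importance_raw)
  expect_identical(nrow(a$records), 2L * 5L)
  expect_true(all(a$records$auc >= 0 & a$records$auc <= 1))
  expect_true(all(abs(a$records$tss) <= 1))

  tiny <- mask_cells(g)[c(1, 50, 200), ]
  flagged <- cross_validate(tiny, g, rf_config(n_repetitions = 2, seed = 1),
                            species_id = "tiny")
  expect_true("reduced_folds" %in% flagged$flags)
  expect_gt(nrow(flagged$records), 0)
  g_rec <- glance(flagged)
  expect_identical(g_rec$flags, "reduced_folds")
})

test_that("training sets are exactly class balanced in every repetition", {
  g <- tiny_grid(16, seed = 6)
  sp <- narrow_species(g, "BIO14", seed = 7, n = 24, id = "bal")
  cv <- cross_validate(sp$presence_cells, g,
                       rf_config(n_repetitions = 3, seed = 2),
                       species_id = "bal")
  balance <- cv$pooled |>
    dplyr::group_by(repetition) |>
    dplyr::summarise(n1 = sum(label == 1), n0 = sum(label == 0))
  expect_true(all(balance$n1 == 24 & balance$n0 == 24))
})

test_that("mean suitability is the average over repetitions and moves with warming", {
  g <- tiny_grid(20, seed = 9)
  # cold-adapted: optimum well below the median temperature
  vals <- g$layers$BIO1[g$mask]
  sp <- generate_virtual_species(
    g, list(BIO1 = response_gaussian(quantile(vals, 0.15), 0.3 * sd(vals))),
    n_presences = 60, detection_noise = 0.05, seed = 10, species_id = "cold"
  )
  hot <- generate_scenario(g, delta_temp = 4, label = "hot")
  cfg <- rf_config(n_repetitions = 3, seed = 5)
  surf <- predict_mean_suitability(sp$presence_cells, g,
                                   target_grids = list(g, hot),
                                   config = cfg, species_id = "cold")
  expect_named(surf, c("baseline", "hot"))
  expect_identical(surf$baseline$n_repetitions, 3L)
  expect_true(all(surf$baseline$values >= 0 & surf$baseline$values <= 1,
                  na.rm = TRUE))
  expect_lt(mean(surf$hot$values, na.rm = TRUE),
            mean(surf$baseline$values, na.rm = TRUE))

  # single repetition equals one direct fit with the same derived seed
  cfg1 <- rf_config(n_repetitions = 1, seed = 5)
  s1 <- predict_mean_suitability(sp$presence_cells, g, list(g),
                                 config = cfg1, species_id = "cold")
  s1b <- predict_mean_suitability(sp$presence_cells, g, list(g),
                                  config = cfg1, species_id = "cold")
  expect_identical(s1$baseline$values, s1b$baseline$values)
})
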