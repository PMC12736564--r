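#' Random-Forest configuration
#'
#' Hyperparameters of the suitability models and the repeated
#' cross-validation protocol: 500 trees, 2 candidate variables per split,
#' 10 repetitions of stratified 5-fold cross-validation, with pseudo-absences
#' resampled independently in every repetition. Remaining Random-Forest
#' settings (tree depth, minimum node size) stay at the library defaults and
#' are recorded in the run manifest.
#'
#' @param n_tree number of trees.
#' @param m_try candidate variables per split (must not exceed the predictor
#'   count at fit time).
#' @param n_repetitions cross-validation repetitions.
#' @param n_folds folds per repetition (>= 2).
#' @param seed integer pipeline seed; per-repetition seeds are derived via
#'   [derive_seed()].
#' @return an `rf_config` list.
#' @export
rf_config <- function(n_tree = 500, m_try = 2, n_repetitions = 10,
                      n_folds = 5, seed = 1) {
  stopifnot(n_tree >= 1, m_try >= 1, n_repetitions >= 1, n_folds >= 2)
  structure(list(n_tree = as.integer(n_tree), m_try = as.integer(m_try),
                 n_repetitions = as.integer(n_repetitions),
                 n_folds = as.integer(n_folds), seed = as.integer(seed)),
            class = "rf_config")
}

#' Matched pseudo-absence sample
#'
#' Draws pseudo-absence cells uniformly across the masked study area,
#' matching the presence count one-to-one (the matched design keeps every
#' training set exactly class-balanced). Known presence cells are excluded by
#' default: sampling a presence as an absence injects label noise; set
#' `exclude_presences = FALSE` for fully unconstrained background sampling.
#'
#' @param grid a [climate_grid()].
#' @param presence_cells tibble `row`, `col` of presence cells.
#' @param n number of pseudo-absences; defaults to the presence count.
#' @param seed integer seed.
#' @param exclude_presences drop presence cells from the candidate pool.
#' @return tibble `row`, `col` with `n` distinct cells.
#' @export
sample_pseudo_absences <- function(grid, presence_cells,
                                   n = nrow(presence_cells), seed,
                                   exclude_presences = TRUE) {
  stopifnot(inherits(grid, "climate_grid"), n >= 1)
  if (missing(seed)) stop("a seed is required")
  pool <- mask_cells(grid)
  if (exclude_presences) {
    pool <- dplyr::anti_join(pool, tibble::as_tibble(presence_cells),
                             by = c("row", "col"))
  }
  if (n > nrow(pool)) {
    stop(sprintf("requested %d pseudo-absences but only %d candidate cells",
                 n, nrow(pool)))
  }
  set.seed(as.integer(seed))
  pool[sample(nrow(pool), n), ]
}

# fit a probability forest on a labelled training tibble
fit_rf <- function(train, variables, config, seed) {
  y <- factor(train$label, levels = c(0, 1))
  if (length(unique(train$label)) < 2) {
    stop("training data contains a single class")
  }
  if (config$m_try > length(variables)) {
    stop("m_try exceeds the number of predictors")
  }
  # a forest has no valid split when every predictor is constant; predict
  # the class prevalence instead of handing the degenerate case to the
  # split search
  if (all(vapply(variables, \(v) length(unique(train[[v]])) <= 1, TRUE))) {
    return(structure(list(prevalence = mean(train$label == 1)),
                     class = "prevalence_model"))
  }
  set.seed(as.integer(seed))
  randomForest::randomForest(
    x = as.data.frame(train[variables]), y = y,
    ntree = config$n_tree, mtry = config$m_try
  )
}

predict_prob <- function(model, newdata) {
  if (inherits(model, "prevalence_model")) {
    return(rep(model$prevalence, nrow(newdata)))
  }
  unname(stats::predict(model, newdata = as.data.frame(newdata),
                        type = "prob")[, "1"])
}

#' Fit a Random Forest and predict suitability on a grid
#'
#' Fits a class-balanced probability forest on the labelled training set and
#' returns the fraction-of-trees suitability prediction on every masked cell
#' of the target grid. Deterministic for a fixed `config$seed`.
#'
#' @param train tibble with a 0/1 `label` column plus predictor columns.
#' @param target_grid a [climate_grid()] to predict on.
#' @param config an [rf_config()].
#' @param variables predictor codes; defaults to the predictor columns
#'   present in `train`.
#' @return a `suitability_surface`: list with `values` (matrix in `[0, 1]`,
#'   `NA` off-mask), `label` (the grid's label), `species_id` = `NA`,
#'   `n_repetitions` = 1.
#' @export
fit_predict <- function(train, target_grid, config = rf_config(),
                        variables = NULL) {
  stopifnot(is.data.frame(train), "label" %in% names(train))
  if (is.null(variables)) {
    variables <- intersect(bio_variables(), names(train))
  }
  model <- fit_rf(train, variables, config, config$seed)
  cells <- mask_cells(target_grid)
  x <- extract_predictors(target_grid, cells, variables)
  p <- predict_prob(model, x[variables])
  suitability_surface(p, cells, target_grid, species_id = NA_character_,
                      n_repetitions = 1L)
}

suitability_surface <- function(p, cells, grid, species_id, n_repetitions) {
  values <- matrix(NA_real_, grid$n_rows, grid$n_cols)
  values[cbind(cells$row, cells$col)] <- p
  structure(
    list(species_id = species_id, label = grid$label, values = values,
         n_repetitions = as.integer(n_repetitions)),
    class = "suitability_surface"
  )
}

#' @export
print.suitability_surface <- function(x, ...) {
  cat(sprintf("<suitability_surface> species %s on '%s' (%d repetition(s) averaged)\n",
              x$species_id, x$label, x$n_repetitions))
  cat(sprintf("suitability range %.3f-%.3f over %d masked cells\n",
              min(x$values, na.rm = TRUE), max(x$values, na.rm = TRUE),
              sum(!is.na(x$values))))
  invisible(x)
}

# stratified fold assignment keeping the 1:1 class balance in every fold
assign_folds <- function(labels, n_folds) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    fold[idx[sample.int(length(idx))]] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

#' Repeated stratified cross-validation of a species model
#'
#' For each repetition a fresh matched pseudo-absence sample is drawn, the
#' combined presence/absence set is split into class-stratified folds, and a
#' forest fit on the training folds is scored on the held-out fold: AUC
#' (rank-sum), plus TSS and Kappa at the fold-specific TSS-maximising
#' threshold. Species occupying fewer cells than the fold count fall back to
#' `n_folds = n_cells` (minimum 2) and are flagged `"reduced_folds"`.
#' Permutation importance (mean decrease in held-out accuracy over
#' `n_shuffles` shuffles per variable) is accumulated over all folds and
#' repetitions. The whole procedure is bit-reproducible for a fixed
#' `config$seed`.
#'
#' @param occ_cells tibble `row`, `col` of the species' presence cells.
#' @param grid baseline [climate_grid()] supplying the predictors and the
#'   pseudo-absence pool.
#' @param config an [rf_config()].
#' @param variables predictor codes (post-screening subset), default all six.
#' @param species_id identifier carried into the records.
#' @param compute_importance also accumulate permutation importance.
#' @param n_shuffles shuffles per variable for the importance estimate.
#' @return a `cv_report`: list with `species_id`, `records` (tibble
#'   `species_id`, `repetition`, `fold`, `auc`, `tss`, `kappa`, `threshold`),
#'   `pooled` (tibble `repetition`, `fold`, `label`, `score` of all held-out
#'   predictions), `importance_raw` (named mean MDA per variable, or `NULL`),
#'   `threshold` (TSS-max threshold on the pooled held-out predictions),
#'   `flags` (character), `config`, `variables`.
#' @export
cross_validate <- function(occ_cells, grid, config = rf_config(),
                           variables = bio_variables(),
                           species_id = "species", compute_importance = TRUE,
                           n_shuffles = 10) {
  occ_cells <- dplyr::distinct(tibble::as_tibble(occ_cells)[c("row", "col")])
  n_pres <- nrow(occ_cells)
  if (n_pres < 2) stop("at least two presence cells are required")
  variables <- intersect(bio_variables(), variables)

  flags <- character(0)
  n_folds <- config$n_folds
  if (n_pres < n_folds) {
    n_folds <- max(2L, n_pres)
    flags <- c(flags, "reduced_folds")
  }

  pres_x <- extract_predictors(grid, occ_cells, variables)
  records <- list()
  pooled <- list()
  mda_acc <- NULL
  n_mda <- 0L

  for (r in seq_len(config$n_repetitions)) {
    rep_seed <- derive_seed(config$seed, paste0(species_id, "/rep/", r))
    pa <- sample_pseudo_absences(grid, occ_cells, n = n_pres, seed = rep_seed)
    abs_x <- extract_predictors(grid, pa, variables)
    data <- dplyr::bind_rows(
      dplyr::mutate(pres_x, label = 1),
      dplyr::mutate(abs_x, label = 0)
    )
    set.seed(derive_seed(rep_seed, "folds"))
    fold <- assign_folds(data$label, n_folds)

    for (f in seq_len(n_folds)) {
      train <- data[fold != f, ]
      test <- data[fold == f, ]
      if (length(unique(test$label)) < 2 || length(unique(train$label)) < 2) {
        next   # degenerate split (possible only at extreme presence counts)
      }
      model <- fit_rf(train, variables, config,
                      seed = derive_seed(rep_seed, paste0("fit/", f)))
      score <- predict_prob(model, test[variables])
      sp <- score[test$label == 1]
      sn <- score[test$label == 0]
      sel <- select_tss_threshold(sp, sn)
      cc <- confusion_at(sp, sn, sel$threshold)
      records[[length(records) + 1]] <- tibble::tibble(
        species_id = species_id, repetition = r, fold = f,
        auc = compute_auc(sp, sn), tss = sel$tss,
        kappa = compute_kappa(cc["tp"], cc["fp"], cc["tn"], cc["fn"]),
        threshold = sel$threshold
      )
      pooled[[length(pooled) + 1]] <- tibble::tibble(
        repetition = r, fold = f, label = test$label, score = score
      )
      if (compute_importance) {
        mda <- permutation_importance(
          model, test, variables = variables, n_shuffles = n_shuffles,
          seed = derive_seed(rep_seed, paste0("mda/", f))
        )
        mda_acc <- if (is.null(mda_acc)) mda else mda_acc + mda
        n_mda <- n_mda + 1L
      }
    }
  }

  records <- dplyr::bind_rows(records)
  pooled <- dplyr::bind_rows(pooled)
  if (nrow(records) == 0) stop("cross-validation produced no usable folds")
  thr <- select_tss_threshold(pooled$score[pooled$label == 1],
                              pooled$score[pooled$label == 0])
  structure(
    list(species_id = species_id, records = records, pooled = pooled,
         importance_raw = if (n_mda > 0) mda_acc / n_mda else NULL,
         threshold = thr$threshold, flags = flags,
         config = config, variables = variables),
    class = "cv_report"
  )
}

#' @export
print.cv_report <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<cv_report> species %s: %d fold records over %d repetition(s)\n",
              x$species_id, nrow(x$records), x$config$n_repetitions))
  cat(sprintf("mean AUC %.3f (%s), TSS %.3f, Kappa %.3f; TSS-max threshold %.3f\n",
              g$auc, g$performance_class, g$tss, g$kappa, g$threshold))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Mean suitability surfaces across repetitions
#'
#' For each repetition, fits a forest on the full presence set plus that
#' repetition's fresh pseudo-absence sample, then predicts every supplied
#' climate grid; the final surface per grid is the arithmetic per-cell mean
#' over repetitions. Future grids are predicted with the same
#' baseline-fitted models (the models are never refit on future climate).
#'
#' @param occ_cells tibble `row`, `col` of presence cells.
#' @param grid baseline [climate_grid()] used for fitting.
#' @param target_grids list of [climate_grid()]s to predict (often the
#'   baseline itself plus scenario grids); defaults to the baseline only.
#' @param config an [rf_config()].
#' @param variables predictor codes.
#' @param species_id identifier.
#' @return named list of `suitability_surface` objects, one per target grid,
#'   keyed by grid label.
#' @export
predict_mean_suitability <- function(occ_cells, grid, target_grids = list(grid),
                                     config = rf_config(),
                                     variables = bio_variables(),
                                     species_id = "species") {
  occ_cells <- dplyr::distinct(tibble::as_tibble(occ_cells)[c("row", "col")])
  if (nrow(occ_cells) < 2) stop("at least two presence cells are required")
  variables <- intersect(bio_variables(), variables)
  pres_x <- dplyr::mutate(extract_predictors(grid, occ_cells, variables), label = 1)

  cell_list <- purrr::map(target_grids, mask_cells)
  x_list <- purrr::map2(target_grids, cell_list,
                        \(g, cl) extract_predictors(g, cl, variables)[variables])
  acc <- purrr::map(x_list, \(x) numeric(nrow(x)))

  for (r in seq_len(config$n_repetitions)) {
    rep_seed <- derive_seed(config$seed, paste0(species_id, "/rep/", r))
    pa <- sample_pseudo_absences(grid, occ_cells, n = nrow(occ_cells),
                                 seed = rep_seed)
    train <- dplyr::bind_rows(
      pres_x,
      dplyr::mutate(extract_predictors(grid, pa, variables), label = 0)
    )
    model <- fit_rf(train, variables, config,
                    seed = derive_seed(rep_seed, "fit/full"))
    for (i in seq_along(x_list)) {
      acc[[i]] <- acc[[i]] + predict_prob(model, x_list[[i]])
    }
  }

  out <- purrr::pmap(
    list(target_grids, cell_list, acc),
    function(g, cl, a) {
      suitability_surface(a / config$n_repetitions, cl, g,
                          species_id = species_id,
                          n_repetitions = config$n_repetitions)
    }
  )
  names(out) <- purrr::map_chr(target_grids, "label")
  out
}

#' @exportS3Method tibble::as_tibble
as_tibble.suitability_surface <- function(x, ...) {
  idx <- which(!is.na(x$values), arr.ind = TRUE)
  tibble::tibble(
    species_id = x$species_id, label = x$label,
    row = as.integer(idx[, 1]), col = as.integer(idx[, 2]),
    suitability = x$values[idx]
  ) |> dplyr::arrange(.data$col, .data$row)
}
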