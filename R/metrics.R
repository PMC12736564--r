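#' Area under the ROC curve (rank-sum formulation)
#'
#' AUC is the probability that a randomly drawn presence scores above a
#' randomly drawn absence, with ties counted half. Computed with the
#' Mann-Whitney rank-sum identity, which equals brute-force pair counting.
#'
#' @param scores_pos,scores_neg numeric suitability scores of the presence
#'   and absence side; both must be non-empty.
#' @return AUC in `[0, 1]`.
#' @export
compute_auc <- function(scores_pos, scores_neg) {
  n1 <- length(scores_pos); n0 <- length(scores_neg)
  if (n1 == 0 || n0 == 0) stop("AUC undefined: one side is empty")
  r <- rank(c(scores_pos, scores_neg), ties.method = "average")
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' True Skill Statistic from confusion counts
#'
#' `TSS = sensitivity + specificity - 1`, i.e. the true positive rate minus
#' the false positive rate; ranges over `[-1, 1]`.
#'
#' @param tp,fp,tn,fn nonnegative confusion-matrix counts; both margins
#'   (`tp + fn` and `tn + fp`) must be positive for the rates to exist.
#' @return TSS.
#' @export
compute_tss <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  if (tp + fn == 0 || tn + fp == 0) {
    stop("TSS undefined: a confusion-matrix margin is empty")
  }
  unname(tp / (tp + fn) + tn / (tn + fp) - 1)
}

#' Cohen's Kappa from confusion counts
#'
#' Chance-corrected agreement: `kappa = (p_o - p_e) / (1 - p_e)` with observed
#' agreement `p_o = (tp + tn) / n` and chance agreement `p_e` from the class
#' margins. When `p_e = 1` (both raters constant and equal) kappa is defined
#' as 0 with a warning.
#'
#' @inheritParams compute_tss
#' @return kappa in `[-1, 1]`.
#' @export
compute_kappa <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  n <- tp + fp + tn + fn
  if (n == 0) stop("kappa undefined: empty confusion matrix")
  p_o <- (tp + tn) / n
  p_e <- ((tp + fn) * (tp + fp) + (tn + fp) * (tn + fn)) / n^2
  if (abs(1 - p_e) < .Machine$double.eps^0.5) {
    warning("chance agreement p_e = 1; kappa defined as 0")
    return(0)
  }
  unname((p_o - p_e) / (1 - p_e))
}

confusion_at <- function(scores_pos, scores_neg, threshold) {
  c(tp = sum(scores_pos >= threshold), fn = sum(scores_pos < threshold),
    tn = sum(scores_neg < threshold), fp = sum(scores_neg >= threshold))
}

#' TSS-maximising threshold
#'
#' Scans the candidate set (midpoints between consecutive distinct sorted
#' scores, plus 0 and 1), classifying `score >= threshold` as presence, and
#' returns the smallest candidate achieving the maximum TSS — the smallest
#' argmax makes the selection reproducible under ties. The candidate set is
#' exhaustive: TSS is piecewise constant between observed scores, so this
#' equals a dense grid scan.
#'
#' @inheritParams compute_auc
#' @return list with `threshold` and `tss` (TSS at that threshold).
#' @export
select_tss_threshold <- function(scores_pos, scores_neg) {
  if (!length(scores_pos) || !length(scores_neg)) {
    stop("threshold selection undefined: one side is empty")
  }
  s <- sort(unique(c(scores_pos, scores_neg)))
  candidates <- sort(unique(c(0, if (length(s) > 1) (s[-1] + s[-length(s)]) / 2, 1)))
  tss <- vapply(candidates, function(t) {
    cc <- confusion_at(scores_pos, scores_neg, t)
    compute_tss(cc["tp"], cc["fp"], cc["tn"], cc["fn"])
  }, numeric(1))
  best <- which(tss >= max(tss) - 1e-12)[1]
  list(threshold = candidates[best], tss = tss[best])
}

#' Performance class of a mean AUC
#'
#' Bins follow the conventional grading of discrimination ability:
#' Perfect (exactly 1), Near-perfect `[0.99, 1)`, Excellent `[0.90, 0.99)`,
#' Very Good `[0.80, 0.90)`, Good `[0.70, 0.80)`, Fair `[0.60, 0.70)`,
#' Poor `[0.50, 0.60)`, Random below 0.5. Half-open decimal bins cover all of
#' `[0, 1]`.
#'
#' @param mean_auc numeric vector of AUC values in `[0, 1]`.
#' @return character vector of class labels.
#' @export
classify_performance <- function(mean_auc) {
  if (any(!is.finite(mean_auc)) || any(mean_auc < 0 | mean_auc > 1)) {
    stop("AUC values must lie in [0, 1]")
  }
  dplyr::case_when(
    mean_auc == 1               ~ "Perfect",
    mean_auc >= 0.99            ~ "Near-perfect",
    mean_auc >= 0.90            ~ "Excellent",
    mean_auc >= 0.80            ~ "Very Good",
    mean_auc >= 0.70            ~ "Good",
    mean_auc >= 0.60            ~ "Fair",
    mean_auc >= 0.50            ~ "Poor",
    TRUE                        ~ "Random"
  )
}

performance_class_levels <- function() {
  c("Perfect", "Near-perfect", "Excellent", "Very Good",
    "Good", "Fair", "Poor", "Random")
}

#' Cohort performance summary
#'
#' Aggregates per-species cross-validation means into the cohort view:
#' species counts and percentages per performance class (percentages rounded
#' half-up to one decimal, so they may not sum to exactly 100), overall
#' mean/SD/min/max of each metric, and the share of species with mean AUC at
#' or above 0.8.
#'
#' @param species_metrics data frame with one row per species: `species_id`,
#'   `auc`, and optionally `tss`, `kappa` (per-species CV means).
#' @return list with `class_table` (tibble `class`, `n`, `pct`),
#'   `metric_table` (tibble `metric`, `mean`, `sd`, `min`, `max`),
#'   `n_species`, and `share_auc_ge_0.8` (percentage).
#' @export
summarize_performance <- function(species_metrics) {
  stopifnot(is.data.frame(species_metrics), nrow(species_metrics) >= 1,
            all(c("species_id", "auc") %in% names(species_metrics)))
  sm <- tibble::as_tibble(species_metrics)
  n <- nrow(sm)
  cls <- factor(classify_performance(sm$auc), levels = performance_class_levels())
  class_table <- tibble::tibble(class = performance_class_levels()) |>
    dplyr::left_join(
      tibble::tibble(class = as.character(cls)) |> dplyr::count(.data$class),
      by = "class"
    ) |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L),
                  pct = round_half_up(100 * .data$n / !!n, 1))
  metrics <- intersect(c("auc", "tss", "kappa"), names(sm))
  metric_table <- sm |>
    tidyr::pivot_longer(dplyr::all_of(metrics), names_to = "metric") |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(mean = mean(.data$value), sd = stats::sd(.data$value),
                     min = min(.data$value), max = max(.data$value),
                     .groups = "drop") |>
    dplyr::arrange(match(.data$metric, c("auc", "tss", "kappa")))
  list(
    class_table = class_table,
    metric_table = metric_table,
    n_species = n,
    share_auc_ge_0.8 = round_half_up(100 * mean(sm$auc >= 0.8), 1)
  )
}
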