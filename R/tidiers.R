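#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' Tidy a cross-validation report
#'
#' @param x a `cv_report`.
#' @param ... unused.
#' @return the per-fold record tibble (`species_id`, `repetition`, `fold`,
#'   `auc`, `tss`, `kappa`, `threshold`).
#' @export
tidy.cv_report <- function(x, ...) x$records

#' One-row summary of a cross-validation report
#'
#' Means, SDs and ranges of AUC/TSS/Kappa across all folds and repetitions,
#' the pooled TSS-max threshold, the AUC performance class, and any flags.
#'
#' @param x a `cv_report`.
#' @param ... unused.
#' @return a one-row tibble.
#' @export
glance.cv_report <- function(x, ...) {
  r <- x$records
  tibble::tibble(
    species_id = x$species_id,
    n_records = nrow(r),
    auc = mean(r$auc), auc_sd = stats::sd(r$auc),
    auc_min = min(r$auc), auc_max = max(r$auc),
    tss = mean(r$tss), tss_sd = stats::sd(r$tss),
    kappa = mean(r$kappa), kappa_sd = stats::sd(r$kappa),
    threshold = x$threshold,
    performance_class = classify_performance(mean(r$auc)),
    flags = paste(x$flags, collapse = ";")
  )
}

#' Tidy a pipeline result
#'
#' @param x a `pipeline_result`.
#' @param ... unused.
#' @return the per-species metrics tibble.
#' @export
tidy.pipeline_result <- function(x, ...) x$species_metrics

#' One-row cohort summary of a pipeline result
#'
#' @param x a `pipeline_result`.
#' @param ... unused.
#' @return one-row tibble with species counts, cohort metric means, and the
#'   share of species at mean AUC >= 0.8.
#' @export
glance.pipeline_result <- function(x, ...) {
  sm <- x$species_metrics
  tibble::tibble(
    n_species = x$manifest$n_species_defined,
    n_retained = x$manifest$n_species_retained,
    auc = mean(sm$auc), tss = mean(sm$tss), kappa = mean(sm$kappa),
    share_auc_ge_0.8 = x$performance_summary$share_auc_ge_0.8
  )
}
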