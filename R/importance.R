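#' Permutation importance (mean decrease in accuracy)
#'
#' For each predictor, the held-out classification accuracy of the fitted
#' forest is compared with its mean accuracy over `n_shuffles` random
#' permutations of that predictor's column; the drop is the variable's raw
#' MDA. A variable that is constant across the held-out rows permutes to
#' itself, so its MDA is exactly zero. Held-out data (rather than the
#' out-of-bag sample) keeps the importance aligned with the cross-validation
#' design.
#'
#' @param model a fitted `randomForest` classifier.
#' @param holdout tibble with a 0/1 `label` column and the predictor columns;
#'   must contain both classes.
#' @param variables predictor codes to assess.
#' @param n_shuffles permutations per variable.
#' @param seed integer seed.
#' @return named numeric vector of raw MDA per variable.
#' @export
permutation_importance <- function(model, holdout, variables = bio_variables(),
                                   n_shuffles = 10, seed = 1) {
  stopifnot(is.data.frame(holdout), "label" %in% names(holdout),
            n_shuffles >= 1)
  variables <- intersect(bio_variables(), intersect(variables, names(holdout)))
  if (length(unique(holdout$label)) < 2) {
    stop("held-out data must contain both classes")
  }
  y <- holdout$label
  x <- as.data.frame(holdout[variables])
  accuracy <- function(d) {
    mean((predict_prob(model, d) >= 0.5) == (y == 1))
  }
  acc0 <- accuracy(x)
  set.seed(as.integer(seed))
  n <- nrow(x)
  mda <- vapply(variables, function(v) {
    if (length(unique(x[[v]])) <= 1) return(0)   # permutation is the identity
    # stack all shuffles into one frame so the forest is queried once
    xp <- x[rep(seq_len(n), n_shuffles), , drop = FALSE]
    xp[[v]] <- as.vector(vapply(seq_len(n_shuffles),
                                function(s) x[[v]][sample.int(n)],
                                numeric(n)))
    hit <- (predict_prob(model, xp) >= 0.5) == rep(y == 1, n_shuffles)
    acc0 - mean(vapply(seq_len(n_shuffles),
                       function(s) mean(hit[((s - 1) * n + 1):(s * n)]),
                       numeric(1)))
  }, numeric(1))
  mda
}

#' Normalise raw importances and rank variables 1-6
#'
#' Negative raw MDA values (a shuffled column scoring better than the intact
#' one, which happens for uninformative variables by chance) are clipped to
#' zero, then the six values are divided by their total so the normalised
#' importances sum to one. If every clipped value is zero the profile is
#' uniform (1/6 each) and flagged `"uninformative"`. Ranks run from 1 (most
#' important) to 6; ties are broken by the fixed variable order BIO1, BIO2,
#' BIO3, BIO12, BIO13, BIO14 so ranks are always a permutation of 1..6.
#'
#' @param raw_mda named numeric of length 6 (one value per bioclim variable).
#' @param species_id identifier carried into the profile.
#' @return an `importance_profile`: tibble `species_id`, `variable`, `raw`,
#'   `normalized`, `rank` (6 rows, canonical variable order) with attributes
#'   `top3` (character, best first), `pattern` (see [classify_pattern()]) and
#'   `flags`.
#' @export
normalize_and_rank <- function(raw_mda, species_id = "species") {
  vars <- bio_variables()
  stopifnot(length(raw_mda) == length(vars))
  if (is.null(names(raw_mda))) names(raw_mda) <- vars
  stopifnot(setequal(names(raw_mda), vars))
  raw <- as.numeric(raw_mda[vars])

  clipped <- pmax(raw, 0)
  flags <- character(0)
  if (any(raw < 0)) flags <- c(flags, "negative_mda_clipped")
  total <- sum(clipped)
  if (total > 0) {
    normalized <- clipped / total
  } else {
    normalized <- rep(1 / 6, 6)
    flags <- c(flags, "uninformative")
  }
  # descending value; ties fall back on the fixed variable order
  ord <- order(-normalized, seq_along(vars))
  rank <- integer(6)
  rank[ord] <- seq_len(6)

  out <- tibble::tibble(species_id = species_id, variable = vars,
                        raw = raw, normalized = normalized, rank = rank)
  attr(out, "top3") <- vars[ord[1:3]]
  attr(out, "pattern") <- classify_pattern(vars[ord[1:3]])
  attr(out, "flags") <- flags
  class(out) <- c("importance_profile", class(out))
  out
}

#' Top-three variable pattern type
#'
#' Classifies the composition of a species' three highest-ranked variables:
#' all temperature variables (BIO1-BIO3) gives "Temperature-centered", all
#' precipitation variables (BIO12-BIO14) gives "Precipitation-centered", and
#' any mixture of the two groups gives "Mixed". The three classes are
#' exhaustive and mutually exclusive.
#'
#' @param top3 character vector of exactly three variable codes.
#' @return one of `"Temperature-centered"`, `"Precipitation-centered"`,
#'   `"Mixed"`.
#' @export
classify_pattern <- function(top3) {
  stopifnot(length(top3) == 3, all(top3 %in% bio_variables()),
            !anyDuplicated(top3))
  if (all(top3 %in% temperature_variables())) return("Temperature-centered")
  if (all(top3 %in% precipitation_variables())) return("Precipitation-centered")
  "Mixed"
}

pattern_levels <- function() {
  c("Temperature-centered", "Precipitation-centered", "Mixed")
}

#' Cohort importance summary
#'
#' From a stack of per-species importance profiles, tabulates how often each
#' variable ranks first (counts and one-decimal percentages), the mean rank
#' of each variable across species, the split of first ranks between the
#' temperature (BIO1-BIO3) and precipitation (BIO12-BIO14) groups, and the
#' counts of top-three pattern types.
#'
#' @param profiles either a list of `importance_profile` objects or a single
#'   long tibble with columns `species_id`, `variable`, `rank` (and
#'   optionally `normalized`).
#' @return list with `first_rank` (tibble `variable`, `n`, `pct`),
#'   `mean_rank` (tibble `variable`, `mean_rank`), `group_split` (tibble
#'   `group`, `n`, `pct`), `patterns` (tibble `pattern`, `n`, `pct`),
#'   `n_species`.
#' @export
summarize_importance <- function(profiles) {
  if (is.data.frame(profiles)) profiles <- list(profiles)
  long <- dplyr::bind_rows(lapply(profiles, tibble::as_tibble))
  stopifnot(all(c("species_id", "variable", "rank") %in% names(long)))
  n_sp <- dplyr::n_distinct(long$species_id)
  vars <- bio_variables()

  per_species <- long |>
    dplyr::group_by(.data$species_id) |>
    dplyr::summarise(
      first = .data$variable[.data$rank == 1],
      top3 = list(.data$variable[.data$rank <= 3]),
      .groups = "drop"
    ) |>
    dplyr::mutate(pattern = purrr::map_chr(.data$top3, classify_pattern))

  first_rank <- tibble::tibble(variable = vars) |>
    dplyr::left_join(dplyr::count(per_species, variable = .data$first),
                     by = "variable") |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L),
                  pct = round_half_up(100 * .data$n / n_sp, 1))

  mean_rank <- long |>
    dplyr::group_by(.data$variable) |>
    dplyr::summarise(mean_rank = mean(.data$rank), .groups = "drop") |>
    dplyr::arrange(match(.data$variable, vars))

  group_split <- per_species |>
    dplyr::mutate(group = dplyr::if_else(.data$first %in% temperature_variables(),
                                         "temperature", "precipitation")) |>
    dplyr::count(.data$group) |>
    tidyr::complete(group = c("temperature", "precipitation"),
                    fill = list(n = 0L)) |>
    dplyr::mutate(pct = round_half_up(100 * .data$n / n_sp, 1)) |>
    dplyr::arrange(dplyr::desc(.data$group == "temperature"))

  patterns <- tibble::tibble(pattern = pattern_levels()) |>
    dplyr::left_join(dplyr::count(per_species, .data$pattern), by = "pattern") |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L),
                  pct = round_half_up(100 * .data$n / n_sp, 1))

  list(first_rank = first_rank, mean_rank = mean_rank,
       group_split = group_split, patterns = patterns, n_species = n_sp)
}
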