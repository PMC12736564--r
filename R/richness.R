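#' Binarise a suitability surface at a species-specific threshold
#'
#' Cells at or above the threshold are predicted presences (the `>=`
#' convention keeps cells whose score equals a candidate threshold stable;
#' set `strict = TRUE` for a strict `>` cut). The threshold is estimated once
#' on baseline cross-validation data and applied unchanged to every scenario
#' surface.
#'
#' @param surface a `suitability_surface`.
#' @param threshold cutoff in `[0, 1]`.
#' @param strict use `>` instead of `>=`.
#' @return a `binary_range_map`: list with `species_id`, `label`, `presence`
#'   (logical matrix, `NA` off-mask), `threshold`.
#' @export
binarize <- function(surface, threshold, strict = FALSE) {
  stopifnot(inherits(surface, "suitability_surface"),
            threshold >= 0, threshold <= 1)
  presence <- if (strict) surface$values > threshold else surface$values >= threshold
  structure(
    list(species_id = surface$species_id, label = surface$label,
         presence = presence, threshold = threshold),
    class = "binary_range_map"
  )
}

#' @export
print.binary_range_map <- function(x, ...) {
  cat(sprintf("<binary_range_map> species %s on '%s': %d suitable of %d cells (threshold %.3f)\n",
              x$species_id, x$label, sum(x$presence, na.rm = TRUE),
              sum(!is.na(x$presence)), x$threshold))
  invisible(x)
}

map_dim <- function(map) dim(map$presence)

#' Stack binary range maps into a species-richness surface
#'
#' Richness is the per-cell count of species whose binarised range map
#' predicts presence. All maps must share the grid shape.
#'
#' @param maps list of `binary_range_map`s (may be empty, given `dims`).
#' @param label scenario tag for the surface; defaults to the first map's.
#' @param dims grid dimension, required only when `maps` is empty.
#' @return a `richness_surface`: list with `label`, `counts` (integer
#'   matrix; 0 on mask cells with no species, `NA` only where every map is
#'   `NA`), `n_species`.
#' @export
stack_richness <- function(maps, label = NULL, dims = NULL) {
  if (length(maps) == 0) {
    if (is.null(dims)) stop("dims is required when no maps are supplied")
    counts <- matrix(0L, dims[1], dims[2])
    return(structure(list(label = label %||% "empty", counts = counts,
                          n_species = 0L),
                     class = "richness_surface"))
  }
  d <- map_dim(maps[[1]])
  for (m in maps) {
    if (!identical(map_dim(m), d)) stop("range maps are on different grids")
  }
  counts <- matrix(0L, d[1], d[2])
  any_obs <- matrix(FALSE, d[1], d[2])
  for (m in maps) {
    counts <- counts + ifelse(is.na(m$presence), 0L, as.integer(m$presence))
    any_obs <- any_obs | !is.na(m$presence)
  }
  counts[!any_obs] <- NA_integer_
  structure(
    list(label = label %||% maps[[1]]$label, counts = counts,
         n_species = length(maps)),
    class = "richness_surface"
  )
}

#' @export
print.richness_surface <- function(x, ...) {
  cat(sprintf("<richness_surface> '%s': %d species stacked, cell richness %d-%d\n",
              x$label, x$n_species, min(x$counts, na.rm = TRUE),
              max(x$counts, na.rm = TRUE)))
  invisible(x)
}

#' @exportS3Method tibble::as_tibble
as_tibble.richness_surface <- function(x, ...) {
  idx <- which(!is.na(x$counts), arr.ind = TRUE)
  tibble::tibble(label = x$label, row = as.integer(idx[, 1]),
                 col = as.integer(idx[, 2]), richness = x$counts[idx]) |>
    dplyr::arrange(.data$col, .data$row)
}

#' Zone-level richness with the any-suitable-cell rule
#'
#' A species counts toward a zone if at least one grid cell inside the zone
#' is predicted suitable; the zone's mean cell richness is the mean of the
#' stacked per-cell counts over its cells. The any-cell rule makes zone
#' richness at least the maximum cell richness within the zone.
#'
#' @param maps list of `binary_range_map`s sharing the zone grid's shape.
#' @param zones a [zone_set()] aligned to the same grid.
#' @param scheme optional richness-class scheme; when given, a `class_label`
#'   column is appended via [bin_richness()].
#' @return tibble `zone_id`, `name`, `n_cells`, `n_species`,
#'   `mean_cell_richness` (one row per zone), plus `class_label` if `scheme`
#'   is supplied.
#' @export
zonal_richness <- function(maps, zones, scheme = NULL) {
  stopifnot(inherits(zones, "zone_set"))
  lab <- zones$zone_labels
  if (length(maps) > 0 && !identical(dim(lab), map_dim(maps[[1]]))) {
    stop("zones are not aligned to the range-map grid")
  }
  rich <- stack_richness(maps, dims = dim(lab))
  zc <- zone_cells(zones)
  per_zone <- zc |>
    dplyr::group_by(.data$zone_id, .data$name) |>
    dplyr::summarise(n_cells = dplyr::n(), .groups = "drop")

  n_species <- integer(nrow(per_zone))
  for (m in maps) {
    pres <- m$presence
    pres[is.na(pres)] <- FALSE
    hit <- zc |>
      dplyr::mutate(p = pres[cbind(.data$row, .data$col)]) |>
      dplyr::group_by(.data$zone_id) |>
      dplyr::summarise(any = any(.data$p), .groups = "drop")
    n_species <- n_species + as.integer(hit$any[match(per_zone$zone_id, hit$zone_id)])
  }

  counts <- rich$counts
  mean_rich <- zc |>
    dplyr::mutate(cnt = dplyr::coalesce(counts[cbind(.data$row, .data$col)], 0L)) |>
    dplyr::group_by(.data$zone_id) |>
    dplyr::summarise(mean_cell_richness = mean(.data$cnt), .groups = "drop")

  out <- per_zone |>
    dplyr::mutate(n_species = n_species) |>
    dplyr::left_join(mean_rich, by = "zone_id")
  if (!is.null(scheme)) {
    out <- dplyr::mutate(out, class_label = bin_richness(.data$n_species, scheme))
  }
  out
}

richness_schemes <- list(
  decadal = list(breaks = c(0, 10, 20, 30, 40),
                 labels = c("0-10", "10-20", "20-30", "30-40")),
  quintal = list(breaks = c(0, 5, 10, 15, 20, 25, 30),
                 labels = c("0-5", "5-10", "10-15", "15-20", "20-25", "25-30"))
)

#' Richness class of a species count
#'
#' Bins are half-open `[lo, hi)` with the top bin closed, which resolves the
#' overlap in conventionally printed class labels ("5-10, 10-15"): a count of
#' 10 falls in "10-15" (quintal) or "10-20" (decadal). Counts above the
#' scheme maximum are assigned to the top class with a warning.
#'
#' @param n_species integer vector of zone species counts.
#' @param scheme `"decadal"` (four 10-wide classes to 40) or `"quintal"`
#'   (six 5-wide classes to 30).
#' @return character vector of class labels (ordered factor levels available
#'   via `attr(, "levels")` on the scheme).
#' @export
bin_richness <- function(n_species, scheme = c("decadal", "quintal")) {
  scheme <- match.arg(scheme)
  sc <- richness_schemes[[scheme]]
  top <- sc$breaks[length(sc$breaks)]
  if (any(n_species > top)) {
    warning("richness count(s) above the '", scheme,
            "' scheme maximum; assigned to the top class")
  }
  idx <- findInterval(pmin(n_species, top), sc$breaks,
                      rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), length(sc$labels))
  sc$labels[idx]
}

#' Zone-level richness change between two scenarios
#'
#' @param baseline,future zone tables from [zonal_richness()] on the same
#'   [zone_set()].
#' @param scheme class scheme used for the transition matrix.
#' @return list with `deltas` (tibble `zone_id`, `name`, `n_baseline`,
#'   `n_future`, `delta`, `class_baseline`, `class_future`) and `transitions`
#'   (tibble `from`, `to`, `n` counting zones per class pair).
#' @export
richness_change <- function(baseline, future, scheme = c("decadal", "quintal")) {
  scheme <- match.arg(scheme)
  stopifnot(is.data.frame(baseline), is.data.frame(future))
  if (!setequal(baseline$zone_id, future$zone_id)) {
    stop("baseline and future tables cover different zones")
  }
  deltas <- dplyr::inner_join(
    dplyr::select(baseline, "zone_id", "name", n_baseline = "n_species"),
    dplyr::select(future, "zone_id", n_future = "n_species"),
    by = "zone_id"
  ) |>
    dplyr::mutate(
      delta = .data$n_future - .data$n_baseline,
      class_baseline = bin_richness(.data$n_baseline, scheme),
      class_future = bin_richness(.data$n_future, scheme)
    )
  transitions <- deltas |>
    dplyr::count(from = .data$class_baseline, to = .data$class_future)
  list(deltas = deltas, transitions = transitions)
}
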