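#' Snap occurrence points onto the grid
#'
#' Each point is assigned to the cell whose half-open square
#' `[edge, edge + cell_size)` contains it (so a point exactly on the
#' lower-left corner of a cell belongs to that cell, and a point on an upper
#' edge to the next cell). Points with non-finite coordinates, outside the
#' grid bounds, or falling on masked-out cells are treated as erroneous
#' records and dropped; the per-species drop count is attached as the
#' `"dropped"` attribute and reported via a message.
#'
#' @param points data frame with columns `species_id`, `x`, `y`.
#' @param grid a [climate_grid()].
#' @return tibble `species_id`, `row`, `col`, `n_points` (cell multiset:
#'   one row per occupied cell with its record count), with attribute
#'   `"dropped"` = tibble `species_id`, `n_dropped`.
#' @export
snap_to_grid <- function(points, grid) {
  stopifnot(is.data.frame(points),
            all(c("species_id", "x", "y") %in% names(points)),
            inherits(grid, "climate_grid"))
  pts <- tibble::as_tibble(points)
  if (nrow(pts) == 0) {
    out <- tibble::tibble(species_id = character(), row = integer(),
                          col = integer(), n_points = integer())
    attr(out, "dropped") <- tibble::tibble(species_id = character(),
                                           n_dropped = integer())
    return(out)
  }
  pts <- dplyr::mutate(
    pts,
    finite = is.finite(.data$x) & is.finite(.data$y),
    row = ifelse(.data$finite,
                 floor((.data$y - grid$origin[2]) / grid$cell_size) + 1, NA),
    col = ifelse(.data$finite,
                 floor((.data$x - grid$origin[1]) / grid$cell_size) + 1, NA),
    inside = .data$finite &
      .data$row >= 1 & .data$row <= grid$n_rows &
      .data$col >= 1 & .data$col <= grid$n_cols
  )
  pts$on_mask <- FALSE
  ok <- which(pts$inside)
  if (length(ok)) {
    pts$on_mask[ok] <- grid$mask[cbind(pts$row[ok], pts$col[ok])]
  }
  kept <- dplyr::filter(pts, .data$on_mask)
  dropped <- pts |>
    dplyr::group_by(.data$species_id) |>
    dplyr::summarise(n_dropped = sum(!.data$on_mask), .groups = "drop") |>
    dplyr::filter(.data$n_dropped > 0)
  if (nrow(dropped)) {
    message(sum(dropped$n_dropped),
            " occurrence record(s) dropped (non-finite, out of bounds, or off-mask)")
  }
  out <- kept |>
    dplyr::count(.data$species_id, .data$row, .data$col, name = "n_points") |>
    dplyr::mutate(row = as.integer(.data$row), col = as.integer(.data$col)) |>
    dplyr::arrange(.data$species_id, .data$row, .data$col)
  attr(out, "dropped") <- dropped
  out
}

#' Merge duplicate records within a cell
#'
#' Collapses the snapped cell multiset to one row per occupied cell per
#' species. Idempotent.
#'
#' @param cells tibble from [snap_to_grid()] (columns `species_id`, `row`,
#'   `col`, optionally `n_points`).
#' @return tibble `species_id`, `row`, `col` with distinct rows.
#' @export
deduplicate <- function(cells) {
  stopifnot(all(c("species_id", "row", "col") %in% names(cells)))
  tibble::as_tibble(cells) |>
    dplyr::distinct(.data$species_id, .data$row, .data$col) |>
    dplyr::arrange(.data$species_id, .data$row, .data$col)
}

#' Exclude species occupying too few grid cells
#'
#' Species present in fewer than `min_cells` independent grid cells are
#' excluded from modelling (single-cell occurrences cannot support
#' cross-validation and inflate apparent accuracy). The default of 2 keeps the
#' boundary case `n_cells == 2`.
#'
#' @param cells deduplicated tibble (`species_id`, `row`, `col`).
#' @param min_cells inclusion threshold; retained iff `n_cells >= min_cells`.
#' @return tibble of retained cells, with attribute `"report"` = tibble
#'   `species_id`, `n_cells`, `excluded`, `reason`.
#' @export
filter_min_cells <- function(cells, min_cells = 2) {
  stopifnot(min_cells >= 0)
  cells <- deduplicate(cells)
  report <- cells |>
    dplyr::count(.data$species_id, name = "n_cells") |>
    dplyr::mutate(
      excluded = .data$n_cells < min_cells,
      reason = ifelse(.data$excluded, "insufficient_cells", NA_character_)
    )
  kept <- dplyr::semi_join(cells,
                           dplyr::filter(report, !.data$excluded),
                           by = "species_id")
  attr(kept, "report") <- report
  kept
}

#' Full occurrence preparation: snap, deduplicate, filter
#'
#' @param points raw occurrence table (`species_id`, `x`, `y`).
#' @param grid a [climate_grid()].
#' @param min_cells inclusion threshold, default 2.
#' @return an `occurrence_set`: tibble `species_id`, `row`, `col` of retained
#'   presence cells, with attribute `"report"` = tibble `species_id`,
#'   `n_raw`, `n_dropped`, `n_cells`, `excluded`, `reason` covering every
#'   input species (also via [occurrence_report()]).
#' @export
prepare_occurrences <- function(points, grid, min_cells = 2) {
  snapped <- snap_to_grid(points, grid)
  dropped <- attr(snapped, "dropped")
  kept <- filter_min_cells(deduplicate(snapped), min_cells)
  rep0 <- attr(kept, "report")
  raw <- tibble::as_tibble(points) |>
    dplyr::count(.data$species_id, name = "n_raw")
  report <- raw |>
    dplyr::left_join(dropped, by = "species_id") |>
    dplyr::left_join(rep0, by = "species_id") |>
    dplyr::mutate(
      n_dropped = dplyr::coalesce(.data$n_dropped, 0L),
      n_cells = dplyr::coalesce(.data$n_cells, 0L),
      excluded = dplyr::coalesce(.data$excluded, TRUE),
      reason = dplyr::if_else(.data$excluded & is.na(.data$reason),
                              "insufficient_cells", .data$reason)
    )
  structure(kept, report = report, class = c("occurrence_set", class(kept)))
}

#' Preparation report of an occurrence set
#'
#' @param occ result of [prepare_occurrences()] or [filter_min_cells()].
#' @return the per-species report tibble.
#' @export
occurrence_report <- function(occ) {
  rep <- attr(occ, "report")
  if (is.null(rep)) stop("no preparation report attached")
  rep
}

#' Read an occurrence CSV (`species_id,x,y[,source]`)
#'
#' @param path file path.
#' @return tibble with `species_id` (character), `x`, `y` (double).
#' @export
read_occurrences <- function(path) {
  readr::read_csv(path, show_col_types = FALSE) |>
    dplyr::mutate(species_id = as.character(.data$species_id),
                  x = as.numeric(.data$x), y = as.numeric(.data$y))
}
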