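#' Zone partitions of a climate grid
#'
#' A `zone_set` assigns every masked cell of a grid to exactly one zone
#' (label 0 marks cells outside any zone, i.e. off-mask). Zones play the role
#' of reporting units such as municipalities or protected areas; they need not
#' be contiguous but must be non-empty.
#'
#' @param zone_labels integer matrix aligned to the grid; 0 = no zone.
#' @param names optional character vector named by zone id.
#' @param level reporting level tag, `"municipality"` or `"park"`.
#' @return an object of class `zone_set` with fields `zone_labels`,
#'   `zone_ids`, `names`, `level`.
#' @export
zone_set <- function(zone_labels, names = NULL, level = "municipality") {
  stopifnot(is.matrix(zone_labels))
  storage.mode(zone_labels) <- "integer"
  ids <- sort(unique(zone_labels[zone_labels > 0L]))
  if (!length(ids)) stop("zone_labels contains no zones")
  if (is.null(names)) {
    names <- stats::setNames(sprintf("zone_%02d", ids), ids)
  } else {
    if (!all(as.character(ids) %in% base::names(names))) {
      stop("names must cover every zone id")
    }
  }
  structure(list(zone_labels = zone_labels, zone_ids = ids,
                 names = names, level = level),
            class = "zone_set")
}

#' @export
print.zone_set <- function(x, ...) {
  cat(sprintf("<zone_set> %d zones (level '%s'), %d zoned cells\n",
              length(x$zone_ids), x$level, sum(x$zone_labels > 0)))
  invisible(x)
}

#' Partition a grid's mask into contiguous-ish zones
#'
#' Seeded region growth: `k_zones` seed cells are drawn uniformly from the
#' mask, then grown breadth-first over 4-neighbourhoods until every reachable
#' masked cell is assigned; masked cells in components that contain no seed
#' (e.g. offshore islands of the mask) are attached to the nearest seed by
#' Euclidean distance, so the zones always partition the mask exactly.
#' Deterministic per seed.
#'
#' @param grid a [climate_grid()].
#' @param k_zones number of zones, at most the masked-cell count.
#' @param seed integer seed.
#' @param level reporting level tag.
#' @return a [zone_set()].
#' @export
generate_zones <- function(grid, k_zones, seed, level = "municipality") {
  stopifnot(inherits(grid, "climate_grid"), k_zones >= 1)
  cells <- mask_cells(grid)
  if (k_zones > nrow(cells)) stop("k_zones exceeds the masked-cell count")
  set.seed(as.integer(seed))
  seeds <- cells[sample(nrow(cells), k_zones), ]

  lab <- matrix(0L, grid$n_rows, grid$n_cols)
  lab[cbind(seeds$row, seeds$col)] <- seq_len(k_zones)

  repeat {
    unassigned <- grid$mask & lab == 0L
    if (!any(unassigned)) break
    # pull each unassigned cell's 4-neighbour labels; adopt a random one
    idx <- which(unassigned, arr.ind = TRUE)
    adopted <- integer(nrow(idx))
    for (i in seq_len(nrow(idx))) {
      r <- idx[i, 1]; c <- idx[i, 2]
      nb <- c(
        if (r > 1) lab[r - 1, c] else 0L,
        if (r < grid$n_rows) lab[r + 1, c] else 0L,
        if (c > 1) lab[r, c - 1] else 0L,
        if (c < grid$n_cols) lab[r, c + 1] else 0L
      )
      nb <- nb[nb > 0L]
      if (length(nb)) adopted[i] <- nb[sample.int(length(nb), 1)]
    }
    if (all(adopted == 0L)) {
      # disconnected components without a seed: nearest seed wins
      for (i in seq_len(nrow(idx))) {
        d2 <- (seeds$row - idx[i, 1])^2 + (seeds$col - idx[i, 2])^2
        lab[idx[i, 1], idx[i, 2]] <- which.min(d2)
      }
      break
    }
    grew <- adopted > 0L
    lab[idx[grew, , drop = FALSE]] <- adopted[grew]
  }
  zone_set(lab, level = level)
}

#' Zones as a tibble of cells
#'
#' @param zones a [zone_set()].
#' @return tibble `zone_id`, `name`, `row`, `col`.
#' @export
zone_cells <- function(zones) {
  stopifnot(inherits(zones, "zone_set"))
  idx <- which(zones$zone_labels > 0L, arr.ind = TRUE)
  id <- zones$zone_labels[idx]
  tibble::tibble(
    zone_id = as.integer(id),
    name = unname(zones$names[as.character(id)]),
    row = as.integer(idx[, 1]), col = as.integer(idx[, 2])
  ) |> dplyr::arrange(.data$zone_id, .data$col, .data$row)
}
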