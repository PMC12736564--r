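#' Climate grids
#'
#' A `climate_grid` holds six bioclim-style layers (BIO1 annual mean
#' temperature, BIO2 mean diurnal range, BIO3 isothermality, BIO12 annual
#' precipitation, BIO13/BIO14 wettest/driest-month precipitation) on a uniform
#' cell grid with a land mask. Cells are indexed 1-based as `(row, col)`;
#' row 1 is the southernmost row and each cell covers the half-open square
#' `[edge, edge + cell_size)` in both coordinates, so a point on a cell's
#' lower or left edge belongs to that cell and a point on its upper or right
#' edge to the next one. Masked-out cells carry `NA` in every layer and are
#' excluded from all statistics.
#'
#' @param layers named list of numeric matrices (codes BIO1, BIO2, BIO3,
#'   BIO12, BIO13, BIO14), all of identical dimension.
#' @param mask logical matrix of the same dimension; `TRUE` marks analyzable
#'   (land) cells.
#' @param cell_size edge length of a cell in map units (nominal km).
#' @param origin numeric length-2, `(x0, y0)` of the lower-left corner of cell
#'   `(1, 1)`.
#' @param label scenario/period tag, e.g. `"baseline-2010"`.
#' @return an object of class `climate_grid`.
#' @export
climate_grid <- function(layers, mask, cell_size = 1, origin = c(0, 0),
                         label = "baseline") {
  stopifnot(is.list(layers), length(layers) >= 1, !is.null(names(layers)))
  dims <- dim(layers[[1]])
  for (nm in names(layers)) {
    if (!identical(dim(layers[[nm]]), dims)) {
      stop("layer ", nm, " does not share the grid dimension")
    }
  }
  stopifnot(is.logical(mask), identical(dim(mask), dims), any(mask))
  for (nm in names(layers)) layers[[nm]][!mask] <- NA_real_
  pr <- intersect(c("BIO12", "BIO13", "BIO14"), names(layers))
  for (nm in pr) {
    if (any(layers[[nm]][mask] < 0, na.rm = TRUE)) {
      stop("precipitation layer ", nm, " has negative cells")
    }
  }
  if (all(c("BIO13", "BIO14") %in% names(layers)) &&
      any((layers$BIO13 - layers$BIO14)[mask] < -1e-9, na.rm = TRUE)) {
    stop("BIO13 < BIO14 on masked cells violates the wet/dry nesting invariant")
  }
  if (all(c("BIO12", "BIO13") %in% names(layers)) &&
      any((layers$BIO12 - layers$BIO13)[mask] < -1e-9, na.rm = TRUE)) {
    stop("BIO12 < BIO13 on masked cells violates the annual/monthly nesting invariant")
  }
  structure(
    list(
      n_rows = dims[1], n_cols = dims[2], cell_size = cell_size,
      origin = as.numeric(origin), layers = layers, mask = mask, label = label
    ),
    class = "climate_grid"
  )
}

#' @export
print.climate_grid <- function(x, ...) {
  cat(sprintf("<climate_grid '%s'> %d x %d cells (%.0f%% masked in), cell size %g\n",
              x$label, x$n_rows, x$n_cols, 100 * mean(x$mask), x$cell_size))
  cat("layers:", paste(names(x$layers), collapse = ", "), "\n")
  invisible(x)
}

#' Generate a synthetic bioclim climate grid
#'
#' Builds a spatially autocorrelated climate surface that emulates
#' temperate-monsoon conditions: BIO1 combines a monotone south-to-north
#' cooling gradient with smoothed noise; the precipitation layers are built
#' driest-month first so that the nesting `BIO12 >= BIO13 >= BIO14 >= 0`
#' holds cell-wise by construction; BIO3 (isothermality) is derived as
#' `BIO2 / annual_range * 100` from BIO2 and an internally generated annual
#' temperature range, hence bounded in (0, 100]. Spatial autocorrelation comes
#' from Gaussian smoothing of white noise with kernel width
#' `spatial_corr_length`. Output is bit-reproducible for a fixed seed.
#'
#' @param n_rows,n_cols grid dimension, each at least 8.
#' @param spatial_corr_length smoothing kernel width in cells.
#' @param seed integer seed (mandatory).
#' @param mask_fraction fraction of cells kept as land; the mask is carved
#'   from a smoothed noise field so it forms coherent coastline-like blobs.
#'   Use 1 for a fully analyzable grid.
#' @param cell_size,origin,label passed to [climate_grid()].
#' @return a [climate_grid()].
#' @export
generate_climate <- function(n_rows, n_cols, spatial_corr_length = 6, seed,
                             mask_fraction = 0.9, cell_size = 1,
                             origin = c(0, 0), label = "baseline") {
  if (n_rows < 8 || n_cols < 8) stop("grid dimensions must be at least 8 x 8")
  stopifnot(mask_fraction > 0, mask_fraction <= 1)
  if (missing(seed)) stop("a seed is required")
  set.seed(as.integer(seed))
  f <- function() random_field(n_rows, n_cols, spatial_corr_length)

  lat <- matrix(rep((seq_len(n_rows) - 1) / max(1, n_rows - 1), n_cols),
                n_rows, n_cols)

  bio1 <- 16 - 12 * lat + 1.5 * f()                 # degC, cooler northwards
  bio2 <- pmax(9 + 1.2 * f(), 2)                    # degC diurnal range
  annual_range <- pmax(28 + 3 * f(), bio2 + 1)      # internal annual range
  bio3 <- pmax(pmin(bio2 / annual_range * 100, 100), 1e-6)
  bio14 <- pmax(35 + 12 * f(), 0)                   # mm, driest month
  bio13 <- bio14 + pmax(280 + 60 * f(), 0)          # mm, wettest month
  bio12 <- bio13 + pmax(800 + 150 * f(), 0)         # mm, annual

  if (mask_fraction < 1) {
    mf <- random_field(n_rows, n_cols, spatial_corr_length)
    mask <- mf >= stats::quantile(mf, 1 - mask_fraction)
  } else {
    mask <- matrix(TRUE, n_rows, n_cols)
  }

  climate_grid(
    layers = list(BIO1 = bio1, BIO2 = bio2, BIO3 = bio3,
                  BIO12 = bio12, BIO13 = bio13, BIO14 = bio14),
    mask = mask, cell_size = cell_size, origin = origin, label = label
  )
}

#' Derive a warming/drying scenario grid from a baseline grid
#'
#' Shifts BIO1 by `delta_temp` on every masked cell and multiplies the three
#' precipitation layers by `precip_factor` (a positive ratio), which preserves
#' their nesting ordering. BIO2 and BIO3 are left unchanged. An optional
#' latitudinal ramp adds `lat_ramp` degrees extra warming at the northernmost
#' row, interpolated linearly from zero at the southern edge.
#'
#' @param base a [climate_grid()].
#' @param delta_temp uniform temperature shift in degC.
#' @param precip_factor multiplicative precipitation change, > 0.
#' @param label tag for the derived grid.
#' @param lat_ramp extra warming (degC) at the northern edge; default 0.
#' @return a [climate_grid()] sharing the base mask and geometry.
#' @export
generate_scenario <- function(base, delta_temp = 0, precip_factor = 1,
                              label = "scenario", lat_ramp = 0) {
  stopifnot(inherits(base, "climate_grid"), precip_factor > 0)
  lat <- matrix(rep((seq_len(base$n_rows) - 1) / max(1, base$n_rows - 1),
                    base$n_cols), base$n_rows, base$n_cols)
  layers <- base$layers
  layers$BIO1 <- layers$BIO1 + delta_temp + lat_ramp * lat
  for (nm in intersect(c("BIO12", "BIO13", "BIO14"), names(layers))) {
    layers[[nm]] <- layers[[nm]] * precip_factor
  }
  climate_grid(layers, base$mask, base$cell_size, base$origin, label)
}

#' Cells of the analysis mask as a tibble
#'
#' @param grid a [climate_grid()].
#' @return tibble with columns `row`, `col` listing every masked-in cell in
#'   column-major order.
#' @export
mask_cells <- function(grid) {
  stopifnot(inherits(grid, "climate_grid"))
  idx <- which(grid$mask, arr.ind = TRUE)
  tibble::tibble(row = as.integer(idx[, 1]), col = as.integer(idx[, 2])) |>
    dplyr::arrange(.data$col, .data$row)
}

#' Map coordinates of cell centers
#'
#' @param grid a [climate_grid()].
#' @param cells tibble with `row`, `col`.
#' @return `cells` with `x`, `y` center coordinates appended.
#' @export
cell_centers <- function(grid, cells) {
  check_cells(cells, grid, require_mask = FALSE)
  dplyr::mutate(
    tibble::as_tibble(cells),
    x = grid$origin[1] + (.data$col - 0.5) * grid$cell_size,
    y = grid$origin[2] + (.data$row - 0.5) * grid$cell_size
  )
}

#' @exportS3Method tibble::as_tibble
as_tibble.climate_grid <- function(x, ...) {
  cells <- mask_cells(x)
  vals <- purrr::map(x$layers, \(m) m[cbind(cells$row, cells$col)])
  dplyr::bind_cols(cell_centers(x, cells), tibble::as_tibble(vals))
}
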