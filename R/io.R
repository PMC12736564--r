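# Plain-text raster interchange: ESRI ASCII grid (.asc), one file per layer.
# Rows are written north to south as the format requires; values use full
# double precision so a write/read round trip is exact.

write_asc_matrix <- function(m, path, cell_size, origin, nodata = -9999) {
  m[is.na(m)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(m)),
    paste("nrows", nrow(m)),
    paste("xllcorner", format(origin[1], digits = 17)),
    paste("yllcorner", format(origin[2], digits = 17)),
    paste("cellsize", format(cell_size, digits = 17)),
    paste("NODATA_value", nodata)
  ), con)
  for (r in rev(seq_len(nrow(m)))) {
    writeLines(paste(format(m[r, ], digits = 17), collapse = " "), con)
  }
  invisible(path)
}

read_asc_matrix <- function(path) {
  hdr <- readLines(path, n = 6)
  kv <- strsplit(hdr, "\\s+")
  h <- stats::setNames(as.numeric(vapply(kv, `[`, "", 2)),
                       tolower(vapply(kv, `[`, "", 1)))
  vals <- scan(path, skip = 6, quiet = TRUE)
  m <- matrix(vals, nrow = h[["nrows"]], ncol = h[["ncols"]], byrow = TRUE)
  m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
  m[m == h[["nodata_value"]]] <- NA_real_
  list(values = m, cell_size = h[["cellsize"]],
       origin = c(h[["xllcorner"]], h[["yllcorner"]]))
}

#' Write a climate grid as ASCII raster layers
#'
#' One `.asc` file per layer, named `<label>_<BIOx>.asc`, in the ESRI ASCII
#' grid format (plain text with a 6-line header), readable by standard GIS
#' tools.
#'
#' @param grid a [climate_grid()].
#' @param dir output directory (created if absent).
#' @return invisibly, the written paths.
#' @export
write_climate_grid <- function(grid, dir) {
  stopifnot(inherits(grid, "climate_grid"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- purrr::imap_chr(grid$layers, function(m, nm) {
    p <- file.path(dir, paste0(grid$label, "_", nm, ".asc"))
    write_asc_matrix(m, p, grid$cell_size, grid$origin)
    p
  })
  invisible(paths)
}

#' Read a climate grid from ASCII raster layers
#'
#' @param dir directory holding `<label>_<BIOx>.asc` files.
#' @param label scenario tag (file-name prefix).
#' @param variables layer codes to read.
#' @return a [climate_grid()]; the mask is the set of non-NODATA cells.
#' @export
read_climate_grid <- function(dir, label, variables = bio_variables()) {
  layers <- list()
  geom <- NULL
  for (v in variables) {
    p <- file.path(dir, paste0(label, "_", v, ".asc"))
    if (!file.exists(p)) stop("missing layer file: ", p)
    a <- read_asc_matrix(p)
    layers[[v]] <- a$values
    geom <- a
  }
  mask <- !is.na(layers[[1]])
  climate_grid(layers, mask, cell_size = geom$cell_size,
               origin = geom$origin, label = label)
}

#' Write a zone set as an integer ASCII raster plus a CSV name map
#'
#' @param zones a [zone_set()].
#' @param dir output directory.
#' @param cell_size,origin grid geometry for the raster header.
#' @return invisibly, the two written paths.
#' @export
write_zones <- function(zones, dir, cell_size = 1, origin = c(0, 0)) {
  stopifnot(inherits(zones, "zone_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rp <- file.path(dir, "zones.asc")
  lab <- zones$zone_labels
  lab[lab == 0L] <- NA_integer_
  write_asc_matrix(lab, rp, cell_size, origin)
  cp <- file.path(dir, "zone_names.csv")
  readr::write_csv(tibble::tibble(zone_id = zones$zone_ids,
                                  name = unname(zones$names[as.character(zones$zone_ids)]),
                                  level = zones$level), cp)
  invisible(c(rp, cp))
}

#' Write a suitability surface as an ASCII raster
#'
#' @param surface a `suitability_surface`.
#' @param dir output directory.
#' @param cell_size,origin grid geometry for the raster header.
#' @return invisibly, the written path.
#' @export
write_suitability <- function(surface, dir, cell_size = 1, origin = c(0, 0)) {
  stopifnot(inherits(surface, "suitability_surface"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- file.path(dir, paste0(surface$species_id, "_", surface$label, ".asc"))
  write_asc_matrix(surface$values, p, cell_size, origin)
  invisible(p)
}
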