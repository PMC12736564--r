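#' Extract per-cell predictor vectors
#'
#' @param grid a [climate_grid()].
#' @param cells tibble with `row`, `col`; every cell must lie inside the
#'   analysis mask (a masked-out request is an error naming the cell).
#' @param variables variable codes to extract, default all six in canonical
#'   order BIO1, BIO2, BIO3, BIO12, BIO13, BIO14.
#' @return tibble `row`, `col`, then one column per variable.
#' @export
extract_predictors <- function(grid, cells, variables = bio_variables()) {
  stopifnot(inherits(grid, "climate_grid"))
  variables <- intersect(bio_variables(), variables)   # canonical column order
  missing_l <- setdiff(variables, names(grid$layers))
  if (length(missing_l)) stop("grid lacks layers: ", paste(missing_l, collapse = ", "))
  check_cells(cells, grid, require_mask = TRUE)
  cells <- tibble::as_tibble(cells)[, c("row", "col")]
  vals <- purrr::map(grid$layers[variables],
                     \(m) m[cbind(cells$row, cells$col)])
  dplyr::bind_cols(cells, tibble::as_tibble(vals))
}

#' Pairwise-correlation collinearity screen
#'
#' Computes pairwise Pearson correlations over the masked baseline cells and
#' applies a greedy pass in priority order: a variable is accepted iff its
#' absolute correlation with every already-accepted variable is at most
#' `threshold`. The default priority order BIO1 > BIO14 > BIO2 > BIO12 >
#' BIO3 > BIO13 reflects the relative ecological importance of coarse thermal
#' and dry-season moisture gradients for temperate plant distributions. A
#' constant layer has undefined correlations; these are treated as 0 with a
#' warning, so constant layers are always retainable.
#'
#' @param grid a [climate_grid()].
#' @param threshold maximum tolerated absolute pairwise correlation
#'   (default 0.7).
#' @param priority ordered character vector of variable codes.
#' @return an object of class `collinearity_screen`: list with `retained`
#'   (character, in canonical variable order), `correlations` (tibble `var1`,
#'   `var2`, `r` for all unordered pairs), `threshold`, `priority`.
#' @export
screen_collinearity <- function(grid, threshold = 0.7,
                                priority = c("BIO1", "BIO14", "BIO2",
                                             "BIO12", "BIO3", "BIO13")) {
  stopifnot(inherits(grid, "climate_grid"), threshold >= 0)
  priority <- intersect(priority, names(grid$layers))
  if (length(priority) < 2) stop("at least two variables are required")
  cells <- mask_cells(grid)
  if (nrow(cells) < 3) stop("at least three masked cells are required")
  x <- as.matrix(extract_predictors(grid, cells, priority)[priority])

  constant <- apply(x, 2, \(v) stats::sd(v) == 0)
  if (any(constant)) {
    warning("constant layer(s) ", paste(priority[constant], collapse = ", "),
            ": correlations undefined, treated as 0")
  }
  cm <- suppressWarnings(stats::cor(x))
  cm[!is.finite(cm)] <- 0
  diag(cm) <- 1

  retained <- character(0)
  for (v in priority) {
    if (all(abs(cm[v, retained]) <= threshold)) retained <- c(retained, v)
  }

  pairs <- utils::combn(priority, 2)
  correlations <- tibble::tibble(
    var1 = pairs[1, ], var2 = pairs[2, ],
    r = cm[t(pairs)]
  )
  structure(
    list(retained = intersect(bio_variables(), retained),
         correlations = correlations,
         threshold = threshold, priority = priority),
    class = "collinearity_screen"
  )
}

#' @export
print.collinearity_screen <- function(x, ...) {
  cat(sprintf("<collinearity_screen> |r| <= %.2f: retained %d of %d variables\n",
              x$threshold, length(x$retained), length(x$priority)))
  cat("retained:", paste(x$retained, collapse = ", "), "\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.collinearity_screen <- function(x, ...) x$correlations
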