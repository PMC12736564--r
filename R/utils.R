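# Internal helpers shared across modules.

#' Derive a reproducible child seed from a pipeline seed and a string key
#'
#' One pipeline seed drives every stochastic stage; per-species and
#' per-repetition seeds are derived as `seed + hash(key)` so that adding or
#' removing a species never perturbs the draws of another. The hash is a
#' 31-ary polynomial accumulation of the UTF-8 bytes of `key`, reduced modulo
#' 2^31 - 1, so derived seeds always fit a 32-bit integer.
#'
#' @param seed integer pipeline seed.
#' @param key character scalar identifying the consumer (e.g.
#'   `"sp03/rep/2"`).
#' @return an integer seed in `[1, 2^31 - 1]`.
#' @export
derive_seed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(key), length(key) == 1)
  m <- 2147483647
  h <- 0
  for (b in utf8ToInt(key)) h <- (h * 31 + b) %% m
  as.integer((abs(seed) %% m + h) %% m + 1)
}

# round half away from zero (base round() is banker's rounding)
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Gaussian smoothing of a matrix (separable 1-D convolution, edge-replicated
# padding). sigma in cells; sigma <= 0 returns the input unchanged.
gauss_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  conv1 <- function(v) {
    vp <- c(rep(v[1], r), v, rep(v[length(v)], r))
    out <- stats::filter(vp, k, sides = 2)
    as.numeric(out)[(r + 1):(r + length(v))]
  }
  m2 <- apply(m, 2, conv1)            # smooth down columns
  t(apply(m2, 1, conv1))              # then along rows
}

# standardized smoothed white-noise field: mean 0, sd 1 over all cells
random_field <- function(n_rows, n_cols, sigma) {
  z <- gauss_smooth(matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols), sigma)
  (z - mean(z)) / stats::sd(z)
}

# canonical bioclim variable order used throughout the package
bio_variables <- function() c("BIO1", "BIO2", "BIO3", "BIO12", "BIO13", "BIO14")

temperature_variables <- function() c("BIO1", "BIO2", "BIO3")
precipitation_variables <- function() c("BIO12", "BIO13", "BIO14")

# validate a tibble of cell indices against a grid; returns it invisibly
check_cells <- function(cells, grid, require_mask = TRUE) {
  stopifnot(is.data.frame(cells), all(c("row", "col") %in% names(cells)))
  bad <- cells$row < 1 | cells$row > grid$n_rows | cells$col < 1 | cells$col > grid$n_cols
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf("cell (%d, %d) lies outside the %dx%d grid",
                 cells$row[i], cells$col[i], grid$n_rows, grid$n_cols))
  }
  if (require_mask) {
    off <- !grid$mask[cbind(cells$row, cells$col)]
    if (any(off)) {
      i <- which(off)[1]
      stop(sprintf("cell (%d, %d) is outside the analysis mask", cells$row[i], cells$col[i]))
    }
  }
  invisible(cells)
}
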