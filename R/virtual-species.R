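#' Niche response functions for virtual species
#'
#' A virtual species' occurrence probability is a known function of one to
#' three climate variables; each per-variable response is one of three kinds:
#' a Gaussian optimum curve, a logistic (sigmoidal) response, or a flat
#' (uninformative) response. Responses for the remaining variables default to
#' flat.
#'
#' @param mean,sd Gaussian optimum and niche breadth, in the variable's units.
#' @param midpoint,slope logistic midpoint and slope (slope > 0 rises with the
#'   variable; negative slope falls).
#' @return a response descriptor used by [generate_virtual_species()].
#' @name niche_response
NULL

#' @rdname niche_response
#' @export
response_gaussian <- function(mean, sd) {
  stopifnot(sd > 0)
  list(kind = "gaussian", mean = mean, sd = sd)
}

#' @rdname niche_response
#' @export
response_logistic <- function(midpoint, slope) {
  list(kind = "logistic", midpoint = midpoint, slope = slope)
}

#' @rdname niche_response
#' @export
response_flat <- function() list(kind = "flat")

eval_response <- function(resp, v) {
  switch(resp$kind,
    gaussian = exp(-0.5 * ((v - resp$mean) / resp$sd)^2),
    logistic = stats::plogis(resp$slope * (v - resp$midpoint)),
    flat     = rep(1, length(v)),
    stop("unknown response kind: ", resp$kind)
  )
}

#' Generate a virtual species with a known niche
#'
#' True suitability is the product of the per-variable responses, rescaled to
#' `[0, 1]` over the masked cells (standard virtual-species practice; the
#' product keeps gradients smooth and the optimum interpretable). Presence
#' cells are then drawn without replacement, weighted by true suitability; a
#' `detection_noise` fraction of the draws is instead taken uniformly from the
#' mask, emulating misdetections and GPS error. Deterministic per seed.
#'
#' @param grid a [climate_grid()].
#' @param response named list of [niche_response] descriptors keyed by
#'   variable code; at least one non-flat entry is required.
#' @param n_presences number of distinct presence cells to draw (>= 1).
#' @param detection_noise fraction in `[0, 1]` of presences drawn uniformly.
#' @param seed integer seed.
#' @param species_id identifier string.
#' @return an object of class `virtual_species` with fields `species_id`,
#'   `response`, `true_suitability` (matrix in `[0, 1]`, `NA` off-mask),
#'   `presence_cells` (tibble `row`, `col`), `detection_noise`, `prevalence`
#'   (mean true suitability over the mask).
#' @export
generate_virtual_species <- function(grid, response, n_presences,
                                     detection_noise = 0, seed,
                                     species_id = "vsp") {
  stopifnot(inherits(grid, "climate_grid"), n_presences >= 1,
            detection_noise >= 0, detection_noise <= 1)
  if (missing(seed)) stop("a seed is required")
  if (!length(response) || !any(vapply(response, \(r) r$kind != "flat", TRUE))) {
    stop("at least one non-flat response is required")
  }
  unknown <- setdiff(names(response), names(grid$layers))
  if (length(unknown)) stop("response names not in grid layers: ",
                            paste(unknown, collapse = ", "))

  cells <- mask_cells(grid)
  n_avail <- nrow(cells)
  if (n_presences > n_avail) {
    stop(sprintf("n_presences (%d) exceeds available masked cells (%d)",
                 n_presences, n_avail))
  }

  s <- rep(1, n_avail)
  for (nm in names(response)) {
    v <- grid$layers[[nm]][cbind(cells$row, cells$col)]
    s <- s * eval_response(response[[nm]], v)
  }
  rng <- range(s)
  s <- if (rng[2] > rng[1]) (s - rng[1]) / (rng[2] - rng[1]) else rep(1, n_avail)

  suit <- matrix(NA_real_, grid$n_rows, grid$n_cols)
  suit[cbind(cells$row, cells$col)] <- s

  set.seed(as.integer(seed))
  n_noise <- round(detection_noise * n_presences)
  n_weighted <- n_presences - n_noise
  idx <- integer(0)
  if (n_weighted > 0) {
    w <- s + 1e-9                       # keep zero-suitability cells reachable
    idx <- sample(n_avail, n_weighted, prob = w)
  }
  if (n_noise > 0) {
    pool <- setdiff(seq_len(n_avail), idx)
    idx <- c(idx, sample(pool, n_noise))
  }

  structure(
    list(
      species_id = species_id,
      response = response,
      true_suitability = suit,
      presence_cells = cells[idx, c("row", "col")],
      n_presences = n_presences,
      detection_noise = detection_noise,
      prevalence = mean(s)
    ),
    class = "virtual_species"
  )
}

#' @export
print.virtual_species <- function(x, ...) {
  cat(sprintf("<virtual_species '%s'> %d presence cells, noise %.2f\n",
              x$species_id, nrow(x$presence_cells), x$detection_noise))
  vars <- names(x$response)[vapply(x$response, \(r) r$kind != "flat", TRUE)]
  cat("informative variables:", paste(vars, collapse = ", "), "\n")
  invisible(x)
}

#' Emit a virtual species' presences as occurrence points
#'
#' Points are placed at cell centers so that snapping them back onto the same
#' grid recovers exactly the source cells (the round-trip used throughout the
#' test-suite).
#'
#' @param species a `virtual_species`.
#' @param grid the [climate_grid()] it was generated on.
#' @return tibble `species_id`, `x`, `y`.
#' @export
species_points <- function(species, grid) {
  stopifnot(inherits(species, "virtual_species"))
  cell_centers(grid, species$presence_cells) |>
    dplyr::transmute(species_id = species$species_id, x = .data$x, y = .data$y)
}

#' Truth table of a set of virtual species
#'
#' @param species_list list of `virtual_species`.
#' @return tibble `species_id`, `variable`, `kind`, `param1`, `param2` (one
#'   row per non-flat response; Gaussian rows carry mean/sd, logistic rows
#'   midpoint/slope).
#' @export
species_truth_table <- function(species_list) {
  purrr::map_dfr(species_list, function(sp) {
    purrr::imap_dfr(sp$response, function(r, nm) {
      if (r$kind == "flat") return(NULL)
      tibble::tibble(
        species_id = sp$species_id, variable = nm, kind = r$kind,
        param1 = if (r$kind == "gaussian") r$mean else r$midpoint,
        param2 = if (r$kind == "gaussian") r$sd else r$slope
      )
    })
  })
}
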