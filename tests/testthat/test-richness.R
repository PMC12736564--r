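make_map <- function(presence, id = "sp", label = "baseline", threshold = 0.5) {
  binarize(toy_surface(ifelse(is.na(presence), NA_real_,
                              ifelse(presence, 1, 0)),
                       species_id = id, label = label),
           threshold)
}

random_maps <- function(n_species, n_rows, n_cols, seed, p = 0.4) {
  set.seed(seed)
  lapply(seq_len(n_species), function(i) {
    make_map(matrix(runif(n_rows * n_cols) < p, n_rows, n_cols),
             id = sprintf("sp%02d", i))
  })
}

test_that("binarisation follows the >= convention and honours the mask", {
  vals <- matrix(c(0.2, 0.5, 0.5, 0.9), 2, 2)
  s <- toy_surface(vals)
  expect_identical(as.vector(binarize(s, 0.5)$presence),
                   c(FALSE, TRUE, TRUE, TRUE))
  expect_identical(as.vector(binarize(s, 0.5, strict = TRUE)$presence),
                   c(FALSE, FALSE, FALSE, TRUE))
  expect_true(all(binarize(s, 0)$presence))
  expect_identical(as.vector(binarize(s, 1)$presence),
                   c(FALSE, FALSE, FALSE, FALSE))

  masked <- toy_surface(matrix(c(NA, 0.8, 0.3, NA), 2, 2))
  bm <- binarize(masked, 0.5)
  expect_identical(as.vector(bm$presence), c(NA, TRUE, FALSE, NA))
  expect_error(binarize(s, 1.5), "threshold")
})

test_that("stacking counts species per cell and matches brute force", {
  empty <- stack_richness(list(), dims = c(3, 3))
  expect_true(all(empty$counts == 0))

  a <- make_map(matrix(c(TRUE, FALSE, FALSE, TRUE), 2, 2), "a")
  b <- make_map(matrix(c(TRUE, FALSE, TRUE, FALSE), 2, 2), "b")
  rs <- stack_richness(list(a, b))
  expect_identical(as.vector(rs$counts), c(2L, 0L, 1L, 1L))

  maps <- random_maps(5, 6, 6, seed = 303)
  expect_identical(stack_richness(maps)$counts, richness_brute(maps))

  wrong <- make_map(matrix(TRUE, 3, 3), "w")
  expect_error(stack_richness(list(a, wrong)), "different grids")
})

test_that("zonal richness applies the any-suitable-cell rule", {
  # zone 1 = top row, zone 2 = bottom row of a 2 x 2 grid
  z <- zone_set(matrix(c(1L, 2L, 1L, 2L), 2, 2))
  a <- make_map(matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2), "a")
  b <- make_map(matrix(c(FALSE, FALSE, TRUE, FALSE), 2, 2), "b")
  zt <- zonal_richness(list(a, b), z)
  expect_identical(zt$n_species[zt$zone_id == 1], 2L)  # one cell each
  expect_identical(zt$n_species[zt$zone_id == 2], 0L)
  expect_identical(zt$mean_cell_richness[zt$zone_id == 2], 0)
})

test_that("zonal tallies equal brute force and conserve cell counts", {
  g <- tiny_grid(10, seed = 41, mask_fraction = 1)
  zones <- generate_zones(g, 12, seed = 3)
  maps <- random_maps(8, 10, 10, seed = 71)
  zt <- zonal_richness(maps, zones)
  oracle <- zonal_brute(maps, zones)
  expect_equal(zt$n_species, oracle$n_species)
  expect_equal(zt$mean_cell_richness, oracle$mean_cell_richness)

  # zone n_species dominates the best single cell in the zone
  counts <- stack_richness(maps)$counts
  for (z in zones$zone_ids) {
    idx <- which(zones$zone_labels == z, arr.ind = TRUE)
    expect_gte(zt$n_species[zt$zone_id == z], max(counts[idx]))
  }

  # conservation: zone means weighted by size recover the global cell sum
  expect_equal(sum(zt$mean_cell_richness * zt$n_cells), sum(counts))
})

test_that("lowering a threshold never decreases any richness quantity", {
  g <- tiny_grid(10, seed = 43)
  zones <- generate_zones(g, 6, seed = 5)
  set.seed(91)
  surfs <- lapply(1:5, function(i) {
    v <- matrix(runif(100), 10, 10)
    v[!g$mask] <- NA
    toy_surface(v, sprintf("sp%d", i))
  })
  thr <- runif(5, 0.3, 0.7)
  base_maps <- Map(binarize, surfs, thr)
  base_counts <- stack_richness(base_maps)$counts
  base_zt <- zonal_richness(base_maps, zones)
  for (k in 1:20) {
    i <- sample(5, 1)
    thr2 <- thr
    thr2[i] <- max(0, thr[i] - runif(1, 0, 0.3))
    maps2 <- Map(binarize, surfs, thr2)
    counts2 <- stack_richness(maps2)$counts
    expect_true(all(counts2 >= base_counts, na.rm = TRUE))
    zt2 <- zonal_richness(maps2, zones)
    expect_true(all(zt2$n_species >= base_zt$n_species))
  }
})

test_that("richness classes use half-open bins with a closed top", {
  expect_identical(bin_richness(33, "decadal"), "30-40")
  expect_identical(bin_richness(0, "quintal"), "0-5")
  expect_identical(bin_richness(10, "decadal"), "10-20")
  expect_identical(bin_richness(10, "quintal"), "10-15")
  expect_identical(bin_richness(40, "decadal"), "30-40")
  expect_identical(bin_richness(30, "quintal"), "25-30")
  expect_warning(top <- bin_richness(45, "decadal"), "top class")
  expect_identical(top, "30-40")
})

test_that("richness change reports deltas and class transitions", {
  zt <- tibble::tibble(zone_id = 1:3, name = c("a", "b", "c"),
                       n_cells = c(5L, 5L, 5L),
                       n_species = c(12L, 3L, 27L),
                       mean_cell_richness = c(2, 1, 4))
  same <- richness_change(zt, zt, "quintal")
  expect_true(all(same$deltas$delta == 0))
  expect_true(all(same$transitions$from == same$transitions$to))

  fut <- dplyr::mutate(zt, n_species = c(5L, 3L, 27L))  # zone 1 drops 12 -> 5
  ch <- richness_change(zt, fut, "quintal")
  expect_identical(ch$deltas$delta[ch$deltas$zone_id == 1], -7L)
  tr <- ch$transitions
  expect_identical(tr$n[tr$from == "10-15" & tr$to == "5-10"], 1L)

  expect_error(richness_change(zt, dplyr::filter(fut, zone_id != 2)),
               "different zones")
})
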