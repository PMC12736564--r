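# Shared fixtures and independent oracles. Everything is generated in code;
# no fixture files are read from disk.

# small fully-masked grid for fast unit tests
tiny_grid <- function(n = 16, seed = 11, mask_fraction = 1, label = "baseline") {
  generate_climate(n, n, spatial_corr_length = 3, seed = seed,
                   mask_fraction = mask_fraction, label = label)
}

# a grid built from explicit layer matrices (constant defaults), for toys
toy_grid <- function(n_rows = 2, n_cols = 2, bio1 = NULL, mask = NULL,
                     label = "toy") {
  m <- function(v) matrix(v, n_rows, n_cols)
  layers <- list(
    BIO1 = if (is.null(bio1)) m(10) else bio1,
    BIO2 = m(9), BIO3 = m(30),
    BIO12 = m(1200), BIO13 = m(300), BIO14 = m(40)
  )
  if (is.null(mask)) mask <- matrix(TRUE, n_rows, n_cols)
  climate_grid(layers, mask, label = label)
}

# suitability surface with prescribed values (NA = off-mask)
toy_surface <- function(values, species_id = "sp", label = "baseline") {
  structure(
    list(species_id = species_id, label = label,
         values = values, n_repetitions = 1L),
    class = "suitability_surface"
  )
}

# species with a narrow single-variable gaussian niche centred mid-gradient
narrow_species <- function(grid, variable = "BIO1", seed = 1, n = 100,
                           noise = 0.1, breadth = 0.08, id = "sp") {
  vals <- grid$layers[[variable]][grid$mask]
  resp <- stats::setNames(
    list(response_gaussian(stats::median(vals), breadth * stats::sd(vals))),
    variable
  )
  generate_virtual_species(grid, resp, n, detection_noise = noise,
                           seed = seed, species_id = id)
}

# --- independent oracles -------------------------------------------------

# brute-force pairwise AUC (ties half credit)
auc_brute <- function(pos, neg) {
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# exhaustive dense-grid scan for the TSS-max threshold
tss_scan <- function(pos, neg, step = 1e-3) {
  grid <- seq(0, 1, by = step)
  tss <- vapply(grid, function(t) {
    sens <- mean(pos >= t)
    spec <- mean(neg < t)
    sens + spec - 1
  }, numeric(1))
  list(threshold = grid[which.max(tss)], tss = max(tss))
}

# brute-force per-cell richness tally
richness_brute <- function(maps) {
  d <- dim(maps[[1]]$presence)
  counts <- matrix(0L, d[1], d[2])
  for (r in seq_len(d[1])) {
    for (c in seq_len(d[2])) {
      k <- 0L
      for (m in maps) if (isTRUE(m$presence[r, c])) k <- k + 1L
      counts[r, c] <- k
    }
  }
  counts
}

# brute-force zone table (double loop over zones x species)
zonal_brute <- function(maps, zones) {
  counts <- richness_brute(maps)
  out <- lapply(zones$zone_ids, function(z) {
    idx <- which(zones$zone_labels == z, arr.ind = TRUE)
    n_sp <- 0L
    for (m in maps) {
      hit <- FALSE
      for (i in seq_len(nrow(idx))) {
        if (isTRUE(m$presence[idx[i, 1], idx[i, 2]])) { hit <- TRUE; break }
      }
      if (hit) n_sp <- n_sp + 1L
    }
    data.frame(zone_id = z, n_species = n_sp,
               mean_cell_richness = mean(counts[idx]))
  })
  do.call(rbind, out)
}
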