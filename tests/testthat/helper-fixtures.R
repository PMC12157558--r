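# Fixture builders and independent oracles used across the suite.
# Oracles are deliberately naive (loops, enumeration) and share no code
# with the package internals they check.

# plain disk mask centred in its own raster
disk_mask <- function(radius_um, pixel_size_um) {
  half <- ceiling(radius_um / pixel_size_um) + 2L
  n <- 2L * half + 1L
  ctr <- (half + 0.5) * pixel_size_um
  xs <- (seq_len(n) - 0.5) * pixel_size_um
  d2 <- outer((xs - ctr)^2, (xs - ctr)^2, `+`)
  mask <- matrix(0L, n, n)
  mask[d2 <= radius_um^2] <- 1L
  mask
}

# axis-aligned rectangle mask (for quadrat and square-window checks)
rect_mask <- function(width_um, height_um, pixel_size_um) {
  nc <- round(width_um / pixel_size_um)
  nr <- round(height_um / pixel_size_um)
  matrix(1L, nr, nc)
}

# an assortment of irregular nuclear masks for mixed-shape tests
irregular_masks <- function(pixel_size_um = 0.2, seeds = 1:5) {
  shapes <- list(
    nucleus_shape_params(6, eccentricity = 0),
    nucleus_shape_params(7, eccentricity = 0.6),
    nucleus_shape_params(6, boundary_roughness = 0.08),
    nucleus_shape_params(8, eccentricity = 0.4, boundary_roughness = 0.05),
    nucleus_shape_params(6, concavity_count = 1)
  )
  lapply(seq_along(seeds), function(i) {
    generate_nucleus_mask(shapes[[((i - 1) %% length(shapes)) + 1]],
                          pixel_size_um, seed = seeds[i])$mask
  })
}

# brute-force Ripley K: explicit double loop over ordered pairs
brute_force_k <- function(x, y, area, radii) {
  n <- length(x)
  sapply(radii, function(r) {
    count <- 0
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i != j && sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2) <= r) {
          count <- count + 1
        }
      }
    }
    area * count / (n * (n - 1))
  })
}

# brute-force two-way median polish (independent of stats::medpolish)
brute_force_polish <- function(mat, max_iter = 100, tol = 1e-9) {
  overall <- 0
  row_eff <- rep(0, nrow(mat))
  col_eff <- rep(0, ncol(mat))
  resid <- mat
  for (it in seq_len(max_iter)) {
    rm_ <- apply(resid, 1, median, na.rm = TRUE)
    rm_[is.na(rm_)] <- 0
    resid <- sweep(resid, 1, rm_)
    row_eff <- row_eff + rm_
    mc <- median(col_eff)
    col_eff <- col_eff - mc
    overall <- overall + mc
    cm <- apply(resid, 2, median, na.rm = TRUE)
    cm[is.na(cm)] <- 0
    resid <- sweep(resid, 2, cm)
    col_eff <- col_eff + cm
    mr <- median(row_eff)
    row_eff <- row_eff - mr
    overall <- overall + mr
    if (max(abs(rm_)) < tol && max(abs(cm)) < tol) break
  }
  list(overall = overall, row = row_eff, col = col_eff, residuals = resid)
}

# nearest-neighbour distances, naive
nn_distances <- function(x, y) {
  n <- length(x)
  sapply(seq_len(n), function(i) {
    min(sqrt((x[i] - x[-i])^2 + (y[i] - y[-i])^2))
  })
}

# small screen design used by several tests (fast: 1 plate, 8x12)
small_screen_design <- function(planted = NULL, seed = 7, ...) {
  screen_design(n_genes = 60, rows = 8L, cols = 12L,
                cells_per_well = 60, planted_effects = planted,
                n_ctrl_per_class = 4L, seed = seed, ...)
}
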