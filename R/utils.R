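# Internal helpers shared across modules.
#
# Raster convention: masks and images are R matrices indexed [row, col],
# 1-based.  Physical coordinates are continuous, in micrometres, with the
# origin at the top-left pixel corner and pixel centres at
# (index - 0.5) * pixel_size; x runs along columns, y along rows.

#' Evaluate code with a temporary RNG seed
#'
#' Sets the seed, runs the expression, and restores the caller's RNG state,
#' so seeded generators compose without perturbing the global stream.
#' A `NULL` seed leaves the RNG untouched.
#' @noRd
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
              add = TRUE)
    }
    set.seed(seed)
  }
  force(code)
}

#' Physical x/y coordinates of pixel centres for a matrix index pair
#' @noRd
pixel_center_xy <- function(row, col, pixel_size_um) {
  cbind(x = (col - 0.5) * pixel_size_um, y = (row - 0.5) * pixel_size_um)
}

#' Map physical coordinates to matrix indices (1-based)
#' @noRd
xy_to_index <- function(x_um, y_um, pixel_size_um) {
  cbind(row = floor(y_um / pixel_size_um) + 1L,
        col = floor(x_um / pixel_size_um) + 1L)
}

#' Vectorised membership test for continuous points against a binary mask
#' @noRd
points_in_mask <- function(mask, x_um, y_um, pixel_size_um) {
  idx <- xy_to_index(x_um, y_um, pixel_size_um)
  ok <- idx[, 1L] >= 1L & idx[, 1L] <= nrow(mask) &
    idx[, 2L] >= 1L & idx[, 2L] <= ncol(mask)
  inside <- ok
  if (any(ok)) {
    inside[ok] <- mask[idx[ok, , drop = FALSE]] > 0
  }
  inside
}

#' Area of a mask in square micrometres
#' @noRd
mask_area_um2 <- function(mask, pixel_size_um) {
  sum(mask > 0) * pixel_size_um^2
}

#' Centroid (x, y in um) of a binary mask, from pixel centres
#' @noRd
mask_centroid_um <- function(mask, pixel_size_um) {
  idx <- which(mask > 0, arr.ind = TRUE)
  c(x = (mean(idx[, 2L]) - 0.5) * pixel_size_um,
    y = (mean(idx[, 1L]) - 0.5) * pixel_size_um)
}

#' Shoelace polygon area from vertex coordinates
#' @noRd
polygon_area <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

#' Crossing-number point-in-polygon test, vectorised over query points
#' @noRd
points_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Solidity of a raster region: pixel count / rasterised convex-hull count
#'
#' The convex image is the set of pixels whose centres fall inside the
#' convex hull of the region's pixel centres (hull vertices included), so
#' solidity is bounded by 1 and equals 1 for convex rasters.
#' @noRd
region_solidity <- function(rows, cols) {
  n <- length(rows)
  if (n <= 3L) return(1)
  h <- chull(cols, rows)
  hx <- cols[h]
  hy <- rows[h]
  rr <- seq(min(rows), max(rows))
  cc <- seq(min(cols), max(cols))
  grid <- expand.grid(row = rr, col = cc)
  inside <- points_in_polygon(grid$col, grid$row, hx, hy)
  # hull boundary pixels are not always caught by the crossing test; make
  # sure every region pixel counts as part of the convex image
  hull_n <- length(union(which(inside),
                         match(paste(rows, cols),
                               paste(grid$row, grid$col))))
  min(1, n / hull_n)
}

#' Otsu threshold on a numeric vector (256-bin histogram)
#' @noRd
otsu_threshold <- function(x, n_bins = 256L) {
  x <- x[is.finite(x)]
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1L])
  breaks <- seq(rng[1L], rng[2L], length.out = n_bins + 1L)
  counts <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE),
                     nbins = n_bins)
  mids <- (breaks[-1L] + breaks[-(n_bins + 1L)]) / 2
  w <- counts / sum(counts)
  cw <- cumsum(w)
  cm <- cumsum(w * mids)
  mt <- cm[n_bins]
  between <- (mt * cw - cm)^2 / (cw * (1 - cw))
  between[!is.finite(between)] <- -Inf
  mids[which.max(between)]
}

#' Stable cheap fingerprint of a binary mask for baseline caching
#' @noRd
mask_key <- function(mask) {
  idx <- which(mask > 0)
  paste(nrow(mask), ncol(mask), length(idx),
        sum(as.numeric(idx)), sum(as.numeric(idx)^2) %% 2^48,
        sep = "|")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
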