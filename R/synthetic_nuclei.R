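# Synthetic nuclei, spot point processes, and rendered two-channel images.
# Every generator is deterministic under a fixed seed and returns the ground
# truth needed to test the downstream measurement code.

#' Nucleus shape parameters
#'
#' Describes a synthetic nuclear outline as a star-shaped radial function:
#' an ellipse of given equivalent radius and eccentricity, optionally
#' perturbed by smooth low-frequency boundary roughness and by deep angular
#' notches that lower the solidity of the rasterised mask (emulating
#' dysmorphic nuclei).
#'
#' @param equivalent_radius_um Radius (micrometres) of the circle with the
#'   same area as the unperturbed ellipse.
#' @param eccentricity Ellipse eccentricity in `[0, 1)`; 0 is a disk.
#' @param boundary_roughness Non-negative amplitude of a smooth random
#'   radial perturbation, as a fraction of the local radius.
#' @param concavity_count Non-negative integer number of deep notches cut
#'   into the boundary; more notches give lower solidity in expectation.
#' @return An object of class `nucleus_shape_params`.
#' @export
nucleus_shape_params <- function(equivalent_radius_um = 8,
                                 eccentricity = 0,
                                 boundary_roughness = 0,
                                 concavity_count = 0L) {
  stopifnot(equivalent_radius_um > 0,
            eccentricity >= 0, eccentricity < 1,
            boundary_roughness >= 0,
            concavity_count >= 0)
  structure(list(equivalent_radius_um = equivalent_radius_um,
                 eccentricity = eccentricity,
                 boundary_roughness = boundary_roughness,
                 concavity_count = as.integer(concavity_count)),
            class = "nucleus_shape_params")
}

#' Generate a rasterised nucleus mask with ground truth
#'
#' Rasterises the star-shaped boundary defined by `params` onto a pixel grid.
#' The returned ground truth reports the area and solidity measured on the
#' raster itself, so recovery tests compare like with like.
#'
#' @param params A [nucleus_shape_params()] object.
#' @param pixel_size_um Pixel size in micrometres (default 0.108, the
#'   effective pixel size of a 60x sCMOS acquisition).
#' @param seed Integer seed controlling the random orientation, roughness
#'   harmonics and notch placement.
#' @return A list with elements `mask` (binary integer matrix), and `truth`
#'   (list with `area_um2`, `solidity`, `centroid_um`, `equivalent_radius_um`
#'   and the input parameters).
#' @export
generate_nucleus_mask <- function(params, pixel_size_um = 0.108, seed = 1L) {
  stopifnot(inherits(params, "nucleus_shape_params"))
  if (params$equivalent_radius_um < 3 * pixel_size_um) {
    stop("equivalent_radius_um must be at least 3 pixels (",
         3 * pixel_size_um, " um) at this pixel size")
  }
  with_seed(seed, {
    r_eq <- params$equivalent_radius_um
    e <- params$eccentricity
    a <- r_eq / (1 - e^2)^0.25
    b <- r_eq * (1 - e^2)^0.25
    phi <- runif(1, 0, 2 * pi)

    # smooth roughness: random low-order harmonics, unit-sd over the circle
    rough_fun <- function(theta) rep(0, length(theta))
    if (params$boundary_roughness > 0) {
      ks <- 2:5
      ca <- rnorm(length(ks))
      cb <- rnorm(length(ks))
      norm <- sqrt(sum(ca^2 + cb^2) / 2)
      rough_fun <- function(theta) {
        g <- rep(0, length(theta))
        for (i in seq_along(ks)) {
          g <- g + ca[i] * cos(ks[i] * theta) + cb[i] * sin(ks[i] * theta)
        }
        g / norm
      }
    }

    notch_fun <- function(theta) rep(1, length(theta))
    if (params$concavity_count > 0) {
      # evenly spaced notches with angular jitter, so deep notches do not
      # collapse onto each other and solidity falls reliably with count
      k <- params$concavity_count
      centers <- seq(0, 2 * pi, length.out = k + 1L)[seq_len(k)] +
        runif(1, 0, 2 * pi) + runif(k, -0.25, 0.25)
      depths <- runif(k, 0.55, 0.8)
      widths <- runif(k, 0.3, 0.5)
      notch_fun <- function(theta) {
        f <- rep(1, length(theta))
        for (j in seq_along(centers)) {
          d <- atan2(sin(theta - centers[j]), cos(theta - centers[j]))
          f <- f * (1 - depths[j] * exp(-0.5 * (d / widths[j])^2))
        }
        f
      }
    }

    radius_fun <- function(theta) {
      th <- theta - phi
      re <- a * b / sqrt((b * cos(th))^2 + (a * sin(th))^2)
      r <- re * (1 + params$boundary_roughness * rough_fun(theta)) *
        notch_fun(theta)
      pmax(r, 0.15 * r_eq)
    }

    max_r <- a * (1 + 3 * params$boundary_roughness)
    half <- ceiling(max_r / pixel_size_um) + 2L
    n_px <- 2L * half + 1L
    cx <- (half + 0.5) * pixel_size_um
    cy <- cx
    xs <- (seq_len(n_px) - 0.5) * pixel_size_um
    ys <- xs
    dx <- matrix(xs - cx, n_px, n_px, byrow = TRUE)
    dy <- matrix(ys - cy, n_px, n_px)
    theta <- atan2(dy, dx)
    rr <- sqrt(dx^2 + dy^2)
    mask <- matrix(0L, n_px, n_px)
    mask[rr <= radius_fun(as.vector(theta))] <- 1L

    idx <- which(mask > 0, arr.ind = TRUE)
    truth <- list(
      area_um2 = nrow(idx) * pixel_size_um^2,
      solidity = region_solidity(idx[, 1L], idx[, 2L]),
      centroid_um = mask_centroid_um(mask, pixel_size_um),
      equivalent_radius_um = sqrt(nrow(idx) * pixel_size_um^2 / pi),
      params = params, pixel_size_um = pixel_size_um, seed = seed
    )
    list(mask = mask, truth = truth)
  })
}

#' Spot point-process parameters
#'
#' @param process One of `"CSR"` (complete spatial randomness, uniform over
#'   the mask support), `"cluster"` (Thomas-type: uniform parents, Gaussian
#'   offspring truncated to the mask by resampling) or `"regular"`
#'   (hard-core inhibition by sequential rejection).
#' @param n_spots Number of points to place.
#' @param n_parents Number of cluster parents (cluster process only).
#' @param cluster_sigma_um Gaussian offspring dispersion in micrometres
#'   (cluster process only).
#' @param inhibition_radius_um Minimum allowed pairwise distance
#'   (regular process only).
#' @return An object of class `spot_process_params`.
#' @export
spot_process_params <- function(process = c("CSR", "cluster", "regular"),
                                n_spots,
                                n_parents = NULL,
                                cluster_sigma_um = NULL,
                                inhibition_radius_um = NULL) {
  process <- match.arg(process)
  stopifnot(n_spots >= 1)
  if (process == "cluster") {
    if (is.null(cluster_sigma_um) || cluster_sigma_um <= 0)
      stop("cluster process requires a positive cluster_sigma_um")
    if (is.null(n_parents) || n_parents < 1)
      stop("cluster process requires n_parents >= 1")
  }
  if (process == "regular" &&
      (is.null(inhibition_radius_um) || inhibition_radius_um <= 0))
    stop("regular process requires a positive inhibition_radius_um")
  structure(list(process = process, n_spots = as.integer(n_spots),
                 n_parents = if (is.null(n_parents)) NULL
                             else as.integer(n_parents),
                 cluster_sigma_um = cluster_sigma_um,
                 inhibition_radius_um = inhibition_radius_um),
            class = "spot_process_params")
}

# uniform points over the mask support: uniform pixel choice + sub-pixel jitter
csr_points <- function(mask, n, pixel_size_um) {
  idx <- which(mask > 0, arr.ind = TRUE)
  pick <- idx[sample.int(nrow(idx), n, replace = TRUE), , drop = FALSE]
  data.frame(
    x_um = (pick[, 2L] - 1L + runif(n)) * pixel_size_um,
    y_um = (pick[, 1L] - 1L + runif(n)) * pixel_size_um
  )
}

#' Sample a spot pattern inside a nuclear mask
#'
#' @param mask Binary matrix; points are placed on its support.
#' @param params A [spot_process_params()] object.
#' @param pixel_size_um Pixel size in micrometres.
#' @param seed Integer seed.
#' @param max_tries Retry budget for the rejection steps.
#' @return A data frame of class `spot_set` with columns `x_um`, `y_um`
#'   and an attribute `process` recording the generating process.
#' @export
sample_spots <- function(mask, params, pixel_size_um = 0.108, seed = 1L,
                         max_tries = 20000L) {
  stopifnot(inherits(params, "spot_process_params"))
  if (!any(mask > 0)) stop("mask is empty")
  with_seed(seed, {
    n <- params$n_spots
    pts <- switch(
      params$process,
      CSR = csr_points(mask, n, pixel_size_um),
      cluster = {
        parents <- csr_points(mask, params$n_parents, pixel_size_um)
        assign_to <- sample.int(params$n_parents, n, replace = TRUE)
        x <- numeric(n); y <- numeric(n)
        for (i in seq_len(n)) {
          px <- parents$x_um[assign_to[i]]
          py <- parents$y_um[assign_to[i]]
          ok <- FALSE
          for (try in seq_len(max_tries)) {
            cx <- px + rnorm(1, 0, params$cluster_sigma_um)
            cy <- py + rnorm(1, 0, params$cluster_sigma_um)
            if (points_in_mask(mask, cx, cy, pixel_size_um)) {
              x[i] <- cx; y[i] <- cy; ok <- TRUE; break
            }
          }
          if (!ok) { # parent wedged against the boundary: fall back to CSR
            p <- csr_points(mask, 1L, pixel_size_um)
            x[i] <- p$x_um; y[i] <- p$y_um
          }
        }
        data.frame(x_um = x, y_um = y)
      },
      regular = {
        x <- numeric(0); y <- numeric(0)
        tries <- 0L
        r2 <- params$inhibition_radius_um^2
        while (length(x) < n) {
          tries <- tries + 1L
          if (tries > max_tries) {
            stop("regular process: could not place ", n, " points with ",
                 "inhibition radius ", params$inhibition_radius_um,
                 " um within the retry budget (packing infeasible?)")
          }
          p <- csr_points(mask, 1L, pixel_size_um)
          if (length(x) == 0L ||
              min((x - p$x_um)^2 + (y - p$y_um)^2) >= r2) {
            x <- c(x, p$x_um); y <- c(y, p$y_um)
          }
        }
        data.frame(x_um = x, y_um = y)
      }
    )
    structure(pts, class = c("spot_set", "data.frame"),
              process = params$process, params = params,
              pixel_size_um = pixel_size_um)
  })
}

#' Render a two-channel cell image from a mask and a spot pattern
#'
#' The DAPI-like channel is the (lightly blurred) filled nucleus; the spot
#' channel is a sum of isotropic Gaussian kernels of width `psf_sigma_um`
#' centred at the spot positions, over a uniform background.  Gaussian read
#' noise is added at the requested peak signal-to-noise ratio; `snr = Inf`
#' gives a noiseless render.
#'
#' @param mask Binary nucleus mask.
#' @param spots `spot_set` data frame (micrometre coordinates).
#' @param psf_sigma_um Width of the emission point-spread function.
#' @param snr Peak amplitude / noise standard deviation; `Inf` for noiseless.
#' @param pixel_size_um Pixel size in micrometres.
#' @param seed Integer seed for the noise.
#' @param spot_amplitude Peak amplitude of one spot kernel.
#' @param background Constant background level of the spot channel.
#' @param dapi_level Foreground level of the DAPI channel.
#' @return List with `dapi`, `spots` (matrices), `pixel_size_um`, and
#'   `truth` carrying the input coordinates and a `merged_spots` flag set
#'   when any pair of spots is closer than twice the PSF sigma (the
#'   separation below which two equal Gaussians no longer produce two
#'   distinct maxima).
#' @export
render_cell_image <- function(mask, spots, psf_sigma_um = 0.3, snr = Inf,
                              pixel_size_um = 0.108, seed = 1L,
                              spot_amplitude = 1, background = 0.02,
                              dapi_level = 0.8) {
  if (psf_sigma_um < pixel_size_um / 2) {
    stop("psf_sigma_um must be at least half a pixel to be representable")
  }
  with_seed(seed, {
    nr <- nrow(mask); nc <- ncol(mask)
    xs <- (seq_len(nc) - 0.5) * pixel_size_um
    ys <- (seq_len(nr) - 0.5) * pixel_size_um
    spot_img <- matrix(background, nr, nc)
    n <- nrow(spots)
    if (n > 0) {
      for (i in seq_len(n)) {
        gx <- exp(-0.5 * ((xs - spots$x_um[i]) / psf_sigma_um)^2)
        gy <- exp(-0.5 * ((ys - spots$y_um[i]) / psf_sigma_um)^2)
        spot_img <- spot_img + spot_amplitude * outer(gy, gx)
      }
    }
    dapi <- matrix(0, nr, nc)
    dapi[mask > 0] <- dapi_level
    dapi <- as.matrix(EBImage::gblur(dapi, sigma = 1))
    noise_sd <- if (is.finite(snr)) spot_amplitude / snr else 0
    if (noise_sd > 0) {
      spot_img <- spot_img + matrix(rnorm(nr * nc, 0, noise_sd), nr, nc)
      dapi <- dapi + matrix(rnorm(nr * nc, 0, noise_sd), nr, nc)
    }
    merged <- FALSE
    if (n >= 2) {
      merged <- min(dist(cbind(spots$x_um, spots$y_um))) <= 2 * psf_sigma_um
    }
    list(dapi = dapi, spots = spot_img, pixel_size_um = pixel_size_um,
         truth = list(coords = as.data.frame(spots)[, c("x_um", "y_um")],
                      psf_sigma_um = psf_sigma_um, snr = snr,
                      noise_sd = noise_sd, merged_spots = merged))
  })
}
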