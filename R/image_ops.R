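# Image operations: nuclear segmentation, Laplacian-of-Gaussian spot
# detection, and per-nucleus intensity measurement.
#
# Segmentation is a classical pipeline (Gaussian smoothing -> Otsu
# threshold -> hole filling -> optional distance-transform watershed);
# precomputed label masks can be passed straight to detect_spots_log()
# and measure_cells(), so any external segmenter can be swapped in.

#' Segmentation parameters
#'
#' @param min_area_um2 Objects smaller than this are discarded.
#' @param smoothing_sigma_um Gaussian pre-smoothing width.
#' @param split_touching Apply a distance-transform watershed to split
#'   touching nuclei.
#' @param exclude_border Drop nuclei touching the image edge (truncated
#'   nuclei bias area and clustering statistics).
#' @param watershed_tolerance Minimum object-height separation for the
#'   watershed split, in distance-map pixels.
#' @return Object of class `segmentation_params`.
#' @export
segmentation_params <- function(min_area_um2 = 20,
                                smoothing_sigma_um = 0.5,
                                split_touching = FALSE,
                                exclude_border = TRUE,
                                watershed_tolerance = 1) {
  structure(list(min_area_um2 = min_area_um2,
                 smoothing_sigma_um = smoothing_sigma_um,
                 split_touching = split_touching,
                 exclude_border = exclude_border,
                 watershed_tolerance = watershed_tolerance),
            class = "segmentation_params")
}

# per-label morphometry + intensities; channels is a named list of matrices
label_records <- function(labels, channels, pixel_size_um) {
  ids <- sort(unique(as.integer(labels[labels > 0])))
  if (length(ids) == 0) {
    rec <- data.frame(nucleus_id = integer(), area_um2 = numeric(),
                      solidity = numeric(), centroid_x_um = numeric(),
                      centroid_y_um = numeric())
    for (ch in names(channels)) {
      rec[[paste0(ch, "_integrated")]] <- numeric()
      rec[[paste0(ch, "_mean")]] <- numeric()
    }
    return(rec)
  }
  recs <- lapply(ids, function(id) {
    idx <- which(labels == id, arr.ind = TRUE)
    rec <- data.frame(
      nucleus_id = id,
      area_um2 = nrow(idx) * pixel_size_um^2,
      solidity = region_solidity(idx[, 1L], idx[, 2L]),
      centroid_x_um = (mean(idx[, 2L]) - 0.5) * pixel_size_um,
      centroid_y_um = (mean(idx[, 1L]) - 0.5) * pixel_size_um
    )
    for (ch in names(channels)) {
      v <- channels[[ch]][idx]
      rec[[paste0(ch, "_integrated")]] <- sum(v)
      rec[[paste0(ch, "_mean")]] <- mean(v)
    }
    rec
  })
  do.call(rbind, recs)
}

#' Segment nuclei from a DAPI image
#'
#' Gaussian smoothing, Otsu thresholding, hole filling, connected-component
#' labelling and (optionally) a distance-transform watershed to split
#' touching nuclei; small and border-touching objects are removed and the
#' surviving labels renumbered 1..n.
#'
#' @param dapi_image 2-D numeric matrix (single channel).
#' @param pixel_size_um Pixel size in micrometres.
#' @param params A [segmentation_params()] object.
#' @return List with `labels` (integer label matrix, 0 = background) and
#'   `records` (data frame of per-nucleus area, solidity, centroid and
#'   DAPI intensities).  A blank image yields zero records, not an error.
#' @export
segment_nuclei <- function(dapi_image, pixel_size_um = 0.108,
                           params = segmentation_params()) {
  stopifnot(is.matrix(dapi_image))
  sigma_px <- max(params$smoothing_sigma_um / pixel_size_um, 0.5)
  sm <- as.matrix(EBImage::gblur(dapi_image, sigma = sigma_px))
  vals <- as.vector(sm)
  if (diff(range(vals)) < .Machine$double.eps) {
    return(list(labels = matrix(0L, nrow(dapi_image), ncol(dapi_image)),
                records = label_records(matrix(0L, 1, 1),
                                        list(dapi = matrix(0, 1, 1)),
                                        pixel_size_um)[0, ]))
  }
  th <- otsu_threshold(vals)
  bw <- sm > th
  bw <- as.matrix(EBImage::fillHull(EBImage::Image(bw * 1)))
  if (params$split_touching) {
    dm <- EBImage::distmap(EBImage::Image(bw))
    labels <- as.matrix(EBImage::watershed(dm,
                                           tolerance = params$watershed_tolerance))
  } else {
    labels <- as.matrix(EBImage::bwlabel(EBImage::Image(bw)))
  }
  labels <- matrix(as.integer(labels), nrow(bw), ncol(bw))
  # drop small objects and (optionally) border-touching nuclei
  min_px <- params$min_area_um2 / pixel_size_um^2
  keep <- integer(0)
  for (id in setdiff(unique(as.integer(labels)), 0L)) {
    idx <- which(labels == id, arr.ind = TRUE)
    if (nrow(idx) < min_px) { labels[idx] <- 0L; next }
    if (params$exclude_border &&
        (any(idx[, 1L] %in% c(1L, nrow(labels))) ||
         any(idx[, 2L] %in% c(1L, ncol(labels))))) {
      labels[idx] <- 0L; next
    }
    keep <- c(keep, id)
  }
  # renumber sequentially
  relabel <- matrix(0L, nrow(labels), ncol(labels))
  for (i in seq_along(keep)) relabel[labels == keep[i]] <- i
  records <- label_records(relabel, list(dapi = dapi_image), pixel_size_um)
  list(labels = relabel, records = records)
}

#' Spot-detection parameters
#'
#' @param sigma_um LoG scale, matched to the expected spot radius.
#' @param threshold_k Detection threshold = median + k * MAD of the LoG
#'   response inside nuclei (robust, so dense spot signal does not
#'   inflate the threshold).
#' @param min_separation_px Minimum peak separation; the weaker of two
#'   closer peaks is suppressed.
#' @param focus_rel_level Focus segmentation level relative to the peak
#'   LoG response (local threshold).
#' @return Object of class `spot_detection_params`.
#' @export
spot_detection_params <- function(sigma_um = 0.25, threshold_k = 5,
                                  min_separation_px = 2,
                                  focus_rel_level = 0.5) {
  structure(list(sigma_um = sigma_um, threshold_k = threshold_k,
                 min_separation_px = min_separation_px,
                 focus_rel_level = focus_rel_level),
            class = "spot_detection_params")
}

# scale-normalized negative-LoG kernel: positive response at bright blobs
log_kernel <- function(sigma_px) {
  half <- max(ceiling(4 * sigma_px), 2L)
  xs <- -half:half
  g <- exp(-0.5 * (xs / sigma_px)^2)
  G <- outer(g, g)
  r2 <- outer(xs^2, xs^2, `+`)
  k <- -(r2 - 2 * sigma_px^2) / sigma_px^2 * G
  k - mean(k) # zero-sum: flat background gives zero response
}

#' Detect spots with a Laplacian-of-Gaussian filter
#'
#' Computes a scale-normalized LoG response at the configured scale,
#' thresholds it adaptively (median + k MAD of the response inside
#' nuclei),
#' seeds spots at local maxima with non-maximum suppression at the
#' configured minimum separation, segments each focus by local
#' thresholding of the LoG response around its peak, and reports the
#' intensity-weighted centroid of the focus in the raw channel.
#' Detections outside any nucleus label are discarded.
#'
#' @param spot_image 2-D numeric matrix (spot channel).
#' @param labels Integer label matrix from [segment_nuclei()] or an
#'   external segmenter; same shape as `spot_image`.
#' @param pixel_size_um Pixel size in micrometres.
#' @param params A [spot_detection_params()] object.
#' @return Data frame with `nucleus_id`, `x_um`, `y_um`, `peak_intensity`,
#'   `focus_area_px`.  An all-zero image yields zero rows.
#' @export
detect_spots_log <- function(spot_image, labels, pixel_size_um = 0.108,
                             params = spot_detection_params()) {
  stopifnot(all(dim(spot_image) == dim(labels)))
  empty <- data.frame(nucleus_id = integer(), x_um = numeric(),
                      y_um = numeric(), peak_intensity = numeric(),
                      focus_area_px = integer())
  inside <- labels > 0
  if (!any(inside)) return(empty)
  if (diff(range(spot_image)) == 0) return(empty)
  sigma_px <- params$sigma_um / pixel_size_um
  kern <- log_kernel(sigma_px)
  # replicate padding: zero or circular padding creates a step edge (or
  # wrap-around ghosts) at the image border that the LoG flags as blobs
  L <- as.matrix(EBImage::filter2(spot_image, kern,
                                  boundary = "replicate"))
  # robust adaptive threshold: median + k * MAD of the response inside
  # nuclei (robust location/scale so the spot signal itself does not
  # inflate the threshold on spot-dense nuclei), with an absolute floor
  # tied to the image dynamic range to reject numerical ripple
  mu <- median(L[inside])
  s <- mad(L[inside])
  thr <- max(mu + params$threshold_k * s,
             1e-6 * diff(range(spot_image)))

  nr <- nrow(L); nc <- ncol(L)
  # 8-neighbour local maxima above threshold (interior pixels only)
  core <- L[2:(nr - 1), 2:(nc - 1)]
  is_max <- core > thr &
    core >= L[1:(nr - 2), 2:(nc - 1)] & core >= L[3:nr, 2:(nc - 1)] &
    core >= L[2:(nr - 1), 1:(nc - 2)] & core >= L[2:(nr - 1), 3:nc] &
    core >= L[1:(nr - 2), 1:(nc - 2)] & core >= L[1:(nr - 2), 3:nc] &
    core >= L[3:nr, 1:(nc - 2)] & core >= L[3:nr, 3:nc]
  pk <- which(is_max, arr.ind = TRUE)
  if (nrow(pk) == 0) return(empty)
  pk <- pk + 1L # back to full-image indices
  resp <- L[pk]
  ord <- order(resp, decreasing = TRUE)
  pk <- pk[ord, , drop = FALSE]; resp <- resp[ord]
  # non-maximum suppression at min_separation_px
  keep <- rep(TRUE, nrow(pk))
  min_sep2 <- params$min_separation_px^2
  for (i in seq_len(nrow(pk))) {
    if (!keep[i]) next
    if (i < nrow(pk)) {
      later <- (i + 1L):nrow(pk)
      d2 <- (pk[later, 1L] - pk[i, 1L])^2 + (pk[later, 2L] - pk[i, 2L])^2
      keep[later][d2 < min_sep2] <- FALSE
    }
  }
  pk <- pk[keep, , drop = FALSE]; resp <- resp[keep]

  win <- max(ceiling(2 * sigma_px), 2L)
  out <- lapply(seq_len(nrow(pk)), function(i) {
    r0 <- pk[i, 1L]; c0 <- pk[i, 2L]
    lab <- labels[r0, c0]
    if (lab == 0L) return(NULL)
    rr <- max(1L, r0 - win):min(nr, r0 + win)
    cc <- max(1L, c0 - win):min(nc, c0 + win)
    sub <- L[rr, cc]
    lev <- max(thr, params$focus_rel_level * resp[i])
    sel <- which(sub >= lev, arr.ind = TRUE)
    w <- pmax(spot_image[cbind(rr[sel[, 1L]], cc[sel[, 2L]])], 0)
    if (sum(w) <= 0) w <- rep(1, nrow(sel))
    cy <- sum((rr[sel[, 1L]] - 0.5) * w) / sum(w)
    cx <- sum((cc[sel[, 2L]] - 0.5) * w) / sum(w)
    data.frame(nucleus_id = lab,
               x_um = cx * pixel_size_um, y_um = cy * pixel_size_um,
               peak_intensity = spot_image[r0, c0],
               focus_area_px = nrow(sel))
  })
  out <- do.call(rbind, out)
  if (is.null(out)) empty else out
}

#' Measure per-nucleus morphometry and channel intensities
#'
#' Integrated intensity is the sum of the raw channel over the labelled
#' pixels; the mean over the same pixels is also reported, together with
#' area, solidity and centroid.
#'
#' @param labels Integer label matrix.
#' @param channel_images Named list of matrices co-registered with
#'   `labels` (e.g. `list(dapi = ..., edu = ...)`).
#' @param pixel_size_um Pixel size in micrometres.
#' @return Data frame with one row per label.
#' @export
measure_cells <- function(labels, channel_images, pixel_size_um = 0.108) {
  stopifnot(is.list(channel_images), length(channel_images) >= 1,
            !is.null(names(channel_images)))
  for (ch in channel_images) stopifnot(all(dim(ch) == dim(labels)))
  label_records(labels, channel_images, pixel_size_um)
}
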