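# DAPI/EdU cell-cycle gating: fit gates on log2-transformed integrated
# intensities, then assign G1 / S / G2M labels, excluding subG1 and >4N
# cells from analysis.

#' Fit cell-cycle gates from integrated DAPI and EdU intensities
#'
#' EdU-positive cells (S phase) are separated by a data-driven threshold
#' on log2 EdU (the density valley between the negative and positive
#' modes; Otsu on the log2 histogram as fallback).  The G1 and G2/M
#' centres are then fitted on the log2 DAPI of EdU-negative cells:
#' `method = "gmm2"` uses a two-component Gaussian mixture,
#' `method = "valley"` uses the two dominant density modes.  Since G2/M
#' cells carry twice the G1 DNA content, the fitted separation is
#' constrained to 1 log2 unit (within `center_tol`); a separation below
#' 0.5 log2 units is treated as a unimodal DAPI distribution and raises
#' an error.  Phase windows default to `window_k` times the fitted
#' component scale.
#'
#' @param cell_table Data frame with `dapi_integrated` and (optionally)
#'   `edu_integrated` columns.
#' @param method `"gmm2"` or `"valley"`.
#' @param window_k Half-width of the G1/G2M windows in units of the
#'   fitted component SD.
#' @param center_tol Allowed deviation of the fitted G2-G1 separation
#'   from 1 log2 unit before it is clamped.
#' @return Object of class `phase_gates`: `g1_center`, `g2_center`,
#'   `g1_window`, `g2_window` (log2 DAPI units), `edu_threshold` (log2
#'   EdU; `NA` when the EdU channel is absent), `method`, `n_cells`.
#' @export
fit_gates <- function(cell_table, method = c("gmm2", "valley"),
                      window_k = 3, center_tol = 0.2) {
  method <- match.arg(method)
  stopifnot("dapi_integrated" %in% names(cell_table))
  n <- nrow(cell_table)
  if (n < 200) {
    warning("fewer than 200 cells; gate estimates may be unstable")
  }
  has_edu <- "edu_integrated" %in% names(cell_table) &&
    any(is.finite(cell_table$edu_integrated))
  edu_threshold <- NA_real_
  edu_neg <- rep(TRUE, n)
  if (has_edu) {
    le <- log2(pmax(cell_table$edu_integrated, .Machine$double.eps))
    edu_threshold <- valley_threshold(le)
    edu_neg <- le < edu_threshold
  }
  ld <- log2(pmax(cell_table$dapi_integrated, .Machine$double.eps))
  x <- ld[edu_neg]
  if (length(x) < 20) stop("too few EdU-negative cells to fit DAPI gates")

  if (method == "gmm2") {
    # two-component unequal-variance Gaussian EM, deterministically
    # initialised from an Otsu split of the log2 DAPI histogram
    init_hi <- x > otsu_threshold(x)
    if (sum(init_hi) < 2 || sum(!init_hi) < 2) {
      stop("DAPI distribution appears unimodal: no G2/M (4N) mode found")
    }
    fit <- mclust::meV(data = x, z = mclust::unmap(init_hi + 1L))
    if (is.null(fit$parameters) || anyNA(fit$parameters$mean)) {
      stop("two-component DAPI mixture fit failed")
    }
    mu <- as.numeric(fit$parameters$mean)
    sdc <- sqrt(as.numeric(fit$parameters$variance$sigmasq))
    if (length(sdc) == 1) sdc <- rep(sdc, 2)
    o <- order(mu)
    mu <- mu[o]; sdc <- sdc[o]
  } else {
    dens <- density(x, n = 512)
    modes <- local_maxima(dens$y)
    if (length(modes) < 2) {
      stop("DAPI distribution appears unimodal: no G2/M (4N) mode found")
    }
    top2 <- modes[order(dens$y[modes], decreasing = TRUE)[1:2]]
    mu <- sort(dens$x[top2])
    split <- mean(mu)
    sdc <- c(mad(x[x < split], center = mu[1]),
             mad(x[x >= split], center = mu[2]))
  }
  sep <- mu[2] - mu[1]
  if (sep < 0.5) {
    stop("DAPI distribution appears unimodal (fitted 2N/4N separation ",
         round(sep, 3), " log2 units < 0.5): no 4N population detected")
  }
  sep <- min(max(sep, 1 - center_tol), 1 + center_tol)
  structure(list(g1_center = mu[1], g2_center = mu[1] + sep,
                 g1_window = window_k * sdc[1],
                 g2_window = window_k * sdc[2],
                 edu_threshold = edu_threshold,
                 method = method, n_cells = n),
            class = "phase_gates")
}

# indices of strict local maxima of a vector
local_maxima <- function(y) {
  n <- length(y)
  which(c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] &
            y[2:(n - 1)] >= y[3:n], FALSE))
}

# threshold between the two modes of a 1-D sample: deepest density valley
# between the two dominant modes; Otsu fallback when unimodal
valley_threshold <- function(x) {
  dens <- density(x, n = 512)
  modes <- local_maxima(dens$y)
  if (length(modes) >= 2) {
    top2 <- sort(modes[order(dens$y[modes], decreasing = TRUE)[1:2]])
    seg <- top2[1]:top2[2]
    return(dens$x[seg[which.min(dens$y[seg])]])
  }
  otsu_threshold(x)
}

#' Assign cell-cycle phases from fitted gates
#'
#' Cells with log2 DAPI below the lower edge of the G1 window (subG1) or
#' above the upper edge of the G2/M window (>4N) are labelled `excluded`
#' and kept out of all phase-stratified analysis.  Of the remaining
#' cells, EdU-positive ones are `S`; EdU-negative cells inside the G1 or
#' G2/M window get that label; EdU-negative cells between the windows are
#' `unassigned` by default, or snapped to the nearest window when
#' `intermediate = "nearest"`.
#'
#' @param cell_table Data frame with `dapi_integrated` and optionally
#'   `edu_integrated`.
#' @param gates A [fit_gates()] result.
#' @param intermediate `"unassigned"` (default) or `"nearest"`.
#' @return Character vector of labels (`G1`, `S`, `G2M`, `excluded`,
#'   `unassigned`), one per row; every cell is labelled.
#' @export
assign_phases <- function(cell_table, gates,
                          intermediate = c("unassigned", "nearest")) {
  intermediate <- match.arg(intermediate)
  stopifnot(inherits(gates, "phase_gates"))
  ld <- log2(pmax(cell_table$dapi_integrated, .Machine$double.eps))
  n <- length(ld)
  edu_pos <- rep(FALSE, n)
  if (!is.na(gates$edu_threshold) &&
      "edu_integrated" %in% names(cell_table)) {
    le <- log2(pmax(cell_table$edu_integrated, .Machine$double.eps))
    edu_pos <- le >= gates$edu_threshold
  }
  lo <- gates$g1_center - gates$g1_window
  hi <- gates$g2_center + gates$g2_window
  phase <- rep("unassigned", n)
  excluded <- ld < lo | ld > hi
  phase[excluded] <- "excluded"
  s <- !excluded & edu_pos
  phase[s] <- "S"
  rest <- !excluded & !edu_pos
  in_g1 <- rest & abs(ld - gates$g1_center) <= gates$g1_window
  in_g2 <- rest & abs(ld - gates$g2_center) <= gates$g2_window
  # ambiguity between overlapping windows resolved by proximity
  both <- in_g1 & in_g2
  nearer_g1 <- abs(ld - gates$g1_center) <= abs(ld - gates$g2_center)
  phase[in_g1 & !both] <- "G1"
  phase[in_g2 & !both] <- "G2M"
  phase[both] <- ifelse(nearer_g1[both], "G1", "G2M")
  if (intermediate == "nearest") {
    mid <- rest & !in_g1 & !in_g2
    phase[mid] <- ifelse(nearer_g1[mid], "G1", "G2M")
  }
  phase
}
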