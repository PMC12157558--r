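# Screen statistics: per-cell QC, per-well aggregation, B-score plate
# normalization, robust Z standardization, replicate merging, hit calling
# and phenotype categorization.

#' QC-filter cells on nuclear morphology
#'
#' Removes dysmorphic nuclei (`solidity < min_solidity`) and abnormally
#' small nuclei indicative of micronuclei (`area_um2 < min_area_um2`).
#' Both comparisons are strict, so a cell exactly at a threshold is
#' retained.  Exclusion counts are tallied per well and reason.
#'
#' @param cell_table Data frame with at least `solidity` and `area_um2`.
#' @param min_solidity Solidity threshold (default 0.85).
#' @param min_area_um2 Area threshold in square micrometres (default 30).
#' @return List with `cells` (passing rows), `excluded` (failing rows) and
#'   `counts` (per-well exclusion counts by reason, when well columns are
#'   present; otherwise totals).
#' @export
qc_filter_cells <- function(cell_table, min_solidity = 0.85,
                            min_area_um2 = 30) {
  need <- c("solidity", "area_um2")
  miss <- setdiff(need, names(cell_table))
  if (length(miss) > 0) {
    stop("cell_table is missing required columns: ",
         paste(miss, collapse = ", "))
  }
  low_sol <- cell_table$solidity < min_solidity
  low_area <- cell_table$area_um2 < min_area_um2
  fail <- low_sol | low_area
  well_cols <- intersect(c("plate", "row", "col", "replicate"),
                         names(cell_table))
  if (length(well_cols) > 0 && any(fail)) {
    key <- interaction(cell_table[fail, well_cols, drop = FALSE],
                       drop = TRUE)
    counts <- data.frame(
      well = levels(key),
      n_low_solidity = as.integer(tapply(low_sol[fail], key, sum)),
      n_low_area = as.integer(tapply(low_area[fail], key, sum)),
      row.names = NULL
    )
  } else {
    counts <- data.frame(well = "all",
                         n_low_solidity = sum(low_sol),
                         n_low_area = sum(low_area))
  }
  list(cells = cell_table[!fail, , drop = FALSE],
       excluded = cell_table[fail, , drop = FALSE],
       counts = counts)
}

#' Aggregate QC-passing cells to per-well summaries
#'
#' Computes arithmetic means (or medians with `fun = "median"`) of the
#' per-cell metrics for every well of the plate map, plus the passing
#' cell count.  Wells present in the plate map but without any passing
#' cell are kept with missing means and `empty_well = TRUE`.
#'
#' @param cell_table QC-passing cells with `plate`, `row`, `col`,
#'   `replicate` keys and metric columns `spot_count`,
#'   `clustering_score`, `mean_norm_radial`, `area_um2` (those present
#'   are summarised).
#' @param plate_map Data frame from [build_plate_map()] (columns `plate`,
#'   `row`, `col`, `perturbation`, `control_class`).
#' @param fun `"mean"` (the default) or `"median"`.
#' @return `well_summary` data frame, one row per well x replicate.
#' @export
aggregate_wells <- function(cell_table, plate_map, fun = c("mean", "median")) {
  fun <- match.arg(fun)
  agg_fun <- if (fun == "mean") {
    function(x) mean(x, na.rm = TRUE)
  } else {
    function(x) median(x, na.rm = TRUE)
  }
  ck <- paste(cell_table$plate, cell_table$row, cell_table$col)
  pk <- paste(plate_map$plate, plate_map$row, plate_map$col)
  orphans <- unique(ck[!ck %in% pk])
  if (length(orphans) > 0) {
    stop("cells reference wells absent from the plate map: ",
         paste(head(orphans, 10), collapse = "; "))
  }
  reps <- sort(unique(cell_table$replicate))
  metrics <- intersect(c("spot_count", "clustering_score",
                         "mean_norm_radial", "area_um2"),
                       names(cell_table))
  out <- vector("list", length(reps))
  for (i in seq_along(reps)) {
    rcells <- cell_table[cell_table$replicate == reps[i], , drop = FALSE]
    rk <- paste(rcells$plate, rcells$row, rcells$col)
    ws <- plate_map
    ws$replicate <- reps[i]
    grp <- match(rk, pk)
    ws$n_cells <- as.integer(tabulate(grp, nbins = nrow(plate_map)))
    for (m in metrics) {
      v <- rep(NA_real_, nrow(plate_map))
      means <- tapply(rcells[[m]], grp, agg_fun)
      v[as.integer(names(means))] <- as.numeric(means)
      ws[[paste0("mean_", sub("^mean_", "", m))]] <- v
    }
    ws$empty_well <- ws$n_cells == 0L
    out[[i]] <- ws
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("well_summary", "data.frame")
  res
}

#' B-score normalization of one plate
#'
#' Centers the plate by the median of the library wells, removes additive
#' row and column effects by two-way median polish computed on the
#' library wells only (control wells are masked out of the polish but
#' still receive residuals), and scales residuals by the robust spread
#' (1.4826 x MAD) of the library-well residuals.
#'
#' @param plate_matrix Numeric rows x columns matrix of well means
#'   (missing wells as `NA`).
#' @param library_mask Logical matrix of the same shape: `TRUE` where the
#'   well carries a library sgRNA.
#' @param max_iter Maximum polish iterations.
#' @param tol Convergence tolerance on the residual row/column medians.
#' @return List with `b_scores` (matrix), `residuals`, `row_effects`,
#'   `col_effects`, `overall`, `scale` (the robust SD used),
#'   `scale_fallback` (TRUE when the MAD was zero and the SD was used)
#'   and `converged` (FALSE when the polish stopped at `max_iter`).
#' @export
bscore_normalize <- function(plate_matrix, library_mask,
                             max_iter = 10L, tol = 1e-6) {
  stopifnot(is.matrix(plate_matrix), is.logical(library_mask),
            all(dim(plate_matrix) == dim(library_mask)))
  lib_vals <- plate_matrix[library_mask]
  if (sum(is.finite(lib_vals)) < 4 ||
      length(unique(which(library_mask, arr.ind = TRUE)[, 1])) < 2 ||
      length(unique(which(library_mask, arr.ind = TRUE)[, 2])) < 2) {
    stop("need library wells in at least 2 rows and 2 columns")
  }
  centered <- plate_matrix - median(lib_vals, na.rm = TRUE)
  polish_in <- centered
  polish_in[!library_mask] <- NA
  converged <- TRUE
  mp <- withCallingHandlers(
    medpolish(polish_in, eps = tol, maxiter = max_iter,
              na.rm = TRUE, trace.iter = FALSE),
    warning = function(w) {
      if (grepl("did not converge", conditionMessage(w))) {
        converged <<- FALSE
        invokeRestart("muffleWarning")
      }
    })
  row_eff <- ifelse(is.na(mp$row), 0, mp$row)
  col_eff <- ifelse(is.na(mp$col), 0, mp$col)
  fitted <- mp$overall + outer(row_eff, col_eff, `+`)
  resid <- centered - fitted
  lib_resid <- resid[library_mask]
  scale <- mad(lib_resid, na.rm = TRUE) # includes the 1.4826 factor
  fallback <- FALSE
  # a MAD at floating-point-residue level (most residuals zero up to
  # rounding) is numerically meaningless as a scale; fall back to the SD
  floor_scale <- 1e-10 * max(abs(resid), 0, na.rm = TRUE)
  if (!is.finite(scale) || scale <= floor_scale) {
    scale <- sd(lib_resid, na.rm = TRUE)
    fallback <- TRUE
    if (!is.finite(scale) || scale == 0) {
      stop("degenerate plate: residuals have zero spread")
    }
  }
  list(b_scores = resid / scale, residuals = resid,
       row_effects = row_eff, col_effects = col_eff,
       overall = mp$overall, scale = scale, scale_fallback = fallback,
       converged = converged)
}

#' Robust Z-score against a reference population
#'
#' `z = (x - median(reference)) / (1.4826 * MAD(reference))`.  A zero MAD
#' falls back to the standard deviation with a warning.
#'
#' @param x Numeric vector to standardize.
#' @param reference Numeric reference values (>= 8 required), e.g. the
#'   library-well values of one replicate.
#' @return Numeric vector of robust Z-scores.
#' @export
robust_z <- function(x, reference) {
  reference <- reference[is.finite(reference)]
  if (length(reference) < 8) {
    stop("need at least 8 finite reference values")
  }
  ctr <- median(reference)
  scale <- mad(reference)
  if (scale == 0) {
    warning("reference MAD is zero; falling back to the SD")
    scale <- sd(reference)
    if (!is.finite(scale) || scale == 0) {
      stop("degenerate reference: zero spread")
    }
  }
  (x - ctr) / scale
}

#' Merge replicate Z-score tables
#'
#' Averages the per-replicate Z-scores of each perturbation x metric into
#' a mean Z-score and records the sample SD over replicates (for two
#' replicates, `|z1 - z2| / sqrt(2)`).  With a single replicate the SD is
#' `NA`.  Missing values propagate as `NA`.
#'
#' @param z_tables List of data frames (one per replicate) with columns
#'   `perturbation`, `metric`, `z`.
#' @return `zscore_table` data frame: `perturbation`, `metric`, `mean_z`,
#'   `z_sd`, `n_replicates`.
#' @export
merge_replicates <- function(z_tables) {
  stopifnot(is.list(z_tables), length(z_tables) >= 1)
  keys <- lapply(z_tables, function(t)
    sort(paste(t$perturbation, t$metric)))
  for (i in seq_along(keys)[-1]) {
    if (!identical(keys[[1]], keys[[i]])) {
      diffs <- c(setdiff(keys[[1]], keys[[i]]),
                 setdiff(keys[[i]], keys[[1]]))
      stop("replicate tables have mismatched keys: ",
           paste(head(diffs, 10), collapse = "; "))
    }
  }
  base <- z_tables[[1]][order(z_tables[[1]]$perturbation,
                              z_tables[[1]]$metric),
                        c("perturbation", "metric")]
  zmat <- vapply(z_tables, function(t) {
    t <- t[order(t$perturbation, t$metric), ]
    t$z
  }, numeric(nrow(base)))
  zmat <- matrix(zmat, nrow = nrow(base))
  base$mean_z <- rowMeans(zmat)
  base$z_sd <- if (ncol(zmat) >= 2) apply(zmat, 1, sd) else NA_real_
  base$n_replicates <- ncol(zmat)
  rownames(base) <- NULL
  class(base) <- c("zscore_table", "data.frame")
  base
}

#' Call screen hits from merged Z-scores
#'
#' Applies the exclusion rules first: a gene is `cytotoxic` when its
#' cell-number mean Z-score is below `cytotox_z`; a metric is
#' `inconsistent` for a gene when the absolute mean Z is smaller than the
#' SD of the replicate Zs; optionally, genes whose dysmorphic-nucleus
#' burden Z exceeds `dysmorphic_z` are excluded (`dysmorphic-excess`).
#' Surviving genes are hits when `|mean_z| >= hit_abs_z` on the spot-count
#' or clustering-score metric; the direction is recorded per metric
#' (`clustered`/`unclustered` for the clustering score, `higher`/`lower`
#' for the spot count).
#'
#' @param zscores A [merge_replicates()] table with metrics
#'   `"clustering_score"` and `"spot_count"`.
#' @param cellcount_z Data frame with `perturbation`, `mean_z` for the
#'   cell-number metric.
#' @param hit_abs_z Absolute mean-Z hit threshold (default 2.5).
#' @param cytotox_z Cell-number Z below which a gene is excluded as
#'   cytotoxic (default -2.5).
#' @param dysmorphic_z Optional named numeric vector (per perturbation) of
#'   dysmorphic-burden Z-scores; values above 2.5 trigger exclusion.
#' @return `hit_table` data frame: per perturbation, per-metric mean Z,
#'   SD, hit flags and directions, overall `hit`, `excluded` and
#'   semicolon-separated `reasons`.
#' @export
call_hits <- function(zscores, cellcount_z, hit_abs_z = 2.5,
                      cytotox_z = -2.5, dysmorphic_z = NULL) {
  stopifnot(inherits(zscores, "data.frame"),
            all(c("perturbation", "metric", "mean_z", "z_sd") %in%
                  names(zscores)))
  genes <- sort(unique(zscores$perturbation))
  get_metric <- function(metric, col) {
    i <- match(paste(genes, metric),
               paste(zscores$perturbation, zscores$metric))
    zscores[[col]][i]
  }
  zc <- get_metric("clustering_score", "mean_z")
  zc_sd <- get_metric("clustering_score", "z_sd")
  zs <- get_metric("spot_count", "mean_z")
  zs_sd <- get_metric("spot_count", "z_sd")
  cc <- cellcount_z$mean_z[match(genes, cellcount_z$perturbation)]

  cytotoxic <- !is.na(cc) & cc < cytotox_z
  incon_c <- !is.na(zc) & !is.na(zc_sd) & abs(zc) < zc_sd
  incon_s <- !is.na(zs) & !is.na(zs_sd) & abs(zs) < zs_sd
  dys <- rep(FALSE, length(genes))
  if (!is.null(dysmorphic_z)) {
    dv <- dysmorphic_z[genes]
    dys <- !is.na(dv) & dv > 2.5
  }
  hit_c <- !cytotoxic & !dys & !incon_c & !is.na(zc) & abs(zc) >= hit_abs_z
  hit_s <- !cytotoxic & !dys & !incon_s & !is.na(zs) & abs(zs) >= hit_abs_z
  reasons <- vapply(seq_along(genes), function(i) {
    r <- c(if (cytotoxic[i]) "cytotoxic",
           if (dys[i]) "dysmorphic-excess",
           if (incon_c[i]) "inconsistent:clustering_score",
           if (incon_s[i]) "inconsistent:spot_count")
    paste(r, collapse = ";")
  }, character(1))
  out <- data.frame(
    perturbation = genes,
    clustering_mean_z = zc, clustering_z_sd = zc_sd,
    spot_mean_z = zs, spot_z_sd = zs_sd,
    cellcount_mean_z = cc,
    hit_clustering = hit_c,
    direction_clustering = ifelse(hit_c,
                                  ifelse(zc > 0, "clustered", "unclustered"),
                                  NA_character_),
    hit_spot = hit_s,
    direction_spot = ifelse(hit_s, ifelse(zs > 0, "higher", "lower"),
                            NA_character_),
    hit = hit_c | hit_s,
    excluded = cytotoxic | dys | (incon_c & incon_s),
    reasons = reasons,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("hit_table", "data.frame")
  out
}

#' Categorize hits by the joint behaviour of the two metrics
#'
#' Each hit is assigned exactly one category: hits on a single metric are
#' `clustering-only` or `count-only`; genes hitting both metrics are split
#' by the sign pattern: increased clustering score with decreased spot
#' count indicates higher overall clustering; the opposite pattern
#' indicates overall dispersion; decreases on both suggest global
#' dispersion with local clustering into fewer, larger clusters; and
#' increases on both indicate more, locally concentrated spots.
#'
#' @param hits A [call_hits()] table.
#' @return List with `genes` (per-hit category assignments) and `counts`
#'   (table of category frequencies).
#' @export
categorize_hits <- function(hits) {
  stopifnot(inherits(hits, "data.frame"),
            all(c("hit_clustering", "hit_spot") %in% names(hits)))
  h <- hits[hits$hit & !hits$excluded, , drop = FALSE]
  category <- character(nrow(h))
  both <- h$hit_clustering & h$hit_spot
  category[h$hit_clustering & !h$hit_spot] <- "clustering-only"
  category[!h$hit_clustering & h$hit_spot] <- "count-only"
  up_c <- h$clustering_mean_z > 0
  up_s <- h$spot_mean_z > 0
  category[both & up_c & !up_s] <- "higher overall clustering"
  category[both & !up_c & up_s] <- "overall dispersion"
  category[both & !up_c & !up_s] <-
    "global dispersion, local clustering"
  category[both & up_c & up_s] <- "increased count and clustering"
  genes <- data.frame(perturbation = h$perturbation, category = category,
                      stringsAsFactors = FALSE)
  list(genes = genes, counts = table(category))
}
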