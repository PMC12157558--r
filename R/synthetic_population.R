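# Simulated cell populations: DAPI/EdU cell-cycle mixtures and full
# multi-plate arrayed screens with planted effects and plate artifacts.

#' Cell-cycle mixture parameters
#'
#' @param fractions Numeric vector `(G1, S, G2M)` summing to 1.
#' @param dapi_2n_mean Mean integrated DAPI intensity of a 2N (G1) cell.
#'   G2/M cells have exactly twice this mean; S-phase DNA content is
#'   uniform between 2N and 4N.
#' @param dapi_cv Coefficient of variation of measured DAPI intensity
#'   around the true DNA content (log-normal measurement error).
#' @param edu_pos_mean,edu_neg_mean Mean integrated EdU intensity of
#'   S-phase (labelled) and non-S (background) cells; must satisfy
#'   `edu_pos_mean > edu_neg_mean`.
#' @param edu_cv Coefficient of variation of EdU intensity.
#' @param spot_count_g1 True centromere spot count of a G1 cell; doubles
#'   across S phase so G2/M cells carry twice as many detectable spots.
#' @return Object of class `cell_cycle_mixture_params`.
#' @export
cell_cycle_mixture_params <- function(fractions = c(0.5, 0.25, 0.25),
                                      dapi_2n_mean = 1e6,
                                      dapi_cv = 0.08,
                                      edu_pos_mean = 5e5,
                                      edu_neg_mean = 1e4,
                                      edu_cv = 0.3,
                                      spot_count_g1 = 46L) {
  stopifnot(length(fractions) == 3, all(fractions >= 0),
            abs(sum(fractions) - 1) < 1e-9,
            dapi_2n_mean > 0, dapi_cv > 0,
            edu_pos_mean > edu_neg_mean, edu_neg_mean > 0,
            spot_count_g1 >= 1)
  structure(list(fractions = fractions, dapi_2n_mean = dapi_2n_mean,
                 dapi_cv = dapi_cv, edu_pos_mean = edu_pos_mean,
                 edu_neg_mean = edu_neg_mean, edu_cv = edu_cv,
                 spot_count_g1 = as.integer(spot_count_g1)),
            class = "cell_cycle_mixture_params")
}

# log-normal with exact mean m and coefficient of variation cv
rlnorm_mean_cv <- function(n, m, cv) {
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate a DAPI/EdU cell-cycle population
#'
#' Draws phases from the mixture fractions, assigns true DNA content
#' (2N for G1, uniform 2N-4N for S, 4N for G2/M), and generates measured
#' integrated intensities with log-normal error.  True spot counts scale
#' with DNA content.  If the DAPI CV is large enough that the 2N and 4N
#' log2 modes overlap substantially (CV > 0.2), a `separability_warning`
#' attribute is set on the result.
#'
#' @param params A [cell_cycle_mixture_params()] object.
#' @param n_cells Number of cells.
#' @param seed Integer seed.
#' @return Data frame with columns `cell_id`, `dapi_integrated`,
#'   `edu_integrated`, `true_phase` and `true_spot_count`.
#' @export
simulate_cell_cycle_population <- function(params, n_cells = 5000L,
                                           seed = 1L) {
  stopifnot(inherits(params, "cell_cycle_mixture_params"), n_cells >= 1)
  with_seed(seed, {
    phase <- sample(c("G1", "S", "G2M"), n_cells, replace = TRUE,
                    prob = params$fractions)
    content <- ifelse(phase == "G1", 1,
                      ifelse(phase == "G2M", 2, NA))
    content[phase == "S"] <- runif(sum(phase == "S"), 1, 2)
    dapi <- rlnorm_mean_cv(n_cells, params$dapi_2n_mean, params$dapi_cv) *
      content
    edu_mean <- ifelse(phase == "S", params$edu_pos_mean,
                       params$edu_neg_mean)
    edu <- rlnorm_mean_cv(n_cells, 1, params$edu_cv) * edu_mean
    spots <- as.integer(round(params$spot_count_g1 * content))
    out <- data.frame(cell_id = seq_len(n_cells),
                      dapi_integrated = dapi,
                      edu_integrated = edu,
                      true_phase = phase,
                      true_spot_count = spots)
    attr(out, "params") <- params
    attr(out, "separability_warning") <- params$dapi_cv > 0.2
    out
  })
}

#' Screen design configuration
#'
#' Describes a multi-plate, multi-replicate arrayed screen on 384-well
#' plates (16 rows x 24 columns by default).  Library sgRNA wells occupy
#' the interior columns; the outer columns carry the four control classes:
#' a scrambled non-targeting control, a neutral gene-targeting control
#' (OR10A5-like), a lethal transfection control (PLK1-like, implemented as
#' a strong cell-count reduction) and a clustering-inducing positive
#' control (NCAPH2-like).
#'
#' Planted per-gene effects are expressed in units of the robust spread
#' (1.4826 x MAD, i.e. SD-equivalents) of the library well means, so an
#' effect of 4 is expected to score close to a robust Z of 4 downstream.
#'
#' @param n_genes Number of library genes (one well per gene per plate set).
#' @param rows,cols Plate dimensions.
#' @param n_replicates Number of biological replicates sharing the layout.
#' @param cells_per_well Expected (Poisson) cell count per healthy well.
#' @param baseline Named list of per-cell feature distributions:
#'   `clustering_mean`, `clustering_sd_cell`, `spot_count_mean`,
#'   `spot_count_sd`, `radial_mean`, `radial_sd`, `area_mean`, `area_sd`,
#'   `solidity_mean`, `solidity_sd`, plus well-to-well biological
#'   variability `well_sd_clustering`, `well_sd_spot` and contamination
#'   rates `dysmorphic_frac`, `micronucleus_frac`.
#' @param planted_effects Data frame with columns `perturbation`,
#'   `d_clustering`, `d_spot`, `d_cellcount` (robust-SD units); genes not
#'   listed are neutral.
#' @param artifact_row_sd,artifact_col_sd Standard deviations of additive
#'   per-plate row and column offsets, in library robust-SD units,
#'   applied to the well-mean scale of both screen metrics.
#' @param lethal_cell_frac Fraction of the baseline cell count retained in
#'   lethal-control wells.
#' @param n_ctrl_per_class Control wells per class per plate.
#' @param clustering_ctrl_effect Planted clustering shift (robust-SD
#'   units) of the NCAPH2-like positive-control wells.
#' @param seed Integer seed.
#' @return Object of class `screen_design`.
#' @export
screen_design <- function(n_genes = 1040L, rows = 16L, cols = 24L,
                          n_replicates = 2L, cells_per_well = 100,
                          baseline = list(), planted_effects = NULL,
                          artifact_row_sd = 0, artifact_col_sd = 0,
                          lethal_cell_frac = 0.03,
                          n_ctrl_per_class = 8L,
                          clustering_ctrl_effect = 5,
                          seed = 1L) {
  base_default <- list(
    clustering_mean = 0, clustering_sd_cell = 1.5,
    spot_count_mean = 46, spot_count_sd = 6,
    radial_mean = 0.66, radial_sd = 0.06,
    area_mean = 120, area_sd = 25,
    solidity_mean = 0.95, solidity_sd = 0.03,
    well_sd_clustering = 0.12, well_sd_spot = 0.5,
    dysmorphic_frac = 0.03, micronucleus_frac = 0.02
  )
  baseline <- modifyList(base_default, baseline)
  if (is.null(planted_effects)) {
    planted_effects <- data.frame(perturbation = character(),
                                  d_clustering = numeric(),
                                  d_spot = numeric(),
                                  d_cellcount = numeric())
  }
  lib_per_plate <- (cols - 2L) * rows
  n_plates <- ceiling(n_genes / lib_per_plate)
  structure(list(n_genes = as.integer(n_genes), rows = as.integer(rows),
                 cols = as.integer(cols), n_plates = as.integer(n_plates),
                 n_replicates = as.integer(n_replicates),
                 cells_per_well = cells_per_well, baseline = baseline,
                 planted_effects = planted_effects,
                 artifact_row_sd = artifact_row_sd,
                 artifact_col_sd = artifact_col_sd,
                 lethal_cell_frac = lethal_cell_frac,
                 n_ctrl_per_class = as.integer(n_ctrl_per_class),
                 clustering_ctrl_effect = clustering_ctrl_effect,
                 seed = as.integer(seed)),
            class = "screen_design")
}

#' Build the plate map for a screen design
#'
#' Library genes fill the interior columns (2..cols-1) row-wise across as
#' many plates as needed; control wells alternate through the first and
#' last columns.  Rows are lettered A.., columns 1-based, matching
#' 384-well convention.
#'
#' @param design A [screen_design()] object.
#' @return Data frame: `plate`, `row`, `col`, `well`, `perturbation`,
#'   `control_class` (one of library, scrambled, neutral_ctrl,
#'   lethal_ctrl, clustering_ctrl, empty).
#' @export
build_plate_map <- function(design) {
  stopifnot(inherits(design, "screen_design"))
  rows <- design$rows; cols <- design$cols
  row_letters <- LETTERS[seq_len(rows)]
  maps <- vector("list", design$n_plates)
  gene_names <- sprintf("GENE%04d", seq_len(design$n_genes))
  g <- 0L
  ctrl_classes <- c("scrambled", "neutral_ctrl", "lethal_ctrl",
                    "clustering_ctrl")
  for (p in seq_len(design$n_plates)) {
    grid <- expand.grid(row = row_letters, col = seq_len(cols),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    grid$plate <- p
    grid$perturbation <- NA_character_
    grid$control_class <- "empty"
    # controls in the outer columns, cycling through the classes
    edge <- which(grid$col %in% c(1L, cols))
    wanted <- rep(ctrl_classes, each = design$n_ctrl_per_class)
    wanted <- rep_len(wanted, length(edge))
    grid$control_class[edge] <- wanted
    grid$perturbation[edge] <- paste0(wanted, "_ctrl")
    grid$perturbation[edge] <- c(scrambled = "SCRAMBLED",
                                 neutral_ctrl = "OR10A5like",
                                 lethal_ctrl = "PLK1like",
                                 clustering_ctrl = "NCAPH2like")[wanted]
    interior <- which(!grid$col %in% c(1L, cols))
    for (i in interior) {
      if (g < design$n_genes) {
        g <- g + 1L
        grid$perturbation[i] <- gene_names[g]
        grid$control_class[i] <- "library"
      }
    }
    maps[[p]] <- grid
  }
  pm <- do.call(rbind, maps)
  pm <- pm[pm$control_class != "empty", ]
  pm$well <- paste0(pm$row, pm$col)
  if (anyDuplicated(pm[, c("plate", "row", "col")]))
    stop("duplicated well assignment in plate map")
  rownames(pm) <- NULL
  pm[, c("plate", "row", "col", "well", "perturbation", "control_class")]
}

#' Simulate a full arrayed imaging screen
#'
#' Generates per-cell feature tables for every well, replicate and plate of
#' the design.  Per-cell features are drawn from the library baseline
#' distributions; each well additionally receives a biological well-level
#' offset, its plate's additive row/column artifact, and - for planted
#' genes and the clustering positive control - the planted effect,
#' converted from robust-SD units to the feature scale using the expected
#' spread of library well means.  Lethal-control wells have their cell
#' counts reduced to `lethal_cell_frac` of baseline.
#'
#' @param design A [screen_design()] object.
#' @return List with `cells` (per-cell data frame across all replicates),
#'   `plate_map`, and `truth` (planted effects with expected directions,
#'   per-plate artifact vectors, effect unit conversions, and the design).
#' @export
simulate_screen <- function(design) {
  stopifnot(inherits(design, "screen_design"))
  pm <- build_plate_map(design)
  bad <- design$planted_effects$perturbation[
    !design$planted_effects$perturbation %in% pm$perturbation]
  if (length(bad) > 0)
    stop("planted_effects reference unknown perturbations: ",
         paste(bad, collapse = ", "))
  b <- design$baseline
  # expected robust spread of library well means (per-cell noise averages out)
  sd_well_clust <- sqrt(b$well_sd_clustering^2 +
                          b$clustering_sd_cell^2 / design$cells_per_well)
  sd_well_spot <- sqrt(b$well_sd_spot^2 +
                         b$spot_count_sd^2 / design$cells_per_well)
  sd_well_count <- sqrt(design$cells_per_well)

  eff <- design$planted_effects
  eff_lookup <- function(pert, col) {
    i <- match(pert, eff$perturbation)
    out <- ifelse(is.na(i), 0, eff[[col]][i])
    out
  }

  with_seed(design$seed, {
    all_cells <- vector("list", design$n_replicates)
    artifacts <- vector("list", design$n_plates)
    for (p in seq_len(design$n_plates)) {
      artifacts[[p]] <- list(
        row = rnorm(design$rows, 0, design$artifact_row_sd),
        col = rnorm(design$cols, 0, design$artifact_col_sd)
      )
    }
    for (rep_i in seq_len(design$n_replicates)) {
      wl <- pm
      wl$replicate <- rep_i
      ri <- match(wl$row, LETTERS)
      d_clust <- eff_lookup(wl$perturbation, "d_clustering")
      d_spot <- eff_lookup(wl$perturbation, "d_spot")
      d_count <- eff_lookup(wl$perturbation, "d_cellcount")
      d_clust[wl$control_class == "clustering_ctrl"] <-
        design$clustering_ctrl_effect
      wl$mu_clust <- b$clustering_mean +
        rnorm(nrow(wl), 0, b$well_sd_clustering) +
        d_clust * sd_well_clust +
        vapply(seq_len(nrow(wl)), function(i)
          artifacts[[wl$plate[i]]]$row[ri[i]] +
            artifacts[[wl$plate[i]]]$col[wl$col[i]], numeric(1)) *
        sd_well_clust
      wl$mu_spot <- b$spot_count_mean +
        rnorm(nrow(wl), 0, b$well_sd_spot) +
        d_spot * sd_well_spot +
        vapply(seq_len(nrow(wl)), function(i)
          artifacts[[wl$plate[i]]]$row[ri[i]] +
            artifacts[[wl$plate[i]]]$col[wl$col[i]], numeric(1)) *
        sd_well_spot
      lam <- design$cells_per_well + d_count * sd_well_count
      lam[wl$control_class == "lethal_ctrl"] <-
        design$cells_per_well * design$lethal_cell_frac
      wl$n_cells <- rpois(nrow(wl), pmax(lam, 0.5))

      # expand wells to cells, vectorised
      widx <- rep.int(seq_len(nrow(wl)), wl$n_cells)
      n_tot <- length(widx)
      cells <- wl[widx, c("plate", "row", "col", "well", "perturbation",
                          "control_class", "replicate")]
      cells$clustering_score <- wl$mu_clust[widx] +
        rnorm(n_tot, 0, b$clustering_sd_cell)
      cells$spot_count <- pmax(0L, as.integer(round(
        wl$mu_spot[widx] + rnorm(n_tot, 0, b$spot_count_sd))))
      cells$mean_norm_radial <- pmin(1, pmax(0,
        rnorm(n_tot, b$radial_mean, b$radial_sd)))
      cells$area_um2 <- pmax(5, rnorm(n_tot, b$area_mean, b$area_sd))
      cells$solidity <- pmin(1, rnorm(n_tot, b$solidity_mean, b$solidity_sd))
      dys <- runif(n_tot) < b$dysmorphic_frac
      cells$solidity[dys] <- runif(sum(dys), 0.55, 0.849)
      micro <- runif(n_tot) < b$micronucleus_frac
      cells$area_um2[micro] <- runif(sum(micro), 8, 29.9)
      rownames(cells) <- NULL
      all_cells[[rep_i]] <- cells
    }
    cells <- do.call(rbind, all_cells)
    planted <- design$planted_effects
    if (nrow(planted) > 0) {
      planted$direction_clustering <- ifelse(
        planted$d_clustering > 0, "clustered",
        ifelse(planted$d_clustering < 0, "unclustered", "none"))
      planted$direction_spot <- ifelse(
        planted$d_spot > 0, "higher",
        ifelse(planted$d_spot < 0, "lower", "none"))
    }
    list(cells = cells, plate_map = pm,
         truth = list(planted = planted, artifacts = artifacts,
                      sd_well_clustering = sd_well_clust,
                      sd_well_spot = sd_well_spot,
                      sd_well_count = sd_well_count,
                      design = design))
  })
}
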