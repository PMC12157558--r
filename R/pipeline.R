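# Orchestration: image -> features, wells -> Z-scores, and the end-to-end
# screen pipeline with deterministic artifacts.

#' Extract per-cell features from a two-channel image
#'
#' Runs segmentation, LoG spot detection and the per-cell spatial metrics
#' on one field of view.
#'
#' @param dapi,spot_image 2-D numeric matrices (co-registered).
#' @param pixel_size_um Pixel size.
#' @param seg_params [segmentation_params()].
#' @param spot_params [spot_detection_params()].
#' @param score_params [clustering_score_params()].
#' @return List with `features` (per-nucleus `cell_features` rows),
#'   `records`, `labels` and `spots`.
#' @export
image_to_features <- function(dapi, spot_image, pixel_size_um = 0.108,
                              seg_params = segmentation_params(),
                              spot_params = spot_detection_params(),
                              score_params = clustering_score_params()) {
  seg <- segment_nuclei(dapi, pixel_size_um, seg_params)
  if (nrow(seg$records) == 0) {
    feats <- data.frame(nucleus_id = integer(), spot_count = integer(),
                        clustering_score = numeric(),
                        clustering_flagged = logical(),
                        mean_norm_radial = numeric(),
                        area_um2 = numeric(), solidity = numeric(),
                        phase = character())
    return(list(features = feats, records = seg$records,
                labels = seg$labels, spots = NULL))
  }
  spots <- detect_spots_log(spot_image, seg$labels, pixel_size_um,
                            spot_params)
  feats <- lapply(seq_len(nrow(seg$records)), function(i) {
    rec <- seg$records[i, ]
    sp <- spots[spots$nucleus_id == rec$nucleus_id, , drop = FALSE]
    m <- seg$labels == rec$nucleus_id
    compute_cell_features(rec, sp, m, pixel_size_um, score_params)
  })
  list(features = do.call(rbind, feats), records = seg$records,
       labels = seg$labels, spots = spots)
}

#' Per-replicate B-scores and robust Z-scores for every well
#'
#' For each replicate and metric, builds the row x column matrix of well
#' means per plate, removes positional artifacts with [bscore_normalize()]
#' (library wells drive the polish), pools the B-scores of all plates of
#' the replicate, and standardizes them against the library wells with
#' [robust_z()].  Control wells are scored but never enter the polish or
#' the reference statistics.
#'
#' @param wells A [aggregate_wells()] summary.
#' @param metrics Named character vector mapping metric names to well
#'   summary columns.
#' @return Long data frame: `perturbation`, `control_class`, `plate`,
#'   `row`, `col`, `replicate`, `metric`, `b_score`, `z`.
#' @export
score_wells <- function(wells,
                        metrics = c(clustering_score = "mean_clustering_score",
                                    spot_count = "mean_spot_count",
                                    cell_count = "n_cells")) {
  stopifnot(all(metrics %in% names(wells)))
  out <- list()
  for (rep_i in sort(unique(wells$replicate))) {
    wr <- wells[wells$replicate == rep_i, , drop = FALSE]
    for (m in names(metrics)) {
      col <- metrics[[m]]
      wr$b <- NA_real_
      for (p in sort(unique(wr$plate))) {
        sel <- wr$plate == p
        wp <- wr[sel, , drop = FALSE]
        ri <- match(wp$row, sort(unique(wp$row)))
        ci <- match(wp$col, sort(unique(wp$col)))
        mat <- matrix(NA_real_, max(ri), max(ci))
        lib <- matrix(FALSE, max(ri), max(ci))
        mat[cbind(ri, ci)] <- as.numeric(wp[[col]])
        lib[cbind(ri, ci)] <- wp$control_class == "library"
        bs <- bscore_normalize(mat, lib)
        wr$b[sel] <- bs$b_scores[cbind(ri, ci)]
      }
      z <- robust_z(wr$b, wr$b[wr$control_class == "library"])
      out[[length(out) + 1L]] <- data.frame(
        perturbation = wr$perturbation,
        control_class = wr$control_class,
        plate = wr$plate, row = wr$row, col = wr$col,
        replicate = rep_i, metric = m,
        b_score = wr$b, z = z,
        stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Run the full screen-statistics chain on per-cell data
#'
#' QC filter, per-well aggregation, B-score plate normalization, robust Z
#' standardization, replicate merging, hit calling and categorization.
#' Control wells are merged per individual well (they occur many times
#' per plate); library genes are merged per perturbation.
#'
#' @param cells Per-cell feature table (e.g. from [simulate_screen()]).
#' @param plate_map Plate map data frame.
#' @param config A [pipeline_config()] (QC and hit-calling blocks used).
#' @return List: `wells`, `well_z` (per-well per-replicate scores),
#'   `merged` (mean Z / SD per perturbation x metric), `hits`,
#'   `categories`, `qc_counts`.
#' @export
score_screen <- function(cells, plate_map, config = pipeline_config()) {
  qc <- qc_filter_cells(cells, config$qc$min_solidity,
                        config$qc$min_area_um2)
  wells <- aggregate_wells(qc$cells, plate_map)
  wz <- score_wells(wells)
  # controls are tracked per physical well; library genes per perturbation
  wz$merge_key <- ifelse(wz$control_class == "library", wz$perturbation,
                         paste0(wz$perturbation, "@", wz$plate, ":",
                                wz$row, wz$col))
  z_tables <- lapply(sort(unique(wz$replicate)), function(r) {
    t <- wz[wz$replicate == r, , drop = FALSE]
    data.frame(perturbation = t$merge_key, metric = t$metric, z = t$z,
               stringsAsFactors = FALSE)
  })
  merged <- merge_replicates(z_tables)
  lib_keys <- unique(wz$merge_key[wz$control_class == "library"])
  lib_merged <- merged[merged$perturbation %in% lib_keys, , drop = FALSE]
  cellcount <- lib_merged[lib_merged$metric == "cell_count", ,
                          drop = FALSE]
  hits <- call_hits(
    lib_merged[lib_merged$metric %in%
                 c("clustering_score", "spot_count"), , drop = FALSE],
    cellcount,
    hit_abs_z = config$hits$hit_abs_z,
    cytotox_z = config$hits$cytotox_z
  )
  cats <- categorize_hits(hits)
  list(wells = wells, well_z = wz, merged = merged, hits = hits,
       categories = cats, qc_counts = qc$counts)
}

#' Run the end-to-end screen pipeline and write its artifacts
#'
#' Simulates a screen from the design, runs [score_screen()], and writes
#' deterministic artifacts to `out_dir`: the per-cell table, plate map,
#' well summaries, per-well Z-scores, merged Z table, hit table, hit
#' categories, the resolved configuration (YAML) and a run manifest with
#' per-stage counts and a config checksum.  Identical design + config
#' yield byte-identical output trees.
#'
#' @param design A [screen_design()].
#' @param out_dir Output directory (created if needed).
#' @param config A [pipeline_config()].
#' @return The [score_screen()] result, invisibly, with `out_dir`
#'   attached.
#' @export
run_screen_pipeline <- function(design, out_dir,
                                config = pipeline_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_screen(design)
  res <- score_screen(sim$cells, sim$plate_map, config)
  write_table(sim$cells, file.path(out_dir, "cells.csv"), "cell_features")
  write_table(sim$plate_map, file.path(out_dir, "plate_map.csv"),
              "plate_map")
  write_table(res$wells, file.path(out_dir, "well_summary.csv"),
              "well_summary")
  write_table(res$well_z, file.path(out_dir, "well_zscores.csv"),
              "well_zscores")
  write_table(res$merged, file.path(out_dir, "merged_zscores.csv"),
              "zscore_table")
  write_table(res$hits, file.path(out_dir, "hits.csv"), "hit_table")
  write_table(res$categories$genes, file.path(out_dir, "hit_categories.csv"),
              "hit_categories")
  write_config(config, file.path(out_dir, "config.yaml"))
  cfg_txt <- paste(readLines(file.path(out_dir, "config.yaml")),
                   collapse = "\n")
  manifest <- list(
    package_version = as.character(utils::packageVersion("centroscreen")),
    seed = design$seed,
    config_checksum = sum(utf8ToInt(cfg_txt)),
    n_cells = nrow(sim$cells),
    n_wells = nrow(res$wells),
    n_library_genes = design$n_genes,
    n_hits = sum(res$hits$hit),
    n_excluded = sum(res$hits$excluded)
  )
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(structure(res, out_dir = out_dir))
}
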