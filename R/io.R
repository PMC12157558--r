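# File formats: schema-versioned CSV tables, multi-page TIFF images,
# YAML configuration.

SCHEMA_VERSION <- "1"

#' Write a table as schema-versioned CSV
#'
#' The first line is a comment header `# centroscreen-schema: <name> v<n>`;
#' numeric columns are serialised with 17 significant digits so the
#' round-trip through [read_table()] is lossless; `NA` encodes missing
#' values explicitly.
#'
#' @param x Data frame.
#' @param path Output file path.
#' @param schema Short schema name recorded in the header.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path, schema = "table") {
  x <- as.data.frame(x)
  out <- x
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      v <- formatC(out[[j]], digits = 17, format = "g")
      v[is.na(out[[j]])] <- NA
      out[[j]] <- v
    }
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# centroscreen-schema: %s v%s", schema,
                     SCHEMA_VERSION), con)
  write.csv(out, con, row.names = FALSE, quote = TRUE, na = "NA")
  invisible(path)
}

#' Read a schema-versioned CSV table
#'
#' @param path File written by [write_table()].
#' @param schema Expected schema name; a mismatch (or a missing header) is
#'   an error reporting both versions.
#' @return Data frame.
#' @export
read_table <- function(path, schema = "table") {
  first <- readLines(path, n = 1L)
  m <- regmatches(first,
                  regexec("^# centroscreen-schema: (\\S+) v(\\S+)$", first))[[1]]
  if (length(m) != 3) {
    stop("file has no centroscreen schema header: ", path)
  }
  if (m[2] != schema || m[3] != SCHEMA_VERSION) {
    stop("schema mismatch for ", path, ": file has '", m[2], " v", m[3],
         "', expected '", schema, " v", SCHEMA_VERSION, "'")
  }
  read.csv(path, skip = 1L, stringsAsFactors = FALSE)
}

#' Write a multi-channel cell image as multi-page TIFF
#'
#' Channels are written as 32-bit float pages in the order given.  Each
#' channel is affinely rescaled to `[0, 1]` for storage (the TIFF baseline
#' range); the offsets and scales, the channel names and the pixel size
#' are recorded in a YAML metadata sidecar (`<path>.meta.yaml`) so
#' [read_cell_image()] restores the original intensity scale.  The round
#' trip is lossless at 32-bit float precision (relative error below
#' 1e-6).
#'
#' @param channels Named list of numeric matrices (e.g. `dapi`, `spots`,
#'   `edu`), all the same shape.
#' @param path Output path.
#' @param pixel_size_um Pixel size recorded in the metadata.
#' @return `path` invisibly.
#' @export
write_cell_image <- function(channels, path, pixel_size_um = 0.108) {
  stopifnot(is.list(channels), !is.null(names(channels)))
  meta <- list(pixel_size_um = pixel_size_um, channels = list())
  pages <- vector("list", length(channels))
  for (i in seq_along(channels)) {
    m <- channels[[i]]
    lo <- min(m)
    rg <- diff(range(m))
    if (rg == 0) rg <- 1
    pages[[i]] <- (m - lo) / rg
    meta$channels[[names(channels)[i]]] <- list(offset = lo, scale = rg)
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L,
                  reduce = FALSE, compression = "none")
  yaml::write_yaml(meta, paste0(path, ".meta.yaml"))
  invisible(path)
}

#' Read a multi-channel cell image
#'
#' Pages are mapped to channel names and rescaled to their original
#' intensity range using the metadata sidecar written by
#' [write_cell_image()].  When the sidecar carries a pixel size that
#' disagrees with `pixel_size_um`, the file metadata wins and a warning
#' is emitted.  Requesting a channel the file does not contain is an
#' error naming the file.
#'
#' @param path TIFF path.
#' @param channels Channel names to extract; defaults to all channels in
#'   the sidecar, or positional `dapi`/`spots` naming without one.
#' @param pixel_size_um Expected pixel size (config value).
#' @return Named list of matrices with attribute `pixel_size_um`.
#' @export
read_cell_image <- function(path, channels = NULL,
                            pixel_size_um = 0.108) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  meta_path <- paste0(path, ".meta.yaml")
  px <- pixel_size_um
  meta <- NULL
  if (file.exists(meta_path)) {
    meta <- yaml::read_yaml(meta_path)
    if (!is.null(meta$pixel_size_um) &&
        abs(meta$pixel_size_um - pixel_size_um) >
          1e-9 * pixel_size_um) {
      warning("pixel size in image metadata (", meta$pixel_size_um,
              " um) overrides configured value (", pixel_size_um, " um)")
    }
    px <- meta$pixel_size_um %||% px
  }
  file_channels <- if (!is.null(meta)) {
    names(meta$channels)
  } else {
    c("dapi", "spots", "edu")[seq_along(pages)]
  }
  if (is.null(channels)) channels <- file_channels
  missing_ch <- setdiff(channels, file_channels)
  if (length(missing_ch) > 0) {
    stop("image ", path, " has no channel(s): ",
         paste(missing_ch, collapse = ", "))
  }
  out <- lapply(channels, function(ch) {
    i <- match(ch, file_channels)
    m <- pages[[i]]
    attributes(m) <- list(dim = dim(m))
    if (!is.null(meta)) {
      info <- meta$channels[[ch]]
      m <- m * info$scale + info$offset
    }
    m
  })
  names(out) <- channels
  attr(out, "pixel_size_um") <- px
  out
}

#' Default pipeline configuration
#'
#' All tunable parameters of the pipeline with their defaults, ready to
#' be overridden, serialised to YAML next to a run's outputs.
#'
#' @param ... Named overrides merged over the defaults.
#' @return Nested list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    pixel_size_um = 0.108,
    seed = 1L,
    segmentation = list(min_area_um2 = 20, smoothing_sigma_um = 0.5,
                        split_touching = FALSE, exclude_border = TRUE),
    detection = list(sigma_um = 0.25, threshold_k = 5,
                     min_separation_px = 2),
    clustering = list(radius_min_rel = 0.05, radius_max_rel = 0.5,
                      n_radii = 10, n_mc = 100, min_spots = 3),
    gating = list(method = "gmm2", window_k = 3),
    qc = list(min_solidity = 0.85, min_area_um2 = 30),
    hits = list(hit_abs_z = 2.5, cytotox_z = -2.5)
  )
  over <- list(...)
  if (length(over) > 0) cfg <- modifyList(cfg, over)
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Read / write a pipeline configuration as YAML
#' @param path YAML file path.
#' @return For `read_config`, a `pipeline_config`; for `write_config`,
#'   `path` invisibly.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(pipeline_config, cfg)
}

#' @rdname read_config
#' @param config A [pipeline_config()] object.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
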