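#' Write a frame as multi-page TIFF with a YAML sidecar
#'
#' Channels are written as 16-bit pages (one per channel, in channel
#' order), quantized on a common linear scale recorded in the sidecar;
#' frames whose intensities are integers within the 16-bit range round-trip
#' bit-identically. The sidecar (`<path minus extension>.yaml`) carries the
#' channel names, pixel size, frame id and the quantization scale, since
#' baseline TIFF has no portable slot for them.
#'
#' @param frame an [image_frame()].
#' @param path output TIFF path.
#' @return the path, invisibly.
#' @export
write_frame <- function(frame, path) {
  stopifnot(inherits(frame, "image_frame"))
  mx <- max(vapply(frame$channels, max, numeric(1)), 1)
  int_valued <- all(vapply(frame$channels,
                           function(m) all(m == round(m)), logical(1)))
  # integer frames within the 16-bit range are stored losslessly
  s <- if (int_valued && mx <= 65535) 65535 else mx
  pages <- lapply(frame$channels, function(m) round(m / s * 65535) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  meta <- list(id = frame$id,
               pixel_size = frame$pixel_size,
               channels = as.list(names(frame$channels)),
               scale = s,
               writer = paste("granulemap",
                              as.character(utils::packageVersion("granulemap"))))
  yaml::write_yaml(meta, sidecar_path(path))
  invisible(path)
}

sidecar_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), ".yaml")
}

#' Read a calibrated multi-channel frame from TIFF
#'
#' Channel names and pixel size come from the YAML sidecar written by
#' [write_frame()]; without a sidecar they must come from the config. A
#' `pixel_size` in the config always overrides file metadata, with a
#' warning. When a channel role map is supplied, every role's channel must
#' exist in the file.
#'
#' @param path TIFF path.
#' @param config optional list with `pixel_size`, `channel_names`
#'   (ordered names for sidecar-less files) and/or `channels` (role map:
#'   role -> channel name).
#' @return an [image_frame()].
#' @export
read_frame <- function(path, config = NULL) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(m) {
    attributes(m) <- list(dim = dim(m))
    m
  })
  sc <- sidecar_path(path)
  meta <- if (file.exists(sc)) yaml::read_yaml(sc) else NULL
  scale <- if (!is.null(meta$scale)) meta$scale else 65535
  channels <- lapply(pages, function(m) round(m * 65535) * (scale / 65535))
  ch_names <- unlist(meta$channels)
  if (is.null(ch_names)) ch_names <- config$channel_names
  if (is.null(ch_names) && !is.null(config$channels)) {
    ch_names <- unlist(config$channels, use.names = FALSE)
  }
  if (is.null(ch_names)) {
    stop("channel names unavailable: no sidecar metadata and none in config")
  }
  if (length(ch_names) != length(channels)) {
    stop(sprintf("config names %d channels but file has %d pages",
                 length(ch_names), length(channels)))
  }
  names(channels) <- ch_names
  if (!is.null(config$channels)) {
    wanted <- unlist(config$channels, use.names = FALSE)
    missing <- setdiff(wanted, ch_names)
    if (length(missing)) {
      stop(sprintf("role map names channels absent from file: %s",
                   paste(missing, collapse = ", ")))
    }
  }
  px <- meta$pixel_size
  if (!is.null(config$pixel_size)) {
    if (!is.null(px) && px != config$pixel_size) {
      warning(sprintf(
        "config pixel_size %.4g overrides file metadata %.4g",
        config$pixel_size, px))
    }
    px <- config$pixel_size
  }
  if (is.null(px)) stop("pixel size missing from both file metadata and config")
  id <- if (!is.null(meta$id)) meta$id else basename(path)
  image_frame(channels, px, id = id)
}

#' Assemble and validate a pipeline configuration
#'
#' The YAML config file is the single source of truth for an analysis run;
#' arguments given here override the file (mirroring CLI flag overrides),
#' each override emitting a warning.
#'
#' @param file optional YAML config path.
#' @param ... overrides of top-level config fields.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(file = NULL, ...) {
  cfg <- if (!is.null(file)) yaml::read_yaml(file) else list()
  overrides <- list(...)
  for (nm in names(overrides)) {
    if (!is.null(cfg[[nm]]) && !is.null(file)) {
      warning(sprintf("config field '%s' overridden by argument", nm))
    }
    cfg[[nm]] <- overrides[[nm]]
  }
  defaults <- list(
    containment_rule = "centroid",
    complete_tol = 1,
    min_size = 4L,
    unsharp = list(enabled = FALSE, radius = 100, weight = 0.7),
    thresholds = list(),
    group_by = "phase",
    seed = 1L)
  for (nm in names(defaults)) {
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  }
  if (!is.null(cfg$pixel_size) && cfg$pixel_size <= 0) {
    stop("pixel_size must be positive")
  }
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Hash of a configuration for output provenance
#'
#' MD5 of the canonical YAML serialisation; identical configs always hash
#' identically, so reruns are verifiable from the output files alone. The
#' output directory is excluded: where results are written must not change
#' what they are.
#'
#' @param config a list / `pipeline_config`.
#' @return hex string.
#' @export
config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  yaml::write_yaml(cfg, tf)
  unname(tools::md5sum(tf))
}

# CSV with a one-line provenance comment; stable byte-for-byte across reruns
# of the same config
write_table_csv <- function(df, path, hash) {
  df <- df[, !vapply(df, is.list, logical(1)), drop = FALSE]
  con <- file(path, open = "w")
  on.exit(close(con))
  writeLines(sprintf("# granulemap %s config=%s",
                     as.character(utils::packageVersion("granulemap")), hash),
             con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, qmethod = "double")
  invisible(path)
}

#' Read a pipeline output CSV (skipping the provenance comment)
#' @param path CSV path.
#' @return data.frame.
#' @export
read_table_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write a generated frame, its ground truth and parameters to a directory
#'
#' Output: `frame.tif` (+ `frame.yaml` sidecar), `truth_foci.csv`,
#' `truth_cells.csv`, `params.yaml`.
#'
#' @param sim result of [generate_frame()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_frame(sim$frame, file.path(dir, "frame.tif"))
  hash <- config_hash(sim$truth$params)
  write_table_csv(sim$truth$foci, file.path(dir, "truth_foci.csv"), hash)
  write_table_csv(sim$truth$cells, file.path(dir, "truth_cells.csv"), hash)
  p <- unclass(sim$truth$params)
  p$foci <- lapply(p$foci, as.list)
  yaml::write_yaml(p, file.path(dir, "params.yaml"))
  invisible(dir)
}
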