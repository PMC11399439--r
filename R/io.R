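#' Read per-channel coordinate CSVs
#'
#' Accepts one CSV per channel with header `x,y[,z]`, or a single
#' long-format CSV with header `channel,x,y[,z]` where channel is the
#' letter A, B, ... or the 1-based channel number.
#'
#' @param files character vector of per-channel files (in channel
#'   order), or a single long-format file.
#' @param unit coordinate unit.
#' @param pixel_size_nm physical pixel size.
#' @param k expected channel count for long format (default: channels
#'   present).
#' @return a [point_cloud_set()].
#' @export
read_point_clouds <- function(files, unit = c("px", "nm"),
                              pixel_size_nm = NA_real_, k = NULL) {
  unit <- match.arg(unit)
  for (f in files) {
    if (!file.exists(f)) stop("missing channel file: ", f)
  }
  if (length(files) == 1) {
    df <- read.csv(files)
    if ("channel" %in% names(df)) {
      chan <- df$channel
      if (is.character(chan)) chan <- match(chan, LETTERS)
      if (anyNA(chan)) stop("malformed channel column in ", files)
      if (is.null(k)) k <- max(chan)
      cols <- intersect(c("x", "y", "z"), names(df))
      if (length(cols) < 2) stop("malformed CSV (need x,y columns): ", files)
      coords <- lapply(seq_len(k), function(ch) {
        as.matrix(df[chan == ch, cols, drop = FALSE])
      })
      return(point_cloud_set(coords, unit = unit,
                             pixel_size_nm = pixel_size_nm))
    }
    stop("a single input file must be long format with a 'channel' column")
  }
  coords <- lapply(files, function(f) {
    df <- read.csv(f)
    cols <- intersect(c("x", "y", "z"), names(df))
    if (length(cols) < 2) stop("malformed CSV (need x,y columns): ", f)
    as.matrix(df[, cols, drop = FALSE])
  })
  point_cloud_set(coords, unit = unit, pixel_size_nm = pixel_size_nm)
}

#' Write matched structures / abundances / curves as CSV
#'
#' @param match a [match_chains()] result.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_structures <- function(match, path) {
  df <- match$structures
  ord <- c("structure", "channel", "particle_index",
           intersect(c("x", "y", "z"), names(df)), "chain_id")
  write.csv(df[, ord, drop = FALSE], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_structures
#' @param abundance named abundance vector (or a curve data.frame).
#' @param scale_n optional particle count for the relative column.
#' @export
write_abundances <- function(abundance, path, scale_n = NA_real_) {
  if (is.data.frame(abundance)) {
    write.csv(abundance, path, row.names = FALSE)
  } else {
    df <- data.frame(structure = names(abundance),
                     count = as.integer(abundance),
                     relative = if (is.finite(scale_n) && scale_n > 0)
                       as.numeric(abundance) / scale_n else NA_real_)
    write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

#' Multi-channel TIFF I/O
#'
#' Channels are stored as pages of one TIFF, float intensities.
#'
#' @param img an `intensity_image`.
#' @param path file path.
#' @export
write_intensity_tiff <- function(img, path) {
  stopifnot(inherits(img, "intensity_image"))
  mats <- lapply(img$channels, function(m) m / max(1, max(m)))
  tiff::writeTIFF(mats, path, bits.per.sample = 32L)
  attr(path, "scale") <- vapply(img$channels, function(m) max(1, max(m)),
                                numeric(1))
  invisible(path)
}

#' @rdname write_intensity_tiff
#' @param pixel_size_nm pixel size to attach on read.
#' @param scale per-channel intensity scale to undo the unit-range
#'   normalization applied on write (default 1: keep normalized).
#' @export
read_intensity_tiff <- function(path, pixel_size_nm = NA_real_, scale = 1) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(scale) == 1) scale <- rep(scale, length(pages))
  channels <- Map(function(m, s) as.matrix(m) * s, pages, scale)
  structure(list(channels = channels, pixel_size_nm = pixel_size_nm,
                 image_size = nrow(channels[[1]])),
            class = "intensity_image")
}

# run manifest: config echo + seed + versions, JSON next to outputs
write_manifest <- function(path, config) {
  config$package <- "chainmatch"
  config$version <- as.character(packageVersion("chainmatch"))
  config$r_version <- R.version.string
  jsonlite::write_json(config, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
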