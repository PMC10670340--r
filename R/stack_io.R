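#' Construct an OffsetStack from in-memory arrays
#'
#' @param frames named list of \code{height x width x n_frames} arrays (or
#'   lists of matrices) for channels \code{offset1..offset4, confocal}
#' @param pixelScale micrometres per pixel
#' @param channelGains optional named per-channel multiplicative gains that
#'   are applied to the stored values (explicit, logged normalization)
#' @return a validated \code{\linkS4class{OffsetStack}}
#' @export
offsetStack <- function(frames, pixelScale, channelGains = NULL) {
  frames <- lapply(frames, function(f) {
    if (is.list(f)) f <- simplify2array(f)
    if (length(dim(f)) == 2) dim(f) <- c(dim(f), 1L)
    storage.mode(f) <- "double"
    f
  })
  missing <- setdiff(.CHANNELS, names(frames))
  if (length(missing) > 0)
    abort("channel-missing",
          sprintf("missing channel(s): %s", paste(missing, collapse = ", ")))
  frames <- frames[.CHANNELS]
  dims <- vapply(frames, function(f) paste(dim(f), collapse = "x"), "")
  if (length(unique(dims)) != 1)
    abort("shape-mismatch",
          paste("per-channel shapes:",
                paste(sprintf("%s=%s", names(dims), dims), collapse = ", ")))
  gains <- stats::setNames(rep(1, 5), .CHANNELS)
  if (!is.null(channelGains)) {
    gains[names(channelGains)] <- channelGains
    for (ch in names(channelGains)) frames[[ch]] <- frames[[ch]] * gains[ch]
  }
  methods::new("OffsetStack", frames = frames, pixelScale = pixelScale,
               channelGains = gains)
}

readTiffPages <- function(path) {
  meta <- tiff::readTIFF(path, payload = FALSE, all = TRUE)
  if (is.data.frame(meta)) meta <- list(meta)
  isFloat <- any(vapply(meta, function(m)
    !is.null(m$sample.format) && identical(m$sample.format, "float"), TRUE))
  # as.is=TRUE returns raw integer counts for integer sample formats but must
  # not be used for float TIFFs, whose samples are already physical values
  pages <- tiff::readTIFF(path, all = TRUE, as.is = !isFloat)
  if (!is.list(pages)) pages <- list(pages)
  lapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]   # collapse grayscale-as-RGB
    storage.mode(p) <- "double"
    p
  })
}

#' Read a five-channel stack from per-channel multi-page TIFF files
#'
#' Each channel is a separate single-channel multi-page grayscale TIFF
#' (8/16-bit integer or 32-bit float). Integer pixel types are promoted to
#' double without rescaling (raw counts are preserved); reading never alters
#' intensity values.
#'
#' @param paths named character vector or list with entries
#'   \code{offset1..offset4, confocal}, or a directory containing
#'   \code{<channel>.tif} files
#' @param pixelScale micrometres per pixel
#' @return an \code{\linkS4class{OffsetStack}}
#' @export
readStack <- function(paths, pixelScale) {
  if (length(paths) == 1 && is.character(paths) && dir.exists(paths))
    paths <- stats::setNames(file.path(paths, paste0(.CHANNELS, ".tif")),
                             .CHANNELS)
  paths <- unlist(paths)
  missing <- setdiff(.CHANNELS, names(paths))
  gone <- names(paths)[!file.exists(paths)]
  if (length(c(missing, gone)) > 0)
    abort("channel-missing",
          sprintf("missing channel(s): %s",
                  paste(unique(c(missing, gone)), collapse = ", ")))
  frames <- lapply(paths[.CHANNELS], readTiffPages)
  shapes <- vapply(frames, function(f)
    sprintf("%dx%dx%d", nrow(f[[1]]), ncol(f[[1]]), length(f)), "")
  if (length(unique(shapes)) != 1)
    abort("shape-mismatch",
          paste("per-channel shapes:",
                paste(sprintf("%s=%s", .CHANNELS, shapes), collapse = ", ")))
  offsetStack(frames, pixelScale = pixelScale)
}

#' Write a stack as per-channel 16-bit multi-page TIFF files
#'
#' Intensities must be nonnegative integers (counts) not exceeding 65535, as
#' produced by the simulator and by typical digitizers; the written files
#' read back bit-identically with \code{\link{readStack}}.
#'
#' @param stack an \code{\linkS4class{OffsetStack}} with integer-valued,
#'   NA-free intensities
#' @param dir output directory (created if needed)
#' @return named vector of written file paths, invisibly
#' @export
writeStack <- function(stack, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- stats::setNames(file.path(dir, paste0(.CHANNELS, ".tif")),
                           .CHANNELS)
  for (ch in .CHANNELS) {
    a <- stack@frames[[ch]]
    if (any(is.na(a)))
      abort("invalid-intensities",
            sprintf("channel %s contains NA; only raw count stacks can be written", ch))
    if (any(a != round(a)) || any(a > 65535))
      abort("invalid-intensities",
            sprintf("channel %s must hold integer counts in [0, 65535]", ch))
    pages <- lapply(seq_len(dim(a)[3]), function(k) a[, , k] / 65535)
    tiff::writeTIFF(pages, paths[ch], bits.per.sample = 16L,
                    compression = "none")
  }
  invisible(paths)
}

#' Write the morphometry report
#'
#' Writes (a) a CSV with columns \code{position_um}, \code{VD_um},
#' \code{LD_um}, \code{wall_thickness_um}, \code{WLR} (plus \code{valid});
#' numbers are serialized at full precision so the file reads back exactly;
#' and (b) overlay PNGs with the outer boundary in magenta and the inner
#' boundary in green over the MPG and motion-contrast images.
#'
#' @param profile a \code{\linkS4class{MorphometryProfile}}
#' @param segmentation a \code{\linkS4class{WallSegmentation}}
#' @param outDir output directory
#' @return named list of written paths, invisibly
#' @export
writeReport <- function(profile, segmentation, outDir) {
  ok <- tryCatch({
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    dir.exists(outDir) && file.access(outDir, 2) == 0
  }, error = function(e) FALSE)
  if (!ok) abort("io-error", sprintf("cannot write to '%s'", outDir))
  csv <- file.path(outDir, "profile.csv")
  writeProfileCsv(profile, csv)
  out <- list(csv = csv)
  for (nm in c("mpg", "stdMotion")) {
    img <- segmentation@images[[nm]]
    if (is.null(img)) img <- matrix(0, nrow(segmentation@lumenMask),
                                    ncol(segmentation@lumenMask))
    p <- file.path(outDir, paste0("overlay_", nm, ".png"))
    writeOverlayPng(img, segmentation, p)
    out[[paste0("overlay_", nm)]] <- p
  }
  invisible(out)
}

writeProfileCsv <- function(profile, path) {
  p <- profile@profile
  cols <- c("position_um", "VD_um", "LD_um", "wall_thickness_um", "WLR")
  lines <- paste(c(cols, "valid"), collapse = ",")
  if (nrow(p) > 0) {
    num <- vapply(cols, function(cn) sprintf("%.17g", p[[cn]]),
                  character(nrow(p)))
    if (nrow(p) == 1) num <- matrix(num, nrow = 1)
    body <- apply(cbind(num, ifelse(p$valid, "TRUE", "FALSE")), 1, paste,
                  collapse = ",")
    lines <- c(lines, body)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read back a morphometry profile CSV
#'
#' @param path CSV written by \code{\link{writeReport}}
#' @param pixelScale micrometres per pixel to record on the object
#' @return a \code{\linkS4class{MorphometryProfile}}
#' @export
readProfileCsv <- function(path, pixelScale = 1) {
  p <- utils::read.csv(path)
  p$valid <- as.logical(p$valid)
  methods::new("MorphometryProfile", profile = p, pixelScale = pixelScale)
}

writeOverlayPng <- function(img, segmentation, path) {
  v <- img
  v[is.na(v)] <- 0
  rng <- range(v)
  if (diff(rng) > 0) v <- (v - rng[1]) / diff(rng)
  rgb <- array(rep(v, 3), dim = c(nrow(v), ncol(v), 3))
  paint <- function(poly, col) {
    if (nrow(poly) == 0) return()
    keep <- !is.na(poly$x) & (is.null(poly$valid) | isTRUE(poly$valid)) &
      TRUE
    pts <- poly[!is.na(poly$x), , drop = FALSE]
    if (!is.null(pts$valid)) pts <- pts[pts$valid, , drop = FALSE]
    if (nrow(pts) == 0) return()
    yy <- pmin(pmax(round(pts$y), 1), nrow(v))
    xx <- pmin(pmax(round(pts$x), 1), ncol(v))
    for (k in 1:3) rgb[cbind(yy, xx, k)] <<- col[k]
  }
  for (b in segmentation@outer) paint(b, c(1, 0, 1))   # magenta outside
  for (b in segmentation@inner) paint(b, c(0, 1, 0))   # green inside
  png::writePNG(rgb, path)
  invisible(path)
}
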