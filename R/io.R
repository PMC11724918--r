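#' Read a 3D volume from disk
#'
#' Supports multi-page TIFF (one page per z-plane, extension `.tif`/`.tiff`)
#' and the native compressed-array container (`.rds`). Label volumes must
#' contain integer values; any fractional value is a hard error, not rounded.
#'
#' TIFF resolution metadata is not trusted (microscopy TIFF tags are
#' unreliable); spacing defaults to 1 micrometre isotropic and a `spacing`
#' argument always wins.
#'
#' @param path file to read.
#' @param kind `"intensity"` or `"label"`.
#' @param spacing optional (z, y, x) voxel size override in micrometres.
#' @return An `intensity_volume` or `label_volume`.
#' @export
read_volume <- function(path, kind = c("intensity", "label"), spacing = NULL) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "rds") {
    obj <- readRDS(path)
    if (inherits(obj, "volume3d")) {
      data <- obj$data
      if (is.null(spacing)) spacing <- obj$spacing
    } else if (is.array(obj) && length(dim(obj)) == 3L) {
      data <- obj
    } else {
      stop("rds container does not hold a 3D volume: ", path)
    }
  } else if (ext %in% c("tif", "tiff")) {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    pages <- lapply(pages, function(p) {
      if (length(dim(p)) == 3L) p <- p[, , 1]  # collapse accidental channels
      p
    })
    d <- dim(pages[[1]])
    data <- array(0, dim = c(length(pages), d[1], d[2]))
    for (z in seq_along(pages)) data[z, , ] <- pages[[z]]
  } else {
    stop("unsupported volume container: .", ext)
  }
  if (is.null(spacing)) spacing <- c(1, 1, 1)
  if (kind == "label") {
    if (any(data != round(data))) {
      stop("label volume contains non-integer values: ", path)
    }
    label_volume(data, spacing)
  } else {
    intensity_volume(data, spacing)
  }
}

#' Write a 3D volume to disk
#'
#' TIFF output (`.tif`/`.tiff`) stores one page per z-plane as unsigned
#' integers, the container width (8/16/32 bit) chosen to fit the maximum
#' value -- the same convention as real microscopy stacks, which are
#' integer-valued. Non-integer intensities are rounded with a warning; use the
#' `.rds` container for bit-exact storage of arbitrary floating-point data.
#'
#' @param vol an `intensity_volume` or `label_volume`.
#' @param path destination file; parent directory must exist.
#' @return Invisibly, `path`.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "volume3d"))
  if (!dir.exists(dirname(path))) {
    stop("parent directory does not exist: ", dirname(path))
  }
  if (any(vol$data < 0)) stop("volumes must be non-negative")
  ext <- tolower(tools::file_ext(path))
  if (ext == "rds") {
    saveRDS(vol, path)
    return(invisible(path))
  }
  if (!ext %in% c("tif", "tiff")) {
    stop("unsupported volume container: .", ext)
  }
  data <- vol$data
  if (any(data != round(data))) {
    warning("rounding non-integer intensities for TIFF storage")
    data <- round(data)
  }
  bits <- tiff_bits(max(data))
  scale <- 2^bits - 1
  pages <- lapply(seq_len(dim(data)[1]), function(z) {
    matrix(data[z, , ] / scale, nrow = dim(data)[2], ncol = dim(data)[3])
  })
  tiff::writeTIFF(pages, path, bits.per.sample = bits, compression = "none",
                  reduce = FALSE)
  invisible(path)
}

# Smallest supported unsigned-integer width that holds max value `m`.
tiff_bits <- function(m) {
  if (m <= 255) 8L else if (m <= 65535) 16L else 32L
}
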