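#' 3D volume containers
#'
#' `intensity_volume()` and `label_volume()` wrap a 3D array together with its
#' physical voxel spacing. The axis order is fixed as (z, y, x) everywhere in
#' the package, matching the microscopy stack convention: `data[z, y, x]`.
#' Coordinates are 0-based and ranges half-open where they appear in
#' interfaces.
#'
#' An intensity volume holds a non-negative scalar signal in arbitrary units
#' (raw or synthetic fluorescence). A label volume holds non-negative integer
#' instance labels; the value 0 is reserved for medium/background. Labels need
#' not be contiguous.
#'
#' @param data 3D numeric array, axis order (z, y, x).
#' @param spacing numeric length-3, physical voxel size in micrometres for the
#'   (z, y, x) axes. Must be strictly positive.
#' @return An object of class `intensity_volume` or `label_volume` (both also
#'   inherit from `volume3d`): a list with elements `data` and `spacing`.
#' @examples
#' v <- label_volume(array(0L, c(3, 4, 4)))
#' dim(v$data)
#' @export
intensity_volume <- function(data, spacing = c(1, 1, 1)) {
  data <- check_volume_data(data)
  spacing <- check_spacing(spacing)
  if (any(data < 0)) {
    stop("intensity volumes must be non-negative")
  }
  structure(list(data = data, spacing = spacing),
            class = c("intensity_volume", "volume3d"))
}

#' @rdname intensity_volume
#' @export
label_volume <- function(data, spacing = c(1, 1, 1)) {
  data <- check_volume_data(data)
  spacing <- check_spacing(spacing)
  if (any(data < 0)) {
    stop("labels must be non-negative integers (0 = medium)")
  }
  if (any(data != round(data))) {
    stop("label volume contains non-integer values")
  }
  storage.mode(data) <- "integer"
  structure(list(data = data, spacing = spacing),
            class = c("label_volume", "volume3d"))
}

check_volume_data <- function(data) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("volume data must be a 3D array in (z, y, x) order")
  }
  if (!all(is.finite(data))) {
    stop("volume data must be finite")
  }
  data
}

check_spacing <- function(spacing) {
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || !all(is.finite(spacing)) || any(spacing <= 0)) {
    stop("spacing must be 3 strictly positive values (z, y, x)")
  }
  spacing
}

#' @export
print.volume3d <- function(x, ...) {
  kind <- if (inherits(x, "label_volume")) "label" else "intensity"
  d <- dim(x$data)
  cat(sprintf("<%s volume> %d x %d x %d (z,y,x), spacing %s um\n",
              kind, d[1], d[2], d[3],
              paste(format(x$spacing, digits = 4), collapse = " x ")))
  if (kind == "label") {
    labs <- volume_labels(x)
    cat(sprintf("  %d labels (medium excluded)\n", length(labs)))
  } else {
    cat(sprintf("  range [%g, %g]\n", min(x$data), max(x$data)))
  }
  invisible(x)
}

#' Nonzero labels present in a label volume
#'
#' @param vol a `label_volume`.
#' @return Sorted integer vector of distinct nonzero labels.
#' @export
volume_labels <- function(vol) {
  stopifnot(inherits(vol, "label_volume"))
  labs <- sort(unique(as.vector(vol$data)))
  labs[labs != 0L]
}

#' Nucleus prototype container
#'
#' A prototype is a masked intensity subvolume cut around a single nucleus:
#' the binary `mask` is its support and `intensity` is exactly zero outside
#' the mask. Prototypes form the database from which the placement stage
#' stamps nuclei into simulated cells.
#'
#' @param intensity 3D numeric array (z, y, x), zero outside `mask`.
#' @param mask 3D array of 0/1 with the same dimensions.
#' @param spacing voxel size in micrometres (z, y, x).
#' @return An object of class `nucleus_prototype`.
#' @export
nucleus_prototype <- function(intensity, mask, spacing = c(1, 1, 1)) {
  intensity <- check_volume_data(intensity)
  mask <- check_volume_data(mask)
  spacing <- check_spacing(spacing)
  if (!identical(dim(intensity), dim(mask))) {
    stop("intensity and mask dimensions differ")
  }
  if (!all(mask %in% c(0, 1))) stop("mask must be binary")
  if (sum(mask) == 0) stop("mask is empty")
  if (any(intensity[mask == 0] != 0)) {
    stop("intensity must be zero outside the mask")
  }
  storage.mode(mask) <- "integer"
  structure(list(intensity = intensity, mask = mask, spacing = spacing),
            class = "nucleus_prototype")
}

#' @export
print.nucleus_prototype <- function(x, ...) {
  d <- dim(x$mask)
  cat(sprintf("<nucleus prototype> %d x %d x %d, %d support voxels\n",
              d[1], d[2], d[3], sum(x$mask)))
  invisible(x)
}
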