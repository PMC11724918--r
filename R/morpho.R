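#' Clean a segmentation label mask into a CPM-ready starting configuration
#'
#' Applies the mask-cleaning rules used to turn an automated segmentation into
#' a simulation starting configuration: labels with fewer than `min_voxels`
#' voxels are removed (almost certainly segmentation errors), labels spanning
#' fewer than `min_z_planes` z-planes are removed for the same reason, and
#' each surviving label undergoes a morphological closing followed by one
#' dilation (3x3x3 structuring element) to fill the resulting holes. Closing
#' and dilation only ever claim medium voxels; where two labels compete for
#' the same voxel, the lower label wins.
#'
#' @param vol a `label_volume`.
#' @param min_voxels minimum voxel count for a label to survive (default 5).
#' @param min_z_planes minimum z-extent in planes (default 4).
#' @return A cleaned `label_volume`; may be empty.
#' @export
clean_labels <- function(vol, min_voxels = 5L, min_z_planes = 4L) {
  stopifnot(inherits(vol, "label_volume"))
  data <- vol$data
  d <- dim(data)
  labs <- volume_labels(vol)
  if (length(labs) == 0) return(vol)

  nz <- data != 0L
  idx <- which(nz)
  lab_of <- data[idx]
  zc <- ((idx - 1L) %% d[1]) + 1L
  counts <- tapply(rep(1L, length(idx)), lab_of, sum)
  zspan <- tapply(zc, lab_of, function(z) diff(range(z)) + 1L)
  drop <- as.integer(names(counts))[counts < min_voxels |
                                    zspan < min_z_planes]
  if (length(drop)) data[data %in% drop] <- 0L
  labs <- setdiff(labs, drop)
  if (length(labs) == 0) return(label_volume(data, vol$spacing))

  se <- ball_offsets(sqrt(3))  # full 3x3x3 element
  out <- data
  for (lab in labs) {
    bb <- label_bbox(out == lab, margin = 2L)
    sub <- out[bb$z, bb$y, bb$x, drop = FALSE]
    mask <- sub == lab
    grown <- binary_dilate3d(binary_close3d(mask, se), se)
    claim <- grown & (sub == 0L)
    sub[claim] <- lab
    out[bb$z, bb$y, bb$x] <- sub
  }
  label_volume(out, vol$spacing)
}

label_bbox <- function(mask, margin = 0L) {
  d <- dim(mask)
  idx <- which(mask)
  ai <- arrayInd(idx, d)
  lo <- pmax(1L, apply(ai, 2, min) - margin)
  hi <- pmin(d, apply(ai, 2, max) + margin)
  list(z = lo[1]:hi[1], y = lo[2]:hi[2], x = lo[3]:hi[3])
}

#' Upsample a label volume to isotropic voxels along z
#'
#' Replicates z-planes by nearest-neighbour interpolation so the z spacing
#' matches the (already isotropic) xy spacing, as required before feature
#' extraction and simulation. Only the z axis is resampled; anisotropy within
#' the xy plane is an error.
#'
#' @param vol a `label_volume` with `spacing[1] >= spacing[2] == spacing[3]`.
#' @param target_spacing target z spacing in micrometres; defaults to the xy
#'   spacing.
#' @return A `label_volume` with isotropic spacing.
#' @export
upsample_isotropic <- function(vol, target_spacing = NULL) {
  stopifnot(inherits(vol, "label_volume"))
  sp <- vol$spacing
  if (abs(sp[2] - sp[3]) > 1e-12) {
    stop("xy spacing is anisotropic; only z resampling is supported")
  }
  if (is.null(target_spacing)) target_spacing <- sp[2]
  if (sp[1] < target_spacing - 1e-12) {
    stop("z spacing is already finer than the target")
  }
  if (abs(sp[1] - target_spacing) < 1e-12) return(vol)
  d <- dim(vol$data)
  new_nz <- max(1L, as.integer(round(d[1] * sp[1] / target_spacing)))
  # nearest-neighbour source plane for each output plane centre
  src <- pmin(d[1], pmax(1L, floor((seq_len(new_nz) - 0.5) *
                                   target_spacing / sp[1]) + 1L))
  label_volume(vol$data[src, , , drop = FALSE],
               c(target_spacing, sp[2], sp[3]))
}

#' Extract per-cell morphological features
#'
#' Computes the seven morphological features used throughout the package for
#' every nonzero label: volume, surface area, volume-to-surface (V/A) ratio,
#' minor and major axis lengths, sphericity and eccentricity.
#'
#' Surface area is measured by exposed-face counting (faces adjacent to a
#' different label, to medium or to the volume edge, 6-connectivity) -- the
#' same definition the CPM Hamiltonian uses for its area terms, so features
#' and simulation see a single geometry. Axis lengths follow the
#' ellipsoid-equivalent convention `4 * sqrt(lambda)` on the eigenvalues
#' `lambda_1 >= lambda_2 >= lambda_3` of the voxel-coordinate covariance;
#' eccentricity is the meridional value `sqrt(1 - lambda_3 / lambda_1)`, and
#' sphericity is `pi^(1/3) * (6 V)^(2/3) / A`.
#'
#' @param vol a `label_volume` with isotropic spacing.
#' @return A data frame with columns `label`, `volume` (um^3), `area` (um^2),
#'   `va_ratio` (um), `minor`, `major` (um), `sphericity`, `eccentricity`.
#' @export
extract_features <- function(vol) {
  stopifnot(inherits(vol, "label_volume"))
  sp <- vol$spacing
  if (max(sp) - min(sp) > 1e-9) {
    stop("extract_features requires isotropic spacing; see upsample_isotropic")
  }
  s <- sp[1]
  data <- vol$data
  d <- dim(data)
  labs <- volume_labels(vol)
  if (length(labs) == 0) stop("label volume has no cells")

  # exposed 6-neighbour faces per voxel, out-of-box counts as exposed
  exposed <- array(0L, d)
  for (i in seq_len(nrow(neigh6))) {
    nb <- shift_array3d(data, neigh6[i, ], fill = -1L)
    exposed <- exposed + as.integer(data != 0L & nb != data)
  }
  idx <- which(data != 0L)
  lab_of <- data[idx]
  ai <- arrayInd(idx, d)
  key <- match(lab_of, labs)
  n_vox <- tabulate(key, length(labs))
  n_faces <- as.vector(rowsum(as.numeric(exposed[idx]), key))

  minor <- major <- ecc <- numeric(length(labs))
  for (k in seq_along(labs)) {
    pts <- ai[key == k, , drop = FALSE] * s
    if (nrow(pts) < 2) {
      warning("label ", labs[k], " has a single voxel; axes set to 0")
      minor[k] <- major[k] <- ecc[k] <- 0
      next
    }
    cv <- stats::cov(pts) * (nrow(pts) - 1) / nrow(pts)  # population moments
    ev <- sort(eigen(cv, symmetric = TRUE, only.values = TRUE)$values,
               decreasing = TRUE)
    ev <- pmax(ev, 0)
    major[k] <- 4 * sqrt(ev[1])
    minor[k] <- 4 * sqrt(ev[3])
    ecc[k] <- if (ev[1] > 0) sqrt(1 - ev[3] / ev[1]) else 0
  }
  volume <- n_vox * s^3
  area <- n_faces * s^2
  data.frame(
    label = labs,
    volume = volume,
    area = area,
    va_ratio = volume / area,
    minor = minor,
    major = major,
    sphericity = pi^(1 / 3) * (6 * volume)^(2 / 3) / area,
    eccentricity = ecc
  )
}

neigh6 <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))

#' Write / read a feature table as CSV
#'
#' @param features data frame from [extract_features()].
#' @param path CSV destination.
#' @return Invisibly `path` (write) or the data frame (read).
#' @export
write_features <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  utils::read.csv(path)
}
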