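#' Imaging simulation configuration
#'
#' Parameters of the microscope forward model applied to a placed-nuclei
#' image: depth-dependent brightness reduction, convolution with a
#' point-spread function (PSF), downsampling to the acquisition grid, and
#' shot/read noise, applied in that order.
#'
#' @param attenuation_depth exponential decay length in micrometres
#'   (`Inf` disables attenuation).
#' @param psf_sigma Gaussian PSF standard deviations (z, y, x), micrometres.
#' @param downsample integer block factors (z, y, x).
#' @param noise_gain photon-scaling gain of the Poisson shot noise
#'   (0 disables shot noise).
#' @param noise_sigma standard deviation of the additive Gaussian read noise.
#' @param seed integer seed for the noise draws.
#' @return An `imaging_config` list.
#' @export
imaging_config <- function(attenuation_depth = Inf,
                           psf_sigma = c(0, 0, 0),
                           downsample = c(1L, 1L, 1L),
                           noise_gain = 0, noise_sigma = 0, seed = 1L) {
  stopifnot(attenuation_depth > 0, all(psf_sigma >= 0), all(downsample >= 1),
            noise_gain >= 0, noise_sigma >= 0)
  structure(list(attenuation_depth = attenuation_depth,
                 psf_sigma = as.numeric(psf_sigma),
                 downsample = as.integer(downsample),
                 noise_gain = noise_gain, noise_sigma = noise_sigma,
                 seed = as.integer(seed)),
            class = "imaging_config")
}

#' Depth-dependent brightness attenuation
#'
#' Multiplies plane z by `exp(-z * spacing_z / depth_len)`, depth measured
#' from the first z-plane: the brightness reduction deeper optical sections
#' suffer in thick samples.
#'
#' @param img an `intensity_volume`.
#' @param depth_len decay length in micrometres (`Inf` = identity).
#' @return The attenuated `intensity_volume`.
#' @export
attenuate <- function(img, depth_len) {
  stopifnot(inherits(img, "intensity_volume"), depth_len > 0)
  if (!is.finite(depth_len)) return(img)
  z <- (seq_len(dim(img$data)[1]) - 1) * img$spacing[1]
  fac <- exp(-z / depth_len)
  intensity_volume(img$data * fac, img$spacing)  # recycles along z (axis 1)
}

#' Convolve with an anisotropic Gaussian point-spread function
#'
#' Separable convolution with a normalized Gaussian kernel (sum 1, truncated
#' at 4 sigma) per axis; `sigma = 0` on an axis leaves it untouched. Constant
#' images are fixed points up to boundary truncation; total intensity is
#' conserved for signals supported away from the volume faces.
#'
#' @param img an `intensity_volume`.
#' @param sigma (z, y, x) standard deviations in micrometres.
#' @return The blurred `intensity_volume`.
#' @export
convolve_psf <- function(img, sigma) {
  stopifnot(inherits(img, "intensity_volume"), all(sigma >= 0))
  sigma_vox <- sigma / img$spacing
  out <- gaussian_blur3d(img$data, sigma_vox)
  out[out < 0] <- 0  # numerical dust from float summation
  intensity_volume(out, img$spacing)
}

#' Downsample by block averaging
#'
#' Averages non-overlapping blocks of `factors` voxels; a trailing remainder
#' not filling a whole block is cropped (with a message). Spacing multiplies
#' by the factors.
#'
#' @param img an `intensity_volume`.
#' @param factors integer (z, y, x) block sizes.
#' @return The downsampled `intensity_volume`.
#' @export
downsample <- function(img, factors) {
  stopifnot(inherits(img, "intensity_volume"), all(factors >= 1))
  factors <- as.integer(factors)
  data <- crop_to_multiple(img$data, factors)
  d <- dim(data)
  dn <- d %/% factors
  # average over blocks axis by axis
  out <- data
  for (axis in 1:3) {
    f <- factors[axis]
    if (f == 1L) next
    dcur <- dim(out)
    perm_dim <- c(f, dcur[axis] / f, dcur[-axis])
    m <- array(aperm(out, c(axis, setdiff(1:3, axis))), perm_dim)
    red <- colMeans(m)  # collapses the within-block axis
    out <- aperm(array(red, c(dcur[axis] / f, dcur[-axis])),
                 order(c(axis, setdiff(1:3, axis))))
  }
  intensity_volume(out, img$spacing * factors)
}

crop_to_multiple <- function(data, factors) {
  d <- dim(data)
  keep <- (d %/% factors) * factors
  if (any(keep < d)) {
    message("cropping trailing remainder before downsampling: ",
            paste(d - keep, collapse = ","), " voxels (z,y,x)")
    data <- data[seq_len(keep[1]), seq_len(keep[2]), seq_len(keep[3]),
                 drop = FALSE]
  }
  data
}

#' Downsample a label volume by per-block majority vote
#'
#' Companion to [downsample()] so instance labels keep matching the image
#' grid. Each block takes its most frequent label; ties go to the lowest
#' label.
#'
#' @param vol a `label_volume`.
#' @param factors integer (z, y, x) block sizes.
#' @return The downsampled `label_volume`.
#' @export
downsample_labels <- function(vol, factors) {
  stopifnot(inherits(vol, "label_volume"), all(factors >= 1))
  factors <- as.integer(factors)
  data <- crop_to_multiple(vol$data, factors)
  d <- dim(data)
  dn <- d %/% factors
  out <- array(0L, dn)
  for (bz in seq_len(dn[1])) for (by in seq_len(dn[2])) for (bx in seq_len(dn[3])) {
    block <- data[(bz - 1L) * factors[1] + seq_len(factors[1]),
                  (by - 1L) * factors[2] + seq_len(factors[2]),
                  (bx - 1L) * factors[3] + seq_len(factors[3])]
    tab <- table(block)
    out[bz, by, bx] <- as.integer(names(tab)[which.max(tab)])
  }
  label_volume(out, vol$spacing * factors)
}

#' Apply shot and read noise
#'
#' `out = Poisson(img / gain) * gain + Gaussian(0, sigma)`, clipped at zero.
#' `gain = 0` disables the Poisson (shot) component; `sigma = 0` the Gaussian
#' (read) component. Uses R's RNG; wrap in a seed for reproducibility.
#'
#' @param img an `intensity_volume`.
#' @param gain photon-scaling gain (>= 0).
#' @param sigma additive noise standard deviation (>= 0).
#' @return The noisy `intensity_volume`.
#' @export
add_noise <- function(img, gain, sigma) {
  stopifnot(inherits(img, "intensity_volume"), gain >= 0, sigma >= 0)
  data <- img$data
  if (gain > 0) {
    data <- array(stats::rpois(length(data), data / gain) * gain, dim(data))
  }
  if (sigma > 0) {
    data <- data + array(stats::rnorm(length(data), 0, sigma), dim(data))
  }
  data[data < 0] <- 0
  intensity_volume(data, img$spacing)
}

#' Full imaging simulation
#'
#' Composition of the microscope forward model in its physical order:
#' [attenuate()], then [convolve_psf()], then [downsample()], then
#' [add_noise()]. With `labels` supplied, the instance labels are
#' majority-vote downsampled alongside so image and label shapes stay
#' matched.
#'
#' @param img an `intensity_volume` (e.g. placed nuclei).
#' @param cfg an [imaging_config()].
#' @param labels optional `label_volume` to carry through the downsampling.
#' @return An `intensity_volume`, or a list `(image, labels)` when `labels`
#'   is given.
#' @export
simulate_imaging <- function(img, cfg = imaging_config(), labels = NULL) {
  stopifnot(inherits(img, "intensity_volume"), inherits(cfg, "imaging_config"))
  out <- attenuate(img, cfg$attenuation_depth)
  out <- convolve_psf(out, cfg$psf_sigma)
  out <- downsample(out, cfg$downsample)
  out <- with_seed(derive_seed(cfg$seed, "imaging:noise"),
                   add_noise(out, cfg$noise_gain, cfg$noise_sigma))
  if (is.null(labels)) return(out)
  list(image = out, labels = downsample_labels(labels, cfg$downsample))
}
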