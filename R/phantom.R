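#' Phantom spheroid specification
#'
#' Bundles the parameters of the synthetic ground-truth generator. The phantom
#' emulates the packed-cell geometry of a cultured spheroid: a digital ball
#' partitioned into convex cells by a nearest-seed (Voronoi) tessellation.
#' It stands in for a real segmented spheroid stack so that every downstream
#' stage is testable without external data.
#'
#' @param shape (z, y, x) lattice size in voxels.
#' @param sphere_radius radius of the spheroid in voxels; the ball must fit
#'   inside `shape`.
#' @param n_cells number of cells (Voronoi seeds) inside the ball.
#' @param seed integer seed for seed-point sampling.
#' @param n_prototypes number of nucleus prototypes to generate.
#' @param axes_range range (min, max) of ellipsoid semi-axes, voxels, for the
#'   prototypes.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(shape = c(48, 48, 48), sphere_radius = 20,
                         n_cells = 30, seed = 1, n_prototypes = 8,
                         axes_range = c(3, 6)) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3, all(shape >= 1), sphere_radius > 0,
            n_cells >= 1, n_prototypes >= 1, length(axes_range) == 2)
  if (any(2 * sphere_radius + 1 > shape)) {
    stop("sphere of radius ", sphere_radius, " does not fit inside the shape")
  }
  if (axes_range[1] <= 0 || diff(axes_range) < 0) {
    stop("degenerate prototype axis range")
  }
  structure(list(shape = shape, sphere_radius = sphere_radius,
                 n_cells = as.integer(n_cells), seed = as.integer(seed),
                 n_prototypes = as.integer(n_prototypes),
                 axes_range = axes_range),
            class = "phantom_spec")
}

#' Generate a phantom spheroid label mask
#'
#' Samples `n_cells` seed points uniformly (without replacement) among the
#' voxels of the digital ball centred in the volume, then labels every
#' in-ball voxel by its nearest seed (ties broken towards the lowest label).
#' Voxels outside the ball are medium (0). Voronoi cells intersected with a
#' ball are convex, hence connected and roughly isotropic, like packed
#' spheroid interiors.
#'
#' @param spec a [phantom_spec()].
#' @return A `label_volume` with labels `1..n_cells`, all non-empty.
#' @export
make_phantom_spheroid <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$shape
  ctr <- (d - 1) / 2
  z <- (seq_len(d[1]) - 1) - ctr[1]
  y <- (seq_len(d[2]) - 1) - ctr[2]
  x <- (seq_len(d[3]) - 1) - ctr[3]
  r2 <- outer(outer(z^2, y^2, `+`), x^2, `+`)
  inside <- which(r2 <= spec$sphere_radius^2)
  if (spec$n_cells > length(inside)) {
    stop("n_cells exceeds the number of voxels inside the sphere")
  }
  idx <- arrayInd(inside, d)
  seeds_at <- with_seed(derive_seed(spec$seed, "phantom:seeds"),
                        sample(length(inside), spec$n_cells))
  seed_xyz <- idx[seeds_at, , drop = FALSE]
  # squared distance from every in-ball voxel to every seed
  d2 <- outer(idx[, 1], seed_xyz[, 1], `-`)^2 +
        outer(idx[, 2], seed_xyz[, 2], `-`)^2 +
        outer(idx[, 3], seed_xyz[, 3], `-`)^2
  lab <- max.col(-d2, ties.method = "first")
  data <- array(0L, d)
  data[inside] <- lab
  label_volume(data, c(1, 1, 1))
}

#' Generate phantom nucleus prototypes
#'
#' Each prototype is a solid, axis-aligned ellipsoid support mask whose
#' semi-axes are drawn uniformly from `spec$axes_range`, filled with a
#' band-limited random texture: Gaussian-smoothed white noise rescaled to
#' [0.3, 1.0] inside the mask and exactly zero outside, mimicking chromatin
#' texture at the fidelity the placement and imaging stages require.
#'
#' @param spec a [phantom_spec()].
#' @return A list of [nucleus_prototype()] objects.
#' @export
make_phantom_prototypes <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(derive_seed(spec$seed, "phantom:prototypes"), {
    lapply(seq_len(spec$n_prototypes), function(i) {
      ax <- sort(stats::runif(3, spec$axes_range[1], spec$axes_range[2]),
                 decreasing = TRUE)
      # longest semi-axis along x so the principal axes are well defined
      semi <- c(ax[3], ax[2], ax[1])  # (z, y, x)
      half <- ceiling(semi)
      dims <- 2 * half + 1
      z <- seq_len(dims[1]) - 1 - half[1]
      y <- seq_len(dims[2]) - 1 - half[2]
      x <- seq_len(dims[3]) - 1 - half[3]
      q <- outer(outer((z / semi[1])^2, (y / semi[2])^2, `+`),
                 (x / semi[3])^2, `+`)
      mask <- array(as.integer(q <= 1), dims)
      noise <- array(stats::rnorm(prod(dims)), dims)
      tex <- gaussian_blur3d(noise, sigma_vox = c(1.5, 1.5, 1.5))
      inside <- mask == 1L
      rng <- range(tex[inside])
      span <- if (diff(rng) > 0) diff(rng) else 1
      tex <- 0.3 + 0.7 * (tex - rng[1]) / span
      intensity <- array(0, dims)
      intensity[inside] <- tex[inside]
      nucleus_prototype(intensity, mask, c(1, 1, 1))
    })
  })
}
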