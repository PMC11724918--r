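make_ellipsoid_proto <- function(semi = c(3, 4, 6)) {
  half <- ceiling(semi)
  dims <- 2 * half + 1
  z <- seq_len(dims[1]) - 1 - half[1]
  y <- seq_len(dims[2]) - 1 - half[2]
  x <- seq_len(dims[3]) - 1 - half[3]
  q <- outer(outer((z / semi[1])^2, (y / semi[2])^2, `+`), (x / semi[3])^2,
             `+`)
  mask <- array(as.integer(q <= 1), dims)
  inten <- array(0, dims)
  inten[mask == 1L] <- 0.5
  nucleus_prototype(inten, mask, c(1, 1, 1))
}

test_that("aligned axes leave the prototype unrotated; scaling follows s^3", {
  proto <- make_ellipsoid_proto(c(3, 4, 6))  # major axis along x already
  axes <- list(directions = diag(3)[, 3:1], lengths = c(12, 8, 6))
  # cell major axis = x = prototype major axis -> pure scaling
  out <- orient_scale_prototype(proto, axes, target_volume = sum(proto$mask))
  expect_lt(abs(sum(out$mask) - sum(proto$mask)) / sum(proto$mask), 0.05)
  big <- orient_scale_prototype(proto, axes,
                                target_volume = 1.5^3 * sum(proto$mask))
  expect_lt(abs(sum(big$mask) - 1.5^3 * sum(proto$mask)) /
              (1.5^3 * sum(proto$mask)), 0.05)
})

test_that("a 90-degree axis swap permutes the prototype axes", {
  proto <- make_ellipsoid_proto(c(3, 4, 6))
  # cell elongated along z: major direction (1,0,0) in (z,y,x)
  axes <- list(directions = diag(3), lengths = c(12, 8, 6))
  out <- orient_scale_prototype(proto, axes, target_volume = sum(proto$mask))
  pm <- principal_axes(arrayInd(which(out$mask == 1L), dim(out$mask)))
  # largest eigenvector now along z
  expect_gt(abs(pm$directions[1, 1]), 0.95)
  # and the axis lengths are preserved up to voxelization
  pm0 <- principal_axes(arrayInd(which(proto$mask == 1L), dim(proto$mask)))
  expect_equal(pm$lengths, pm0$lengths, tolerance = 0.15)
})

test_that("sphere-like cells skip rotation", {
  proto <- make_ellipsoid_proto(c(3, 4, 6))
  axes <- list(directions = diag(3), lengths = c(10, 10, 10))
  out <- orient_scale_prototype(proto, axes, target_volume = sum(proto$mask))
  pm <- principal_axes(arrayInd(which(out$mask == 1L), dim(out$mask)))
  expect_gt(abs(pm$directions[3, 1]), 0.95)  # major axis still along x
})

test_that("position sampling concentrates at the centroid", {
  ph <- tiny_phantom(shape = c(24, 24, 24), radius = 9, n_cells = 5, seed = 9)
  lin <- which(ph$data == 2L)
  coords <- arrayInd(lin, dim(ph$data)) - 1L
  ctr <- colMeans(coords)
  expect_identical(sample_position(coords, 0), as.integer(round(ctr)))
  set.seed(5)
  draws <- t(replicate(3000, sample_position(coords, 0.25)))
  r_eq <- (3 * nrow(coords) / (4 * pi))^(1 / 3)
  sigma <- 0.25 * r_eq
  # CLT bound on the empirical mean (+ 0.5 voxel rounding slack)
  expect_true(all(abs(colMeans(draws) - ctr) <
                  3 * sigma / sqrt(3000) + 0.5))
  set.seed(6)
  a <- replicate(5, sample_position(coords, 0.3))
  set.seed(6)
  b <- replicate(5, sample_position(coords, 0.3))
  expect_identical(a, b)
})

test_that("overlap fraction counts free cell voxels only", {
  cells <- cuboid_volume(c(9, 9, 9), c(1, 1, 1), c(9, 9, 5))  # half-space x<=5
  proto <- make_ellipsoid_proto(c(2, 2, 2))
  occupied <- array(FALSE, c(9, 9, 9))
  expect_equal(overlap_fraction(proto, c(4, 4, 2), cells, 1L, occupied), 1)
  # centred on the boundary plane x = 5 (0-based 4): half the mask inside
  f_half <- overlap_fraction(proto, c(4, 4, 4) + c(0, 0, 1), cells, 1L,
                             occupied)
  n_in <- sum(arrayInd(which(proto$mask == 1L), dim(proto$mask))[, 3] <= 2)
  expect_equal(f_half, n_in / sum(proto$mask))
  # fully inside but fully occupied -> 0
  occupied[] <- TRUE
  expect_equal(overlap_fraction(proto, c(4, 4, 2), cells, 1L, occupied), 0)
})

test_that("placement at threshold 1 yields disjoint nuclei inside parents", {
  ph <- tiny_phantom(shape = c(32, 32, 32), radius = 13, n_cells = 15,
                     seed = 1)
  spec <- phantom_spec(shape = c(32, 32, 32), sphere_radius = 13,
                       n_cells = 15, seed = 1, n_prototypes = 4)
  protos <- make_phantom_prototypes(spec)
  res <- suppressMessages(suppressWarnings(
    place_nuclei(ph, protos, placement_config(volume_ratio = 0.25,
                                              overlap_threshold = 1,
                                              seed = 2))))
  lab <- res$labels$data
  expect_true(all(ph$data[lab > 0L] == lab[lab > 0L]))  # subset of parent
  expect_true(all(res$intensity$data >= 0))
  expect_gt(sum(res$placements$placed), 0)
  # reproducibility
  res2 <- suppressMessages(suppressWarnings(
    place_nuclei(ph, protos, placement_config(volume_ratio = 0.25,
                                              overlap_threshold = 1,
                                              seed = 2))))
  expect_identical(res$labels$data, res2$labels$data)
  expect_identical(res$intensity$data, res2$intensity$data)
})

test_that("an impossible prototype skips every cell", {
  ph <- tiny_phantom(shape = c(24, 24, 24), radius = 9, n_cells = 8, seed = 2)
  huge <- make_ellipsoid_proto(c(9, 9, 9))
  res <- suppressMessages(suppressWarnings(
    place_nuclei(ph, list(huge), placement_config(volume_ratio = 2,
                                                  overlap_threshold = 1,
                                                  max_positions = 3,
                                                  max_prototypes = 2,
                                                  seed = 1))))
  expect_equal(sum(res$placements$placed), 0)
  expect_setequal(res$skipped, volume_labels(ph))
  expect_true(all(res$labels$data == 0L))
})

test_that("claimed nucleus volumes respect the acceptance-rule band", {
  ph <- tiny_phantom(shape = c(32, 32, 32), radius = 13, n_cells = 15,
                     seed = 1)
  spec <- phantom_spec(shape = c(32, 32, 32), sphere_radius = 13,
                       n_cells = 15, seed = 1, n_prototypes = 4)
  protos <- make_phantom_prototypes(spec)
  rho <- 0.3
  thr <- 0.8
  res <- suppressMessages(suppressWarnings(
    place_nuclei(ph, protos, placement_config(volume_ratio = rho,
                                              overlap_threshold = thr,
                                              seed = 3))))
  v <- res$placements[res$placements$placed, ]
  ratio <- v$nucleus_voxels / v$cell_voxels
  # claims = overlap * mask volume, with mask within 5% of rho * V_cell
  expect_true(all(ratio >= thr * 0.95 * rho - 1e-9))
  expect_true(all(ratio <= 1.05 * rho + 1e-9))
})
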