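# Shared fixtures, all generated in code.

# Small phantom spheroid, cached per (radius, n_cells, seed) within a session.
tiny_phantom <- local({
  cache <- list()
  function(shape = c(32, 32, 32), radius = 13, n_cells = 15, seed = 1) {
    key <- paste(c(shape, radius, n_cells, seed), collapse = "_")
    if (is.null(cache[[key]])) {
      spec <- phantom_spec(shape = shape, sphere_radius = radius,
                           n_cells = n_cells, seed = seed)
      cache[[key]] <<- make_phantom_spheroid(spec)
    }
    cache[[key]]
  }
})

# A label volume holding a single axis-aligned cuboid.
cuboid_volume <- function(dims, lo, hi, label = 1L, spacing = c(1, 1, 1)) {
  a <- array(0L, dims)
  a[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- label
  label_volume(a, spacing)
}

# Digital ball of radius r centred in a box of side 2r + 3.
ball_volume <- function(r, spacing = c(1, 1, 1)) {
  n <- 2 * r + 3
  ctr <- (n + 1) / 2
  g <- expand.grid(z = 1:n, y = 1:n, x = 1:n)
  a <- array(0L, c(n, n, n))
  a[(g$z - ctr)^2 + (g$y - ctr)^2 + (g$x - ctr)^2 <= r^2] <- 1L
  label_volume(a, spacing)
}

# Brute-force exposed-face count per label (6-connectivity, box faces count).
brute_surface_area <- function(vol) {
  d <- dim(vol$data)
  labs <- volume_labels(vol)
  counts <- stats::setNames(numeric(length(labs)), labs)
  for (z in 1:d[1]) for (y in 1:d[2]) for (x in 1:d[3]) {
    a <- vol$data[z, y, x]
    if (a == 0L) next
    for (off in list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0),
                     c(0,0,1), c(0,0,-1))) {
      p <- c(z, y, x) + off
      nb <- if (any(p < 1) || any(p > d)) 0L else vol$data[p[1], p[2], p[3]]
      if (nb != a) counts[as.character(a)] <- counts[as.character(a)] + 1
    }
  }
  counts
}

# Brute-force 1-Wasserstein via optimal assignment over permutations after
# replicating both samples to a common size (lcm), n small.
brute_wasserstein <- function(a, b) {
  l <- pracma_lcm(length(a), length(b))
  a <- rep(sort(a), each = l / length(a))
  b <- rep(sort(b), each = l / length(b))
  perms <- all_permutations(l)
  min(vapply(seq_len(nrow(perms)),
             function(i) mean(abs(a - b[perms[i, ]])), numeric(1)))
}

pracma_lcm <- function(x, y) {
  g <- function(a, b) if (b == 0) a else g(b, a %% b)
  x * y / g(x, y)
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

# Naive loop implementation of the unbiased polynomial-kernel MMD^2.
brute_mmd2 <- function(fx, fy, d = ncol(fx)) {
  kpoly <- function(a, b) (sum(a * b) / d + 1)^3
  n <- nrow(fx); m <- nrow(fy)
  t1 <- 0
  for (i in 1:n) for (j in 1:n) if (i != j) t1 <- t1 + kpoly(fx[i, ], fx[j, ])
  t1 <- t1 / (n * (n - 1))
  t2 <- 0
  for (i in 1:m) for (j in 1:m) if (i != j) t2 <- t2 + kpoly(fy[i, ], fy[j, ])
  t2 <- t2 / (m * (m - 1))
  if (n == m) {
    t3 <- 0
    for (i in 1:n) for (j in 1:m) if (i != j) t3 <- t3 + kpoly(fx[i, ], fy[j, ])
    t3 <- 2 * t3 / (n * (n - 1))
  } else {
    t3 <- 0
    for (i in 1:n) for (j in 1:m) t3 <- t3 + kpoly(fx[i, ], fy[j, ])
    t3 <- 2 * t3 / (n * m)
  }
  t1 + t2 - t3
}

# Count connected components (6-connectivity) of a binary mask via flood fill.
n_components <- function(mask) {
  comp <- spheroidsim:::connected_components3d(mask)
  max(comp)
}

expect_same_volume <- function(a, b) {
  expect_identical(dim(a$data), dim(b$data))
  expect_true(all(a$data == b$data))
}
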