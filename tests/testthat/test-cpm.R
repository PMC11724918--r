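test_that("neighbourhood shells have the CompuCell3D sizes", {
  expect_equal(vapply(1:4, spheroidsim:::cpm_shell_size_cpp, integer(1)),
               c(6L, 18L, 26L, 32L))
})

test_that("target assignment is a derangement preserving the multiset", {
  ph <- tiny_phantom(shape = c(24, 24, 24), radius = 9, n_cells = 5, seed = 2)
  p <- cpm_params()
  st <- cpm_state(ph, p)
  st2 <- assign_targets(st, seed = 13)
  labs <- volume_labels(ph) + 1L
  expect_true(all(st2$V_target[labs] != st$V[labs] |
                  st2$A_target[labs] != st$A[labs]))
  # no fixed point: each cell's (V,A) target pair differs from its own
  expect_setequal(st2$V_target[labs], st$V[labs])
  expect_setequal(st2$A_target[labs], st$A[labs])
  expect_identical(assign_targets(st, seed = 13)$V_target, st2$V_target)

  # two cells (different sizes): the only derangement is the swap
  a <- array(0L, c(7, 7, 7))
  a[2:3, 2:3, 2:3] <- 1L
  a[2:4, 2:4, 5:6] <- 2L
  s2 <- assign_targets(cpm_state(label_volume(a), p), seed = 1)
  s0 <- cpm_state(label_volume(a), p)
  expect_equal(s2$V_target[2:3 + 0], s0$V[c(3, 2)])
  expect_equal(s2$A_target[2:3 + 0], s0$A[c(3, 2)])
})

test_that("single cell warns and keeps its own targets", {
  a <- array(0L, c(5, 5, 5))
  a[2:3, 2:3, 2:3] <- 1L
  st <- cpm_state(label_volume(a), cpm_params())
  expect_warning(st1 <- assign_targets(st), "fewer than 2")
  expect_identical(st1$V_target, st$V_target)
})

test_that("Hamiltonian matches hand enumeration on a one-voxel cell", {
  a <- array(0L, c(3, 3, 3))
  a[2, 2, 2] <- 1L
  # contact order 1: six faces to medium; targets default to actuals
  p <- cpm_params(lambda_V = 1, lambda_A = 0, J_cc = 0, J_cm = 2, T = 1,
                  contact_neighbor_order = 1)
  st <- cpm_state(label_volume(a), p)
  expect_equal(hamiltonian(st, p), 12)
  # all cells at their targets with zero contact energies -> H = 0
  p0 <- cpm_params(J_cc = 0, J_cm = 0)
  ph <- tiny_phantom()
  expect_equal(hamiltonian(cpm_state(ph, p0), p0), 0)
  # doubling J_cm doubles the cell-medium term only
  p1 <- cpm_params(lambda_V = 0, lambda_A = 0, J_cc = 0, J_cm = 2)
  p2 <- cpm_params(lambda_V = 0, lambda_A = 0, J_cc = 0, J_cm = 4)
  st1 <- cpm_state(ph, p1)
  expect_equal(2 * hamiltonian(st1, p1), hamiltonian(st1, p2))
})

test_that("incremental deltaH equals full recomputation", {
  ph <- tiny_phantom(shape = c(16, 16, 16), radius = 6, n_cells = 6, seed = 3)
  p <- cpm_params(lambda_V = 0.5, lambda_A = 0.1, J_cc = 1, J_cm = 5, T = 50)
  st <- assign_targets(cpm_state(ph, p), seed = 5)
  set.seed(21)
  for (i in 1:300) {
    h0 <- hamiltonian(st, p)
    pr <- propose_and_apply(st, p)
    h1 <- hamiltonian(pr$state, p)
    if (pr$null) {
      expect_identical(h1, h0)
    } else if (pr$accepted) {
      expect_equal(h1 - h0, pr$deltaH, tolerance = 1e-9)
    } else {
      expect_identical(h1, h0)
      expect_gt(pr$deltaH, 0)
    }
    st <- pr$state
  }
})

test_that("caches equal brute-force recounts after many proposals", {
  ph <- tiny_phantom(shape = c(16, 16, 16), radius = 6, n_cells = 6, seed = 3)
  p <- cpm_params(lambda_V = 0.5, lambda_A = 0.1, J_cc = 1, J_cm = 5, T = 50)
  st <- assign_targets(cpm_state(ph, p), seed = 5)
  res <- spheroidsim:::cpm_run_core(st, p, n_attempts = 2000,
                                    mcs_len = 0L, snapshot_at = integer(0))
  final <- res$state
  tally <- spheroidsim:::cpm_tally_cpp(as.integer(final$lattice$data),
                                       dim(final$lattice$data),
                                       p$contact_neighbor_order,
                                       length(final$V) - 1L)
  expect_equal(final$V, tally$V)
  expect_equal(final$A, tally$A)
  expect_equal(final$total_cc, tally$total_cc)
  expect_equal(final$total_cm, tally$total_cm)
})

test_that("Metropolis acceptance respects the boundary cases", {
  ph <- tiny_phantom(shape = c(16, 16, 16), radius = 6, n_cells = 6, seed = 3)
  # flat energy landscape: every proposal has deltaH = 0 -> always accepted
  p_flat <- cpm_params(lambda_V = 0, lambda_A = 0, J_cc = 0, J_cm = 0, T = 1)
  st <- cpm_state(ph, p_flat)
  set.seed(31)
  n_real <- 0
  for (i in 1:200) {
    pr <- propose_and_apply(st, p_flat)
    if (!pr$null) {
      n_real <- n_real + 1
      expect_equal(pr$deltaH, 0)
      expect_true(pr$accepted)
    }
    st <- pr$state
  }
  expect_gt(n_real, 0)
  # huge uphill penalty at small T: acceptance frequency -> 0
  p_cold <- cpm_params(lambda_V = 1e6, lambda_A = 0, J_cc = 0, J_cm = 0,
                       T = 0.01, mcs = 0)
  st2 <- cpm_state(ph, p_cold)  # targets = actuals: any flip costs >= 2e6
  res <- spheroidsim:::cpm_run_core(st2, p_cold, n_attempts = 1e4,
                                    mcs_len = 0L, snapshot_at = integer(0),
                                    record = TRUE)
  expect_equal(res$raw$n_accepted, 0)
})

test_that("MCS bookkeeping: zero steps, site conservation, snapshots", {
  ph <- tiny_phantom(shape = c(16, 16, 16), radius = 6, n_cells = 6, seed = 3)
  p0 <- cpm_params(mcs = 0)
  st <- assign_targets(cpm_state(ph, p0), seed = 1)
  res0 <- run_mcs(st, p0, seed = 2)
  expect_same_volume(res0$state$lattice, ph)

  p5 <- cpm_params(mcs = 5, T = 100, lambda_V = 0.01, lambda_A = 0.01)
  res5 <- run_mcs(st, cpm_params(mcs = 5, T = 100, lambda_V = 0.01,
                                 lambda_A = 0.01),
                  snapshot_at = c(0, 2), seed = 2)
  expect_equal(prod(dim(res5$state$lattice$data)), 16^3)
  expect_length(res5$H_trace, 6)
  expect_same_volume(res5$snapshots[["0"]], ph)
  expect_identical(dim(res5$snapshots[["2"]]$data), dim(ph$data))
})

test_that("energy relaxes from permuted targets at calibration-scale params", {
  ph <- tiny_phantom()
  p <- cpm_params(mcs = 40)
  st <- assign_targets(cpm_state(ph, p), seed = 3)
  res <- run_mcs(st, p, seed = 4)
  ht <- res$H_trace
  expect_lt(ht[length(ht)], ht[1])
  expect_lt(mean(tail(ht, 10)), mean(head(ht, 10)))
})

test_that("Metropolis samples the Boltzmann law on a two-state toy system", {
  # 1x1x3 lattice, labels (1,1,2); only the middle site can flip between the
  # two low-energy states S1 = (1,1,2) and S2 = (1,2,2), and the copy
  # proposal between them is exactly symmetric. Targets make
  # H(S2) - H(S1) = 2*lambda_V; all other states are >400 energy units
  # uphill and effectively unreachable.
  lat <- label_volume(array(c(1L, 1L, 2L), c(1, 1, 3)))
  p <- cpm_params(lambda_V = 10, lambda_A = 5, J_cc = 0, J_cm = 0, T = 30,
                  potts_neighbor_order = 1, contact_neighbor_order = 1,
                  mcs = 1e5)
  st <- cpm_state(lat, p)
  st$V_target <- c(NA, 2, 1)
  st$A_target <- c(NA, 8, 8)
  h1 <- hamiltonian(st, p)                      # S1 energy (= 40)
  res <- run_mcs(st, p, seed = 11)
  h <- round(res$H_trace[-1])
  expect_true(all(h %in% c(40, 60)))            # only the two states visited
  pi2 <- exp(-20 / 30) / (1 + exp(-20 / 30))    # Boltzmann weight of S2
  n <- length(h)
  n2 <- sum(h == 60)
  # 3-sigma band with the Markov-chain variance correction (samples taken
  # every MCS are autocorrelated; rho from the exact transition probabilities)
  q12 <- (1 / 18) * exp(-20 / 30)
  q21 <- 1 / 18
  p12 <- 1 - (1 - q12)^3
  p21 <- 1 - (1 - q21)^3
  rho <- 1 - p12 - p21
  sig <- sqrt(n * pi2 * (1 - pi2) * (1 + rho) / (1 - rho))
  expect_lt(abs(n2 - n * pi2), 3 * sig)
})

test_that("stability: self-targets, small J and T keep cells in place", {
  ph <- tiny_phantom(shape = c(32, 32, 32), radius = 13, n_cells = 20,
                     seed = 5)
  p <- cpm_params(lambda_V = 2, lambda_A = 2, J_cc = 0.1, J_cm = 0.1,
                  T = 0.5, mcs = 20)
  st <- cpm_state(ph, p)  # targets = initial actuals
  res <- run_mcs(st, p, seed = 6)
  iou <- vapply(volume_labels(ph),
                function(l) cell_iou(ph, res$state$lattice, l), numeric(1))
  expect_gt(mean(iou), 0.95)
})

test_that("border export and membrane rasterization", {
  a <- array(0L, c(1, 1, 2))
  a[1, 1, 1] <- 1L
  a[1, 1, 2] <- 2L
  two <- label_volume(a)
  expect_same_volume(export_borders(two), two)
  # two adjacent one-voxel cells: both are membrane
  memb <- rasterize_membrane(two)
  expect_true(all(memb$data == 1L))
  # 3x3x3 block inside medium: shell is membrane, centre is not
  blk <- cuboid_volume(c(5, 5, 5), c(2, 2, 2), c(4, 4, 4))
  m <- rasterize_membrane(blk)
  expect_equal(m$data[3, 3, 3], 0L)
  expect_equal(sum(m$data), 26)
  expect_true(all(m$data[blk$data == 0L] == 0L))
  # all-medium volume stays empty
  expect_true(all(rasterize_membrane(label_volume(array(0L, c(3, 3, 3))))$data
                  == 0L))
  # relabeling equivariance
  perm <- blk
  perm$data[perm$data == 1L] <- 9L
  expect_same_volume(rasterize_membrane(perm), m)
})
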