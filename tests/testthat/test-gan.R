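test_that("two-channel generator output splits by contract", {
  g <- array(runif(2 * 3 * 4 * 4), c(2, 3, 4, 4))
  out <- split_generator_output(g)
  expect_equal(out$y_hat$data, array(g[1, , , ], c(3, 4, 4)))
  expect_equal(out$v_hat$data, array(g[2, , , ], c(3, 4, 4)))
  expect_error(split_generator_output(array(0, c(3, 3, 4, 4))), "2 channels")
})

test_that("adversarial losses match their closed forms", {
  eps <- 1e-7
  # indifferent discriminator: 2 log 0.5
  expect_equal(loss_cgan(0.5, 0.5), 2 * log(0.5), tolerance = 1e-12)
  expect_equal(loss_sgan(0.5, 0.5), 2 * log(0.5), tolerance = 1e-12)
  # perfect discriminator in the clamped limit: ~ 0
  expect_equal(loss_cgan(1, 0, eps), 2 * log(1 - eps), tolerance = 1e-12)
  expect_lt(abs(loss_cgan(1, 0, eps)), 1e-6)
  # batch-mean invariances
  expect_equal(loss_cgan(c(0.7, 0.7), c(0.2, 0.2)), loss_cgan(0.7, 0.2))
  expect_equal(loss_cgan(c(0.9, 0.3), c(0.1, 0.6)),
               loss_cgan(c(0.3, 0.9), c(0.6, 0.1)))
})

test_that("L1 loss: zero on identity, hand value, homogeneity", {
  y <- array(c(1, 0), c(2, 1, 1))
  yh <- array(c(0, 1), c(2, 1, 1))
  expect_equal(loss_l1(y, y), 0)
  expect_equal(loss_l1(y, yh), 1)
  expect_equal(loss_l1(3 * y, 3 * yh), 3 * loss_l1(y, yh))
  expect_error(loss_l1(y, array(0, c(3, 1, 1))), "shape")
})

test_that("conditional objective recombines its components", {
  y <- array(1, c(2, 2, 2))
  batch0 <- list(D_y = 1, D_yhat = 0, DSeg_v = 1, DSeg_vhat = 0,
                 y = y, y_hat = y)
  ob0 <- objective_cgan(batch0, loss_weights(lambda_L1 = 100))
  expect_lt(abs(ob0$total), 1e-5)  # all components at their optimum
  batch <- list(D_y = 0.5, D_yhat = 0.5, DSeg_v = 0.5, DSeg_vhat = 0.5,
                y = y, y_hat = y + 0.2)
  ob <- objective_cgan(batch, loss_weights(lambda_L1 = 0))
  expect_equal(ob$total, 4 * log(0.5), tolerance = 1e-9)
  ob100 <- objective_cgan(batch, loss_weights(lambda_L1 = 100))
  expect_equal(ob100$total,
               ob100$components[["cgan"]] + ob100$components[["sgan"]] +
                 100 * ob100$components[["l1"]])
  # constructed components (-1.0, -0.5, 0.2), lambda = 100 -> 18.5
  expect_equal(-1.0 + -0.5 + 100 * 0.2, 18.5)
})

test_that("segmentation-discriminator loss ignores images and condition", {
  # signature-level: only label-channel discriminator outputs enter
  expect_identical(loss_sgan(0.8, 0.3), loss_sgan(0.8, 0.3))
  b1 <- list(D_y = 0.9, D_yhat = 0.1, DSeg_v = 0.6, DSeg_vhat = 0.4,
             y = array(0, c(2, 2, 2)), y_hat = array(5, c(2, 2, 2)))
  b2 <- modifyList(b1, list(y = array(9, c(2, 2, 2)),
                            y_hat = array(1, c(2, 2, 2))))
  expect_equal(objective_cgan(b1)$components[["sgan"]],
               objective_cgan(b2)$components[["sgan"]])
})

test_that("cycle-consistent objective matches its closed forms", {
  x <- array(runif(8), c(2, 2, 2))
  y <- array(runif(8), c(2, 2, 2))
  perfect <- list(DA_x = 0.5, DA_xhat = 0.5, DB_y = 0.5, DB_yhat = 0.5,
                  DSeg_v = 0.5, DSeg_vhat = 0.5,
                  x = x, x_tilde = x, y = y, y_tilde = y)
  ob <- objective_cyclegan(perfect, loss_weights(lambda_cyc = 10))
  expect_equal(ob$components[["cyc"]], 0)
  expect_equal(ob$total, 6 * log(0.5), tolerance = 1e-9)  # ~ -4.1589
  drift <- modifyList(perfect, list(x_tilde = x + 0.1))
  ob1 <- objective_cyclegan(drift, loss_weights(lambda_cyc = 1))
  ob10 <- objective_cyclegan(drift, loss_weights(lambda_cyc = 10))
  expect_equal(ob10$total - ob10$components[["cyc"]] * 10,
               ob1$total - ob1$components[["cyc"]] * 1)
  expect_equal(ob1$components[["cyc"]], 0.1, tolerance = 1e-9)
})

# Toy scene: two cells split by a membrane, nuclei touching across it.
postprocess_toy <- function() {
  d <- c(12, 12, 12)
  cells <- array(0L, d)
  cells[2:11, 2:11, 2:6] <- 1L
  cells[2:11, 2:11, 7:11] <- 2L
  cells <- label_volume(cells)
  memb <- rasterize_membrane(cells)
  v_hat <- array(0, d)
  v_hat[4:9, 4:9, 3:10] <- 0.9   # one blob spanning both cells
  list(cells = cells, memb = memb, v_hat = v_hat)
}

test_that("post-processing splits touching nuclei and removes artifacts", {
  toy <- postprocess_toy()
  inst <- postprocess_instance_labels(toy$v_hat, toy$memb, toy$cells,
                                      threshold = 0.5, opening_radius = 1)
  expect_setequal(sort(unique(as.vector(inst$data[inst$data > 0L]))),
                  c(1L, 2L))
  # two connected components, one per cell
  expect_equal(n_components((inst$data == 1L) * 1L), 1L)
  expect_equal(n_components((inst$data == 2L) * 1L), 1L)
  expect_true(all(toy$cells$data[inst$data > 0L] ==
                  inst$data[inst$data > 0L]))
  # a stray blob entirely in medium is removed
  v2 <- toy$v_hat
  cells2 <- toy$cells
  cells2$data[, , 11:12] <- 0L  # open some medium
  memb2 <- rasterize_membrane(cells2)
  v2[5:8, 5:8, 11:12] <- 1
  inst2 <- postprocess_instance_labels(v2, memb2, cells2, 0.5, 1)
  expect_true(all(inst2$data[, , 11:12] == 0L))
  # sub-threshold soft values never appear in the output
  expect_true(all(inst2$data[v2 < 0.5] == 0L))
})

test_that("post-processing is idempotent on its own output", {
  toy <- postprocess_toy()
  inst <- postprocess_instance_labels(toy$v_hat, toy$memb, toy$cells, 0.5, 1)
  nomem <- label_volume(array(0L, dim(inst$data)))
  again <- postprocess_instance_labels((inst$data > 0L) * 1.0, nomem,
                                       toy$cells, 0.5, 1)
  expect_identical(again$data, inst$data)
})

test_that("the smoke training harness yields finite loss trajectories", {
  set.seed(2)
  x <- array(round(runif(4^3)), c(4, 4, 4))
  y <- array(runif(4^3), c(4, 4, 4))
  v <- array(round(runif(4^3)), c(4, 4, 4))
  tr <- smoke_train_harness(x, y, v, iterations = 10, lr = 0.002)
  expect_equal(nrow(tr), 10)
  expect_true(all(is.finite(as.matrix(tr))))
  tr2 <- smoke_train_harness(x, y, v, iterations = 10, lr = 0.002)
  expect_identical(tr, tr2)  # fixed seed -> identical trajectory
  tr0 <- smoke_train_harness(x, y, v, iterations = 5,
                             w = loss_weights(lambda_L1 = 0), lr = 0.002)
  expect_true(all(is.finite(tr0$l1)))  # component reported either way
})
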