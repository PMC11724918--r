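#' Loss weights for the label-co-generating GAN objectives
#'
#' @param lambda_L1 weight of the L1 reconstruction term in the conditional
#'   objective.
#' @param lambda_cyc weight of the cycle-consistency term in the
#'   cycle-consistent objective.
#' @param eps_clamp discriminator outputs are clamped to
#'   `[eps_clamp, 1 - eps_clamp]` before the logarithms, keeping every loss
#'   finite.
#' @return A `loss_weights` list.
#' @export
loss_weights <- function(lambda_L1 = 100, lambda_cyc = 10, eps_clamp = 1e-7) {
  stopifnot(lambda_L1 >= 0, lambda_cyc >= 0,
            eps_clamp > 0, eps_clamp < 0.5)
  structure(list(lambda_L1 = lambda_L1, lambda_cyc = lambda_cyc,
                 eps_clamp = eps_clamp),
            class = "loss_weights")
}

clamp01 <- function(p, eps) pmin(pmax(p, eps), 1 - eps)

#' Split a two-channel generator output
#'
#' The generator's last layer produces a two-channel image: channel 1 is the
#' synthetic nuclei signal, channel 2 the corresponding soft binary label
#' mask. Both channels share the decoder path, which promotes alignment
#' between image and label.
#'
#' @param two_channel 4D array, channels in the first dimension
#'   (channel, z, y, x); exactly 2 channels.
#' @param spacing voxel size (z, y, x), micrometres.
#' @return A list `(y_hat, v_hat)`: an `intensity_volume` and a soft label
#'   array in `[0, 1]` wrapped as an `intensity_volume`.
#' @export
split_generator_output <- function(two_channel, spacing = c(1, 1, 1)) {
  d <- dim(two_channel)
  if (length(d) != 4L || d[1] != 2L) {
    stop("generator output must have exactly 2 channels (channel, z, y, x)")
  }
  y_hat <- array(two_channel[1, , , ], d[-1])
  v_hat <- array(two_channel[2, , , ], d[-1])
  list(y_hat = intensity_volume(y_hat, spacing),
       v_hat = intensity_volume(v_hat, spacing))
}

#' Adversarial losses of the conditional scheme
#'
#' `loss_cgan` is the conditional adversarial term: the batch mean of
#' `log D(y, x) + log(1 - D(y_hat, x))`, where the discriminator sees the
#' membrane condition x alongside real (y) or generated (y_hat) nuclei.
#' `loss_sgan` is the label-channel term from the extra segmentation
#' discriminator, `log D_Seg(v) + log(1 - D_Seg(v_hat))`; `D_Seg` receives no
#' condition, so the real binary labels v may come from any unpaired pool.
#' `loss_l1` is the mean absolute voxel difference between real and generated
#' nuclei.
#'
#' @param d_real,d_fake discriminator outputs in (0, 1), one per batch
#'   element: `D(y, x)` and `D(y_hat, x)` (or `D_Seg(v)` and `D_Seg(v_hat)`).
#' @param eps clamp applied before the logarithms.
#' @return Scalar loss (natural log).
#' @export
loss_cgan <- function(d_real, d_fake, eps = 1e-7) {
  stopifnot(length(d_real) == length(d_fake), length(d_real) >= 1)
  mean(log(clamp01(d_real, eps)) + log(1 - clamp01(d_fake, eps)))
}

#' @rdname loss_cgan
#' @export
loss_sgan <- function(d_real, d_fake, eps = 1e-7) {
  loss_cgan(d_real, d_fake, eps)
}

#' @rdname loss_cgan
#' @param y,y_hat arrays (or `intensity_volume`s) of identical shape.
#' @export
loss_l1 <- function(y, y_hat) {
  y <- volume_data(y)
  y_hat <- volume_data(y_hat)
  if (!identical(dim(y), dim(y_hat))) stop("shape mismatch in loss_l1")
  mean(abs(y - y_hat))
}

volume_data <- function(x) {
  if (inherits(x, "volume3d")) x$data else x
}

#' Conditional objective with the extra segmentation discriminator
#'
#' Total objective of the adapted conditional scheme:
#' `loss_cgan + loss_sgan + lambda_L1 * loss_l1`. The generator minimises and
#' the discriminators maximise this value; here it is evaluated for a given
#' batch of discriminator outputs and images.
#'
#' @param batch list with elements `D_y` (= D(y, x)), `D_yhat`, `DSeg_v`,
#'   `DSeg_vhat` (numeric vectors over the batch) and `y`, `y_hat` (arrays or
#'   volumes).
#' @param w a [loss_weights()].
#' @return List `(total, components)`; components named `cgan`, `sgan`, `l1`.
#' @export
objective_cgan <- function(batch, w = loss_weights()) {
  eps <- w$eps_clamp
  comp <- c(cgan = loss_cgan(batch$D_y, batch$D_yhat, eps),
            sgan = loss_sgan(batch$DSeg_v, batch$DSeg_vhat, eps),
            l1 = loss_l1(batch$y, batch$y_hat))
  list(total = comp[["cgan"]] + comp[["sgan"]] + w$lambda_L1 * comp[["l1"]],
       components = comp)
}

#' Cycle-consistent objective with the extra segmentation discriminator
#'
#' Total objective of the adapted cycle-consistent scheme: the two domain
#' adversarial terms (membrane domain A, nuclei domain B), the segmentation
#' adversarial term from `D_Seg`, and the cycle-consistency term
#' `mean|x - x_tilde| + mean|y - y_tilde|` weighted by `lambda_cyc`. The
#' membrane-to-nuclei generator emits the two-channel output (nuclei and soft
#' label); the reverse generator maps nuclei back to membranes.
#'
#' @param batch list with discriminator outputs `DA_x`, `DA_xhat`, `DB_y`,
#'   `DB_yhat`, `DSeg_v`, `DSeg_vhat` and images `x`, `x_tilde`, `y`,
#'   `y_tilde` (arrays or volumes).
#' @param w a [loss_weights()].
#' @return List `(total, components)`; components named `gan_A`, `gan_B`,
#'   `gan_S`, `cyc`.
#' @export
objective_cyclegan <- function(batch, w = loss_weights()) {
  eps <- w$eps_clamp
  comp <- c(gan_A = loss_cgan(batch$DA_x, batch$DA_xhat, eps),
            gan_B = loss_cgan(batch$DB_y, batch$DB_yhat, eps),
            gan_S = loss_sgan(batch$DSeg_v, batch$DSeg_vhat, eps),
            cyc = loss_l1(batch$x, batch$x_tilde) +
                  loss_l1(batch$y, batch$y_tilde))
  list(total = comp[["gan_A"]] + comp[["gan_B"]] + comp[["gan_S"]] +
         w$lambda_cyc * comp[["cyc"]],
       components = comp)
}

#' Instance labels from a generated soft label channel
#'
#' Post-processing from the generated binary label channel to the instance
#' labels segmentation training requires: (1) threshold the soft channel to a
#' true binary mask; (2) subtract the binary membrane signal that conditioned
#' the generator, splitting touching labels; (3) binary opening with a
#' ball-shaped element to remove artifacts; (4) assign each remaining
#' foreground voxel the label of the simulated cell underneath it. Foreground
#' over medium has no cell label and is thereby removed automatically.
#'
#' @param v_hat soft label volume (`intensity_volume` or array, values in
#'   `[0, 1]`).
#' @param membrane binary membrane `label_volume` (the generator condition).
#' @param cells simulated cell `label_volume`.
#' @param threshold binarisation threshold in (0, 1), default 0.5.
#' @param opening_radius radius (voxels) of the opening element, default 1.
#' @return A `label_volume` of nucleus instance labels (= parent cell
#'   labels).
#' @export
postprocess_instance_labels <- function(v_hat, membrane, cells,
                                        threshold = 0.5, opening_radius = 1L) {
  v <- volume_data(v_hat)
  stopifnot(identical(dim(v), dim(membrane$data)),
            identical(dim(v), dim(cells$data)),
            threshold > 0, threshold < 1)
  b <- v >= threshold
  b <- b & (membrane$data == 0L)
  if (opening_radius >= 1) {
    b <- binary_open3d(b, ball_offsets(opening_radius))
  }
  out <- array(0L, dim(v))
  keep <- b & (cells$data > 0L)
  out[keep] <- cells$data[keep]
  label_volume(out, cells$spacing)
}

#' Smoke-scale training harness for the GAN objectives
#'
#' Validates that the objectives are optimisable end to end on a miniature
#' problem, using a built-in base-R backend: an affine two-channel generator
#' (`y_hat = a1 * x + b1`, `v_hat = sigmoid(a2 * x + b2)`) and logistic
#' discriminators on simple image statistics, trained by alternating
#' finite-difference gradient steps. This is a plumbing check, not a model:
#' it only asserts that every loss component stays finite over the
#' trajectory.
#'
#' @param x condition volume (binary membrane array), at most 16^3 voxels.
#' @param y real nuclei array of the same shape.
#' @param v real binary label array of the same shape.
#' @param iterations training iterations (<= 200).
#' @param w a [loss_weights()].
#' @param lr step size.
#' @param seed integer seed.
#' @return A data frame with one row per iteration: `cgan`, `sgan`, `l1`,
#'   `total`.
#' @export
smoke_train_harness <- function(x, y, v, iterations = 50, w = loss_weights(),
                                lr = 0.05, seed = 1L) {
  stopifnot(prod(dim(x)) <= 16^3, iterations <= 200,
            identical(dim(x), dim(y)), identical(dim(x), dim(v)))
  sigmoid <- function(t) 1 / (1 + exp(-t))
  gen <- c(a1 = 0.5, b1 = 0.1, a2 = 0.5, b2 = 0)
  dis <- c(w0 = 0, w1 = 0.1, w2 = 0.1)   # D(y, x): on mean(y), mean(x)
  dseg <- c(s0 = 0, s1 = 0.1)            # D_Seg(v): on mean(v)

  d_out <- function(dis, img, cond) {
    sigmoid(dis[1] + dis[2] * mean(img) + dis[3] * mean(cond))
  }
  dseg_out <- function(dseg, lab) sigmoid(dseg[1] + dseg[2] * mean(lab))
  gen_out <- function(gen) {
    list(y_hat = gen["a1"] * x + gen["b1"],
         v_hat = sigmoid(gen["a2"] * x + gen["b2"]))
  }
  batch_of <- function(gen, dis, dseg) {
    g <- gen_out(gen)
    list(D_y = d_out(dis, y, x), D_yhat = d_out(dis, g$y_hat, x),
         DSeg_v = dseg_out(dseg, v), DSeg_vhat = dseg_out(dseg, g$v_hat),
         y = y, y_hat = g$y_hat)
  }
  fd_grad <- function(par, f, h = 1e-4) {
    vapply(seq_along(par), function(i) {
      p1 <- par; p1[i] <- p1[i] + h
      p2 <- par; p2[i] <- p2[i] - h
      (f(p1) - f(p2)) / (2 * h)
    }, numeric(1))
  }

  rows <- with_seed(derive_seed(seed, "gan:smoke"), {
    lapply(seq_len(iterations), function(it) {
      # discriminators ascend, generator descends the shared objective
      dis <<- dis + lr * fd_grad(dis, function(p) {
        objective_cgan(batch_of(gen, p, dseg), w)$total
      })
      dseg <<- dseg + lr * fd_grad(dseg, function(p) {
        objective_cgan(batch_of(gen, dis, p), w)$total
      })
      gen <<- gen - lr * fd_grad(gen, function(p) {
        objective_cgan(batch_of(p, dis, dseg), w)$total
      })
      ob <- objective_cgan(batch_of(gen, dis, dseg), w)
      data.frame(iteration = it, cgan = ob$components[["cgan"]],
                 sgan = ob$components[["sgan"]], l1 = ob$components[["l1"]],
                 total = ob$total)
    })
  })
  do.call(rbind, rows)
}
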