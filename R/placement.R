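#' Nucleus placement configuration
#'
#' Parameters of the prototype-based nucleus placement stage. The placement
#' mechanism follows the enhanced simulation-based synthesis path: per cell a
#' prototype is drawn, oriented, scaled to a predefined volume fraction of the
#' cell, and stamped at positions drawn around the cell centre until the
#' overlap rule is satisfied or the attempt budgets are exhausted.
#'
#' @param volume_ratio target nucleus/cell volume fraction.
#' @param overlap_threshold minimum admissible fraction of the prototype's
#'   volume that must fall on free (unoccupied) voxels of the cell, in (0, 1].
#' @param sigma_frac positional spread of the placement Gaussian, as a
#'   fraction of the cell's equivalent-sphere radius.
#' @param max_positions positions tried per prototype.
#' @param max_prototypes prototypes tried per cell before the cell is skipped.
#' @param seed integer seed.
#' @return A `placement_config` list.
#' @export
placement_config <- function(volume_ratio = 0.35, overlap_threshold = 0.8,
                             sigma_frac = 0.25, max_positions = 10L,
                             max_prototypes = 5L, seed = 1L) {
  stopifnot(volume_ratio > 0, overlap_threshold > 0, overlap_threshold <= 1,
            sigma_frac >= 0, max_positions >= 1, max_prototypes >= 1)
  structure(list(volume_ratio = volume_ratio,
                 overlap_threshold = overlap_threshold,
                 sigma_frac = sigma_frac,
                 max_positions = as.integer(max_positions),
                 max_prototypes = as.integer(max_prototypes),
                 seed = as.integer(seed)),
            class = "placement_config")
}

#' Principal axes of a voxel set
#'
#' Eigen-decomposition of the population covariance of the voxel coordinates
#' (in micrometres). Directions are the eigenvectors, major first; lengths
#' follow the `4 * sqrt(lambda)` ellipsoid convention used by
#' [extract_features()].
#'
#' @param coords matrix of voxel indices (rows = voxels, columns = z, y, x).
#' @param spacing voxel size (z, y, x), micrometres.
#' @return List with `directions` (3x3, columns major to minor) and `lengths`.
#' @export
principal_axes <- function(coords, spacing = c(1, 1, 1)) {
  stopifnot(is.matrix(coords), ncol(coords) == 3, nrow(coords) >= 2)
  pts <- sweep(coords, 2, spacing, `*`)
  cv <- stats::cov(pts) * (nrow(pts) - 1) / nrow(pts)
  e <- eigen(cv, symmetric = TRUE)
  list(directions = e$vectors, lengths = 4 * sqrt(pmax(e$values, 0)))
}

#' Orient and scale a nucleus prototype for one cell
#'
#' Rotates the prototype so its major principal axis aligns with the cell's
#' major axis (the minimal-angle rotation between the two unit vectors), then
#' scales it isotropically until the support-mask volume is within 5% of
#' `target_volume`. The mask is resampled by nearest neighbour, the intensity
#' trilinearly. Sphere-like cells (no well-defined orientation) skip the
#' rotation.
#'
#' @param proto a [nucleus_prototype()].
#' @param cell_axes output of [principal_axes()] for the cell, or `NULL` to
#'   skip rotation.
#' @param target_volume desired mask volume in cubic micrometres (> 0).
#' @return A transformed `nucleus_prototype`.
#' @export
orient_scale_prototype <- function(proto, cell_axes, target_volume) {
  stopifnot(inherits(proto, "nucleus_prototype"), target_volume > 0)
  sp <- proto$spacing
  R <- diag(3)
  degenerate <- is.null(cell_axes) ||
    cell_axes$lengths[1] < 1.05 * cell_axes$lengths[3]
  if (!degenerate) {
    m_idx <- which(proto$mask == 1L)
    pm <- principal_axes(arrayInd(m_idx, dim(proto$mask)), sp)
    u <- pm$directions[, 1]
    v <- cell_axes$directions[, 1]
    if (sum(u * v) < 0) v <- -v  # axes are directionless; take the near side
    R <- rotation_between(u, v)
  }
  vox <- prod(sp)
  s <- (target_volume / (sum(proto$mask) * vox))^(1 / 3)
  out <- best <- resample_prototype(proto, R, s)
  best_err <- Inf
  for (it in 1:10) {
    out <- resample_prototype(proto, R, s)
    err <- abs(sum(out$mask) * vox - target_volume)
    if (err < best_err) {
      best <- out
      best_err <- err
    }
    if (err <= 0.01 * target_volume) break
    s <- s * (target_volume / (sum(out$mask) * vox))^(1 / 3)
  }
  if (best_err > 0.05 * target_volume) {
    warning("prototype volume off target by more than 5% after rescaling")
  }
  best
}

# Minimal rotation taking unit vector u onto unit vector v (Rodrigues).
rotation_between <- function(u, v) {
  u <- u / sqrt(sum(u^2))
  v <- v / sqrt(sum(v^2))
  c_ <- sum(u * v)
  w <- c(u[2] * v[3] - u[3] * v[2],
         u[3] * v[1] - u[1] * v[3],
         u[1] * v[2] - u[2] * v[1])
  s2 <- sum(w^2)
  if (s2 < 1e-18) {
    if (c_ > 0) return(diag(3))
    # opposite vectors: rotate pi about any perpendicular axis
    p <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    w <- p - sum(p * u) * u
    w <- w / sqrt(sum(w^2))
    return(2 * outer(w, w) - diag(3))
  }
  K <- matrix(c(0, -w[3], w[2], w[3], 0, -w[1], -w[2], w[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + K + K %*% K * ((1 - c_) / s2)
}

# Resample a prototype under rotation R followed by isotropic scale s.
resample_prototype <- function(proto, R, s) {
  d <- dim(proto$mask)
  half_in <- (d - 1) / 2
  half_out <- ceiling(s * (abs(R) %*% half_in)) + 1
  dn <- as.integer(2 * half_out + 1)
  g <- as.matrix(expand.grid(z = seq_len(dn[1]) - 1 - half_out[1],
                             y = seq_len(dn[2]) - 1 - half_out[2],
                             x = seq_len(dn[3]) - 1 - half_out[3]))
  src <- g %*% R / s  # (R^T %*% t(g)) / s, transposed
  src <- sweep(src, 2, half_in, `+`)  # to 0-based input indices

  nn <- round(src) + 1
  ok <- nn[, 1] >= 1 & nn[, 1] <= d[1] & nn[, 2] >= 1 & nn[, 2] <= d[2] &
        nn[, 3] >= 1 & nn[, 3] <= d[3]
  mask <- integer(nrow(g))
  mask[ok] <- proto$mask[nn[ok, , drop = FALSE]]

  intensity <- trilinear_sample(proto$intensity, src)
  intensity[mask == 0L] <- 0
  nucleus_prototype(array(intensity, dn), array(mask, dn), proto$spacing)
}

# Trilinear interpolation of array `a` at 0-based fractional coords (rows).
trilinear_sample <- function(a, src) {
  d <- dim(a)
  f <- floor(src)
  w <- src - f
  out <- numeric(nrow(src))
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    iz <- f[, 1] + dz
    iy <- f[, 2] + dy
    ix <- f[, 3] + dx
    wt <- (if (dz) w[, 1] else 1 - w[, 1]) *
          (if (dy) w[, 2] else 1 - w[, 2]) *
          (if (dx) w[, 3] else 1 - w[, 3])
    ok <- iz >= 0 & iz < d[1] & iy >= 0 & iy < d[2] & ix >= 0 & ix < d[3] &
          wt > 0
    if (any(ok)) {
      lin <- cbind(iz[ok] + 1, iy[ok] + 1, ix[ok] + 1)
      out[ok] <- out[ok] + wt[ok] * a[lin]
    }
  }
  out
}

#' Sample a placement position inside a cell
#'
#' Draws from an isotropic Gaussian centred at the cell centroid with
#' standard deviation `sigma_frac * r_eq` (equivalent-sphere radius),
#' rejection-sampled until the draw falls inside the cell's bounding box, and
#' returned as integer voxel indices. Nuclei are most likely at the cell
#' centre but not pinned there. `sigma_frac = 0` returns the centroid voxel.
#'
#' @param cell_coords matrix of the cell's voxel indices (rows; z, y, x).
#' @param sigma_frac positional spread fraction.
#' @return Integer (z, y, x) voxel index.
#' @export
sample_position <- function(cell_coords, sigma_frac) {
  stopifnot(nrow(cell_coords) >= 1)
  ctr <- colMeans(cell_coords)
  if (sigma_frac <= 0) return(as.integer(round(ctr)))
  r_eq <- (3 * nrow(cell_coords) / (4 * pi))^(1 / 3)
  sigma <- sigma_frac * r_eq
  lo <- apply(cell_coords, 2, min)
  hi <- apply(cell_coords, 2, max)
  for (i in 1:1000) {
    p <- round(ctr + stats::rnorm(3, 0, sigma))
    if (all(p >= lo) && all(p <= hi)) return(as.integer(p))
  }
  as.integer(round(ctr))
}

#' Fraction of a placed prototype lying on free cell voxels
#'
#' The fraction of the prototype's support that falls on voxels of the cell
#' not yet claimed by previously placed nuclei. Voxels of the cell already
#' occupied count as unavailable, which enforces the overlap rule and
#' prevents nucleus-nucleus collisions at once.
#'
#' @param proto a (transformed) `nucleus_prototype`.
#' @param position integer (z, y, x) voxel index for the prototype centre.
#' @param cells a `label_volume` of cells.
#' @param cell_label the target cell id.
#' @param occupied logical array marking voxels claimed by placed nuclei.
#' @return Fraction in `[0, 1]`.
#' @export
overlap_fraction <- function(proto, position, cells, cell_label, occupied) {
  pv <- placed_voxels(proto, position, dim(cells$data))
  if (pv$n_mask == 0) stop("prototype mask is empty")
  if (length(pv$lin) == 0) return(0)
  good <- cells$data[pv$lin] == cell_label & !occupied[pv$lin]
  sum(good) / pv$n_mask
}

# Linear volume indices covered by the prototype mask centred at `position`
# (0-based voxel index), clipped to the volume.
placed_voxels <- function(proto, position, dims) {
  m_idx <- which(proto$mask == 1L)
  half <- (dim(proto$mask) - 1) / 2
  ai <- arrayInd(m_idx, dim(proto$mask))
  vz <- ai[, 1] - 1 - half[1] + position[1]
  vy <- ai[, 2] - 1 - half[2] + position[2]
  vx <- ai[, 3] - 1 - half[3] + position[3]
  ok <- vz >= 0 & vz < dims[1] & vy >= 0 & vy < dims[2] &
        vx >= 0 & vx < dims[3]
  lin <- (vz[ok] + 1) + dims[1] * (vy[ok] + dims[2] * vx[ok])
  list(lin = lin, mask_idx = m_idx[ok], n_mask = length(m_idx))
}

#' Place nucleus prototypes into simulated cells
#'
#' Cells are processed in ascending label order. For each cell a prototype is
#' drawn uniformly from the database, oriented and scaled to
#' `volume_ratio * V_cell`, and up to `max_positions` centre positions are
#' drawn; the first with [overlap_fraction()] at or above
#' `overlap_threshold` is accepted. If no position works, the next drawn
#' prototype is tried, up to `max_prototypes`, after which the cell is
#' skipped and carries no nucleus.
#'
#' An accepted placement max-blends the full prototype intensity into the
#' image (soft boundary) and labels the voxels of `mask` intersected with the
#' cell and not previously claimed; the nucleus label equals the parent cell
#' label, so border, membrane and nucleus volumes stay joinable.
#'
#' @param cells a `label_volume` of simulated cells.
#' @param protos list of [nucleus_prototype()] objects.
#' @param cfg a [placement_config()].
#' @return A list: `intensity` (`intensity_volume`), `labels`
#'   (`label_volume`), `placements` (data frame with per-cell outcome), and
#'   `skipped` (labels of cells left empty).
#' @export
place_nuclei <- function(cells, protos, cfg = placement_config()) {
  stopifnot(inherits(cells, "label_volume"), length(protos) >= 1,
            inherits(cfg, "placement_config"))
  labs <- volume_labels(cells)
  if (length(labs) == 0) stop("no cells to place nuclei into")
  d <- dim(cells$data)
  sp <- cells$spacing
  vox <- prod(sp)
  intensity <- array(0, d)
  labels <- array(0L, d)
  occupied <- array(FALSE, d)
  recs <- vector("list", length(labs))

  with_seed(derive_seed(cfg$seed, "placement"), {
    for (ci in seq_along(labs)) {
      lab <- labs[ci]
      lin <- which(cells$data == lab)
      coords <- arrayInd(lin, d) - 1L
      v_cell <- length(lin) * vox
      axes <- if (length(lin) >= 2) principal_axes(coords + 1L, sp) else NULL
      placed <- FALSE
      for (pi in seq_len(cfg$max_prototypes)) {
        proto <- protos[[sample.int(length(protos), 1)]]
        tp <- orient_scale_prototype(proto, axes, cfg$volume_ratio * v_cell)
        for (ai in seq_len(cfg$max_positions)) {
          pos <- sample_position(coords, cfg$sigma_frac)
          f <- overlap_fraction(tp, pos, cells, lab, occupied)
          if (f >= cfg$overlap_threshold) {
            pv <- placed_voxels(tp, pos, d)
            intensity[pv$lin] <- pmax(intensity[pv$lin],
                                       tp$intensity[pv$mask_idx])
            claim <- pv$lin[cells$data[pv$lin] == lab & !occupied[pv$lin]]
            labels[claim] <- lab
            occupied[claim] <- TRUE
            recs[[ci]] <- data.frame(label = lab, placed = TRUE,
                                      overlap = f,
                                      nucleus_voxels = length(claim),
                                      cell_voxels = length(lin))
            placed <- TRUE
            break
          }
        }
        if (placed) break
      }
      if (!placed) {
        recs[[ci]] <- data.frame(label = lab, placed = FALSE, overlap = NA,
                                  nucleus_voxels = 0L,
                                  cell_voxels = length(lin))
      }
    }
  })
  placements <- do.call(rbind, recs)
  skipped <- placements$label[!placements$placed]
  if (length(skipped)) {
    message("no nucleus placed in cell(s): ", paste(skipped, collapse = ", "))
  }
  list(intensity = intensity_volume(intensity, sp),
       labels = label_volume(labels, sp),
       placements = placements, skipped = skipped)
}
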