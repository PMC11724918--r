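# Low-level 3D array helpers shared by the morphology, CPM export, placement
# and imaging stages. All operate on plain arrays in (z, y, x) order.

# Value of the array at offset `off` from every voxel: out[v] = a[v + off],
# with `fill` where v + off falls outside the box.
shift_array3d <- function(a, off, fill = 0) {
  d <- dim(a)
  out <- array(fill, d)
  src_lo <- pmax(1, 1 + off)
  src_hi <- pmin(d, d + off)
  if (any(src_lo > src_hi)) return(out)
  dst_lo <- src_lo - off
  dst_hi <- src_hi - off
  out[dst_lo[1]:dst_hi[1], dst_lo[2]:dst_hi[2], dst_lo[3]:dst_hi[3]] <-
    a[src_lo[1]:src_hi[1], src_lo[2]:src_hi[2], src_lo[3]:src_hi[3]]
  out
}

# Offsets (dz, dy, dx) with 0 < dz^2+dy^2+dx^2 <= max_d2, as a matrix.
neighborhood_offsets <- function(max_d2) {
  r <- floor(sqrt(max_d2))
  g <- expand.grid(dz = -r:r, dy = -r:r, dx = -r:r)
  d2 <- g$dz^2 + g$dy^2 + g$dx^2
  as.matrix(g[d2 > 0 & d2 <= max_d2, , drop = FALSE])
}

ball_offsets <- function(radius) {
  rbind(c(0, 0, 0), neighborhood_offsets(radius^2))
}

binary_dilate3d <- function(mask, offsets) {
  out <- mask
  for (i in seq_len(nrow(offsets))) {
    o <- offsets[i, ]
    if (all(o == 0)) next
    out <- out | shift_array3d(mask, o, fill = FALSE)
  }
  out
}

binary_erode3d <- function(mask, offsets) {
  out <- mask
  for (i in seq_len(nrow(offsets))) {
    o <- offsets[i, ]
    if (all(o == 0)) next
    out <- out & shift_array3d(mask, o, fill = FALSE)
  }
  out
}

binary_close3d <- function(mask, offsets) {
  binary_erode3d(binary_dilate3d(mask, offsets), offsets)
}

binary_open3d <- function(mask, offsets) {
  binary_dilate3d(binary_erode3d(mask, offsets), offsets)
}

# Normalized 1D Gaussian kernel truncated at 4 sigma (in voxels).
gaussian_kernel1d <- function(sigma_vox, truncate = 4) {
  if (sigma_vox <= 0) return(1)
  r <- max(1L, ceiling(truncate * sigma_vox))
  k <- exp(-((-r:r)^2) / (2 * sigma_vox^2))
  k / sum(k)
}

# Separable convolution along one axis with zero padding outside the box.
convolve_axis3d <- function(a, kernel, axis) {
  n <- length(kernel)
  if (n == 1L) return(a * kernel)
  r <- (n - 1L) / 2L
  out <- array(0, dim(a))
  for (j in seq_len(n)) {
    off <- c(0, 0, 0)
    off[axis] <- j - 1L - r
    out <- out + kernel[j] * shift_array3d(a, off, fill = 0)
  }
  out
}

gaussian_blur3d <- function(a, sigma_vox, truncate = 4) {
  for (axis in 1:3) {
    a <- convolve_axis3d(a, gaussian_kernel1d(sigma_vox[axis], truncate), axis)
  }
  a
}

# Connected components of a binary mask (6-connectivity), small volumes only.
connected_components3d <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  nxt <- 0L
  todo <- which(mask != 0)
  offs <- neighborhood_offsets(1)
  for (start in todo) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue)) {
      v <- queue[[1]]
      queue <- queue[-1]
      vi <- arrayInd(v, d)
      for (i in seq_len(nrow(offs))) {
        w <- vi + offs[i, ]
        if (any(w < 1) || any(w > d)) next
        wl <- w[1] + d[1] * (w[2] - 1 + d[2] * (w[3] - 1))
        if (mask[wl] != 0 && lab[wl] == 0L) {
          lab[wl] <- nxt
          queue <- c(queue, wl)
        }
      }
    }
  }
  lab
}
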