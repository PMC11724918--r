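#' Unbiased squared maximum mean discrepancy (MMD)
#'
#' Polynomial-kernel MMD^2 between two feature sets, the statistic behind the
#' Kernel Inception Distance: `k(a, b) = (a . b / d + 1)^3` with `d` the
#' feature dimension. Within-set sums exclude the diagonal. When the two sets
#' have equal size the estimator also excludes matched-index cross pairs
#' (the fully unbiased paired form), so element-wise identical sets score
#' exactly 0 by term cancellation. Note the paired form depends on the row
#' pairing: reordering both sets jointly leaves it unchanged, reordering one
#' set alone re-pairs the excluded cross terms. With unequal sizes the
#' standard full-cross-sum estimator is used and either set may be permuted
#' freely.
#'
#' @param f_real,f_synth matrices, one feature vector per row (>= 2 rows
#'   each).
#' @param d kernel dimension divisor; defaults to `ncol(f_real)`.
#' @return Scalar MMD^2 estimate.
#' @export
mmd2_unbiased <- function(f_real, f_synth, d = ncol(f_real)) {
  f_real <- as.matrix(f_real)
  f_synth <- as.matrix(f_synth)
  n <- nrow(f_real)
  m <- nrow(f_synth)
  if (n < 2 || m < 2) stop("each feature set needs at least 2 vectors")
  stopifnot(ncol(f_real) == ncol(f_synth))
  kxx <- (f_real %*% t(f_real) / d + 1)^3
  kyy <- (f_synth %*% t(f_synth) / d + 1)^3
  kxy <- (f_real %*% t(f_synth) / d + 1)^3
  t1 <- (sum(kxx) - sum(diag(kxx))) / (n * (n - 1))
  t2 <- (sum(kyy) - sum(diag(kyy))) / (m * (m - 1))
  t3 <- if (n == m) {
    2 * (sum(kxy) - sum(diag(kxy))) / (n * (n - 1))
  } else {
    2 * sum(kxy) / (n * m)
  }
  t1 + t2 - t3
}

#' Default slice feature extractor
#'
#' A deterministic, download-free stand-in for a pretrained 2D feature
#' network: slices are resized bilinearly to `input_size` x `input_size`,
#' flattened, and projected onto `d` fixed random orthogonal directions
#' (drawn once from an internal seed). Any function mapping a 2D matrix to a
#' fixed-length finite vector can replace it, e.g. an adapter around a
#' pretrained InceptionV3 whose weights live outside this package.
#'
#' @param d output feature dimension.
#' @param input_size resize target (pixels per side).
#' @return A function `slice matrix -> numeric(d)`.
#' @export
default_feature_extractor <- function(d = 64L, input_size = 16L) {
  p <- input_size^2
  stopifnot(d <= p)
  proj <- with_seed(20240101L, {
    qr.Q(qr(matrix(stats::rnorm(p * p), p, p)))[, seq_len(d), drop = FALSE]
  })
  function(slice) {
    as.vector(crossprod(proj,
                        as.vector(resize_bilinear2d(slice, input_size))))
  }
}

resize_bilinear2d <- function(m, size) {
  d <- dim(m)
  if (all(d == size)) return(m)
  # output pixel centres mapped into input pixel-centre coordinates
  u <- (seq_len(size) - 0.5) * d[1] / size - 0.5
  v <- (seq_len(size) - 0.5) * d[2] / size - 0.5
  u <- pmin(pmax(u, 0), d[1] - 1)
  v <- pmin(pmax(v, 0), d[2] - 1)
  u0 <- pmin(floor(u), d[1] - 2); fu <- u - u0
  v0 <- pmin(floor(v), d[2] - 2); fv <- v - v0
  m00 <- m[cbind(rep(u0 + 1, size), rep(v0 + 1, each = size))]
  m10 <- m[cbind(rep(u0 + 2, size), rep(v0 + 1, each = size))]
  m01 <- m[cbind(rep(u0 + 1, size), rep(v0 + 2, each = size))]
  m11 <- m[cbind(rep(u0 + 2, size), rep(v0 + 2, each = size))]
  wu <- rep(fu, size); wv <- rep(fv, each = size)
  matrix((1 - wu) * (1 - wv) * m00 + wu * (1 - wv) * m10 +
         (1 - wu) * wv * m01 + wu * wv * m11, size, size)
}

#' Slice-wise Kernel Inception Distance between two volumes
#'
#' A pretrained 2D feature extractor cannot see 3D images directly, so the
#' KID is computed slice by slice: for each of the three major plane
#' directions (xy, xz, yz) the features of every slice of both volumes are
#' extracted and [mmd2_unbiased()] is averaged over `n_subsets` random
#' subsets of `subset_size` slices; the final value is the mean over the
#' three directions.
#'
#' @param real,synth `intensity_volume`s.
#' @param fx feature extractor (see [default_feature_extractor()]).
#' @param subset_size slices per subset (reduced with a warning when a
#'   direction has fewer slices).
#' @param n_subsets number of random subsets.
#' @param seed integer seed for the subset draws.
#' @param paired draw the same subset indices for both volumes (requires
#'   equal slice counts); identical volumes then score exactly 0.
#' @return Scalar KID with attribute `directions` (named per-direction
#'   means).
#' @export
kid_volume <- function(real, synth, fx = default_feature_extractor(),
                       subset_size = 50L, n_subsets = 20L, seed = 1L,
                       paired = FALSE) {
  stopifnot(inherits(real, "intensity_volume"),
            inherits(synth, "intensity_volume"))
  slice_fun <- list(
    xy = function(a, i) a[i, , ],
    xz = function(a, i) a[, i, ],
    yz = function(a, i) a[, , i]
  )
  n_slices <- function(a, dir) dim(a)[match(dir, c("xy", "xz", "yz"))]
  per_dir <- numeric(3)
  names(per_dir) <- names(slice_fun)
  for (dir in names(slice_fun)) {
    fr <- t(vapply(seq_len(n_slices(real$data, dir)),
                   function(i) fx(slice_fun[[dir]](real$data, i)),
                   numeric(length(fx(slice_fun[[dir]](real$data, 1))))))
    fs <- t(vapply(seq_len(n_slices(synth$data, dir)),
                   function(i) fx(slice_fun[[dir]](synth$data, i)),
                   numeric(ncol(fr))))
    ss <- min(subset_size, nrow(fr), nrow(fs))
    if (ss < subset_size) {
      warning("subset size reduced to ", ss, " (", dir, " direction)")
    }
    if (ss < 2) stop("need at least 2 slices per direction")
    vals <- with_seed(derive_seed(seed, paste0("kid:", dir)), {
      vapply(seq_len(n_subsets), function(k) {
        ir <- sample.int(nrow(fr), ss)
        is <- if (paired) {
          if (nrow(fr) != nrow(fs)) {
            stop("paired subset draws require equal slice counts")
          }
          ir
        } else {
          sample.int(nrow(fs), ss)
        }
        mmd2_unbiased(fr[ir, , drop = FALSE], fs[is, , drop = FALSE],
                      d = ncol(fr))
      }, numeric(1))
    })
    per_dir[dir] <- mean(vals)
  }
  structure(mean(per_dir), directions = per_dir)
}

# Majority-overlap match table between GT objects and predicted labels:
# GT object R matches predicted S iff |R n S| > 0.5 |R| (strict majority;
# at most one such S exists). Returns per-GT match info and per-pred claims.
match_objects <- function(gt, pred) {
  stopifnot(identical(dim(gt$data), dim(pred$data)))
  gt_labs <- volume_labels(gt)
  if (length(gt_labs) == 0) stop("ground truth has no objects")
  pred_labs <- volume_labels(pred)
  gt_sizes <- tabulate_labels(gt$data, gt_labs)
  pred_sizes <- tabulate_labels(pred$data, pred_labs)
  both <- gt$data != 0L & pred$data != 0L
  matched_pred <- rep(NA_integer_, length(gt_labs))
  jacc <- numeric(length(gt_labs))
  if (any(both)) {
    ov <- table(gt = gt$data[both], pred = pred$data[both])
    for (gi in seq_along(gt_labs)) {
      gl <- as.character(gt_labs[gi])
      if (!gl %in% rownames(ov)) next
      counts <- ov[gl, ]
      best <- which(counts > 0.5 * gt_sizes[gi])
      if (length(best) == 1) {
        pl <- as.integer(colnames(ov)[best])
        inter <- as.numeric(counts[best])
        uni <- gt_sizes[gi] + pred_sizes[match(pl, pred_labs)] - inter
        matched_pred[gi] <- pl
        jacc[gi] <- inter / uni
      }
    }
  }
  claims <- table(factor(matched_pred, levels = pred_labs))
  list(gt_labs = gt_labs, pred_labs = pred_labs,
       matched_pred = matched_pred, jaccard = jacc,
       claims = as.integer(claims))
}

tabulate_labels <- function(data, labs) {
  vapply(labs, function(l) sum(data == l), numeric(1))
}

#' SEG score (Cell Tracking Challenge convention)
#'
#' For each ground-truth object the predicted label covering a strict
#' majority of its voxels (if any) is its match; the object scores the
#' Jaccard index with its match, or 0 when unmatched. SEG is the mean over
#' ground-truth objects.
#'
#' @param gt,pred `label_volume`s of identical shape.
#' @return SEG in `[0, 1]`.
#' @export
seg_score <- function(gt, pred) {
  mt <- match_objects(gt, pred)
  mean(mt$jaccard)
}

#' DET score (Cell Tracking Challenge convention)
#'
#' Detection accuracy from the majority-overlap matching: unmatched
#' ground-truth objects are false negatives (FN), predicted labels claimed by
#' no object are false positives (FP), and a predicted label claimed by k >= 2
#' objects requires k - 1 splitting operations (NS). With the standard
#' detection weights, `AOGM-D = 5 NS + 10 FN + 1 FP`, `AOGM-D0 = 10 |GT|`
#' (the cost of building the detection from nothing), and
#' `DET = 1 - min(AOGM-D, AOGM-D0) / AOGM-D0`.
#'
#' @param gt,pred `label_volume`s of identical shape.
#' @return DET in `[0, 1]` with attribute `counts` (`FN`, `FP`, `NS`).
#' @export
det_score <- function(gt, pred) {
  mt <- match_objects(gt, pred)
  fn <- sum(is.na(mt$matched_pred))
  fp <- sum(mt$claims == 0L)
  ns <- sum(pmax(mt$claims - 1L, 0L))
  aogm_d <- 5 * ns + 10 * fn + 1 * fp
  aogm_d0 <- 10 * length(mt$gt_labs)
  structure(1 - min(aogm_d, aogm_d0) / aogm_d0,
            counts = c(FN = fn, FP = fp, NS = ns))
}

#' Whole-image-then-crop evaluation protocol
#'
#' Segmentation quality is assessed by segmenting the whole image and only
#' then cropping the prediction to the ground-truth patch: nuclei stay fully
#' visible to the model, and objects truncated by the crop are scored as
#' cropped. Predicted objects lying entirely outside the crop never count as
#' false positives.
#'
#' @param pred_full `label_volume` prediction over the full image.
#' @param gt_patch `label_volume` ground-truth patch.
#' @param offset integer (z, y, x) position of the patch within the full
#'   image, 0-based.
#' @return List `(SEG, DET)`.
#' @export
eval_protocol_crop <- function(pred_full, gt_patch, offset) {
  stopifnot(inherits(pred_full, "label_volume"),
            inherits(gt_patch, "label_volume"), length(offset) == 3)
  offset <- as.integer(offset)
  dp <- dim(pred_full$data)
  dg <- dim(gt_patch$data)
  if (any(offset < 0) || any(offset + dg > dp)) {
    stop("crop offset out of bounds")
  }
  crop <- pred_full$data[offset[1] + seq_len(dg[1]),
                         offset[2] + seq_len(dg[2]),
                         offset[3] + seq_len(dg[3]), drop = FALSE]
  pred <- label_volume(crop, gt_patch$spacing)
  list(SEG = seg_score(gt_patch, pred), DET = det_score(gt_patch, pred))
}
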