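#' Derive a stage-specific random seed
#'
#' All stochastic stages draw from an independent substream keyed by a stage
#' name, so that adding or reordering stages never perturbs another stage's
#' draws. The derivation hashes the stage label (FNV-1a, 32 bit) and folds in
#' the top-level seed; the result is a valid 32-bit R seed.
#'
#' @param seed top-level integer seed.
#' @param stage character label of the stage (e.g. `"cpm"`, `"placement"`).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(length(seed) == 1, is.finite(seed), length(stage) == 1)
  m <- 2147483647  # 2^31 - 1, keeps everything exact in doubles
  h <- fnv1a32(paste0(stage))
  s <- ((seed %% m) * 69069) %% m
  as.integer((h %% m + s) %% m)
}

# FNV-1a 32-bit hash, kept exact by splitting the multiply into 16-bit halves.
fnv1a32 <- function(x) {
  bytes <- utf8ToInt(enc2utf8(x))
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    h <- bitwXor32(h, b %% 256)
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- ((lo * p) %% 4294967296 + ((hi * p) %% 65536) * 65536) %% 4294967296
  }
  h
}

bitwXor32 <- function(a, b) {
  # xor on doubles holding 32-bit unsigned values
  r <- 0
  bit <- 1
  for (i in 1:32) {
    ab <- a %% 2
    bb <- b %% 2
    if (ab != bb) r <- r + bit
    a <- (a - ab) / 2
    b <- (b - bb) / 2
    bit <- bit * 2
    if (a == 0 && b == 0) break
  }
  r
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed`, so library code never disturbs the
#' caller's RNG state.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

default_run_config <- function() {
  list(
    seed = 1L,
    phantom = list(shape = c(48L, 48L, 48L), sphere_radius = 20, n_cells = 30L,
                   n_prototypes = 8L, axes_range = c(3, 6)),
    clean = list(min_voxels = 5L, min_z_planes = 4L),
    cpm = list(lambda_V = 10, lambda_A = 0.001, J_cc = 2, J_cm = 55, T = 30,
               potts_neighbor_order = 3L, contact_neighbor_order = 4L,
               mcs = 1000L, snapshot_at = integer(0)),
    scan = list(lambda_V = c(0.001, 2, 4, 6, 8, 10),
                lambda_A = c(0.001, 2, 4, 6, 8, 10),
                J_cc = c(0.0001, 2, 4, 6, 8, 10),
                J_cm = c(10, 55, 100),
                mcs = 1000L),
    placement = list(volume_ratio = 0.35, overlap_threshold = 0.8,
                     sigma_frac = 0.25, max_positions = 10L,
                     max_prototypes = 5L),
    imaging = list(attenuation_depth = Inf, psf_sigma = c(1, 0.5, 0.5),
                   downsample = c(1L, 1L, 1L), noise_gain = 0,
                   noise_sigma = 0),
    postprocess = list(threshold = 0.5, opening_radius = 1L),
    eval = list(subset_size = 50L, n_subsets = 20L)
  )
}

#' Read a run configuration
#'
#' Loads a YAML file and merges it over the package defaults. Unknown keys are
#' kept (forward compatibility); known blocks are merged element-wise.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @return A named list with one block per pipeline stage plus `seed`.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    cfg <- modify_list_deep(cfg, user)
  }
  cfg
}

modify_list_deep <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- modify_list_deep(base[[nm]], user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}
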