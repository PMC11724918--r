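#' Cellular Potts Model parameters
#'
#' The CPM Hamiltonian models the total free energy of the cell conglomerate:
#' \deqn{H = \sum_i \lambda_V (V_i - V_i^{t})^2
#'         + \sum_i \lambda_A (A_i - A_i^{t})^2
#'         + \sum_{i<j} J^{(c-c)} A_{ij}^{(c-c)}
#'         + \sum_i J^{(c-m)} A_i^{(c-m)}}
#' where \eqn{V_i}, \eqn{A_i} are the volume (voxel count) and surface area
#' (boundary-pair count) of cell i, the t superscripts are per-cell target
#' values, \eqn{A_{ij}^{(c-c)}} is the cell-cell contact area and
#' \eqn{A_i^{(c-m)}} the cell-medium contact area. `lambda_V` and `lambda_A`
#' set the strength of the volume and area constraints, the contact energies
#' `J_cc`, `J_cm` are the surface-tension parameters, and the temperature `T`
#' sets the strength of fluctuations around the energy minimum.
#'
#' Neighbourhood shells follow the squared-Euclidean-distance convention
#' (order k = all offsets with squared distance at most k, i.e. 6/18/26/32
#' sites for orders 1-4). `potts_neighbor_order` governs where copy sources
#' are drawn from, `contact_neighbor_order` the neighbourhood used for
#' contact and area counting; the defaults (3 and 4) are the standard choice
#' for spheroid-scale simulations. Default parameter values are the
#' best-ranked set from the calibration scan (`lambda_V` 10, `lambda_A`
#' 0.001, `J_cc` 2, `J_cm` 55, `T` 30).
#'
#' @param lambda_V volume-constraint weight.
#' @param lambda_A area-constraint weight.
#' @param J_cc cell-cell contact energy per boundary pair.
#' @param J_cm cell-medium contact energy per boundary pair.
#' @param T temperature (> 0).
#' @param potts_neighbor_order copy-source shell order (>= 1).
#' @param contact_neighbor_order contact/area shell order (>= 1).
#' @param mcs number of Monte Carlo steps for [run_mcs()] (>= 0).
#' @return A `cpm_params` list.
#' @export
cpm_params <- function(lambda_V = 10, lambda_A = 0.001, J_cc = 2, J_cm = 55,
                       T = 30, potts_neighbor_order = 3L,
                       contact_neighbor_order = 4L, mcs = 1000L) {
  stopifnot(T > 0, potts_neighbor_order >= 1, contact_neighbor_order >= 1,
            mcs >= 0, lambda_V >= 0, lambda_A >= 0)
  structure(list(lambda_V = lambda_V, lambda_A = lambda_A, J_cc = J_cc,
                 J_cm = J_cm, T = T,
                 potts_neighbor_order = as.integer(potts_neighbor_order),
                 contact_neighbor_order = as.integer(contact_neighbor_order),
                 mcs = as.integer(mcs)),
            class = "cpm_params")
}

#' Create a CPM state from a label volume
#'
#' Tallies per-cell volumes `V_i`, surface areas `A_i` (boundary-pair counts
#' in the contact-order neighbourhood; sites outside the box count as medium)
#' and the total cell-cell / cell-medium contact pair counts. Target values
#' default to the initial actual values; use [assign_targets()] to permute
#' them. Medium (label 0) carries no targets.
#'
#' @param vol a `label_volume` starting configuration.
#' @param params a [cpm_params()] object (sets the contact order).
#' @return A `cpm_state` list with elements `lattice`, `V`, `A`, `V_target`,
#'   `A_target` (vectors indexed by label), `total_cc`, `total_cm`.
#' @export
cpm_state <- function(vol, params = cpm_params()) {
  stopifnot(inherits(vol, "label_volume"), inherits(params, "cpm_params"))
  max_label <- max(0L, max(vol$data))
  t <- cpm_tally_cpp(as.integer(vol$data), dim(vol$data),
                     params$contact_neighbor_order, max_label)
  V <- t$V
  A <- t$A
  tgt <- rep(NA_real_, max_label + 1L)
  present <- which(V > 0)  # 1-based position = label + 1
  Vt <- tgt; At <- tgt
  Vt[present] <- V[present]
  At[present] <- A[present]
  structure(list(lattice = vol, V = V, A = A, V_target = Vt, A_target = At,
                 total_cc = t$total_cc, total_cm = t$total_cm,
                 contact_order = params$contact_neighbor_order),
            class = "cpm_state")
}

state_labels <- function(state) {
  which(state$V > 0) - 1L
}

#' @export
print.cpm_state <- function(x, ...) {
  cat(sprintf("<cpm_state> %s lattice, %d cells, %d cell voxels\n",
              paste(dim(x$lattice$data), collapse = "x"),
              length(state_labels(x)), sum(x$V)))
  invisible(x)
}

#' Assign permuted target values to every cell
#'
#' Sets the target volume and area of cell i to the initial actual values of
#' cell P(i), where P is a uniformly drawn derangement (a permutation with no
#' fixed point, resampled until none remains). Every cell therefore has
#' targets different from its initial values, ensuring some dynamics in the
#' simulation, while the multiset of targets over the ensemble equals the
#' multiset of initial actual values, preserving the volume/area distribution.
#'
#' @param state a [cpm_state()].
#' @param seed integer seed for the permutation draw.
#' @return The state with `V_target` and `A_target` replaced.
#' @export
assign_targets <- function(state, seed = 1L) {
  stopifnot(inherits(state, "cpm_state"))
  labs <- state_labels(state)
  n <- length(labs)
  if (n < 2) {
    warning("fewer than 2 cells; targets left at initial values")
    return(state)
  }
  perm <- with_seed(derive_seed(seed, "cpm:targets"), {
    repeat {
      p <- sample(n)
      if (all(p != seq_len(n))) break
    }
    p
  })
  state$V_target[labs + 1L] <- state$V[labs[perm] + 1L]
  state$A_target[labs + 1L] <- state$A[labs[perm] + 1L]
  state
}

#' Hamiltonian of a CPM state
#'
#' Recomputes the total energy from scratch (tallying the lattice), the
#' reference against which the incremental updates of the Metropolis kernel
#' are validated. Cells that have vanished but still carry targets contribute
#' their full penalty terms.
#'
#' @param state a [cpm_state()].
#' @param params a [cpm_params()].
#' @return The scalar energy.
#' @export
hamiltonian <- function(state, params) {
  stopifnot(inherits(state, "cpm_state"), inherits(params, "cpm_params"))
  cpm_hamiltonian_cpp(as.integer(state$lattice$data), dim(state$lattice$data),
                      params$contact_neighbor_order,
                      na_to_nan(state$V_target), na_to_nan(state$A_target),
                      params$lambda_V, params$lambda_A,
                      params$J_cc, params$J_cm)
}

na_to_nan <- function(x) {
  x[is.na(x)] <- NaN
  x
}

#' Run a single Metropolis proposal
#'
#' Picks a uniformly random lattice site and a uniformly random copy source
#' among its Potts-order neighbours (an out-of-box source, or a source with
#' the same label, is a null attempt). The energy change of copying the
#' source label onto the site is computed incrementally and accepted with
#' probability 1 if `deltaH <= 0`, else `exp(-deltaH / T)`. Draws come from
#' R's RNG, so `set.seed()` controls reproducibility.
#'
#' @param state a [cpm_state()].
#' @param params a [cpm_params()].
#' @return A list `(state, accepted, null, deltaH)`; `deltaH` is `NA` for a
#'   null attempt.
#' @export
propose_and_apply <- function(state, params) {
  res <- cpm_run_core(state, params, n_attempts = 1, mcs_len = 0L,
                      snapshot_at = integer(0), record = TRUE)
  list(state = res$state,
       accepted = res$raw$status[1] == 1L,
       null = res$raw$status[1] == -1L,
       deltaH = res$raw$deltaH[1])
}

cpm_run_core <- function(state, params, n_attempts, mcs_len, snapshot_at,
                         record = FALSE) {
  raw <- cpm_run_cpp(as.integer(state$lattice$data), dim(state$lattice$data),
                     params$potts_neighbor_order,
                     params$contact_neighbor_order,
                     na_to_nan(state$V_target), na_to_nan(state$A_target),
                     params$lambda_V, params$lambda_A, params$J_cc,
                     params$J_cm, params$T, as.numeric(n_attempts),
                     as.integer(mcs_len), as.integer(snapshot_at), record)
  out <- state
  out$lattice <- label_volume(array(raw$lattice, dim(state$lattice$data)),
                              state$lattice$spacing)
  out$V <- raw$V
  out$A <- raw$A
  out$total_cc <- raw$total_cc
  out$total_cm <- raw$total_cm
  list(state = out, raw = raw)
}

#' Run Monte Carlo steps
#'
#' One Monte Carlo step (MCS) is N site-update attempts, N being the total
#' lattice site count. Cells may shrink to zero volume (the label disappears);
#' this is permitted and reported. The running energy is recorded at every
#' MCS boundary.
#'
#' @param state a [cpm_state()], typically after [assign_targets()].
#' @param params a [cpm_params()]; `params$mcs` sets the step count.
#' @param snapshot_at integer MCS indices at which to capture lattice
#'   snapshots (0 = starting configuration).
#' @param seed optional integer seed applied before the run.
#' @return A list with `state` (final), `H_trace` (energy at MCS boundaries,
#'   length `mcs + 1`), `snapshots` (named list of `label_volume`s),
#'   `n_accepted`, `n_null`, and `vanished` (labels that disappeared).
#' @export
run_mcs <- function(state, params, snapshot_at = integer(0), seed = NULL) {
  stopifnot(inherits(state, "cpm_state"), inherits(params, "cpm_params"))
  before <- state_labels(state)
  N <- prod(dim(state$lattice$data))
  run1 <- function() {
    cpm_run_core(state, params, n_attempts = as.numeric(params$mcs) * N,
                 mcs_len = N, snapshot_at = snapshot_at)
  }
  res <- if (is.null(seed)) run1() else with_seed(seed, run1())
  snaps <- lapply(res$raw$snapshots, function(s) {
    label_volume(array(s, dim(state$lattice$data)), state$lattice$spacing)
  })
  names(snaps) <- as.character(snapshot_at)
  vanished <- setdiff(before, state_labels(res$state))
  if (length(vanished)) {
    message("cells vanished during simulation: ",
            paste(vanished, collapse = ", "))
  }
  list(state = res$state, H_trace = res$raw$H_trace, snapshots = snaps,
       n_accepted = res$raw$n_accepted, n_null = res$raw$n_null,
       vanished = vanished)
}

#' Export a simulated lattice as a cell-border image
#'
#' The cell-border image is the label lattice itself: each cell is a set of
#' voxels with the same intensity, medium is 0. Provided as an explicit stage
#' so pipeline outputs are named by what they are.
#'
#' @param lattice a `label_volume`.
#' @return The same `label_volume`.
#' @export
export_borders <- function(lattice) {
  stopifnot(inherits(lattice, "label_volume"))
  lattice
}

#' Rasterize cell borders into a binary membrane volume
#'
#' A voxel is membrane (1) iff it carries a nonzero label and at least one of
#' its 6-neighbours carries a different label (medium and out-of-box sites
#' count as different). This converts simulated cell borders into the binary
#' membrane signal used as the GAN condition input.
#'
#' @param lattice a `label_volume`.
#' @return A binary `label_volume` (values 0/1).
#' @export
rasterize_membrane <- function(lattice) {
  stopifnot(inherits(lattice, "label_volume"))
  data <- lattice$data
  memb <- array(FALSE, dim(data))
  for (i in seq_len(nrow(neigh6))) {
    nb <- shift_array3d(data, neigh6[i, ], fill = 0L)
    memb <- memb | (data != 0L & nb != data)
  }
  label_volume(array(as.integer(memb), dim(data)), lattice$spacing)
}
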