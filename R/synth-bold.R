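#' @title Synthetic BOLD runs
#' @description AR(1) voxel noise plus latent neighborhood structure: each
#'   ROI voxel loads on the latent time series of its spatial parcel, so
#'   the ILC map over the ROI has a reproducible spatial pattern
#'   determined by a pattern seed. Post-learning rest runs mix the task
#'   pattern's structure back in with a per-subject fidelity weight,
#'   emulating offline memory reactivation. Realism is deliberately
#'   limited to this AR(1) + latent-neighborhood structure: no
#'   physiological or motion confounds are simulated.
#' @name synth_bold
NULL

#' Default ROI masks on the simulation grid
#'
#' Disjoint corner boxes standing in for the M1 hand-knob region (the MRS
#' voxel), the true planted engram cube inside it, the right and left
#' putamen, and the PCC control region.
#'
#' @param grid_shape 3 integers (each >= 8).
#' @return named list of \code{roi_mask} objects (\code{M1_box},
#'   \code{engram_true}, \code{putamen_R}, \code{putamen_L}, \code{PCC}).
#' @export
default_roi_masks <- function(grid_shape) {
  g <- as.integer(grid_shape)
  stopifnot(length(g) == 3, all(g >= 8))
  box <- function(x, y, z) {
    m <- array(FALSE, g)
    m[x, y, z] <- TRUE
    m
  }
  s1 <- max(4L, min(g) %/% 3L)
  m1 <- box(1:s1, 1:s1, 1:s1)
  se <- max(3L, s1 - 2L)
  o <- (s1 - se) %/% 2L
  engram <- box(o + 1:se, o + 1:se, o + 1:se)
  list(
    M1_box = roi_mask(m1, "M1_box"),
    engram_true = roi_mask(engram, "engram_true"),
    putamen_R = roi_mask(box((g[1] - 2):g[1], (g[2] - 2):g[2], 1:3), "putamen_R"),
    putamen_L = roi_mask(box((g[1] - 2):g[1], 1:3, (g[3] - 2):g[3]), "putamen_L"),
    PCC = roi_mask(box(1:3, (g[2] - 2):g[2], (g[3] - 2):g[3]), "PCC")
  )
}

# Voronoi parcellation of the ROI voxels around K random seed voxels, with
# per-voxel signal gains; fully determined by `seed`.
.pattern_structure <- function(roi, seed, effects) {
  idx <- which(roi$mask)
  co <- arrayInd(idx, dim(roi$mask))
  set.seed(seed)
  K <- max(4L, length(idx) %/% 8L)
  ctr <- co[sample(length(idx), K), , drop = FALSE]
  d2 <- outer(rowSums(co^2), rep(1, K)) + outer(rep(1, nrow(co)), rowSums(ctr^2)) -
    2 * co %*% t(ctr)
  assign <- max.col(-d2, ties.method = "first")
  gain <- effects$bold_signal_sd * (0.5 + stats::runif(length(idx)))
  list(idx = idx, assign = assign, K = K, gain = gain)
}

# stationary AR(1) with marginal sd `sd`; row 1 drawn from the marginal
# distribution so no burn-in is needed
.ar1_series <- function(n, rho, sd = 1, ncol = 1) {
  if (rho == 0) return(matrix(stats::rnorm(n * ncol, 0, sd), n, ncol))
  X <- matrix(stats::rnorm(n * ncol, 0, sd * sqrt(1 - rho^2)), n, ncol)
  X[1, ] <- X[1, ] / sqrt(1 - rho^2)
  for (t in 2:n) X[t, ] <- rho * X[t - 1L, ] + X[t, ]
  X
}

#' Simulate one BOLD run
#'
#' Voxel time series are AR(1) noise; ROI voxels additionally load on the
#' latent AR(1) time series of their spatial parcel. The parcellation and
#' loadings of the *task* structure are determined by \code{pattern_seed}
#' and reused across a subject's runs; each run draws fresh latent time
#' series. \code{fidelity} mixes the task structure (weight
#' \code{sqrt(fidelity)}) with a run-specific independent structure
#' (weight \code{sqrt(1 - fidelity)}): 1 reproduces the task's spatial ILC
#' pattern, 0 yields an unrelated pattern. Voxels outside the ROI are pure
#' noise unless touched by \code{injections} or \code{active}.
#'
#' @param condition one of "task", "task_day2", "pre_rest", "post_rest",
#'   "day2_rest" (selects the run length from \code{config}).
#' @param roi \code{roi_mask} carrying the latent structure (the M1 box).
#' @param pattern_seed integer determining the task spatial structure.
#' @param fidelity mixing weight of the task structure, in [0, 1].
#' @param config a \code{\link{cohort_config}}.
#' @param effects an \code{\link{effect_spec}}.
#' @param run_seed seed for this run's noise and latent draws (default
#'   derived from \code{pattern_seed} and the condition).
#' @param injections optional list of \code{list(mask=, weight=, id=)}:
#'   every voxel of \code{mask} receives \code{weight} times a shared
#'   AR(1) latent keyed by \code{id} (used to plant ROI-to-ROI
#'   connectivity).
#' @param active optional \code{list(mask=, onsets=, duration=,
#'   amplitude=)} adding an HRF-convolved boxcar to the masked voxels.
#' @param n_vol override the run length.
#' @return a \code{\link{bold_run}}.
#' @export
simulate_bold_run <- function(condition, roi, pattern_seed, fidelity = 0,
                              config = cohort_config(),
                              effects = effect_spec(), run_seed = NULL,
                              injections = NULL, active = NULL,
                              n_vol = NULL) {
  if (fidelity < 0 || fidelity > 1) stop("fidelity must lie in [0, 1]")
  stopifnot(inherits(roi, "roi_mask"))
  g <- config$grid_shape
  if (!all(dim(roi$mask) == g)) stop("roi does not lie on the config grid")
  if (is.null(n_vol)) {
    n_vol <- switch(condition,
                    task = config$n_volumes_task,
                    task_day2 = config$n_volumes_task_day2,
                    config$n_volumes_rest)
  }
  cond_off <- c(task = 1L, task_day2 = 2L, pre_rest = 3L, post_rest = 4L,
                day2_rest = 5L)
  if (is.null(run_seed)) {
    off <- if (condition %in% names(cond_off)) cond_off[[condition]] else 6L
    run_seed <- (pattern_seed + 65537L * off) %% (2147483647L - 1L) + 1L
  }

  task_str <- .pattern_structure(roi, pattern_seed, effects)
  ind_str <- .pattern_structure(roi, (run_seed + 977L) %% 2147483647L, effects)

  set.seed(run_seed)
  nv <- prod(g)
  Y <- .ar1_series(n_vol, effects$ar1_coef, effects$bold_noise_sd, nv)  # t x v

  wt <- sqrt(fidelity); wi <- sqrt(1 - fidelity)
  if (wt > 0) {
    L <- .ar1_series(n_vol, effects$ar1_coef, 1, task_str$K)
    Y[, task_str$idx] <- Y[, task_str$idx] +
      L[, task_str$assign] * rep(wt * task_str$gain, each = n_vol)
  }
  if (wi > 0) {
    L <- .ar1_series(n_vol, effects$ar1_coef, 1, ind_str$K)
    Y[, ind_str$idx] <- Y[, ind_str$idx] +
      L[, ind_str$assign] * rep(wi * ind_str$gain, each = n_vol)
  }
  if (!is.null(injections)) {
    ids <- unique(vapply(injections, `[[`, character(1), "id"))
    lat <- .ar1_series(n_vol, effects$ar1_coef, 1, length(ids))
    colnames(lat) <- ids
    for (inj in injections) {
      midx <- if (is.array(inj$mask)) which(inj$mask) else inj$mask
      Y[, midx] <- Y[, midx] + inj$weight * lat[, inj$id]
    }
  }
  if (!is.null(active)) {
    stim <- numeric(n_vol)
    times <- (seq_len(n_vol) - 1) * config$tr
    for (on in active$onsets) {
      stim[times >= on & times < on + active$duration] <- 1
    }
    reg <- .convolve_hrf(stim, config$tr) * active$amplitude
    midx <- if (is.array(active$mask)) which(active$mask) else active$mask
    Y[, midx] <- Y[, midx] + reg
  }
  arr <- array(t(Y), c(g, n_vol))
  bold_run(arr, tr = config$tr, condition = condition,
           voxel_size = config$voxel_size)
}

#' Concatenate the late-phase volumes of a task run
#'
#' Extracts, for each late-phase block, the volumes from
#' \code{drop_volumes} after block onset to block offset (dropping the
#' hemodynamic transition), and concatenates them into a new run used to
#' compute the task MVLC pattern.
#'
#' @param run a task \code{bold_run}.
#' @param onsets late-block onsets in seconds.
#' @param duration block duration in seconds.
#' @param drop_volumes transition volumes dropped at each block start.
#' @return a \code{bold_run} with condition "task_late".
#' @export
extract_late_volumes <- function(run, onsets, duration, drop_volumes = 5) {
  n_vol <- dim(run$data)[4]
  keep <- integer(0)
  for (on in onsets) {
    i0 <- floor(on / run$tr) + 1L + drop_volumes
    i1 <- floor((on + duration) / run$tr)
    if (i1 > n_vol) i1 <- n_vol
    if (i0 <= i1) keep <- c(keep, i0:i1)
  }
  if (length(keep) < 20) stop("too few late-phase volumes after dropping transitions")
  bold_run(run$data[, , , keep, drop = FALSE], tr = run$tr,
           condition = "task_late", voxel_size = run$voxel_size)
}

# Solve uniform injection weights (one latent per edge, equal weight on
# both ends) so that the ROI-mean time courses of the M1 engram cube and
# each partner region correlate at the target values. Fixed-point
# iteration on the M1-side variance, which includes all edges' latents.
.solve_fc_weights <- function(target_r, n_m1, n_partner, parcel_var_m1,
                              noise_sd) {
  stopifnot(all(abs(target_r) < 1))
  sgn <- ifelse(target_r >= 0, 1, -1)
  # the M1 mean carries every edge's latent, so the squared correlations
  # with the (independent) edge latents must jointly stay below 1; cap and,
  # if needed, rescale to keep the system solvable. A negative target is
  # realized by flipping the sign of the partner-side weight.
  r <- pmin(abs(target_r), 0.8)
  r <- pmax(r, 1e-4)
  if (sum(r^2) > 0.8) r <- r * sqrt(0.8 / sum(r^2))
  base_m1 <- noise_sd^2 / n_m1 + parcel_var_m1
  base_p <- noise_sd^2 / n_partner
  w2 <- rep(0.05, length(r))
  for (it in 1:200) {
    var_m1 <- base_m1 + sum(w2)
    w2_new <- w2
    # per edge solve x from r = x / sqrt(var_m1 * (base_p + x))
    for (j in seq_along(w2)) {
      a <- r[j]^2 * var_m1
      w2_new[j] <- (a + sqrt(a^2 + 4 * a * base_p[j])) / 2
    }
    w2_new <- 0.5 * w2 + 0.5 * w2_new
    if (max(abs(w2_new - w2)) < 1e-12) { w2 <- w2_new; break }
    w2 <- w2_new
  }
  list(m1 = sqrt(w2), partner = sgn * sqrt(w2))
}
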