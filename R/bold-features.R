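#' @title BOLD-derived features
#' @description Simplified task GLM and engram-conjunction ROI definition,
#'   integrated local correlation (ILC) maps, multivoxel local correlation
#'   (MVLC) reactivation patterns and their task-rest similarity, and
#'   ROI-to-ROI functional connectivity.
#' @name bold_features
NULL

#' Construct a BOLD run object
#'
#' @param data 4D numeric array (x, y, z, t) of intensities.
#' @param tr repetition time in seconds.
#' @param condition label such as "task", "pre_rest", "post_rest".
#' @param voxel_size isotropic voxel size in mm.
#' @return object of class \code{bold_run}.
#' @export
bold_run <- function(data, tr, condition = "rest", voxel_size = 1.6) {
  stopifnot(is.array(data), length(dim(data)) == 4)
  if (dim(data)[4] < 20) stop("a BOLD run needs at least 20 volumes")
  if (!all(is.finite(data))) stop("BOLD data must be finite")
  if (voxel_size <= 0 || tr <= 0) stop("tr and voxel_size must be positive")
  structure(list(data = data, tr = tr, condition = condition,
                 voxel_size = voxel_size), class = "bold_run")
}

#' Construct an ROI mask on a run's grid
#'
#' @param mask logical or 0/1 3D array.
#' @param name ROI name (e.g. "M1_engram", "putamen_R", "PCC").
#' @return object of class \code{roi_mask}.
#' @export
roi_mask <- function(mask, name = "roi") {
  stopifnot(is.array(mask), length(dim(mask)) == 3)
  structure(list(mask = array(as.logical(mask), dim(mask)), name = name),
            class = "roi_mask")
}

#' Canonical double-gamma hemodynamic response function
#'
#' SPM-style double gamma: response peak at 6 s, undershoot peak at 16 s,
#' undershoot ratio 1/6, unit peak scaling not applied (the GLM absorbs
#' amplitude).
#'
#' @param t time in seconds (vector).
#' @return HRF values.
#' @export
double_gamma_hrf <- function(t) {
  h <- stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
  h[t < 0] <- 0
  h
}

# convolve a stimulus vector (per TR) with the HRF sampled at the TR;
# the tr factor keeps the convolution a Riemann sum of the continuous
# convolution, so regressor amplitude is TR-invariant
.convolve_hrf <- function(stim, tr) {
  hk <- double_gamma_hrf(seq(0, 32, by = tr)) * tr
  n <- length(stim)
  full <- stats::convolve(stim, rev(hk), type = "open")
  full[seq_len(n)]
}

#' Build a task GLM design matrix
#'
#' Boxcar regressors (one per onset set) convolved with the canonical
#' double-gamma HRF, a temporal-derivative regressor of the combined task
#' time course, an intercept and a linear drift.
#'
#' @param n_vol number of volumes.
#' @param tr repetition time (s).
#' @param onsets named list of onset vectors (seconds), one element per
#'   task regressor (e.g. \code{list(early = ..., late = ...)}).
#' @param durations block durations in seconds; scalar or per regressor.
#' @return design matrix with named columns.
#' @export
glm_design <- function(n_vol, tr, onsets, durations) {
  if (is.null(names(onsets))) names(onsets) <- paste0("task", seq_along(onsets))
  durations <- rep(durations, length.out = length(onsets))
  times <- (seq_len(n_vol) - 1) * tr
  cols <- list()
  combined <- numeric(n_vol)
  for (i in seq_along(onsets)) {
    stim <- numeric(n_vol)
    for (on in onsets[[i]]) {
      if (on < 0 || on >= n_vol * tr) stop("onset outside run: ", on)
      stim[times >= on & times < on + durations[i]] <- 1
    }
    reg <- .convolve_hrf(stim, tr)
    cols[[names(onsets)[i]]] <- reg
    combined <- combined + reg
  }
  cols[["temporal_derivative"]] <- c(0, diff(combined))
  cols[["intercept"]] <- rep(1, n_vol)
  cols[["drift"]] <- seq_len(n_vol) / n_vol - 0.5
  do.call(cbind, cols)
}

#' Voxelwise task GLM z-statistic maps
#'
#' Ordinary least squares fit of each voxel's time course on the design
#' from \code{\link{glm_design}}; returns one z map per task regressor
#' (t statistics mapped through the t CDF to standard normal quantiles).
#' Voxels with zero residual variance get z = 0.
#'
#' @param run a \code{bold_run}.
#' @param block_onsets named list of onset vectors in seconds.
#' @param durations block durations in seconds.
#' @return named list: \code{z} (list of 3D z arrays, one per task
#'   regressor), \code{beta} (list of 3D effect-size arrays),
#'   \code{design}.
#' @export
glm_activation <- function(run, block_onsets, durations) {
  stopifnot(inherits(run, "bold_run"))
  dims <- dim(run$data)
  n_vol <- dims[4]
  X <- glm_design(n_vol, run$tr, block_onsets, durations)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop("rank-deficient design; collinear columns: ", paste(bad, collapse = ", "))
  }
  Y <- matrix(run$data, prod(dims[1:3]), n_vol)  # voxels x time
  XtXi <- chol2inv(chol(crossprod(X)))
  B <- Y %*% X %*% XtXi                          # voxels x p
  E <- Y - B %*% t(X)
  dfres <- n_vol - ncol(X)
  s2 <- rowSums(E^2) / dfres
  task_cols <- which(!colnames(X) %in% c("temporal_derivative", "intercept", "drift"))
  zmaps <- list(); betas <- list()
  for (j in task_cols) {
    se <- sqrt(s2 * XtXi[j, j])
    tval <- ifelse(se > 0, B[, j] / se, 0)
    z <- sign(tval) * stats::qnorm(
      stats::pt(abs(tval), dfres, lower.tail = FALSE, log.p = TRUE),
      lower.tail = FALSE, log.p = TRUE)
    z[!is.finite(z)] <- 0
    zmaps[[colnames(X)[j]]] <- array(z, dims[1:3])
    betas[[colnames(X)[j]]] <- array(B[, j], dims[1:3])
  }
  list(z = zmaps, beta = betas, design = X, df = dfres)
}

# 26-connectivity connected components by flood fill over mask voxels
.connected_components <- function(mask) {
  dims <- dim(mask)
  lab <- array(0L, dims)
  idx <- which(mask)
  if (!length(idx)) return(lab)
  coord <- arrayInd(idx, dims)
  key <- (coord[, 3] - 1L) * dims[1] * dims[2] + (coord[, 2] - 1L) * dims[1] + coord[, 1]
  inmask <- logical(prod(dims)); inmask[key] <- TRUE
  nb <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nb <- nb[rowSums(abs(nb)) > 0, ]
  cur <- 0L
  for (i in seq_along(idx)) {
    if (lab[idx[i]] != 0L) next
    cur <- cur + 1L
    queue <- idx[i]
    lab[idx[i]] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      co <- arrayInd(v, dims)
      for (k in seq_len(nrow(nb))) {
        cc <- co + nb[k, ]
        if (any(cc < 1L) || any(cc > dims)) next
        vi <- cc[1] + (cc[2] - 1L) * dims[1] + (cc[3] - 1L) * dims[1] * dims[2]
        if (inmask[vi] && lab[vi] == 0L) {
          lab[vi] <- cur
          queue <- c(queue, vi)
        }
      }
    }
  }
  lab
}

#' Engram-conjunction ROI from two activation maps
#'
#' Voxels significantly active (z above threshold) in both maps -- e.g.
#' the last practice block of day 1 and the day-2 test block -- with
#' connected components (26-connectivity) smaller than \code{min_cluster}
#' removed, optionally intersected with an anatomical mask first.
#'
#' @param zmap_day1_last,zmap_day2_test 3D z arrays on the same grid.
#' @param z_threshold voxelwise threshold (default 3.1).
#' @param min_cluster minimum cluster size in voxels (default 1 = keep all).
#' @param anatomical_mask optional logical 3D array intersected with both
#'   maps' suprathreshold sets.
#' @return a \code{roi_mask} named "M1_engram".
#' @export
conjunction_roi <- function(zmap_day1_last, zmap_day2_test, z_threshold = 3.1,
                            min_cluster = 1, anatomical_mask = NULL) {
  stopifnot(all(dim(zmap_day1_last) == dim(zmap_day2_test)))
  m <- zmap_day1_last > z_threshold & zmap_day2_test > z_threshold
  if (!is.null(anatomical_mask)) m <- m & anatomical_mask
  if (!any(m)) {
    stop(sprintf(
      "empty conjunction: %d voxels above z=%.2f in map 1, %d in map 2, overlap 0",
      sum(zmap_day1_last > z_threshold), z_threshold,
      sum(zmap_day2_test > z_threshold)))
  }
  if (min_cluster > 1) {
    lab <- .connected_components(m)
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= min_cluster)
    m <- array(lab %in% keep, dim(m))
    if (!any(m)) stop("empty conjunction after minimum-cluster filtering")
  }
  roi_mask(m, "M1_engram")
}

# neighbor offsets and Gaussian weights for the ILC kernel
.ilc_offsets <- function(kernel_mm, voxel_size) {
  reach <- max(1L, floor(3 * kernel_mm / voxel_size))
  g <- expand.grid(dx = -reach:reach, dy = -reach:reach, dz = -reach:reach)
  d <- sqrt(rowSums(g^2)) * voxel_size
  keep <- d > 0 & d <= 3 * kernel_mm
  g <- g[keep, , drop = FALSE]
  list(offsets = as.matrix(g), w = exp(-d[keep]^2 / (2 * kernel_mm^2)))
}

#' Integrated local correlation (ILC) map
#'
#' For each voxel, the Gaussian-weighted average Pearson correlation of
#' its time course with the time courses of neighboring voxels: weights
#' \code{exp(-d^2 / (2 kernel_mm^2))} over neighbors within three kernel
#' widths (distances in mm via the voxel size), self-correlation excluded,
#' normalized by the available weight mass (edge voxels simply have fewer
#' neighbors). Zero-variance voxels contribute correlation 0 to their
#' neighbors and receive ILC 0.
#'
#' With a 1 mm kernel and 1.6 mm voxels the truncated support is exactly
#' the 26-neighborhood, i.e. each voxel's directly surrounding voxels.
#'
#' @param run a \code{bold_run}.
#' @param kernel_mm Gaussian kernel width in mm (default 1).
#' @param roi optional \code{roi_mask}; if given, ILC is evaluated only at
#'   ROI voxels (their neighbors may lie outside the ROI), and non-ROI
#'   entries of the returned map are NA.
#' @return 3D array of ILC values.
#' @export
compute_ilc <- function(run, kernel_mm = 1, roi = NULL) {
  stopifnot(inherits(run, "bold_run"))
  if (kernel_mm <= 0) stop("kernel_mm must be positive")
  dims <- dim(run$data)
  nv <- prod(dims[1:3]); nt <- dims[4]
  Y <- matrix(run$data, nv, nt)
  Yc <- Y - rowMeans(Y)
  nrm <- sqrt(rowSums(Yc^2))
  flat <- nrm == 0
  if (any(flat)) {
    message(sum(flat), " zero-variance voxel(s): pairwise correlations set to 0")
    nrm[flat] <- 1
  }
  Z <- Yc / nrm  # unit-norm rows; corr(u,v) = sum_t Z_u Z_v

  ks <- .ilc_offsets(kernel_mm, run$voxel_size)
  co <- arrayInd(seq_len(nv), dims[1:3])
  if (!is.null(roi)) {
    stopifnot(inherits(roi, "roi_mask"), all(dim(roi$mask) == dims[1:3]))
    at <- which(roi$mask)
  } else {
    at <- seq_len(nv)
  }
  num <- numeric(length(at))
  den <- numeric(length(at))
  cat_at <- co[at, , drop = FALSE]
  for (k in seq_len(nrow(ks$offsets))) {
    off <- ks$offsets[k, ]
    nbc <- sweep(cat_at, 2, off, `+`)
    ok <- nbc[, 1] >= 1 & nbc[, 1] <= dims[1] &
      nbc[, 2] >= 1 & nbc[, 2] <= dims[2] &
      nbc[, 3] >= 1 & nbc[, 3] <= dims[3]
    if (!any(ok)) next
    nbi <- nbc[ok, 1] + (nbc[ok, 2] - 1L) * dims[1] +
      (nbc[ok, 3] - 1L) * dims[1] * dims[2]
    cc <- rowSums(Z[at[ok], , drop = FALSE] * Z[nbi, , drop = FALSE])
    num[ok] <- num[ok] + ks$w[k] * cc
    den[ok] <- den[ok] + ks$w[k]
  }
  val <- ifelse(den > 0, num / den, 0)
  val[flat[at]] <- 0
  out <- array(NA_real_, dims[1:3])
  out[at] <- val
  out
}

#' MVLC pattern: Fisher-z ILC values over ROI voxels
#'
#' Extracts the ILC values at the ROI voxels in a canonical, reproducible
#' ordering (ascending linear array index, shared across conditions by
#' construction) and Fisher z-transforms them. ILC values at or beyond
#' |1| are clipped to 1 - 1e-6 in magnitude with a warning.
#'
#' @param ilc_map 3D ILC array.
#' @param roi a \code{roi_mask} with at least 10 voxels.
#' @return numeric vector (class \code{mvlc_pattern}) with attribute
#'   \code{voxels} giving the linear indices.
#' @export
mvlc_pattern <- function(ilc_map, roi) {
  stopifnot(inherits(roi, "roi_mask"), all(dim(roi$mask) == dim(ilc_map)))
  idx <- which(roi$mask)  # ascending linear index = canonical ordering
  if (length(idx) < 10) stop("ROI has fewer than 10 voxels; pattern unreliable")
  v <- ilc_map[idx]
  if (any(!is.finite(v))) stop("ROI contains voxels with no ILC value")
  if (any(abs(v) >= 1)) {
    warning("ILC magnitude >= 1 at ", sum(abs(v) >= 1), " voxel(s); clipping")
    v <- pmax(pmin(v, 1 - 1e-6), -(1 - 1e-6))
  }
  structure(atanh(v), voxels = idx, class = "mvlc_pattern")
}

#' Task-rest MVLC pattern similarity difference
#'
#' Pearson-correlates the task pattern with the pre-rest and post-rest
#' patterns (element i of every vector is the same ROI voxel) and returns
#' the reactivation index r(task, post) - r(task, pre).
#'
#' @param task_pattern,pre_pattern,post_pattern numeric vectors of equal
#'   length (typically \code{mvlc_pattern} objects from the same ROI).
#' @return list with \code{r_task_pre}, \code{r_task_post},
#'   \code{similarity_difference}.
#' @export
similarity_difference <- function(task_pattern, pre_pattern, post_pattern) {
  n <- length(task_pattern)
  if (length(pre_pattern) != n || length(post_pattern) != n) {
    stop("pattern vectors must have equal length")
  }
  sds <- c(stats::sd(task_pattern), stats::sd(pre_pattern), stats::sd(post_pattern))
  if (any(sds == 0)) stop("constant pattern: similarity undefined")
  r_pre <- stats::cor(task_pattern, pre_pattern)
  r_post <- stats::cor(task_pattern, post_pattern)
  list(r_task_pre = r_pre, r_task_post = r_post,
       similarity_difference = r_post - r_pre)
}

#' ROI-to-ROI functional connectivity (Fisher z)
#'
#' Correlates the ROI-averaged time courses of two regions and Fisher
#' z-transforms the result.
#'
#' @param run a \code{bold_run}.
#' @param roi_a,roi_b \code{roi_mask} objects on the run's grid; must not
#'   be identical (r = 1 is degenerate under atanh).
#' @return Fisher-z connectivity (scalar).
#' @export
roi_to_roi_fc <- function(run, roi_a, roi_b) {
  stopifnot(inherits(run, "bold_run"),
            inherits(roi_a, "roi_mask"), inherits(roi_b, "roi_mask"))
  dims <- dim(run$data)
  if (!any(roi_a$mask) || !any(roi_b$mask)) stop("both ROIs must be nonempty")
  if (identical(roi_a$mask, roi_b$mask)) {
    stop("identical ROIs give r = 1 (infinite z); use disjoint ROIs")
  }
  Y <- matrix(run$data, prod(dims[1:3]), dims[4])
  ta <- colMeans(Y[which(roi_a$mask), , drop = FALSE])
  tb <- colMeans(Y[which(roi_b$mask), , drop = FALSE])
  if (stats::sd(ta) == 0 || stats::sd(tb) == 0) {
    stop("constant ROI-mean time course; connectivity undefined")
  }
  r <- stats::cor(ta, tb)
  if (abs(r) >= 1) stop("degenerate |r| = 1 between ROI time courses")
  atanh(r)
}

#' Functional connectivity change
#'
#' @param post_z,pre_z Fisher-z connectivity values.
#' @return \code{post_z - pre_z}.
#' @export
fc_change <- function(post_z, pre_z) post_z - pre_z
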