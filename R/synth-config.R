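#' @title Synthetic cohort configuration
#' @description Configuration objects for the seeded synthetic two-day
#'   motor-learning cohort: cohort dimensions and the planted effect
#'   structure, plus the internal linear-latent calibration that maps
#'   planted population correlations onto generative coefficients.
#' @name synth_config
NULL

#' Cohort configuration
#'
#' Dimensions and acquisition parameters of the simulated cohort. Defaults
#' mirror the study design being emulated: 36 learning and 21 control
#' subjects, six MRS time points (baseline, four post scans across the
#' first ~30 minutes, and a day-2 baseline), 12 thirty-second practice
#' blocks plus a single day-2 test block, and resting BOLD runs. The BOLD
#' grid and run length default to a scaled-down 16^3 grid with 120 rest
#' volumes so a full cohort stays cheap; the acquisition-scale value (420
#' volumes) can be requested explicitly.
#'
#' @param n_learning,n_control group sizes (each >= 4).
#' @param n_post_scans number of post-learning MRS scans (default 4).
#' @param n_blocks_day1 practice blocks on day 1 (default 12).
#' @param block_duration block length in seconds (default 30; fixation
#'   blocks of equal length separate practice blocks).
#' @param tr BOLD repetition time in seconds.
#' @param grid_shape BOLD grid (3 integers).
#' @param voxel_size isotropic voxel size in mm.
#' @param n_volumes_rest volumes per resting run.
#' @param master_seed integer master seed; every subject receives an
#'   independent substream derived from it.
#' @return validated list of class \code{cohort_config}.
#' @export
cohort_config <- function(n_learning = 36, n_control = 21, n_post_scans = 4,
                          n_blocks_day1 = 12, block_duration = 30, tr = 1,
                          grid_shape = c(16, 16, 16), voxel_size = 1.6,
                          n_volumes_rest = 120, master_seed = 1) {
  cfg <- list(n_learning = as.integer(n_learning),
              n_control = as.integer(n_control),
              n_post_scans = as.integer(n_post_scans),
              n_blocks_day1 = as.integer(n_blocks_day1),
              block_duration = block_duration, tr = tr,
              grid_shape = as.integer(grid_shape), voxel_size = voxel_size,
              n_volumes_rest = as.integer(n_volumes_rest),
              master_seed = as.integer(master_seed))
  counts <- c(cfg$n_learning, cfg$n_control, cfg$n_post_scans,
              cfg$n_blocks_day1, cfg$n_volumes_rest)
  if (any(counts < 1)) stop("invalid config: all counts must be >= 1")
  if (cfg$n_learning < 4 || cfg$n_control < 4) {
    stop("invalid config: group sizes must be >= 4")
  }
  if (cfg$voxel_size <= 0 || cfg$tr <= 0 || cfg$block_duration <= 0) {
    stop("invalid config: voxel_size, tr and block_duration must be positive")
  }
  if (length(cfg$grid_shape) != 3 || any(cfg$grid_shape < 8)) {
    stop("invalid config: grid_shape must be 3 integers >= 8")
  }
  # derived run lengths (task blocks alternate with equal fixation blocks)
  cfg$n_volumes_task <- as.integer(round(2 * cfg$n_blocks_day1 *
                                           cfg$block_duration / cfg$tr))
  cfg$n_volumes_task_day2 <- as.integer(round((cfg$block_duration + 30) / cfg$tr))
  class(cfg) <- "cohort_config"
  cfg
}

.MET_DEFAULT <- list(
  mean = c(Glu = 9.5, GABA = 2.0, NAA = 13.5, Gln = 3.2, Cr = 8.0),
  sd = c(Glu = 0.8, GABA = 0.35, NAA = 1.0, Gln = 0.45, Cr = 0.55),
  scan_sd = c(Glu = 0.25, GABA = 0.12, NAA = 0.30, Gln = 0.25, Cr = 0.18),
  crlb = c(Glu = 3, GABA = 8, NAA = 1.5, Gln = 9, Cr = 2)
)

#' Planted effect structure
#'
#' The statistical structure written into the synthetic cohort. Defaults
#' are the study conditions the package emulates: a weak baseline
#' excitation-inhibition coupling (r = 0.18) that strengthens to r = 0.58
#' over the post-learning period in the learning group only; strongly
#' baseline-dependent GABA changes and (learning group only) moderately
#' baseline-dependent Glu changes; a mean overnight gain of 10.46% with
#' between-subject SD chosen to match its reported standard error; a
#' partial correlation of 0.45 between averaged Glu change and overnight
#' gain given GABA change; a correlation of -0.48 between the 30-min GABA
#' change and overnight M1 gray-matter change; and latent correlations of
#' 0.45 between Glu change and both overnight M1-right-putamen
#' connectivity change and reactivation pattern fidelity (realized
#' subject-level correlations are somewhat lower once BOLD sampling noise
#' is added, in line with the effect sizes the design assumes).
#'
#' All cross-subject targets are planted on the measurement scale: an
#' internal linear-latent calibration (see \code{calibrate_effects})
#' solves for generative coefficients such that the population correlation
#' of the simulated *measured* quantities (including scan-to-scan noise)
#' equals the planted value.
#'
#' @param ... named overrides of any default field (see
#'   \code{str(effect_spec())}).
#' @return validated list of class \code{effect_spec}.
#' @export
effect_spec <- function(...) {
  spec <- list(
    baseline_mean = .MET_DEFAULT$mean,
    baseline_sd = .MET_DEFAULT$sd,
    scan_noise_sd = .MET_DEFAULT$scan_sd,
    crlb_mean = .MET_DEFAULT$crlb,
    # regression to the mean: delta = slope * (baseline - mu) + response + noise
    regression_to_mean_slope = list(
      Learning = c(Glu = -0.50, GABA = -0.85, NAA = -0.35, Gln = -0.35, Cr = -0.20),
      Control  = c(Glu = -0.15, GABA = -0.85, NAA = -0.35, Gln = -0.35, Cr = -0.20)),
    delta_noise_sd = list(
      Learning = c(Glu = 0.72, GABA = 0.30, NAA = 0.35, Gln = 0.30, Cr = 0.15),
      Control  = c(Glu = 0.64, GABA = 0.30, NAA = 0.35, Gln = 0.30, Cr = 0.15)),
    group_response = list(  # mean shift of all post scans, mM
      Learning = c(Glu = 0.15, GABA = 0.00, NAA = 0.0, Gln = 0.0, Cr = 0.0),
      Control  = c(Glu = 0.20, GABA = 0.00, NAA = 0.0, Gln = 0.0, Cr = 0.0)),
    day2_retest_r = 0.5,
    coupling_r_pre = 0.18,
    coupling_r_post = 0.58,           # learning group
    coupling_r_post_control = 0.18,
    glu_gain_partial_r = 0.45,
    gaba_gain_partial_r = 0.15,
    overnight_gain_mean = 10.46,      # percent
    overnight_gain_sd = 10.8,         # percent, between subjects
    day1_gain_r = -0.30,              # higher day-1 score -> smaller gain
    gaba_gm_r = -0.48,                # measured 30-min GABA change vs M1 dGM
    glu_fc_overnight_r = 0.55,        # latent: Glu change vs overnight M1-putR dz
    glu_reactivation_r = 0.45,        # latent: Glu change vs reactivation fidelity
    reactivation_fidelity = 0.20,     # base mixing weight of the task pattern
    reactivation_fidelity_spread = 0.20,
    fc_z_pre_mean = 0.30, fc_z_pre_sd = 0.15,
    fc_overnight_sd = 0.45, fc_short_sd = 0.20,
    # behavior
    plateau_mean = 20, plateau_sd = 4,
    early_fraction = c(0.45, 0.80, 0.99),  # of plateau, blocks before changepoint
    changepoint_block = 4,
    block_noise_sd = 2.5, block_noise_ar1 = 0.65,
    keypress_error_rate = 0.04,       # doubled-press insertions per press
    # gray matter (modulated GM units)
    gm_mean = c(M1 = 0.65, PCC = 0.60), gm_sd = 0.05, gm_change_sd = 0.012,
    # tissue fractions and QC
    tissue_fraction_mean = c(gm = 0.55, wm = 0.40, csf = 0.05),
    tissue_fraction_sd = 0.02,
    snr_mean = 55, snr_sd = 8,
    linewidth_mean = 10.5, linewidth_sd = 1.2,
    qc_contamination_rate = 0.02,
    # BOLD
    bold_noise_sd = 1, ar1_coef = 0.3, bold_signal_sd = 0.8,
    activation_amplitude = 3.5
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(spec))
  if (length(unknown)) stop("unknown effect_spec fields: ",
                            paste(unknown, collapse = ", "))
  spec[names(dots)] <- dots
  rr <- c(spec$coupling_r_pre, spec$coupling_r_post,
          spec$coupling_r_post_control, spec$glu_gain_partial_r,
          spec$gaba_gain_partial_r, spec$gaba_gm_r, spec$glu_fc_overnight_r,
          spec$glu_reactivation_r, spec$day1_gain_r)
  if (any(abs(rr) >= 1)) stop("planted correlations must lie in (-1, 1)")
  if (spec$reactivation_fidelity < 0 || spec$reactivation_fidelity > 1) {
    stop("reactivation_fidelity must lie in [0, 1]")
  }
  sds <- c(spec$baseline_sd, spec$scan_noise_sd, spec$overnight_gain_sd,
           spec$block_noise_sd, spec$gm_sd, spec$gm_change_sd)
  if (any(sds <= 0)) stop("all standard deviations must be positive")
  if (spec$block_noise_ar1 < 0 || spec$block_noise_ar1 >= 1 ||
      spec$ar1_coef < 0 || spec$ar1_coef >= 1) {
    stop("AR(1) coefficients must lie in [0, 1)")
  }
  class(spec) <- "effect_spec"
  spec
}

#' Null effect structure
#'
#' An \code{effect_spec} with every planted cross-subject effect removed:
#' no baseline dependence of the changes, no coupling change, no
#' metabolite-behavior, metabolite-connectivity or metabolite-structure
#' correlations, and zero reactivation fidelity. Group mean responses are
#' equalized. Used for specificity and type-I-error studies.
#'
#' @param ... further overrides passed to \code{\link{effect_spec}}.
#' @export
null_effect_spec <- function(...) {
  zero <- c(Glu = 0, GABA = 0, NAA = 0, Gln = 0, Cr = 0)
  effect_spec(
    regression_to_mean_slope = list(Learning = zero, Control = zero),
    group_response = list(Learning = zero, Control = zero),
    coupling_r_post = 0.18, coupling_r_post_control = 0.18,
    glu_gain_partial_r = 0, gaba_gain_partial_r = 0, day1_gain_r = 0,
    gaba_gm_r = 0, glu_fc_overnight_r = 0, glu_reactivation_r = 0,
    reactivation_fidelity = 0, reactivation_fidelity_spread = 0,
    ...)
}

# ---------------------------------------------------------------------------
# Linear-latent calibration.
#
# Per subject, Glu and GABA are driven by independent standard-normal basis
# components: u1, u2 (baselines, correlated via coupling_r_pre), v1, v2
# (change-score noise, cross-correlated via kappa), scan noises m0..m4 /
# b0..b4 (Glu / GABA: baseline scan + n_post scans). Every observable is a
# linear combination of the basis, so every covariance is a dot product of
# coefficient vectors; the planted measured-scale correlations are solved
# for exactly on that algebra.

.lv <- function(...) {
  x <- c(...)
  x[x != 0]
}
.lv_dot <- function(a, b) {
  nm <- intersect(names(a), names(b))
  if (!length(nm)) return(0)
  sum(a[nm] * b[nm])
}
.lv_cor <- function(a, b) .lv_dot(a, b) / sqrt(.lv_dot(a, a) * .lv_dot(b, b))
.lv_add <- function(a, b) {
  nm <- union(names(a), names(b))
  out <- stats::setNames(numeric(length(nm)), nm)
  out[names(a)] <- out[names(a)] + a
  out[names(b)] <- out[names(b)] + b
  out
}

# coefficient vectors for one group's Glu/GABA observables, given kappa
.metab_coefs <- function(effects, group, kappa, n_post) {
  sG <- unname(effects$baseline_sd["Glu"]); sB <- unname(effects$baseline_sd["GABA"])
  slG <- unname(effects$regression_to_mean_slope[[group]]["Glu"])
  slB <- unname(effects$regression_to_mean_slope[[group]]["GABA"])
  eG <- unname(effects$delta_noise_sd[[group]]["Glu"])
  eB <- unname(effects$delta_noise_sd[[group]]["GABA"])
  nG <- unname(effects$scan_noise_sd["Glu"]); nB <- unname(effects$scan_noise_sd["GABA"])
  r0 <- effects$coupling_r_pre

  zG <- .lv(u1 = 1)
  zB <- .lv(u1 = r0, u2 = sqrt(1 - r0^2))
  preG <- sG * zG
  preB <- sB * zB
  dG <- .lv_add(slG * preG, .lv(v1 = eG))
  dB <- .lv_add(slB * preB, c(v1 = unname(eB * kappa),
                              v2 = unname(eB * sqrt(1 - kappa^2))))
  post_noise <- function(prefix, sd) {
    stats::setNames(rep(sd / n_post, n_post), paste0(prefix, seq_len(n_post)))
  }
  list(
    preG_true = preG, preB_true = preB, dG = dG, dB = dB,
    preG_meas = .lv_add(preG, .lv(m0 = nG)),
    preB_meas = .lv_add(preB, .lv(b0 = nB)),
    postG_avg_meas = .lv_add(.lv_add(preG, dG), post_noise("m", nG)),
    postB_avg_meas = .lv_add(.lv_add(preB, dB), post_noise("b", nB)),
    dG_avg_meas = .lv_add(dG, .lv_add(post_noise("m", nG), .lv(m0 = -nG))),
    dB_avg_meas = .lv_add(dB, .lv_add(post_noise("b", nB), .lv(b0 = -nB))),
    dG_imm_meas = .lv_add(dG, .lv(m1 = nG, m0 = -nG)),
    dB_30_meas = .lv_add(dB, stats::setNames(c(nB, -nB), c(paste0("b", n_post), "b0")))
  )
}

#' Calibrate generative coefficients from the planted effect structure
#'
#' Solves, on the exact covariance algebra of the generator's latent
#' model, for (i) the cross-correlation \code{kappa} between the Glu and
#' GABA change-score noises that realizes the planted post-period
#' coupling on the measured averaged post concentrations, (ii) the gain
#' loadings on the standardized true Glu and GABA changes that realize the
#' planted measured-scale partial correlations with overnight gain, and
#' (iii) the loadings that realize the GABA/gray-matter and
#' Glu/connectivity targets. Returns a list keyed by group. Mostly
#' internal, exported for inspection and testing.
#'
#' @param effects an \code{effect_spec}.
#' @param n_post number of post-learning MRS scans.
#' @return list with per-group calibration constants.
#' @export
calibrate_effects <- function(effects, n_post = 4) {
  key <- paste(n_post, paste(unlist(effects), collapse = ","), sep = "|")
  hit <- .calibration_cache[[key]]
  if (!is.null(hit)) return(hit)
  cal <- list()
  for (group in c("Learning", "Control")) {
    target_post <- if (group == "Learning") effects$coupling_r_post else
      effects$coupling_r_post_control
    f_kappa <- function(k) {
      cf <- .metab_coefs(effects, group, k, n_post)
      .lv_cor(cf$postG_avg_meas, cf$postB_avg_meas) - target_post
    }
    lo <- f_kappa(-0.995); hi <- f_kappa(0.995)
    kappa <- if (lo * hi > 0) {
      warning("post coupling target unattainable for ", group,
              "; using closest achievable")
      if (abs(lo) < abs(hi)) -0.995 else 0.995
    } else stats::uniroot(f_kappa, c(-0.995, 0.995), tol = 1e-10)$root
    cf <- .metab_coefs(effects, group, kappa, n_post)

    sd_dG <- sqrt(.lv_dot(cf$dG, cf$dG))
    sd_dB <- sqrt(.lv_dot(cf$dB, cf$dB))
    dG_std <- if (sd_dG > 0) cf$dG / sd_dG else cf$dG
    dB_std <- if (sd_dB > 0) cf$dB / sd_dB else cf$dB
    rho_d <- if (sd_dG > 0 && sd_dB > 0) .lv_dot(dG_std, dB_std) else 0

    # gain loadings: gain_std = a*dG_std + b*dB_std + c*geps (learning only)
    ab <- c(0, 0)
    if (group == "Learning" &&
        (effects$glu_gain_partial_r != 0 || effects$gaba_gain_partial_r != 0) &&
        sd_dG > 0 && sd_dB > 0) {
      obj <- function(par) {
        a <- par[1]; b <- par[2]
        c2 <- 1 - (a^2 + b^2 + 2 * a * b * rho_d)
        if (c2 <= 1e-6) return(1e6)
        gain <- .lv_add(.lv_add(a * dG_std, b * dB_std), .lv(geps = sqrt(c2)))
        pr <- function(x, y, z) {
          rxy <- .lv_cor(x, y); rxz <- .lv_cor(x, z); ryz <- .lv_cor(y, z)
          (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
        }
        (pr(cf$dG_avg_meas, gain, cf$dB_avg_meas) - effects$glu_gain_partial_r)^2 +
          (pr(cf$dB_avg_meas, gain, cf$dG_avg_meas) - effects$gaba_gain_partial_r)^2
      }
      fit <- stats::optim(c(effects$glu_gain_partial_r,
                            effects$gaba_gain_partial_r), obj,
                          method = "Nelder-Mead",
                          control = list(reltol = 1e-14, maxit = 2000))
      if (fit$value > 1e-8) {
        warning("gain partial-correlation targets only approximately met (",
                group, ")")
      }
      ab <- fit$par
    }
    gain_c <- sqrt(max(0, 1 - (ab[1]^2 + ab[2]^2 + 2 * ab[1] * ab[2] * rho_d)))

    # gray-matter loading: dGM_std = g*dB_std + sqrt(1-g^2)*eps,
    # targeting corr(measured 30-min GABA change, dGM) = gaba_gm_r
    alpha_b <- if (sd_dB > 0) .lv_cor(cf$dB_30_meas, dB_std) else 0
    g_gm <- if (group == "Learning" && alpha_b != 0 && effects$gaba_gm_r != 0) {
      max(min(effects$gaba_gm_r / alpha_b, 0.99), -0.99)
    } else 0

    # connectivity / reactivation loading on dG via measured immediate change
    alpha_g <- if (sd_dG > 0) .lv_cor(cf$dG_imm_meas, dG_std) else 0
    q_fc <- if (group == "Learning" && alpha_g != 0 &&
                effects$glu_fc_overnight_r != 0) {
      max(min(effects$glu_fc_overnight_r / alpha_g, 0.99), -0.99)
    } else 0
    q_react <- if (group == "Learning" && alpha_g != 0 &&
                   effects$glu_reactivation_r != 0) {
      max(min(effects$glu_reactivation_r / alpha_g, 0.99), -0.99)
    } else 0

    cal[[group]] <- list(kappa = kappa, coefs = cf,
                         sd_dG = sd_dG, sd_dB = sd_dB, rho_d = rho_d,
                         gain_a = ab[1], gain_b = ab[2], gain_c = gain_c,
                         g_gm = g_gm, q_fc = q_fc, q_react = q_react)
  }
  .calibration_cache[[key]] <- cal
  cal
}

# solved calibrations are deterministic in (effects, n_post); cache them
.calibration_cache <- new.env(parent = emptyenv())
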