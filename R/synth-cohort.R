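#' @title Synthetic cohort generation
#' @description Seeded generation of the two-day cohort: subject roster,
#'   metabolite panel with QC columns, key-press behavior streams,
#'   gray-matter volume tables. All cross-subject structure is planted via
#'   the calibrated latent model in \code{\link{calibrate_effects}}.
#' @name synth_cohort
NULL

.subject_stage_seed <- function(subject_seed, stage) {
  (subject_seed + 7919L * stage) %% (2147483647L - 1L) + 1L
}

#' Generate the subject roster
#'
#' @param config a \code{\link{cohort_config}}.
#' @return data.frame with \code{subject_id}, \code{group},
#'   \code{subject_seed} (independent per-subject substream derived from
#'   the master seed). Deterministic: the same config yields a
#'   byte-identical roster.
#' @export
make_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_learning + config$n_control
  set.seed(config$master_seed)
  data.frame(
    subject_id = sprintf("sub-%02d", seq_len(n)),
    group = rep(c("Learning", "Control"), c(config$n_learning, config$n_control)),
    subject_seed = sample.int(2147483647L - 10L, n),
    stringsAsFactors = FALSE
  )
}

# draw the per-subject latent basis used by the calibrated metabolite model
.BASIS <- c("u1", "u2", "v1", "v2", "geps", "gmeps", "fceps", "reps",
            "d2G", "d2B", "m5", "b5")

.draw_basis <- function(n_post) {
  nm <- c(.BASIS, paste0("m", 0:n_post), paste0("b", 0:n_post))
  stats::setNames(stats::rnorm(length(nm)), nm)
}

.lv_eval <- function(coef, basis) sum(coef * basis[names(coef)])

#' Simulate the metabolite panel
#'
#' One row per subject x 6 time points x metabolite {Glu, GABA, NAA, Gln,
#' Cr}. Change scores follow \code{delta = slope * (baseline - mu) + group
#' response + noise} with negative slope (regression to the mean); the Glu
#' and GABA change noises are cross-correlated so that the measured
#' averaged post-period concentrations realize the planted coupling. QC
#' columns (CRLB, SNR, linewidth) are drawn with a configurable
#' contamination rate; contaminated rows receive a failing linewidth, a
#' failing SNR, or a 5-SD concentration excursion.
#'
#' The returned panel carries a \code{latents} attribute (per-subject
#' standardized true change scores and the calibration) consumed by the
#' downstream generators so that behavioral, structural and functional
#' effects are planted against the same subject-level responses.
#'
#' @param roster from \code{\link{make_cohort}}.
#' @param effects an \code{\link{effect_spec}}.
#' @param config a \code{\link{cohort_config}}.
#' @return long data.frame (see \code{\link{qc_flags}} for the schema).
#' @export
simulate_metabolites <- function(roster, effects = effect_spec(),
                                 config = cohort_config()) {
  stopifnot(nrow(roster) > 0)
  n_post <- config$n_post_scans
  cal <- calibrate_effects(effects, n_post)
  mets <- .METABOLITES
  tps <- c("pre", paste0("post", round((seq_len(n_post) - 1) *
                                         30 / max(1, n_post - 1))), "day2")
  rows <- vector("list", nrow(roster))
  lat <- vector("list", nrow(roster))

  for (i in seq_len(nrow(roster))) {
    grp <- roster$group[i]
    set.seed(.subject_stage_seed(roster$subject_seed[i], 0L))
    basis <- .draw_basis(n_post)
    cf <- cal[[grp]]$coefs

    # tissue fractions, one draw per day
    frac <- function() {
      f <- abs(stats::rnorm(3, effects$tissue_fraction_mean,
                            effects$tissue_fraction_sd))
      f / sum(f)
    }
    f_day1 <- frac(); f_day2 <- frac()

    true_pre <- true_delta <- true_day2 <- numeric(length(mets))
    names(true_pre) <- names(true_delta) <- names(true_day2) <- mets
    for (met in mets) {
      mu <- effects$baseline_mean[met]; sd0 <- effects$baseline_sd[met]
      slope <- effects$regression_to_mean_slope[[grp]][met]
      resp <- effects$group_response[[grp]][met]
      dnoise <- effects$delta_noise_sd[[grp]][met]
      if (met == "Glu") {
        z_pre <- .lv_eval(cf$preG_true, basis) / sd0
        dd <- .lv_eval(cf$dG, basis)
        z2 <- basis["d2G"]
      } else if (met == "GABA") {
        z_pre <- .lv_eval(cf$preB_true, basis) / sd0
        dd <- .lv_eval(cf$dB, basis)
        z2 <- basis["d2B"]
      } else {
        z_pre <- stats::rnorm(1)
        dd <- slope * sd0 * z_pre + stats::rnorm(1, 0, dnoise)
        z2 <- stats::rnorm(1)
      }
      true_pre[met] <- mu + sd0 * z_pre
      true_delta[met] <- dd + resp
      r2 <- effects$day2_retest_r
      true_day2[met] <- mu + sd0 * (r2 * z_pre + sqrt(1 - r2^2) * z2)
    }

    # scan-level measurements; Glu/GABA reuse the basis scan noises so the
    # calibrated measured-scale covariances hold exactly (plain numeric
    # vectors here, one data.frame assembly at the end)
    ntp <- n_post + 2L
    conc <- crlb <- numeric(length(mets) * ntp)
    for (k in seq_along(mets)) {
      met <- mets[k]
      sn <- effects$scan_noise_sd[met]
      nois <- switch(met,
                     Glu = basis[c(paste0("m", 0:n_post), "m5")] * sn,
                     GABA = basis[c(paste0("b", 0:n_post), "b5")] * sn,
                     stats::rnorm(ntp, 0, sn))
      at <- (k - 1L) * ntp + seq_len(ntp)
      conc[at] <- c(true_pre[met] + nois[1],
                    true_pre[met] + true_delta[met] + nois[2:(n_post + 1)],
                    true_day2[met] + nois[ntp])
      crlb[at] <- pmax(0.3, stats::rnorm(ntp, effects$crlb_mean[met],
                                         effects$crlb_mean[met] / 5))
    }
    fr <- rbind(matrix(f_day1, n_post + 1, 3, byrow = TRUE), f_day2)
    rows[[i]] <- list(
      subject_id = rep(roster$subject_id[i], length(conc)),
      group = rep(grp, length(conc)),
      timepoint = rep(tps, length(mets)),
      metabolite = rep(mets, each = ntp),
      conc_true = conc,
      crlb_pct = crlb,
      snr = stats::rnorm(length(conc), effects$snr_mean, effects$snr_sd),
      linewidth_hz = pmax(6, stats::rnorm(length(conc),
                                          effects$linewidth_mean,
                                          effects$linewidth_sd)),
      f_gm = rep(fr[, 1], length(mets)),
      f_wm = rep(fr[, 2], length(mets)),
      f_csf = rep(fr[, 3], length(mets))
    )

    lat[[i]] <- data.frame(
      subject_id = roster$subject_id[i], group = grp,
      dglu_std = if (cal[[grp]]$sd_dG > 0)
        .lv_eval(cf$dG, basis) / cal[[grp]]$sd_dG else 0,
      dgaba_std = if (cal[[grp]]$sd_dB > 0)
        .lv_eval(cf$dB, basis) / cal[[grp]]$sd_dB else 0,
      geps = unname(basis["geps"]), gmeps = unname(basis["gmeps"]),
      fceps = unname(basis["fceps"]), reps = unname(basis["reps"]),
      stringsAsFactors = FALSE
    )
  }
  panel <- as.data.frame(
    lapply(stats::setNames(names(rows[[1]]), names(rows[[1]])),
           function(col) unlist(lapply(rows, `[[`, col), use.names = FALSE)),
    stringsAsFactors = FALSE)

  # QC contamination (seeded off the master seed, after subject loops)
  set.seed(config$master_seed + 104729L)
  bad <- which(stats::runif(nrow(panel)) < effects$qc_contamination_rate)
  if (length(bad)) {
    kind <- sample(3, length(bad), replace = TRUE)
    panel$linewidth_hz[bad[kind == 1]] <-
      stats::runif(sum(kind == 1), 15.2, 19)
    panel$snr[bad[kind == 2]] <- stats::runif(sum(kind == 2), 15, 29)
    v <- bad[kind == 3]
    if (length(v)) {
      sds <- effects$baseline_sd[panel$metabolite[v]]
      panel$conc_true[v] <- panel$conc_true[v] +
        sample(c(-1, 1), length(v), replace = TRUE) * 5 * sds
    }
  }

  # emit the water-scaled (uncorrected) estimate: correcting it with the
  # row's tissue fractions recovers the concentration in mM
  panel$conc_mM <- panel$conc_true /
    tissue_correction_factor(panel$f_gm, panel$f_wm, panel$f_csf)
  panel$conc_true <- NULL
  attr(panel, "latents") <- do.call(rbind, lat)
  attr(panel, "calibration") <- cal
  panel
}

# AR(1) noise with unit-marginal-variance scaling, length n
.ar1_noise <- function(n, rho, sd) {
  if (rho == 0) return(stats::rnorm(n, 0, sd))
  as.numeric(stats::filter(stats::rnorm(n, 0, sd * sqrt(1 - rho^2)),
                           rho, method = "recursive",
                           init = stats::rnorm(1, 0, sd)))
}

# emit a key-press stream scoring exactly `count` under score_block:
# `count` contiguous copies of the target with doubled-press insertions at
# copy boundaries (a doubled symbol can never lie inside an occurrence of
# 4-1-3-2-4, which has no repeated adjacent keys) and an optional trailing
# partial prefix.
.encode_stream <- function(count, error_rate, target = .TARGET_SEQ) {
  copies <- rep(list(target), count)
  n_err <- stats::rpois(1, error_rate * 5 * count)
  gaps <- sample(count + 1L, n_err, replace = TRUE)
  pieces <- vector("list", count + 1L)
  for (g in seq_len(count + 1L)) {
    k <- sum(gaps == g)
    if (k > 0) {
      syms <- sample(4L, k, replace = TRUE)
      pieces[[g]] <- as.integer(rbind(syms, syms))  # doubled presses
    } else pieces[[g]] <- integer(0)
  }
  out <- integer(0)
  for (g in seq_len(count)) out <- c(out, pieces[[g]], target)
  out <- c(out, pieces[[count + 1L]])
  if (stats::runif(1) < 0.7) out <- c(out, target[seq_len(sample(4L, 1))])
  paste(out, collapse = "")
}

#' Simulate key-press behavior for the learning group
#'
#' Correct-sequence counts follow a saturating learning curve: a fast rise
#' over the blocks before the changepoint (fractions
#' \code{early_fraction} of the subject's plateau) and a flat plateau from
#' the changepoint block onward, perturbed by serially correlated
#' block-to-block noise (AR(1), reflecting slow attention/arousal
#' fluctuations). The day-2 test count applies the planted overnight gain
#' -- correlated with the subject's Glu change at the calibrated loading
#' and negatively with day-1 final performance -- and is rounded to an
#' integer count. Key-press streams decode to their intended counts under
#' \code{\link{score_block}} exactly (round-trip property).
#'
#' @param roster subject roster; only Learning-group rows are used.
#' @param effects an \code{\link{effect_spec}}.
#' @param config a \code{\link{cohort_config}}.
#' @param latents optional latents attribute from
#'   \code{\link{simulate_metabolites}} (if omitted, fresh independent
#'   latents are drawn, i.e. behavior uncoupled from metabolites).
#' @return data.frame with \code{subject_id}, \code{day}, \code{block},
#'   \code{keystream}, \code{n_correct} (intended count) and attribute
#'   \code{truth} (per-subject planted gain and partition).
#' @export
simulate_behavior <- function(roster, effects = effect_spec(),
                              config = cohort_config(), latents = NULL) {
  learners <- roster[roster$group == "Learning", , drop = FALSE]
  if (nrow(learners) == 0) stop("no Learning-group subjects in roster")
  nb <- config$n_blocks_day1
  cp <- effects$changepoint_block
  if (cp < 2 || cp > nb) stop("changepoint must lie in 2..n_blocks_day1")
  frac <- c(effects$early_fraction, rep(1, nb))[seq_len(nb)]
  frac[seq.int(cp, nb)] <- 1
  if (cp > 1 && length(effects$early_fraction) < cp - 1) {
    stop("early_fraction must cover blocks 1..(changepoint-1)")
  }
  cal <- calibrate_effects(effects, config$n_post_scans)$Learning

  rows <- list(); truth <- list()
  for (i in seq_len(nrow(learners))) {
    sid <- learners$subject_id[i]
    set.seed(.subject_stage_seed(learners$subject_seed[i], 1L))
    if (!is.null(latents)) {
      li <- latents[latents$subject_id == sid, ]
      dg <- li$dglu_std; db <- li$dgaba_std; ge <- li$geps
    } else {
      dg <- stats::rnorm(1); db <- stats::rnorm(1); ge <- stats::rnorm(1)
    }
    plateau <- max(6, stats::rnorm(1, effects$plateau_mean, effects$plateau_sd))
    noise <- .ar1_noise(nb, effects$block_noise_ar1, effects$block_noise_sd)
    counts <- pmax(1L, as.integer(round(plateau * frac + noise)))

    # day-1 dependence replaces part of the gain's independent noise, so
    # the calibrated partial correlations with the metabolite changes are
    # untouched (day-1 performance is independent of the latents)
    d1s <- (counts[nb] - effects$plateau_mean) /
      sqrt(effects$plateau_sd^2 + effects$block_noise_sd^2)
    r1 <- sign(effects$day1_gain_r) * min(abs(effects$day1_gain_r), cal$gain_c)
    c_eps <- sqrt(max(0, cal$gain_c^2 - r1^2))
    gain_std <- cal$gain_a * dg + cal$gain_b * db + r1 * d1s + c_eps * ge
    gain <- effects$overnight_gain_mean + effects$overnight_gain_sd * gain_std
    day2 <- max(1L, as.integer(round(counts[nb] * (1 + gain / 100))))

    all_counts <- c(counts, day2)
    streams <- vapply(all_counts, .encode_stream, character(1),
                      error_rate = effects$keypress_error_rate)
    rows[[i]] <- data.frame(
      subject_id = sid, day = c(rep(1L, nb), 2L), block = c(seq_len(nb), 1L),
      keystream = streams, n_correct = all_counts, stringsAsFactors = FALSE)
    truth[[i]] <- data.frame(
      subject_id = sid, planted_gain = gain, day1_last = counts[nb],
      day2_test = day2,
      partition = c("declined", "levelled", "improved")[
        sign(day2 - counts[nb]) + 2], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "truth") <- do.call(rbind, truth)
  out
}

#' Simulate per-subject ROI gray-matter volumes
#'
#' Day-1 and day-2 modulated GM values for M1 and PCC. The overnight M1
#' change loads on the subject's standardized GABA change at the
#' calibrated coefficient (so that its correlation with the measured
#' 30-minute GABA change equals the planted value, default -0.48); the
#' PCC change is independent noise.
#'
#' @inheritParams simulate_behavior
#' @return data.frame with \code{subject_id}, \code{group}, \code{roi},
#'   \code{gm_day1}, \code{gm_day2}, \code{gm_change}.
#' @export
simulate_gm_volumes <- function(roster, effects = effect_spec(),
                                config = cohort_config(), latents = NULL) {
  cal <- calibrate_effects(effects, config$n_post_scans)
  rows <- list()
  for (i in seq_len(nrow(roster))) {
    sid <- roster$subject_id[i]; grp <- roster$group[i]
    set.seed(.subject_stage_seed(roster$subject_seed[i], 2L))
    if (!is.null(latents)) {
      li <- latents[latents$subject_id == sid, ]
      db <- li$dgaba_std; gme <- li$gmeps
    } else {
      db <- stats::rnorm(1); gme <- stats::rnorm(1)
    }
    g <- cal[[grp]]$g_gm
    d_m1 <- effects$gm_change_sd * (g * db + sqrt(1 - g^2) * gme)
    d_pcc <- effects$gm_change_sd * stats::rnorm(1)
    base <- stats::rnorm(2, effects$gm_mean[c("M1", "PCC")], effects$gm_sd)
    rows[[i]] <- data.frame(
      subject_id = sid, group = grp, roi = c("M1", "PCC"),
      gm_day1 = base, gm_day2 = base + c(d_m1, d_pcc),
      gm_change = c(d_m1, d_pcc), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
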