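#' @title End-to-end pipeline
#' @description Orchestrates simulate -> quantify -> behavior -> bold ->
#'   stats into one seeded, reproducible run, and writes the tabular
#'   outputs, a structured report and a validation manifest.
#' @name pipeline
NULL

#' Pipeline run configuration
#'
#' @param cohort a \code{\link{cohort_config}}.
#' @param effects an \code{\link{effect_spec}}.
#' @param tissue_correction apply tissue correction to concentrations.
#' @param cr_reference use Cr-referenced measures instead.
#' @param group_pooled_qc pool groups for the 3-SD QC rule.
#' @param strict_reset use the strict-reset key-press scanner.
#' @param ilc_kernel_mm ILC kernel width (mm).
#' @param z_threshold voxelwise z threshold for the engram conjunction.
#' @param min_cluster minimum conjunction cluster size (voxels).
#' @param drop_transition_volumes volumes dropped at late-block onsets.
#' @param alpha significance level used in reporting.
#' @param out_dir output directory (NULL = in-memory only).
#' @param write_nifti also write per-subject NIfTI runs and masks.
#' @return list of class \code{run_config}.
#' @export
run_config <- function(cohort = cohort_config(), effects = effect_spec(),
                       tissue_correction = TRUE, cr_reference = FALSE,
                       group_pooled_qc = FALSE, strict_reset = FALSE,
                       ilc_kernel_mm = 1, z_threshold = 3.1, min_cluster = 2,
                       drop_transition_volumes = 5, alpha = 0.05,
                       out_dir = NULL, write_nifti = FALSE) {
  stopifnot(inherits(cohort, "cohort_config"), inherits(effects, "effect_spec"))
  structure(list(cohort = cohort, effects = effects,
                 tissue_correction = tissue_correction,
                 cr_reference = cr_reference,
                 group_pooled_qc = group_pooled_qc,
                 strict_reset = strict_reset, ilc_kernel_mm = ilc_kernel_mm,
                 z_threshold = z_threshold, min_cluster = min_cluster,
                 drop_transition_volumes = drop_transition_volumes,
                 alpha = alpha, out_dir = out_dir,
                 write_nifti = write_nifti),
            class = "run_config")
}

# ---- BOLD feature stage -----------------------------------------------

.block_onsets <- function(config) {
  bd <- config$block_duration
  all_on <- (seq_len(config$n_blocks_day1) - 1) * 2 * bd
  list(all = all_on,
       early = all_on[1:3],
       late = all_on[4:config$n_blocks_day1],
       last = all_on[config$n_blocks_day1])
}

.write_run_nifti <- function(run, rc, sub_id, label) {
  if (!isTRUE(rc$write_nifti) || is.null(rc$out_dir)) return(invisible(NULL))
  dir.create(rc$out_dir, showWarnings = FALSE, recursive = TRUE)
  img <- RNifti::asNifti(run$data,
                         pixdim = c(rep(rc$cohort$voxel_size, 3), run$tr))
  RNifti::writeNifti(img, file.path(rc$out_dir,
                                    paste0(sub_id, "_", label, ".nii.gz")))
  invisible(NULL)
}

# per-subject BOLD simulation + feature extraction; returns small numbers
.subject_bold_features <- function(sub, rc, masks, latents, cal) {
  cc <- rc$cohort; es <- rc$effects
  grp <- sub$group
  seed <- sub$subject_seed
  is_learner <- grp == "Learning"
  on <- .block_onsets(cc)
  bd <- cc$block_duration

  li <- latents[latents$subject_id == sub$subject_id, ]
  calg <- cal[[grp]]

  # session-level connectivity targets (Fisher z) for the three edges
  set.seed(.subject_stage_seed(seed, 3L))
  z_pre <- stats::rnorm(3, es$fc_z_pre_mean, es$fc_z_pre_sd)
  z_post <- z_pre + stats::rnorm(3, 0, es$fc_short_sd)
  d_overnight <- stats::rnorm(3, 0, es$fc_overnight_sd)
  if (is_learner && calg$q_fc != 0) {
    d_overnight[1] <- es$fc_overnight_sd *
      (calg$q_fc * li$dglu_std + sqrt(1 - calg$q_fc^2) * li$fceps)
  }
  z_day2 <- z_post + d_overnight
  clampz <- function(z) pmin(pmax(z, -1.2), 1.2)
  ztab <- rbind(pre_rest = clampz(z_pre), post_rest = clampz(z_post),
                day2_rest = clampz(z_day2))
  colnames(ztab) <- c("putamen_R", "putamen_L", "PCC")

  fid <- if (is_learner) {
    qr_ <- calg$q_react
    min(max(es$reactivation_fidelity + es$reactivation_fidelity_spread *
              (qr_ * li$dglu_std + sqrt(1 - qr_^2) * li$reps), 0), 1)
  } else 0

  pattern_seed <- .subject_stage_seed(seed, 4L)
  task_str <- .pattern_structure(masks$M1_box, pattern_seed, es)
  cube_idx <- which(masks$engram_true$mask)
  n_cube <- length(cube_idx)
  pv <- 0
  for (p in seq_len(task_str$K)) {
    inp <- task_str$idx %in% cube_idx & task_str$assign == p
    pv <- pv + (sum(task_str$gain[inp]) / n_cube)^2
  }
  inj_for <- function(session) {
    w <- .solve_fc_weights(tanh(ztab[session, ]), n_cube,
                           c(sum(masks$putamen_R$mask),
                             sum(masks$putamen_L$mask),
                             sum(masks$PCC$mask)), pv, es$bold_noise_sd)
    list(
      list(mask = masks$M1_box$mask, weight = w$m1[1], id = "edge_R"),
      list(mask = masks$putamen_R$mask, weight = w$partner[1], id = "edge_R"),
      list(mask = masks$M1_box$mask, weight = w$m1[2], id = "edge_L"),
      list(mask = masks$putamen_L$mask, weight = w$partner[2], id = "edge_L"),
      list(mask = masks$M1_box$mask, weight = w$m1[3], id = "edge_P"),
      list(mask = masks$PCC$mask, weight = w$partner[3], id = "edge_P"))
  }

  feat <- list(subject_id = sub$subject_id, group = grp)
  conj <- masks$engram_true  # anatomical stand-in, replaced for learners
  if (is_learner) {
    act <- list(mask = masks$engram_true$mask, onsets = on$all,
                duration = bd, amplitude = es$activation_amplitude)
    task_run <- simulate_bold_run("task", masks$M1_box, pattern_seed, 1,
                                  cc, es, run_seed = .subject_stage_seed(seed, 5L),
                                  active = act)
    g1 <- glm_activation(task_run, list(early = on$early,
                                        late = on$late[-length(on$late)],
                                        last = on$last), bd)
    act2 <- list(mask = masks$engram_true$mask, onsets = 10,
                 duration = bd, amplitude = es$activation_amplitude)
    day2_run <- simulate_bold_run("task_day2", masks$M1_box, pattern_seed, 1,
                                  cc, es, run_seed = .subject_stage_seed(seed, 6L),
                                  active = act2)
    .write_run_nifti(task_run, rc, sub$subject_id, "task")
    .write_run_nifti(day2_run, rc, sub$subject_id, "task_day2")
    g2 <- glm_activation(day2_run, list(test = 10), bd)
    conj <- conjunction_roi(g1$z$last, g2$z$test, rc$z_threshold,
                            rc$min_cluster)
    feat$n_engram_voxels <- sum(conj$mask)
    feat$beta_task <- mean(g1$beta$late[conj$mask])

    task_late <- extract_late_volumes(task_run, on$late, bd,
                                      rc$drop_transition_volumes)
    pat_task <- mvlc_pattern(compute_ilc(task_late, rc$ilc_kernel_mm, conj), conj)
    rm(task_run, day2_run, task_late)
  }

  rest_runs <- list()
  for (session in c("pre_rest", "post_rest", "day2_rest")) {
    f <- if (session == "post_rest") fid else 0
    run <- simulate_bold_run(session, masks$M1_box, pattern_seed, f, cc, es,
                             run_seed = .subject_stage_seed(
                               seed, match(session, c("pre_rest", "post_rest",
                                                      "day2_rest")) + 6L),
                             injections = inj_for(session))
    .write_run_nifti(run, rc, sub$subject_id, session)
    for (edge in colnames(ztab)) {
      feat[[paste0("z_", edge, "_", session)]] <-
        roi_to_roi_fc(run, conj, masks[[edge]])
    }
    if (is_learner && session %in% c("pre_rest", "post_rest")) {
      rest_runs[[session]] <-
        mvlc_pattern(compute_ilc(run, rc$ilc_kernel_mm, conj), conj)
    }
    rm(run)
  }
  if (is_learner) {
    sim <- similarity_difference(pat_task, rest_runs$pre_rest,
                                 rest_runs$post_rest)
    feat$r_task_pre <- sim$r_task_pre
    feat$r_task_post <- sim$r_task_post
    feat$similarity_difference <- sim$similarity_difference
  }
  feat
}

# ---- battery -----------------------------------------------------------

.battery_spec <- function() {
  metab_pairs <- function(met, other, y, fam, xs = c("imm", "30", "avg"),
                          cov = NULL, tail = "two.sided") {
    do.call(rbind, lapply(xs, function(tp) data.frame(
      x = paste0(met, "_", tp), y = y, control = paste0(other, "_", tp),
      covariate = if (is.null(cov)) "" else cov, family = fam, tail = tail,
      stringsAsFactors = FALSE)))
  }
  rbind(
    metab_pairs("glu", "gaba", "gain", "glu_gain", cov = "day1_last"),
    metab_pairs("gaba", "glu", "gain", "gaba_gain", cov = "day1_last"),
    metab_pairs("glu", "gaba", "fc_R_overnight", "glu_fc_putamen_R"),
    metab_pairs("gaba", "glu", "fc_R_overnight", "gaba_fc_putamen_R"),
    metab_pairs("glu", "gaba", "fc_L_overnight", "glu_fc_putamen_L"),
    metab_pairs("gaba", "glu", "fc_L_overnight", "gaba_fc_putamen_L"),
    metab_pairs("glu", "gaba", "fc_PCC_overnight", "glu_fc_pcc",
                xs = c("imm", "avg")),
    metab_pairs("glu", "gaba", "fc_R_short", "fc_short", xs = "imm"),
    metab_pairs("gaba", "glu", "fc_R_short", "fc_short", xs = "imm"),
    metab_pairs("glu", "gaba", "fc_L_short", "fc_short", xs = "imm"),
    metab_pairs("gaba", "glu", "fc_L_short", "fc_short", xs = "imm"),
    metab_pairs("glu", "gaba", "gm_M1", "glu_gm_m1"),
    metab_pairs("gaba", "glu", "gm_M1", "gaba_gm_m1"),
    metab_pairs("gaba", "glu", "gm_PCC", "gaba_gm_pcc", xs = "30"),
    metab_pairs("glu", "gaba", "similarity_difference", "mvlc", xs = "imm"),
    metab_pairs("gaba", "glu", "similarity_difference", "mvlc", xs = "imm"),
    data.frame(x = "fc_R_overnight", y = "gain", control = "",
               covariate = "day1_last", family = "fc_behavior",
               tail = "greater", stringsAsFactors = FALSE),
    data.frame(x = "gm_M1", y = "gain", control = "",
               covariate = "day1_last", family = "gm_behavior",
               tail = "greater", stringsAsFactors = FALSE),
    metab_pairs("glu", "gaba", "beta_task", "task_engagement",
                xs = c("imm", "avg")),
    metab_pairs("gaba", "glu", "beta_task", "task_engagement",
                xs = c("imm", "avg")),
    metab_pairs("glu", "gaba", "total_keypresses", "task_engagement",
                xs = c("imm", "avg")),
    metab_pairs("gaba", "glu", "total_keypresses", "task_engagement",
                xs = c("imm", "avg"))
  )
}

.run_battery <- function(features, spec = .battery_spec()) {
  rows <- vector("list", nrow(spec))
  for (i in seq_len(nrow(spec))) {
    s <- spec[i, ]
    if (!s$x %in% names(features) || !s$y %in% names(features)) next
    ctrl <- if (nzchar(s$control)) features[s$control] else NULL
    cov <- if (nzchar(s$covariate)) features[s$covariate] else NULL
    res <- tryCatch(
      partial_correlation(features[[s$x]], features[[s$y]], ctrl, cov,
                          tail = s$tail),
      error = function(e) NULL)
    if (is.null(res)) next
    rows[[i]] <- data.frame(
      x = s$x, y = s$y, controls = s$control, covariates = s$covariate,
      family = s$family, tail = s$tail, r = res$r, df = res$df, p = res$p,
      n = res$n, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p, out$family)
  out
}

# ---- run_all -----------------------------------------------------------

#' Run the full pipeline
#'
#' Simulates the cohort, quantifies and QCs the metabolite panel, scores
#' behavior and segments the learning phases, extracts the BOLD features
#' (engram-conjunction ROI, MVLC reactivation similarity, ROI-to-ROI
#' connectivity), assembles the subject feature table, and runs the
#' statistical battery (mixed models, coupling change,
#' baseline-dependence, partial-correlation families with within-family
#' FDR). Deterministic given the configuration: the same config yields an
#' identical report.
#'
#' @param rc a \code{\link{run_config}}.
#' @return list of class \code{engram_report} (also written to
#'   \code{rc$out_dir} if set, as CSV tables plus \code{report.json} /
#'   \code{report.md}).
#' @export
run_all <- function(rc = run_config()) {
  stopifnot(inherits(rc, "run_config"))
  cc <- rc$cohort; es <- rc$effects
  t0 <- Sys.time()
  timing <- c()
  tick <- function(stage) {
    timing[[stage]] <<- round(as.numeric(Sys.time() - t0, units = "secs"), 2)
    t0 <<- Sys.time()
  }

  # --- simulate
  roster <- make_cohort(cc)
  panel <- simulate_metabolites(roster, es, cc)
  latents <- attr(panel, "latents")
  cal <- attr(panel, "calibration")
  behav <- simulate_behavior(roster, es, cc, latents)
  gm <- simulate_gm_volumes(roster, es, cc, latents)
  tick("simulate")

  # --- quantify
  qc <- qc_flags(panel, group_pooled = rc$group_pooled_qc)
  value_col <- if (rc$cr_reference) "cr_ratio" else
    if (rc$tissue_correction) "conc_corrected" else "conc_mM"
  deltas <- suppressWarnings(delta_features(qc, value_col = value_col))
  tick("quantify")

  # --- behavior
  scored <- score_blocks(behav, strict_reset = rc$strict_reset)
  day1 <- scored[scored$day == 1, ]
  seg <- segment_phases(day1, alpha = rc$alpha)
  last_block <- max(day1$block)
  d1_last <- day1[day1$block == last_block, c("subject_id", "n_correct")]
  names(d1_last)[2] <- "day1_last"
  d2 <- scored[scored$day == 2, c("subject_id", "n_correct")]
  names(d2)[2] <- "day2_test"
  gains <- merge(d1_last, d2, by = "subject_id")
  gains$gain_pct <- overnight_gain(gains$day1_last, gains$day2_test)
  kp <- stats::aggregate(n_keypresses ~ subject_id, day1, sum)
  names(kp)[2] <- "total_keypresses"
  tick("behavior")

  # --- bold
  masks <- default_roi_masks(cc$grid_shape)
  feats <- lapply(seq_len(nrow(roster)), function(i) {
    tryCatch(.subject_bold_features(roster[i, ], rc, masks, latents, cal),
             error = function(e) stop("bold stage failed for ",
                                      roster$subject_id[i], ": ",
                                      conditionMessage(e)))
  })
  all_names <- unique(unlist(lapply(feats, names)))
  bold_tab <- do.call(rbind, lapply(feats, function(f) {
    f[setdiff(all_names, names(f))] <- NA
    as.data.frame(f[all_names], stringsAsFactors = FALSE)
  }))
  tick("bold")

  # --- feature table
  wide_delta <- function(met, col, nm) {
    d <- deltas[deltas$metabolite == met, c("subject_id", col)]
    names(d)[2] <- nm
    d
  }
  ft <- Reduce(function(a, b) merge(a, b, by = "subject_id", all = TRUE), list(
    roster[, c("subject_id", "group")],
    wide_delta("Glu", "immediate_change", "glu_imm"),
    wide_delta("Glu", "change_30min", "glu_30"),
    wide_delta("Glu", "averaged_change", "glu_avg"),
    wide_delta("Glu", "pre", "glu_pre"),
    wide_delta("GABA", "immediate_change", "gaba_imm"),
    wide_delta("GABA", "change_30min", "gaba_30"),
    wide_delta("GABA", "averaged_change", "gaba_avg"),
    wide_delta("GABA", "pre", "gaba_pre"),
    gains, kp, bold_tab[, setdiff(names(bold_tab), "group")]
  ))
  ft$fc_R_short <- fc_change(ft$z_putamen_R_post_rest, ft$z_putamen_R_pre_rest)
  ft$fc_L_short <- fc_change(ft$z_putamen_L_post_rest, ft$z_putamen_L_pre_rest)
  ft$fc_R_overnight <- fc_change(ft$z_putamen_R_day2_rest, ft$z_putamen_R_post_rest)
  ft$fc_L_overnight <- fc_change(ft$z_putamen_L_day2_rest, ft$z_putamen_L_post_rest)
  ft$fc_PCC_overnight <- fc_change(ft$z_PCC_day2_rest, ft$z_PCC_post_rest)
  gmw <- stats::reshape(gm[, c("subject_id", "roi", "gm_change")], direction = "wide",
                 idvar = "subject_id", timevar = "roi")
  names(gmw) <- c("subject_id", "gm_M1", "gm_PCC")
  ft <- merge(ft, gmw, by = "subject_id", all.x = TRUE)

  # IQR outlier rule on the non-metabolite continuous measures
  for (v in c("gain_pct", "fc_R_short", "fc_L_short", "fc_R_overnight",
              "fc_L_overnight", "fc_PCC_overnight", "gm_M1", "gm_PCC",
              "similarity_difference", "beta_task", "total_keypresses")) {
    if (v %in% names(ft) && sum(is.finite(ft[[v]])) >= 4) {
      ft[[v]][iqr_outliers(ft[[v]])] <- NA
    }
  }
  ft$gain <- ft$gain_pct
  learn <- ft[ft$group == "Learning", ]
  tick("features")

  # --- stats
  lmm <- list()
  for (met in c("Glu", "GABA")) {
    sub <- qc[!qc$qc_flag & qc$metabolite == met, ]
    lmm[[met]] <- tryCatch({
      f <- fit_time_group_lmm(sub, dv = "conc_corrected")
      f$fit <- NULL
      f
    }, error = function(e) list(error = conditionMessage(e)))
  }

  coupling <- lapply(split(ft, ft$group), function(d) {
    tryCatch(coupling_change(d$glu_pre, d$gaba_pre,
                             d$glu_pre + d$glu_avg, d$gaba_pre + d$gaba_avg),
             error = function(e) list(error = conditionMessage(e)))
  })

  bd_rows <- list()
  for (grp in unique(ft$group)) for (met in c("glu", "gaba")) {
    d <- ft[ft$group == grp, ]
    res <- tryCatch(partial_correlation(d[[paste0(met, "_pre")]],
                                        d[[paste0(met, "_avg")]]),
                    error = function(e) NULL)
    if (!is.null(res)) {
      bd_rows[[paste(grp, met)]] <- data.frame(
        group = grp, metabolite = met, r = res$r, df = res$df, p = res$p)
    }
  }
  baseline_dep <- do.call(rbind, bd_rows)
  baseline_dep$q <- bh_fdr(baseline_dep$p)

  battery <- .run_battery(learn)

  mvlc_t <- tryCatch({
    tt <- stats::t.test(learn$similarity_difference)
    list(mean = unname(tt$estimate), t = unname(tt$statistic),
         df = unname(tt$parameter), p = tt$p.value)
  }, error = function(e) list(error = conditionMessage(e)))
  tick("stats")

  report <- structure(list(
    meta = list(master_seed = cc$master_seed, n_learning = cc$n_learning,
                n_control = cc$n_control, grid_shape = cc$grid_shape,
                n_volumes_rest = cc$n_volumes_rest, alpha = rc$alpha,
                value_col = value_col),
    gain_summary = list(mean_pct = mean(learn$gain, na.rm = TRUE),
                        se_pct = stats::sd(learn$gain, na.rm = TRUE) /
                          sqrt(sum(is.finite(learn$gain))),
                        n_improved = sum(learn$day2_test > learn$day1_last, na.rm = TRUE),
                        n_levelled = sum(learn$day2_test == learn$day1_last, na.rm = TRUE),
                        n_declined = sum(learn$day2_test < learn$day1_last, na.rm = TRUE)),
    segmentation = seg[c("boundary", "early", "late", "no_plateau", "method")],
    lmm = lapply(lmm, function(l) l[setdiff(names(l), "fit")]),
    coupling = coupling,
    baseline_dependence = baseline_dep,
    battery = battery,
    mvlc_group = mvlc_t,
    family_significant = vapply(split(battery$q, battery$family),
                                function(q) any(q < rc$alpha, na.rm = TRUE),
                                logical(1))
  ), class = "engram_report")
  attr(report, "timing_s") <- timing

  if (!is.null(rc$out_dir)) {
    .write_outputs(rc, roster, panel, qc, deltas, behav, scored, seg, gains,
                   gm, ft, battery, report, masks)
  }
  attr(report, "features") <- ft
  attr(report, "qc") <- qc
  report
}

#' @export
print.engram_report <- function(x, ...) {
  cat("engramflow pipeline report (seed", x$meta$master_seed, ")\n")
  cat(sprintf("  overnight gain: %.2f %% (SE %.2f), %d improved / %d levelled / %d declined\n",
              x$gain_summary$mean_pct, x$gain_summary$se_pct,
              x$gain_summary$n_improved, x$gain_summary$n_levelled,
              x$gain_summary$n_declined))
  cat("  learning plateau from block", x$segmentation$boundary, "\n")
  cl <- x$coupling$Learning
  if (is.null(cl$error)) {
    cat(sprintf("  E-I coupling (Learning): r_pre = %.3f, r_post = %.3f, Z = %.2f, p = %.3g\n",
                cl$r_pre, cl$r_post, cl$Z, cl$p))
  }
  sig <- names(x$family_significant)[x$family_significant]
  cat("  FDR-significant families:",
      if (length(sig)) paste(sig, collapse = ", ") else "none", "\n")
  invisible(x)
}

.write_outputs <- function(rc, roster, panel, qc, deltas, behav, scored, seg,
                           gains, gm, ft, battery, report, masks) {
  dir.create(rc$out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(d, f) utils::write.csv(d, file.path(rc$out_dir, f),
                                       row.names = FALSE)
  w(panel, "metabolites.csv")
  w(qc, "metabolites_qc.csv")
  w(deltas, "delta_features.csv")
  w(behav, "behavior.csv")
  w(scored[, c("subject_id", "day", "block", "n_correct", "n_keypresses")],
    "block_scores.csv")
  w(gains, "overnight_gains.csv")
  w(gm, "gm_volumes.csv")
  fc_cols <- grep("^z_", names(ft), value = TRUE)
  w(ft[, c("subject_id", "group", fc_cols)], "fc_edges.csv")
  w(ft[ft$group == "Learning",
       intersect(c("subject_id", "r_task_pre", "r_task_post",
                   "similarity_difference"), names(ft))],
    "mvlc_similarity.csv")
  w(battery, "correlation_battery.csv")
  for (met in names(report$lmm)) {
    if (!is.null(report$lmm[[met]]$anova)) {
      w(report$lmm[[met]]$anova, paste0("lmm_effects_", met, ".csv"))
    }
  }
  writeLines(jsonlite::toJSON(seg[c("boundary", "early", "late",
                                    "no_plateau", "method")],
                              auto_unbox = TRUE, digits = NA),
             file.path(rc$out_dir, "phase_segmentation.json"))
  writeLines(jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = 10,
                              pretty = TRUE, dataframe = "rows", force = TRUE),
             file.path(rc$out_dir, "report.json"))
  md <- c("# engramflow pipeline report", "",
          sprintf("- master seed: %d", rc$cohort$master_seed),
          sprintf("- overnight gain: %.2f %% (SE %.2f)",
                  report$gain_summary$mean_pct, report$gain_summary$se_pct),
          sprintf("- learning plateau from block %d", report$segmentation$boundary),
          sprintf("- FDR-significant families: %s",
                  paste(names(report$family_significant)[report$family_significant],
                        collapse = ", ")))
  writeLines(md, file.path(rc$out_dir, "report.md"))
  if (rc$write_nifti) {
    for (nm in names(masks)) {
      RNifti::writeNifti(
        RNifti::asNifti(array(as.integer(masks[[nm]]$mask),
                              dim(masks[[nm]]$mask)),
                        pixdim = rep(rc$cohort$voxel_size, 3)),
        file.path(rc$out_dir, paste0("roi_", nm, ".nii.gz")))
    }
  }
  invisible(NULL)
}

#' Validate a pipeline output directory
#'
#' Checks file presence, schema columns and basic invariants (tissue
#' fractions sum to 1, correlations bounded by 1, q-values never below
#' their p-values). Missing files are listed but only fail the final
#' verdict.
#'
#' @param out_dir directory written by \code{\link{run_all}}.
#' @return data.frame manifest (\code{check}, \code{pass}, \code{detail})
#'   with attribute \code{pass} giving the overall verdict.
#' @export
validate_outputs <- function(out_dir) {
  checks <- list()
  add <- function(check, pass, detail = "") {
    checks[[length(checks) + 1L]] <<- data.frame(
      check = check, pass = pass, detail = detail, stringsAsFactors = FALSE)
  }
  expected <- c("metabolites.csv", "metabolites_qc.csv", "delta_features.csv",
                "behavior.csv", "block_scores.csv", "overnight_gains.csv",
                "gm_volumes.csv", "fc_edges.csv", "mvlc_similarity.csv",
                "correlation_battery.csv", "phase_segmentation.json",
                "report.json", "report.md")
  for (f in expected) {
    add(paste0("exists:", f), file.exists(file.path(out_dir, f)))
  }
  rd <- function(f) tryCatch(utils::read.csv(file.path(out_dir, f)),
                             error = function(e) NULL)
  met <- rd("metabolites.csv")
  if (!is.null(met)) {
    need <- c("subject_id", "group", "timepoint", "metabolite", "conc_mM",
              "crlb_pct", "snr", "linewidth_hz", "f_gm", "f_wm", "f_csf")
    add("schema:metabolites", all(need %in% names(met)),
        paste(setdiff(need, names(met)), collapse = ","))
    add("invariant:fractions_sum_1",
        all(abs(met$f_gm + met$f_wm + met$f_csf - 1) < 1e-6))
  } else add("schema:metabolites", FALSE, "unreadable")
  bat <- rd("correlation_battery.csv")
  if (!is.null(bat) && all(c("r", "p", "q", "family") %in% names(bat)) &&
      nrow(bat) > 0) {
    add("schema:battery", TRUE)
    add("invariant:abs_r_le_1", all(abs(bat$r) <= 1, na.rm = TRUE))
    add("invariant:q_ge_p", all(bat$q >= bat$p - 1e-12, na.rm = TRUE))
  } else add("schema:battery", FALSE, "unreadable or missing columns")
  manifest <- do.call(rbind, checks)
  attr(manifest, "pass") <- all(manifest$pass)
  manifest
}
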