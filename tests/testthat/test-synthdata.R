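test_that("make_cohort produces the study groups deterministically", {
  cc <- cohort_config(master_seed = 9)
  r <- make_cohort(cc)
  expect_equal(nrow(r), 57)
  expect_equal(sum(r$group == "Learning"), 36)
  expect_equal(sum(r$group == "Control"), 21)
  expect_identical(r, make_cohort(cohort_config(master_seed = 9)))
  r2 <- make_cohort(cohort_config(n_learning = 4, n_control = 4))
  expect_equal(nrow(r2), 8)
  expect_error(cohort_config(n_learning = 3), "group sizes")
  expect_error(cohort_config(voxel_size = -1), "positive")
  expect_error(cohort_config(grid_shape = c(8, 8)), "grid_shape")
})

test_that("metabolite panel has the full schema and is deterministic", {
  cc <- tiny_cohort(10)
  p <- simulate_metabolites(make_cohort(cc), effect_spec(), cc)
  expect_equal(nrow(p), 13 * 6 * 5)
  expect_true(all(c("subject_id", "group", "timepoint", "metabolite",
                    "conc_mM", "crlb_pct", "snr", "linewidth_hz",
                    "f_gm", "f_wm", "f_csf") %in% names(p)))
  expect_true(all(abs(p$f_gm + p$f_wm + p$f_csf - 1) < 1e-9))
  p2 <- simulate_metabolites(make_cohort(cc), effect_spec(), cc)
  expect_identical(p, p2)
})

test_that("negative regression-to-the-mean slope produces negative baseline-change correlation", {
  cc <- cohort_config(n_learning = 200, n_control = 4, master_seed = 11,
                      grid_shape = c(8, 8, 8))
  es <- effect_spec(qc_contamination_rate = 0)
  p <- simulate_metabolites(make_cohort(cc), es, cc)
  d <- suppressWarnings(delta_features(qc_flags(p)))
  gb <- d[d$metabolite == "GABA" & d$group == "Learning", ]
  expect_lt(cor(gb$pre, gb$averaged_change), 0)
  gl <- d[d$metabolite == "Glu" & d$group == "Learning", ]
  expect_lt(cor(gl$pre, gl$averaged_change), 0)
})

test_that("planted post-learning coupling is realized at large n", {
  cc <- cohort_config(n_learning = 500, n_control = 4, master_seed = 12,
                      grid_shape = c(8, 8, 8))
  es <- effect_spec(qc_contamination_rate = 0)
  p <- simulate_metabolites(make_cohort(cc), es, cc)
  d <- suppressWarnings(delta_features(qc_flags(p)))
  dl <- d[d$group == "Learning", ]
  g <- dl[dl$metabolite == "Glu", ]
  b <- dl[dl$metabolite == "GABA", ]
  m <- merge(g, b, by = "subject_id")
  r_post <- cor(m$pre.x + m$averaged_change.x, m$pre.y + m$averaged_change.y)
  expect_lt(abs(r_post - 0.58), 0.1)
  r_pre <- cor(m$pre.x, m$pre.y)
  expect_lt(abs(r_pre - 0.18), 0.1)
})

test_that("degenerate noise settings yield exactly zero change scores", {
  cc <- tiny_cohort(13)
  zero <- c(Glu = 0, GABA = 0, NAA = 0, Gln = 0, Cr = 0)
  eps <- c(Glu = 1e-12, GABA = 1e-12, NAA = 1e-12, Gln = 1e-12, Cr = 1e-12)
  es <- effect_spec(regression_to_mean_slope = list(Learning = zero, Control = zero),
                    delta_noise_sd = list(Learning = eps, Control = eps),
                    scan_noise_sd = eps,
                    group_response = list(Learning = zero, Control = zero),
                    qc_contamination_rate = 0)
  # near-zero change noise makes the coupling/gain targets unattainable;
  # the calibrator warns and degrades gracefully, which is fine here
  p <- suppressWarnings(simulate_metabolites(make_cohort(cc), es, cc))
  d <- suppressWarnings(delta_features(qc_flags(p)))
  expect_true(all(abs(d$averaged_change) < 1e-8))
  expect_true(all(abs(d$immediate_change) < 1e-8))
})

test_that("overnight gains match the planted mean and partial correlation at large n", {
  cc <- cohort_config(n_learning = 500, n_control = 4, master_seed = 14,
                      grid_shape = c(8, 8, 8))
  es <- effect_spec(qc_contamination_rate = 0)
  ro <- make_cohort(cc)
  p <- simulate_metabolites(ro, es, cc)
  be <- simulate_behavior(ro, es, cc, latents = attr(p, "latents"))
  tr <- attr(be, "truth")
  gain <- 100 * (tr$day2_test - tr$day1_last) / tr$day1_last
  expect_lt(abs(mean(gain) - 10.46), 1)
  d <- suppressWarnings(delta_features(qc_flags(p)))
  g <- d[d$metabolite == "Glu" & d$group == "Learning", ]
  b <- d[d$metabolite == "GABA" & d$group == "Learning", ]
  m <- merge(merge(g[, c("subject_id", "averaged_change")],
                   b[, c("subject_id", "averaged_change")], by = "subject_id"),
             tr, by = "subject_id")
  mg <- 100 * (m$day2_test - m$day1_last) / m$day1_last
  pr <- partial_correlation(m$averaged_change.x, mg, m$averaged_change.y)$r
  expect_lt(abs(pr - 0.45), 0.07)
})

test_that("gray-matter changes realize the planted GABA coupling and PCC independence", {
  cc <- cohort_config(n_learning = 1000, n_control = 4, master_seed = 15,
                      grid_shape = c(8, 8, 8))
  es <- effect_spec(qc_contamination_rate = 0)
  ro <- make_cohort(cc)
  p <- simulate_metabolites(ro, es, cc)
  gm <- simulate_gm_volumes(ro, es, cc, latents = attr(p, "latents"))
  d <- suppressWarnings(delta_features(qc_flags(p)))
  b30 <- d[d$metabolite == "GABA" & d$group == "Learning",
           c("subject_id", "change_30min")]
  m1 <- merge(b30, gm[gm$roi == "M1", ], by = "subject_id")
  expect_lt(abs(cor(m1$change_30min, m1$gm_change,
                    use = "complete.obs") - (-0.48)), 0.06)
  pcc <- merge(b30, gm[gm$roi == "PCC", ], by = "subject_id")
  expect_lt(abs(cor(pcc$change_30min, pcc$gm_change, use = "complete.obs")), 0.1)
  # null spec kills the coupling
  gm0 <- simulate_gm_volumes(ro, null_effect_spec(), cc,
                             latents = attr(p, "latents"))
  m0 <- merge(b30, gm0[gm0$roi == "M1", ], by = "subject_id")
  expect_lt(abs(cor(m0$change_30min, m0$gm_change, use = "complete.obs")), 0.1)
})

test_that("BOLD runs are seeded, grid-checked and reject bad fidelity", {
  cc <- tiny_cohort(16)
  masks <- default_roi_masks(cc$grid_shape)
  r1 <- simulate_bold_run("pre_rest", masks$M1_box, 5, 0, cc, run_seed = 77)
  r2 <- simulate_bold_run("pre_rest", masks$M1_box, 5, 0, cc, run_seed = 77)
  expect_identical(r1$data, r2$data)
  expect_equal(dim(r1$data), c(8, 8, 8, 60))
  expect_error(simulate_bold_run("pre_rest", masks$M1_box, 5, 1.2, cc),
               "fidelity")
  wrong <- roi_mask(array(TRUE, c(6, 6, 6)), "x")
  expect_error(simulate_bold_run("pre_rest", wrong, 5, 0, cc), "grid")
})

test_that("without latent structure the ILC field is null on average", {
  cc <- tiny_cohort(17)
  es <- effect_spec(bold_signal_sd = 1e-9, ar1_coef = 0)
  masks <- default_roi_masks(cc$grid_shape)
  means <- sapply(1:20, function(s) {
    run <- simulate_bold_run("pre_rest", masks$M1_box, s, 0, cc, es,
                             run_seed = 9000 + s)
    mean(compute_ilc(run, 1))
  })
  expect_lt(abs(mean(means)), 2 * sd(means) / sqrt(20))
})

test_that("reactivation fidelity moves the task/post-rest pattern similarity", {
  cc <- tiny_cohort(18)
  es <- effect_spec()
  masks <- default_roi_masks(cc$grid_shape)
  cube <- masks$engram_true
  sim_at <- function(fid, s) {
    task <- simulate_bold_run("task", masks$M1_box, 300 + s, 1, cc, es,
                              run_seed = s * 13 + 1, n_vol = 80)
    post <- simulate_bold_run("post_rest", masks$M1_box, 300 + s, fid, cc, es,
                              run_seed = s * 13 + 2)
    cor(mvlc_pattern(compute_ilc(task, 1, cube), cube),
        mvlc_pattern(compute_ilc(post, 1, cube), cube))
  }
  lo <- sapply(1:15, sim_at, fid = 0)
  hi <- sapply(1:15, sim_at, fid = 1)
  expect_gt(mean(hi), mean(lo) + 0.3)
})
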