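make_run <- function(seed, d = c(6, 6, 6), nt = 60, vs = 1.6, tr = 1) {
  set.seed(seed)
  bold_run(array(rnorm(prod(d) * nt), c(d, nt)), tr = tr, voxel_size = vs)
}

test_that("ILC equals the naive double-loop oracle on random volumes", {
  for (s in 1:5) {
    run <- make_run(s)
    expect_equal(compute_ilc(run, 1), naive_ilc(run, 1), tolerance = 1e-12)
  }
  # non-default kernel exercises a different truncation radius
  run <- make_run(99, d = c(5, 5, 5), nt = 40)
  expect_equal(compute_ilc(run, 1.4), naive_ilc(run, 1.4), tolerance = 1e-12)
})

test_that("ILC is 1 for perfectly shared time courses and ~0 for iid noise", {
  set.seed(51)
  ts <- rnorm(50)
  arr <- array(rep(ts, each = 6 * 6 * 6), c(6, 6, 6, 50)) * 0
  arr <- sweep(arr, 4, ts, `+`)
  run <- bold_run(arr, tr = 1)
  expect_true(all(abs(compute_ilc(run, 1) - 1) < 1e-10))
  means <- sapply(1:30, function(s) mean(compute_ilc(make_run(400 + s,
                                                              nt = 40), 1)))
  expect_lt(abs(mean(means)), 2 * sd(means) / sqrt(30))
})

test_that("ILC restricted to an ROI matches the full map at ROI voxels", {
  run <- make_run(52, d = c(8, 8, 8), nt = 40)
  m <- array(FALSE, c(8, 8, 8)); m[3:5, 3:5, 3:5] <- TRUE
  roi <- roi_mask(m, "roi")
  full <- compute_ilc(run, 1)
  part <- compute_ilc(run, 1, roi)
  expect_equal(part[m], full[m], tolerance = 1e-12)
  expect_true(all(is.na(part[!m])))
})

test_that("zero-variance voxels get ILC 0 and contribute 0 correlations", {
  run <- make_run(53)
  run$data[2, 2, 2, ] <- 7
  expect_message(ilc <- compute_ilc(run, 1), "zero-variance")
  expect_identical(ilc[2, 2, 2], 0)
})

test_that("GLM recovers planted activation and guards degeneracies", {
  cc <- cohort_config(grid_shape = c(8, 8, 8), master_seed = 1)
  d <- c(8, 8, 8); nt <- 240
  onsets <- seq(0, 180, by = 60)
  set.seed(54)
  arr <- array(rnorm(prod(d) * nt), c(d, nt))
  stim <- numeric(nt); for (on in onsets) stim[(on + 1):(on + 30)] <- 1
  hrf <- engramflow:::.convolve_hrf(stim, 1)
  arr[4, 4, 4, ] <- arr[4, 4, 4, ] + 3 * hrf
  arr[1, 1, 1, ] <- 0  # all-zero voxel
  run <- bold_run(arr, tr = 1)
  g <- glm_activation(run, list(task = onsets), 30)
  expect_gt(g$z$task[4, 4, 4], 3.1)
  expect_identical(g$z$task[1, 1, 1], 0)
  off <- abs(g$z$task[2:8, 2, 2])
  expect_lt(mean(off), 2)
  # permuting volumes destroys the planted response
  run_perm <- bold_run(run$data[, , , sample(nt)], tr = 1)
  gp <- glm_activation(run_perm, list(task = onsets), 30)
  expect_lt(abs(gp$z$task[4, 4, 4]), 3.1)
  expect_error(glm_activation(run, list(a = onsets, b = onsets), 30),
               "collinear")
  expect_error(glm_activation(run, list(a = 1e6), 30), "onset outside")
})

test_that("conjunction ROI is idempotent, errors on disjoint maps, recovers a planted cube", {
  z1 <- array(0, c(8, 8, 8)); z1[2:4, 2:4, 2:4] <- 5
  expect_equal(conjunction_roi(z1, z1)$mask, z1 > 3.1)
  z2 <- array(0, c(8, 8, 8)); z2[6:8, 6:8, 6:8] <- 5
  expect_error(conjunction_roi(z1, z2), "empty conjunction")
  # planted 27-voxel cube active in two noisy runs of one synthetic subject
  cc <- cohort_config(grid_shape = c(8, 8, 8), n_volumes_rest = 60, tr = 1,
                      master_seed = 2)
  es <- effect_spec()
  masks <- default_roi_masks(cc$grid_shape)
  onsets <- (0:5) * 60
  act <- list(mask = masks$engram_true$mask, onsets = onsets, duration = 30,
              amplitude = es$activation_amplitude)
  r1 <- simulate_bold_run("task", masks$M1_box, 71, 1, cc, es, run_seed = 1,
                          active = act, n_vol = 360)
  r2 <- simulate_bold_run("task", masks$M1_box, 71, 1, cc, es, run_seed = 2,
                          active = act, n_vol = 360)
  g1 <- glm_activation(r1, list(task = onsets), 30)
  g2 <- glm_activation(r2, list(task = onsets), 30)
  conj <- conjunction_roi(g1$z$task, g2$z$task, 3.1, min_cluster = 2)
  planted <- which(masks$engram_true$mask)
  got <- which(conj$mask)
  expect_gte(length(intersect(got, planted)) / length(planted), 0.9)
  expect_lte(length(setdiff(got, planted)) / max(1, length(got)), 0.05)
})

test_that("MVLC patterns are Fisher-z ILC values in a fixed voxel order", {
  m <- array(FALSE, c(6, 6, 6)); m[2:4, 2:4, 2:4] <- TRUE
  roi <- roi_mask(m, "roi")
  ilc <- array(0, c(6, 6, 6))
  expect_equal(as.numeric(mvlc_pattern(ilc, roi)), rep(0, 27))
  ilc[3, 3, 3] <- 0.5
  pat <- mvlc_pattern(ilc, roi)
  expect_equal(max(pat), atanh(0.5), tolerance = 1e-9)
  expect_equal(round(max(pat), 5), 0.54931)
  expect_identical(as.numeric(pat), as.numeric(mvlc_pattern(ilc, roi)))
  ilc[3, 3, 3] <- 1.5
  expect_warning(mvlc_pattern(ilc, roi), "clipping")
  small <- roi_mask(array(c(rep(TRUE, 5), rep(FALSE, 211)), c(6, 6, 6)), "s")
  expect_error(mvlc_pattern(ilc, small), "fewer than 10")
})

test_that("similarity difference behaves at its limiting cases and under permutation", {
  set.seed(55)
  task <- rnorm(500)
  orth <- rnorm(500)
  s <- similarity_difference(task, orth, task)
  expect_equal(s$r_task_post, 1)
  expect_gt(s$similarity_difference, 0.8)
  pre <- rnorm(500)
  expect_equal(similarity_difference(task, pre, pre)$similarity_difference, 0)
  perm <- sample(500)
  s1 <- similarity_difference(task, pre, orth)
  s2 <- similarity_difference(task[perm], pre[perm], orth[perm])
  expect_equal(s1$similarity_difference, s2$similarity_difference,
               tolerance = 1e-12)
  expect_error(similarity_difference(rep(1, 10), rnorm(10), rnorm(10)),
               "constant")
  expect_error(similarity_difference(task, pre[1:10], orth), "equal length")
})

test_that("ROI-to-ROI connectivity recovers a planted shared signal", {
  set.seed(56)
  d <- c(8, 8, 8); nt <- 4000
  # two disjoint ROIs; every voxel = own noise + c * shared latent, with c
  # chosen so the ROI-mean correlation is 0.6 analytically
  n_roi <- 8
  target_r <- 0.6
  cc <- target_r / (1 - target_r) / n_roi  # c^2/(1/n + c^2) = r with sd 1
  cval <- sqrt(cc)
  lat <- rnorm(nt)
  arr <- array(rnorm(prod(d) * nt), c(d, nt))
  ra <- array(FALSE, d); ra[1:2, 1:2, 1:2] <- TRUE
  rb <- array(FALSE, d); rb[7:8, 7:8, 7:8] <- TRUE
  for (v in which(ra | rb)) {
    co <- arrayInd(v, d)
    arr[co[1], co[2], co[3], ] <- arr[co[1], co[2], co[3], ] + cval * lat
  }
  run <- bold_run(arr, tr = 1)
  z <- roi_to_roi_fc(run, roi_mask(ra, "a"), roi_mask(rb, "b"))
  expect_equal(z, atanh(0.6), tolerance = 0.08)
  expect_error(roi_to_roi_fc(run, roi_mask(ra, "a"), roi_mask(ra, "a")),
               "identical")
  # independent ROIs: null distribution of z centered on 0
  zs <- sapply(1:30, function(s) {
    r <- make_run(600 + s, d = c(6, 6, 6), nt = 80)
    ma <- array(FALSE, c(6, 6, 6)); ma[1:2, 1:2, 1:2] <- TRUE
    mb <- array(FALSE, c(6, 6, 6)); mb[5:6, 5:6, 5:6] <- TRUE
    roi_to_roi_fc(r, roi_mask(ma, "a"), roi_mask(mb, "b"))
  })
  expect_lt(abs(mean(zs)), 2 * sd(zs) / sqrt(30))
})

test_that("fc_change is an antisymmetric difference", {
  expect_equal(fc_change(0.5, 0.5), 0)
  expect_equal(fc_change(0.7, 0.4), 0.3)
  expect_equal(fc_change(0.2, 0.9), -fc_change(0.9, 0.2))
})
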