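test_that("tissue correction factor matches direct arithmetic from the water constants", {
  expect_identical(tissue_correction_factor(1, 0, 0), 43.3)
  expect_equal(tissue_correction_factor(0.5, 0.5, 0), (0.5 * 43.3 + 0.5 * 35.88))
  # (0.4*43.3 + 0.4*35.88 + 0.2*5.556) / 0.8, computed independently
  expect_equal(tissue_correction_factor(0.4, 0.4, 0.2),
               (17.32 + 14.352 + 1.1112) / 0.8, tolerance = 1e-12)
})

test_that("tissue correction factor is monotone in GM fraction and guards its domain", {
  for (f_csf in c(0, 0.1, 0.3)) {
    fg <- seq(0, 1 - f_csf, length.out = 11)
    vals <- tissue_correction_factor(fg, 1 - f_csf - fg, f_csf)
    expect_true(all(diff(vals) > 0))
  }
  expect_error(tissue_correction_factor(0, 0, 1), "degenerate")
  expect_error(tissue_correction_factor(0.5, 0.6, -0.1), "non-negative")
  expect_error(tissue_correction_factor(0.5, 0.4, 0.2), "sum to 1")
})

test_that("concentration correction is linear in the raw value", {
  expect_equal(correct_concentration(0.1, 1, 0, 0), 4.33)
  expect_equal(correct_concentration(0.2, 0.4, 0.4, 0.2),
               0.2 * (17.32 + 14.352 + 1.1112) / 0.8)
  expect_identical(correct_concentration(0, 0.4, 0.4, 0.2), 0)
  set.seed(1)
  raw <- rnorm(20)
  a <- runif(1, 0.5, 2)
  expect_equal(correct_concentration(a * raw, 0.5, 0.45, 0.05),
               a * correct_concentration(raw, 0.5, 0.45, 0.05))
})

test_that("Cr referencing divides and guards zero creatine", {
  expect_identical(cr_referenced(1, 1), 1)
  expect_equal(cr_referenced(8.2, 7.5), 8.2 / 7.5, tolerance = 1e-12)
  expect_error(cr_referenced(1, 0), "positive")
})

test_that("QC boundaries: linewidth strictly above 15, SNR at or below 30", {
  p <- rbind(panel_row("s1", conc = 0.20, linewidth = 15.0),
             panel_row("s2", conc = 0.21, linewidth = 15.01),
             panel_row("s3", conc = 0.22, snr = 30),
             panel_row("s4", conc = 0.23, snr = 30.1))
  out <- suppressWarnings(qc_flags(p))
  expect_equal(out$qc_flag, c(FALSE, TRUE, TRUE, FALSE))
  expect_match(out$qc_reason[2], "linewidth")
  expect_match(out$qc_reason[3], "snr")
})

test_that("the 3-SD rule flags a planted outlier and is order-independent", {
  set.seed(7)
  n <- 1000
  p <- panel_row(sprintf("s%03d", 1:n), conc = rnorm(n, 0.2, 0.01))
  p$conc_mM[500] <- 0.2 + 5 * 0.01  # 5-SD excursion
  out <- qc_flags(p)
  expect_true(out$qc_flag[500])
  expect_lt(sum(out$qc_flag), 10)  # only genuine tail values
  # order independence / idempotence
  perm <- sample(n)
  out2 <- qc_flags(p[perm, ])
  expect_equal(out2$qc_flag[order(perm)], out$qc_flag)
  expect_equal(qc_flags(out[, names(p)])$qc_flag, out$qc_flag)
})

test_that("3-SD rule is skipped with a warning on tiny groups", {
  p <- rbind(panel_row("s1", conc = 0.2), panel_row("s2", conc = 0.9))
  expect_warning(qc_flags(p), "fewer than 3")
})

test_that("delta features reproduce the change arithmetic", {
  mk <- function(pre, posts) {
    rbind(panel_row("s1", "pre", conc = pre),
          do.call(rbind, lapply(seq_along(posts), function(i) {
            panel_row("s1", paste0("post", c(0, 10, 20, 30)[i]),
                      conc = posts[i])
          })))
  }
  # constant factor (same fractions everywhere) so raw-scale arithmetic
  # carries over to corrected values
  fac <- tissue_correction_factor(0.55, 0.40, 0.05)
  d <- suppressWarnings(delta_features(mk(8 / fac, c(9, 9, 9, 9) / fac)))
  expect_equal(d$immediate_change, 1, tolerance = 1e-9)
  expect_equal(d$change_30min, 1, tolerance = 1e-9)
  expect_equal(d$averaged_change, 1, tolerance = 1e-9)
  d2 <- suppressWarnings(delta_features(mk(8 / fac, c(9, 8, 7, 8) / fac)))
  expect_equal(d2$immediate_change, 1, tolerance = 1e-9)
  expect_equal(d2$change_30min, 0, tolerance = 1e-9)
  expect_equal(d2$averaged_change, 0, tolerance = 1e-9)
  # averaged change lies between the extreme single-scan changes
  expect_gte(d2$averaged_change, -1)
  expect_lte(d2$averaged_change, 1)
})

test_that("subjects without a usable baseline are dropped with a warning", {
  p <- rbind(panel_row("s1", "post0"), panel_row("s1", "post30"),
             panel_row("s2", "pre"), panel_row("s2", "post0"),
             panel_row("s2", "post30"))
  expect_warning(d <- delta_features(suppressWarnings(qc_flags(p))), "dropped")
  expect_equal(d$subject_id, "s2")
})

test_that("flagged post scans are excluded from the averaged change", {
  fac <- tissue_correction_factor(0.55, 0.40, 0.05)
  p <- rbind(panel_row("s1", "pre", conc = 8 / fac),
             panel_row("s1", "post0", conc = 9 / fac),
             panel_row("s1", "post30", conc = 20 / fac, linewidth = 16))
  d <- suppressWarnings(delta_features(suppressWarnings(qc_flags(p))))
  expect_equal(d$averaged_change, 1, tolerance = 1e-9)  # bad scan ignored
  expect_true(is.na(d$change_30min))
  expect_equal(d$n_post_used, 1)
})
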