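# Independent oracles and small fixtures used across the suite.

# Brute-force ILC: double loop over voxel pairs within the truncation
# radius, plain cor() per pair.
naive_ilc <- function(run, kernel_mm = 1) {
  d <- dim(run$data)
  out <- array(NA_real_, d[1:3])
  vs <- run$voxel_size
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    ts1 <- run$data[x, y, z, ]
    num <- 0; den <- 0
    for (u in 1:d[1]) for (v in 1:d[2]) for (w in 1:d[3]) {
      if (u == x && v == y && w == z) next
      dist <- sqrt(sum((c(u, v, w) - c(x, y, z))^2)) * vs
      if (dist > 3 * kernel_mm) next
      wt <- exp(-dist^2 / (2 * kernel_mm^2))
      ts2 <- run$data[u, v, w, ]
      cc <- if (sd(ts1) == 0 || sd(ts2) == 0) 0 else cor(ts1, ts2)
      num <- num + wt * cc
      den <- den + wt
    }
    out[x, y, z] <- if (den > 0) num / den else 0
  }
  out
}

# Brute-force sequence count: greedy leftmost non-overlapping substring scan.
brute_score <- function(keys, target = c(4, 1, 3, 2, 4)) {
  if (is.character(keys)) keys <- as.integer(strsplit(keys, "")[[1]])
  m <- length(target)
  n <- length(keys)
  count <- 0L
  i <- 1L
  while (i + m - 1L <= n) {
    if (all(keys[i:(i + m - 1L)] == target)) {
      count <- count + 1L
      i <- i + m
    } else i <- i + 1L
  }
  count
}

# Partial correlation via precision-matrix (covariance inversion) identity.
precision_partial_r <- function(x, y, Z = NULL) {
  M <- cbind(x = x, y = y, Z)
  P <- solve(stats::cov(M))
  -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
}

# Null data drawn from the random-intercept + random-slope model itself.
lmm_null_data <- function(seed, n1 = 36, n2 = 21, ntp = 6, sd_b0 = 0.6,
                          sd_b1 = 0.2, sd_e = 0.3, interaction = 0) {
  set.seed(seed)
  n <- n1 + n2
  id <- rep(seq_len(n), each = ntp)
  tp <- rep(seq_len(ntp), n)
  ts <- as.numeric(scale(tp))
  grp <- rep(c("Learning", "Control"), c(n1, n2))[id]
  b0 <- rnorm(n, 0, sd_b0)[id]
  b1 <- rnorm(n, 0, sd_b1)[id]
  y <- 9 + b0 + b1 * ts + interaction * (grp == "Learning") * ts +
    rnorm(n * ntp, 0, sd_e)
  data.frame(subject_id = id, group = grp,
             timepoint = c("pre", "post0", "post10", "post20", "post30",
                           "day2")[tp],
             conc_corrected = y)
}

# Small-cohort configs used by many tests.
tiny_cohort <- function(seed, n_learning = 8, n_control = 5) {
  cohort_config(n_learning = n_learning, n_control = n_control,
                grid_shape = c(8, 8, 8), n_volumes_rest = 60, tr = 2,
                master_seed = seed)
}

# Minimal metabolite panel builder for QC / delta tests.
panel_row <- function(subject_id = "s1", timepoint = "pre",
                      metabolite = "Glu", conc = 0.22, snr = 50,
                      linewidth = 10, f = c(0.55, 0.40, 0.05),
                      group = "Learning") {
  data.frame(subject_id = subject_id, group = group, timepoint = timepoint,
             metabolite = metabolite, conc_mM = conc, crlb_pct = 3,
             snr = snr, linewidth_hz = linewidth,
             f_gm = f[1], f_wm = f[2], f_csf = f[3],
             stringsAsFactors = FALSE)
}
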