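#' @title Statistical battery
#' @description Repeated-measures mixed models, excitation-inhibition
#'   coupling change, partial correlations with covariate adjustment,
#'   comparisons of dependent and independent correlations, within-family
#'   Benjamini-Hochberg FDR, and the interquartile-range outlier rule.
#' @name stats_battery
NULL

#' Partial Pearson correlation with controls and covariates
#'
#' Residual-based partial correlation: both variables are residualized
#' (with intercept) on the union of control variables and covariates, and
#' the Pearson correlation of the residuals is returned. Controls and
#' covariates are treated identically in the algebra; the two arguments
#' exist to keep the scientific roles (e.g. "the other metabolite" vs
#' "day-1 performance") explicit in reported results. Degrees of freedom
#' are n - 2 - (number of controls + covariates).
#'
#' @param x,y numeric vectors.
#' @param controls,covariates NULL, a numeric vector, or a data.frame /
#'   matrix of numeric columns.
#' @param tail "two.sided" (default), "greater" or "less".
#' @return object of class \code{corr_result}: list with \code{r},
#'   \code{df}, \code{statistic}, \code{p}, \code{n}, \code{tail},
#'   \code{controls}, \code{covariates}.
#' @export
partial_correlation <- function(x, y, controls = NULL, covariates = NULL,
                                tail = c("two.sided", "greater", "less")) {
  tail <- match.arg(tail)
  as_mat <- function(v, nm) {
    if (is.null(v)) return(NULL)
    m <- as.matrix(as.data.frame(v))
    if (is.null(colnames(m)) || any(colnames(m) == "")) {
      colnames(m) <- paste0(nm, seq_len(ncol(m)))
    }
    m
  }
  C <- as_mat(controls, "control")
  V <- as_mat(covariates, "covariate")
  Z <- cbind(C, V)
  keep <- stats::complete.cases(x, y, if (is.null(Z)) rep(TRUE, length(x)) else Z)
  x <- x[keep]; y <- y[keep]
  if (!is.null(Z)) Z <- Z[keep, , drop = FALSE]
  n <- length(x)
  k <- if (is.null(Z)) 0L else ncol(Z)
  if (n <= 2 + k) stop("not enough complete observations (n must exceed 2 + #controls)")

  if (k > 0) {
    X <- cbind(`(Intercept)` = 1, Z)
    qx <- qr(X)
    if (qx$rank < ncol(X)) {
      bad <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
      stop("collinear control/covariate columns: ", paste(bad, collapse = ", "))
    }
    rx <- stats::resid(stats::lm.fit(X, x))
    ry <- stats::resid(stats::lm.fit(X, y))
  } else {
    rx <- x - mean(x)
    ry <- y - mean(y)
  }
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    stop("residual variance is zero; correlation undefined")
  }
  r <- stats::cor(rx, ry)
  df <- n - 2L - k
  tstat <- r * sqrt(df / (1 - r^2))
  p <- switch(tail,
              two.sided = 2 * stats::pt(abs(tstat), df, lower.tail = FALSE),
              greater = stats::pt(tstat, df, lower.tail = FALSE),
              less = stats::pt(tstat, df))
  structure(list(r = r, df = df, statistic = tstat, p = p, n = n, tail = tail,
                 controls = colnames(C), covariates = colnames(V)),
            class = "corr_result")
}

#' @export
print.corr_result <- function(x, ...) {
  cat(sprintf("partial r = %.4f, df = %d, p = %.4g (%s)\n",
              x$r, x$df, x$p, x$tail))
  if (length(x$controls)) cat(" controls:", paste(x$controls, collapse = ", "), "\n")
  if (length(x$covariates)) cat(" covariates:", paste(x$covariates, collapse = ", "), "\n")
  invisible(x)
}

#' Compare two correlations from independent samples
#'
#' Fisher r-to-z comparison: \code{Z = (atanh(r1) - atanh(r2)) /
#' sqrt(1/(n1-3) + 1/(n2-3))}, with a two-sided p-value.
#'
#' @param r1,r2 correlations (strictly inside (-1, 1)).
#' @param n1,n2 sample sizes (> 3).
#' @return list with \code{Z} and \code{p}.
#' @export
compare_correlations_independent <- function(r1, n1, r2, n2) {
  if (any(abs(c(r1, r2)) >= 1)) stop("correlations must be strictly inside (-1, 1)")
  if (n1 <= 3 || n2 <= 3) stop("both sample sizes must exceed 3")
  Z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(Z = Z, p = 2 * stats::pnorm(abs(Z), lower.tail = FALSE))
}

# Steiger (1980) asymptotic covariance of two sample correlations sharing
# the variable set {j,k} x {h,m} (Pearson-Filon), on the r scale times n.
.psi_nonoverlap <- function(rjk, rhm, rjh, rjm, rkh, rkm) {
  0.5 * rjk * rhm * (rjh^2 + rjm^2 + rkh^2 + rkm^2) +
    rjh * rkm + rjm * rkh -
    (rjk * rjh * rjm + rjk * rkh * rkm + rhm * rjh * rkh + rhm * rjm * rkm)
}

#' Compare two dependent overlapping correlations (Steiger's Z)
#'
#' Tests r(x,y) against r(x,z) measured on the same n subjects (the two
#' correlations share variable x), using Fisher z transforms and the
#' Pearson-Filon/Steiger asymptotic covariance.
#'
#' @param r_xy,r_xz the two correlations being compared.
#' @param r_yz the correlation between the non-shared variables.
#' @param n sample size.
#' @return list with \code{Z} and two-sided \code{p}.
#' @export
compare_correlations_dependent <- function(r_xy, r_xz, r_yz, n) {
  R <- matrix(c(1, r_xy, r_xz,
                r_xy, 1, r_yz,
                r_xz, r_yz, 1), 3, 3)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-12) stop("correlation triplet is not positive definite")
  if (n <= 3) stop("n must exceed 3")
  # psi for r_xy vs r_xz: overlapping case (shared index x)
  psi <- r_yz * (1 - r_xy^2 - r_xz^2) -
    0.5 * r_xy * r_xz * (1 - r_xy^2 - r_xz^2 - r_yz^2)
  c_z <- psi / ((1 - r_xy^2) * (1 - r_xz^2))
  Z <- (atanh(r_xy) - atanh(r_xz)) * sqrt((n - 3) / (2 - 2 * c_z))
  list(Z = Z, p = 2 * stats::pnorm(abs(Z), lower.tail = FALSE))
}

#' Compare two dependent non-overlapping correlations
#'
#' Tests r(x1,y1) against r(x2,y2) measured on the same subjects with no
#' shared variable (e.g. the Glu-GABA correlation before vs after
#' learning), using Fisher z transforms with the Pearson-Filon covariance
#' (the Raghunathan-Rosenthal-Rubin style test).
#'
#' @param r12,r34 the two correlations being compared (variables 1,2 and
#'   3,4).
#' @param r13,r14,r23,r24 the four cross correlations.
#' @param n sample size.
#' @return list with \code{Z} and two-sided \code{p}.
#' @export
compare_correlations_nonoverlapping <- function(r12, r34, r13, r14, r23, r24, n) {
  if (n <= 3) stop("n must exceed 3")
  psi <- .psi_nonoverlap(r12, r34, r13, r14, r23, r24)
  c_z <- psi / ((1 - r12^2) * (1 - r34^2))
  c_z <- max(min(c_z, 0.999), -0.999)
  Z <- (atanh(r12) - atanh(r34)) * sqrt((n - 3) / (2 - 2 * c_z))
  list(Z = Z, p = 2 * stats::pnorm(abs(Z), lower.tail = FALSE))
}

#' Change in excitation-inhibition coupling after learning
#'
#' Correlates Glu and GABA levels across subjects at baseline and over the
#' averaged post-learning period, and tests whether the coupling changed
#' using the dependent non-overlapping r-to-z comparison (the same
#' subjects contribute both correlations).
#'
#' @param pre_glu,pre_gaba baseline concentrations across subjects.
#' @param post_glu_avg,post_gaba_avg averaged post-period concentrations.
#' @return list with \code{r_pre}, \code{r_post}, \code{Z}, \code{p},
#'   \code{n}.
#' @export
coupling_change <- function(pre_glu, pre_gaba, post_glu_avg, post_gaba_avg) {
  keep <- stats::complete.cases(pre_glu, pre_gaba, post_glu_avg, post_gaba_avg)
  x1 <- pre_glu[keep]; x2 <- pre_gaba[keep]
  x3 <- post_glu_avg[keep]; x4 <- post_gaba_avg[keep]
  n <- length(x1)
  if (n < 5) stop("need at least 5 complete subject pairs")
  r_pre <- stats::cor(x1, x2); r_post <- stats::cor(x3, x4)
  # post coupling is variable pair (1,2) so that Z > 0 means increased
  # coupling after learning
  cmp <- compare_correlations_nonoverlapping(
    r_post, r_pre,
    r13 = stats::cor(x3, x1), r14 = stats::cor(x3, x2),
    r23 = stats::cor(x4, x1), r24 = stats::cor(x4, x2), n = n)
  list(r_pre = r_pre, r_post = r_post, Z = cmp$Z, p = cmp$p, n = n)
}

#' Benjamini-Hochberg FDR within hypothesis families
#'
#' Step-up BH adjustment computed independently within each family of
#' tests. With a single family this is the ordinary BH procedure; q-values
#' are monotone and never smaller than their p-values.
#'
#' @param p_values numeric vector of p-values in [0, 1].
#' @param family_labels optional vector assigning each p-value to a
#'   family; NULL treats all p-values as one family.
#' @return numeric vector of q-values, same order as the input.
#' @export
bh_fdr <- function(p_values, family_labels = NULL) {
  if (any(!is.na(p_values) & (p_values < 0 | p_values > 1))) {
    stop("p-values must lie in [0, 1]")
  }
  if (is.null(family_labels)) family_labels <- rep("all", length(p_values))
  stopifnot(length(family_labels) == length(p_values))
  q <- rep(NA_real_, length(p_values))
  for (fam in unique(family_labels)) {
    idx <- which(family_labels == fam & !is.na(p_values))
    m <- length(idx)
    if (m == 0) next
    p <- p_values[idx]
    o <- order(p, decreasing = TRUE)
    ro <- order(o)
    q[idx] <- pmin(1, cummin(p[o] * m / (m - seq_len(m) + 1L)))[ro]
  }
  q
}

#' Interquartile-range outlier mask
#'
#' Flags values more than \code{k} times the IQR below the first quartile
#' or above the third quartile, with linear-interpolation quantiles
#' (type 7). Strict inequalities, so constant data flags nothing.
#'
#' @param values numeric vector (at least 4 finite values).
#' @param k fence multiplier (default 3).
#' @return logical mask, TRUE for outliers (NA values are never flagged).
#' @export
iqr_outliers <- function(values, k = 3) {
  if (sum(is.finite(values)) < 4) stop("need at least 4 finite values")
  qs <- stats::quantile(values, c(0.25, 0.75), na.rm = TRUE, names = FALSE, type = 7)
  iqr <- qs[2] - qs[1]
  out <- values < qs[1] - k * iqr | values > qs[2] + k * iqr
  out[is.na(out)] <- FALSE
  out
}

#' Repeated-measures mixed model of metabolite dynamics
#'
#' Fits the random-intercept and random-slope model
#' \code{value ~ Time * Group + (time | ID)} by REML (time enters the
#' random part as a scaled continuous term, and the fixed part as a
#' categorical factor), and reports Type-III F tests with Satterthwaite
#' denominator degrees of freedom plus FDR-corrected post-hoc pairwise
#' time-point contrasts (averaged over groups). A singular random-effects
#' fit triggers a refit with random intercepts only, with a warning.
#'
#' @param panel long data.frame with columns \code{subject_id},
#'   \code{group}, \code{timepoint} and the dependent variable.
#' @param dv name of the dependent-variable column.
#' @param timepoints ordering of the time factor.
#' @return list with \code{anova} (Time, Group, Time:Group rows),
#'   \code{posthoc} (pairwise time contrasts with q-values),
#'   \code{singular}, and the fitted model \code{fit}.
#' @export
fit_time_group_lmm <- function(panel, dv = "conc_corrected",
                               timepoints = .TIMEPOINTS) {
  stopifnot(all(c("subject_id", "group", "timepoint") %in% names(panel)),
            dv %in% names(panel))
  d <- data.frame(
    y = panel[[dv]],
    time = factor(panel$timepoint, levels = intersect(timepoints, unique(panel$timepoint))),
    group = factor(panel$group),
    id = factor(panel$subject_id)
  )
  d <- d[stats::complete.cases(d), ]
  if (nlevels(droplevels(d$time)) < 2) stop("need at least 2 time points")
  if (nlevels(droplevels(d$group)) < 2) stop("both groups must be present")
  if (stats::sd(d$y) == 0) stop("degenerate fit: dependent variable is constant")
  d$time_s <- as.numeric(scale(as.integer(d$time)))

  fit <- suppressMessages(suppressWarnings(
    lmerTest::lmer(y ~ time * group + (1 + time_s | id), data = d,
                   control = lme4::lmerControl(calc.derivs = FALSE))
  ))
  singular <- lme4::isSingular(fit, tol = 1e-4)
  if (singular) {
    warning("singular random-effects fit; refitting with random intercepts only")
    fit <- suppressMessages(suppressWarnings(
      lmerTest::lmer(y ~ time * group + (1 | id), data = d,
                     control = lme4::lmerControl(calc.derivs = FALSE))
    ))
  }
  an <- as.data.frame(stats::anova(fit, type = 3, ddf = "Satterthwaite"))
  an$term <- rownames(an)

  # pairwise time contrasts averaged over groups, on the fixed-effect scale
  X <- stats::model.matrix(fit)
  tl <- levels(d$time)
  rowmean_at <- function(tp) colMeans(X[d$time == tp, , drop = FALSE])
  combs <- utils::combn(tl, 2)
  ph <- data.frame(contrast = character(0), estimate = numeric(0),
                   df = numeric(0), t = numeric(0), p = numeric(0))
  for (j in seq_len(ncol(combs))) {
    L <- rowmean_at(combs[2, j]) - rowmean_at(combs[1, j])
    ct <- lmerTest::contest1D(fit, L)
    ph <- rbind(ph, data.frame(
      contrast = paste(combs[2, j], "-", combs[1, j]),
      estimate = ct$Estimate, df = ct$df, t = ct$`t value`, p = ct$`Pr(>|t|)`))
  }
  ph$q <- bh_fdr(ph$p)
  list(anova = an, posthoc = ph, singular = singular, fit = fit)
}
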