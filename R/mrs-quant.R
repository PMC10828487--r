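#' @title Tissue-corrected MRS quantification
#' @description Functions that turn water-scaled LCModel-style metabolite
#'   estimates plus voxel tissue fractions into tissue-corrected
#'   concentrations, apply quality-control exclusion rules, and derive the
#'   post-learning change features used by the correlation battery.
#' @name mrs_quant
NULL

# Water concentrations (molar) assumed per tissue class; metabolites are
# assumed absent from CSF, hence the 1 - f_csf renormalization.
.WATER_GM  <- 43.3
.WATER_WM  <- 35.88
.WATER_CSF <- 5.556

.TIMEPOINTS <- c("pre", "post0", "post10", "post20", "post30", "day2")
.POST_TIMEPOINTS <- c("post0", "post10", "post20", "post30")
.METABOLITES <- c("Glu", "GABA", "NAA", "Gln", "Cr")

#' Tissue correction factor for a single-voxel MRS measurement
#'
#' Computes the multiplicative water-scaling factor for a voxel with the
#' given gray matter, white matter and CSF fractions, assuming water
#' concentrations of 43.3 M in GM, 35.88 M in WM and 5.556 M in CSF, no
#' metabolites in CSF, a single T2 regime for GM and WM, and no T1
#' correction (long-TR acquisition):
#' \deqn{factor = (f_{gm} 43.3 + f_{wm} 35.88 + f_{csf} 5.556) / (1 - f_{csf})}
#'
#' @param f_gm,f_wm,f_csf tissue fractions; must be non-negative and sum to
#'   1 (within 1e-6). Vectorized.
#' @return numeric factor on the molar scale.
#' @examples
#' tissue_correction_factor(1, 0, 0)        # 43.3
#' tissue_correction_factor(0.4, 0.4, 0.2)  # 40.979
#' @export
tissue_correction_factor <- function(f_gm, f_wm, f_csf) {
  if (any(f_gm < 0 | f_wm < 0 | f_csf < 0)) {
    stop("tissue fractions must be non-negative")
  }
  if (any(abs(f_gm + f_wm + f_csf - 1) > 1e-6)) {
    stop("tissue fractions must sum to 1 (within 1e-6)")
  }
  if (any(f_csf >= 1 - 1e-9)) {
    stop("degenerate voxel: CSF fraction is (numerically) 1, no tissue signal")
  }
  (f_gm * .WATER_GM + f_wm * .WATER_WM + f_csf * .WATER_CSF) / (1 - f_csf)
}

#' Tissue-correct a water-scaled metabolite estimate
#'
#' Multiplies the raw water-scaled ratio by the voxel's tissue correction
#' factor, yielding a concentration on the mM scale. Linear in the raw
#' value.
#'
#' @param raw water-scaled metabolite estimate (unitless ratio).
#' @param f_gm,f_wm,f_csf voxel tissue fractions.
#' @return tissue-corrected concentration (mM scale).
#' @export
correct_concentration <- function(raw, f_gm, f_wm, f_csf) {
  raw * tissue_correction_factor(f_gm, f_wm, f_csf)
}

#' Creatine-referenced metabolite measure
#'
#' @param metabolite_value metabolite estimate (any consistent scale).
#' @param cr_value creatine estimate on the same scale; must be positive.
#' @return dimensionless metabolite/Cr ratio.
#' @export
cr_referenced <- function(metabolite_value, cr_value) {
  if (any(cr_value <= 0)) stop("cr_value must be positive")
  metabolite_value / cr_value
}

#' Quality-control flags for a metabolite panel
#'
#' Flags measurements that fail any of three rules: concentration more than
#' 3 standard deviations from the mean of all time-point measurements of
#' that metabolite (pooled over subjects and time points, by default within
#' group), water linewidth exceeding 15 Hz FWHM, or SNR of 30 or less.
#' Flagged rows are excluded downstream but retained here as an audit
#' table. The 3-SD rule operates on the tissue-corrected concentration so
#' that between-voxel composition differences do not masquerade as
#' outliers. CRLB is carried along for reporting but is not an exclusion
#' criterion.
#'
#' @param panel data.frame with columns \code{subject_id}, \code{group},
#'   \code{timepoint}, \code{metabolite}, \code{conc_mM} (water-scaled
#'   estimate), \code{crlb_pct}, \code{snr}, \code{linewidth_hz},
#'   \code{f_gm}, \code{f_wm}, \code{f_csf}.
#' @param group_pooled if TRUE, the 3-SD rule pools both groups; the
#'   default computes thresholds within group.
#' @param linewidth_max linewidth threshold in Hz (flag if strictly above).
#' @param snr_min SNR threshold (flag if less than or equal).
#' @param sd_mult multiplier for the SD rule.
#' @return the panel with added columns \code{conc_corrected},
#'   \code{qc_flag} (logical) and \code{qc_reason} (string, "" if kept).
#' @export
qc_flags <- function(panel, group_pooled = FALSE, linewidth_max = 15,
                     snr_min = 30, sd_mult = 3) {
  stopifnot(is.data.frame(panel), nrow(panel) > 0)
  need <- c("subject_id", "metabolite", "conc_mM", "snr", "linewidth_hz",
            "f_gm", "f_wm", "f_csf")
  miss <- setdiff(need, names(panel))
  if (length(miss)) stop("panel is missing columns: ", paste(miss, collapse = ", "))

  out <- panel
  out$conc_corrected <- correct_concentration(panel$conc_mM, panel$f_gm,
                                              panel$f_wm, panel$f_csf)
  reason <- character(nrow(out))
  lw <- out$linewidth_hz > linewidth_max
  reason[lw] <- paste0(reason[lw], "linewidth>", linewidth_max, "Hz;")
  sn <- out$snr <= snr_min
  reason[sn] <- paste0(reason[sn], "snr<=", snr_min, ";")

  grp <- if (group_pooled || is.null(out$group)) rep("all", nrow(out)) else out$group
  key <- interaction(out$metabolite, grp, drop = TRUE)
  for (k in levels(key)) {
    idx <- which(key == k)
    v <- out$conc_corrected[idx]
    if (sum(is.finite(v)) < 3) {
      warning("fewer than 3 values for ", k, "; 3-SD rule skipped")
      next
    }
    m <- mean(v, na.rm = TRUE)
    s <- stats::sd(v, na.rm = TRUE)
    if (!is.finite(s) || s == 0) next
    bad <- idx[abs(v - m) > sd_mult * s]
    reason[bad] <- paste0(reason[bad], sd_mult, "SD;")
  }
  out$qc_flag <- reason != ""
  out$qc_reason <- reason
  out
}

#' Post-learning metabolite change features
#'
#' Derives, per subject and metabolite, the immediate change (first post
#' scan minus baseline), the 30-minute change (last post scan minus
#' baseline), the averaged change (mean of the unflagged post scans minus
#' baseline) and the day-2 overnight level, using tissue-corrected
#' concentrations from QC-passed measurements only. Subjects missing an
#' unflagged baseline for a metabolite are dropped from that metabolite's
#' delta table with a warning.
#'
#' @param panel a metabolite panel; if it lacks QC columns,
#'   \code{\link{qc_flags}} is applied first with default settings.
#' @param value_col which value to difference: "conc_corrected" (default),
#'   "conc_mM" (no tissue correction), or "cr_ratio" (Cr-referenced; the
#'   ratio is formed per subject and time point before differencing).
#' @return data.frame with columns \code{subject_id}, \code{group},
#'   \code{metabolite}, \code{pre}, \code{immediate_change},
#'   \code{change_30min}, \code{averaged_change}, \code{overnight_level},
#'   \code{n_post_used}.
#' @export
delta_features <- function(panel, value_col = c("conc_corrected", "conc_mM",
                                                "cr_ratio")) {
  value_col <- match.arg(value_col)
  if (is.null(panel$qc_flag)) panel <- qc_flags(panel)
  if (value_col == "cr_ratio") {
    cr <- panel[panel$metabolite == "Cr", c("subject_id", "timepoint", "conc_mM")]
    names(cr)[3] <- "cr_raw"
    panel <- merge(panel, cr, by = c("subject_id", "timepoint"), sort = FALSE)
    panel$value <- cr_referenced(panel$conc_mM, panel$cr_raw)
    panel <- panel[panel$metabolite != "Cr", ]
  } else {
    panel$value <- panel[[value_col]]
  }
  ok <- panel[!panel$qc_flag, ]

  # wide layout: one row per subject x metabolite, one column per time point
  tps <- unique(panel$timepoint)
  posts <- tps[startsWith(tps, "post")]
  posts <- posts[order(as.numeric(sub("post", "", posts)))]
  if (!"pre" %in% tps || !length(posts)) {
    stop("panel must contain a pre time point and at least one post scan")
  }
  key <- paste(ok$subject_id, ok$metabolite, sep = "\r")
  ukey <- unique(key)
  ki <- match(key, ukey)
  ti <- match(ok$timepoint, tps)
  W <- matrix(NA_real_, length(ukey), length(tps),
              dimnames = list(NULL, tps))
  W[cbind(ki, ti)] <- ok$value
  first <- match(ukey, key)

  pre <- W[, "pre"]
  PW <- W[, posts, drop = FALSE]
  n_post_used <- rowSums(!is.na(PW))
  keep <- is.finite(pre) & n_post_used > 0
  dropped <- sum(!keep)
  if (dropped > 0) {
    warning(dropped, " subject x metabolite series dropped ",
            "(missing usable baseline or all post scans flagged)")
  }
  if (!any(keep)) stop("no subject had a usable baseline and post scan")
  out <- data.frame(
    subject_id = ok$subject_id[first],
    group = if (!is.null(ok$group)) ok$group[first] else NA_character_,
    metabolite = ok$metabolite[first],
    pre = pre,
    immediate_change = PW[, 1] - pre,
    change_30min = PW[, length(posts)] - pre,
    averaged_change = rowMeans(PW, na.rm = TRUE) - pre,
    overnight_level = if ("day2" %in% tps) W[, "day2"] else NA_real_,
    n_post_used = n_post_used,
    stringsAsFactors = FALSE
  )[keep, ]
  rownames(out) <- NULL
  out
}
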