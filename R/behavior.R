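#' @title Motor sequence learning behavior
#' @description Scoring of key-press streams from the five-digit tapping
#'   task (4-1-3-2-4), segmentation of the practice session into early and
#'   late learning phases, and overnight offline gains.
#' @name behavior
NULL

.TARGET_SEQ <- c(4L, 1L, 3L, 2L, 4L)

# KMP failure function: fail[i] = length of the longest proper prefix of
# target[1..i] that is also a suffix of it.
.kmp_failure <- function(target) {
  m <- length(target)
  fail <- integer(m)
  k <- 0L
  for (i in 2:m) {
    while (k > 0L && target[k + 1L] != target[i]) k <- fail[k]
    if (target[k + 1L] == target[i]) k <- k + 1L
    fail[i] <- k
  }
  fail
}

#' Score a key-press stream
#'
#' Counts the number of correct target sequences completed in a stream of
#' key presses by a single left-to-right scan. The default scanner advances
#' a cursor through the target on each matching press and, on a mismatch,
#' resets the cursor to the longest viable restart position (the
#' Knuth-Morris-Pratt failure function), so a stray press does not erase a
#' partially correct continuation. Completed sequences are counted
#' non-overlapping: after a completion the cursor returns to the start.
#' With \code{strict_reset = TRUE} a mismatching press instead resets the
#' cursor to the start outright (the mismatching press itself is not
#' reconsidered as the start of a new attempt).
#'
#' @param keystream either a string such as "41324" or an integer vector of
#'   presses; symbols must be in 1..4.
#' @param target_sequence integer vector, default \code{c(4,1,3,2,4)}.
#' @param strict_reset use the full-reset mismatch rule.
#' @return list with \code{n_correct} and \code{n_keypresses}.
#' @examples
#' score_block("41324")$n_correct      # 1
#' score_block("4132441324")$n_correct # 2
#' @export
score_block <- function(keystream, target_sequence = .TARGET_SEQ,
                        strict_reset = FALSE) {
  keys <- parse_keystream(keystream)
  if (length(keys) && (any(is.na(keys)) || any(!keys %in% 1:4))) {
    stop("invalid key symbol: presses must be in {1,2,3,4}")
  }
  m <- length(target_sequence)
  fail <- .kmp_failure(target_sequence)
  state <- 0L
  n_correct <- 0L
  for (key in keys) {
    if (strict_reset) {
      state <- if (target_sequence[state + 1L] == key) state + 1L else 0L
    } else {
      while (state > 0L && target_sequence[state + 1L] != key) state <- fail[state]
      if (target_sequence[state + 1L] == key) state <- state + 1L
    }
    if (state == m) {
      n_correct <- n_correct + 1L
      state <- 0L  # non-overlapping count
    }
  }
  list(n_correct = n_correct, n_keypresses = length(keys))
}

#' @rdname score_block
#' @export
parse_keystream <- function(keystream) {
  if (is.character(keystream)) {
    stopifnot(length(keystream) == 1)
    if (!nzchar(keystream)) return(integer(0))
    as.integer(strsplit(keystream, "")[[1]])
  } else {
    as.integer(keystream)
  }
}

#' Score every block of a behavior table
#'
#' @param behavior data.frame with columns \code{subject_id}, \code{day},
#'   \code{block}, \code{keystream}.
#' @param ... passed to \code{\link{score_block}}.
#' @return data.frame of block scores (\code{n_correct},
#'   \code{n_keypresses} appended).
#' @export
score_blocks <- function(behavior, ...) {
  stopifnot(all(c("subject_id", "day", "block", "keystream") %in% names(behavior)))
  sc <- lapply(behavior$keystream, score_block, ...)
  behavior$n_correct <- vapply(sc, `[[`, integer(1), "n_correct")
  behavior$n_keypresses <- vapply(sc, `[[`, integer(1), "n_keypresses")
  behavior
}

#' Segment a practice session into early and late learning phases
#'
#' Fits a random-intercept and random-slope linear mixed model of correct
#' sequence count on practice block (block as a categorical fixed effect,
#' a scaled continuous block term in the random part), then performs
#' uncorrected pairwise comparisons between consecutive blocks. The late
#' phase starts at the first block from which no block-to-block change is
#' significant at \code{alpha}: the boundary is the smallest block b >= 2
#' such that the contrasts (b-1 to b) through (n-1 to n) all have p >=
#' alpha. If even the final contrast is significant the session has no
#' plateau and the boundary is n+1 (flagged). If the mixed model fails to
#' converge the contrasts fall back to paired t-tests with a warning.
#'
#' @param block_scores data.frame with columns \code{subject_id},
#'   \code{block}, \code{n_correct} for a single day and group.
#' @param alpha significance level for the consecutive contrasts.
#' @return list with \code{boundary}, \code{early}, \code{late},
#'   \code{no_plateau}, \code{contrasts} (data.frame), \code{method}.
#' @export
segment_phases <- function(block_scores, alpha = 0.05) {
  stopifnot(all(c("subject_id", "block", "n_correct") %in% names(block_scores)))
  blocks <- sort(unique(block_scores$block))
  n_blocks <- length(blocks)
  if (n_blocks < 3) stop("need at least 3 blocks to segment phases")
  if (length(unique(block_scores$subject_id)) < 5) {
    stop("need at least 5 subjects to segment phases")
  }

  d <- block_scores
  d$blockf <- factor(d$block, levels = blocks)
  d$block_s <- as.numeric(scale(d$block))
  d$id <- factor(d$subject_id)

  pvals <- rep(NA_real_, n_blocks - 1L)
  est <- rep(NA_real_, n_blocks - 1L)
  method <- "lmm"
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lmerTest::lmer(n_correct ~ blockf + (1 + block_s | id), data = d,
                     control = lme4::lmerControl(calc.derivs = FALSE))
    )),
    error = function(e) NULL
  )
  if (!is.null(fit)) {
    cf <- lme4::fixef(fit)
    p <- length(cf)
    for (i in seq_len(n_blocks - 1L)) {
      # contrast: block i+1 minus block i under treatment coding
      L <- numeric(p)
      if (i + 1L <= n_blocks) L[i + 1L] <- 1   # coef of blockf level i+1
      if (i >= 2L) L[i] <- -1                  # minus level i (absent for i=1)
      ct <- tryCatch(lmerTest::contest1D(fit, L), error = function(e) NULL)
      if (is.null(ct)) next
      est[i] <- ct$Estimate
      pvals[i] <- ct$`Pr(>|t|)`
    }
  }
  if (is.null(fit) || anyNA(pvals)) {
    warning("mixed model unavailable or non-converged; ",
            "falling back to paired t-tests between consecutive blocks")
    method <- "paired-t"
    wide <- tapply(block_scores$n_correct,
                   list(block_scores$subject_id, block_scores$block), mean)
    for (i in seq_len(n_blocks - 1L)) {
      tt <- tryCatch(stats::t.test(wide[, i + 1L], wide[, i], paired = TRUE),
                     error = function(e) NULL)
      if (is.null(tt)) {  # zero-variance differences: no evidence of change
        est[i] <- mean(wide[, i + 1L] - wide[, i])
        pvals[i] <- 1
      } else {
        est[i] <- unname(tt$estimate)
        pvals[i] <- tt$p.value
      }
    }
  }
  pvals[!is.finite(pvals)] <- 1

  sig <- pvals < alpha
  # contrast i compares blocks[i] -> blocks[i+1]; boundary b requires all
  # contrasts from (b-1 -> b) onward, i.e. indices >= b-1, non-significant
  suffix_ok <- rev(cumprod(rev(!sig))) == 1
  boundary <- if (any(suffix_ok)) blocks[which(suffix_ok)[1] + 1L] else blocks[n_blocks] + 1L
  boundary <- max(boundary, blocks[2])  # earliest allowed boundary is block 2
  no_plateau <- !any(suffix_ok)
  list(
    boundary = boundary,
    early = blocks[blocks < boundary],
    late = blocks[blocks >= boundary],
    no_plateau = no_plateau,
    contrasts = data.frame(from = blocks[-n_blocks], to = blocks[-1],
                           estimate = est, p = pvals),
    method = method
  )
}

#' Overnight offline gain in skill performance
#'
#' Percent change between the last practice block on day 1 and the test
#' block on day 2: \code{100 * (day2_test - day1_last) / day1_last}.
#' Scale-invariant; undefined when the day-1 reference is zero.
#'
#' @param day1_last correct-sequence count of the last day-1 block (> 0).
#' @param day2_test correct-sequence count of the day-2 test block.
#' @return percent gain (negative for overnight decline). Vectorized.
#' @export
overnight_gain <- function(day1_last, day2_test) {
  if (any(day1_last <= 0)) {
    stop("undefined gain: day-1 reference count must be positive")
  }
  100 * (day2_test - day1_last) / day1_last
}
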