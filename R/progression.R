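#' Stage carriers from the CDR plus NACC FTLD global score
#'
#' Global score 0 or 0.5 maps to `"presymptomatic"`; 1, 2 or 3 to
#' `"symptomatic"`. Any other value is an error.
#'
#' @param clinical Data frame with `participant_id`, `cdr_global` (and
#'   optionally `visit`; only baseline rows are staged when present).
#' @return Data frame `participant_id`, `stage`.
#' @export
stage_participants <- function(clinical) {
  check_columns(clinical, c("participant_id", "cdr_global"), "clinical")
  if ("visit" %in% names(clinical))
    clinical <- clinical[clinical$visit == "baseline", , drop = FALSE]
  bad <- !clinical$cdr_global %in% c(0, 0.5, 1, 2, 3)
  if (any(bad))
    stop_wnorm("stage_participants: invalid CDR global score for: %s",
               paste(utils::head(clinical$participant_id[bad], 5),
                     collapse = ", "))
  data.frame(participant_id = clinical$participant_id,
             stage = ifelse(clinical$cdr_global < 1, "presymptomatic",
                            "symptomatic"),
             stringsAsFactors = FALSE)
}

#' Pair baseline and 12-month visits on one clinical scale
#'
#' Keeps participants with exactly one baseline and one month-12 record;
#' participants with a single visit are logged as unpaired. Duplicate
#' visit labels per participant are an error.
#'
#' @param clinical Long clinical table with `participant_id`, `visit`
#'   (`"baseline"`/`"month12"`) and the score column named by `scale`.
#' @param scale `"cdr_sb"` or `"cbi_r"`.
#' @return Data frame `participant_id`, `scale`, `baseline`, `month12`,
#'   `delta` (follow-up minus baseline, points).
#' @export
pair_visits <- function(clinical, scale = c("cdr_sb", "cbi_r")) {
  scale <- match.arg(scale)
  check_columns(clinical, c("participant_id", "visit", scale), "clinical")
  clinical <- clinical[clinical$visit %in% c("baseline", "month12"), ,
                       drop = FALSE]
  dup <- duplicated(clinical[c("participant_id", "visit")])
  if (any(dup))
    stop_wnorm("pair_visits: duplicate visit label for: %s",
               paste(utils::head(unique(clinical$participant_id[dup]), 5),
                     collapse = ", "))
  wide <- stats::reshape(clinical[c("participant_id", "visit", scale)],
                         idvar = "participant_id", timevar = "visit",
                         direction = "wide")
  b <- wide[[paste0(scale, ".baseline")]]
  f <- wide[[paste0(scale, ".month12")]]
  if (is.null(b)) b <- rep(NA_real_, nrow(wide))
  if (is.null(f)) f <- rep(NA_real_, nrow(wide))
  paired <- !is.na(b) & !is.na(f)
  if (any(!paired))
    wn_log("pair_visits: %d participant(s) unpaired (single visit)",
           sum(!paired))
  out <- data.frame(participant_id = wide$participant_id[paired],
                    scale = scale, baseline = b[paired],
                    month12 = f[paired],
                    delta = f[paired] - b[paired],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Exact Wilcoxon signed-rank test on paired differences
#'
#' Zero differences are dropped before ranking (their count is reported);
#' tied absolute differences receive midranks. For `n_used` up to
#' `exact_max_n` the p-value is exact: the null distribution of the
#' positive-rank sum is obtained over all `2^n` equally likely sign
#' assignments of the observed (possibly tied) rank vector, computed by a
#' counting recursion that is mathematically identical to full
#' enumeration. The two-sided p doubles the smaller tail (each tail
#' inclusive of the observed statistic), capped at 1. Beyond
#' `exact_max_n`, a normal approximation with tie-corrected variance is
#' used.
#'
#' @param deltas Numeric paired differences.
#' @param exact_max_n Largest `n_used` for which the exact distribution is
#'   enumerated (default 20).
#' @return List of class `wilcoxon_exact`: `statistic` (positive-rank sum
#'   W), `p.value`, `n_used`, `n_zero`, `method`. If all differences are
#'   zero, `p.value` is `NA` with `method = "not-available"` and a
#'   `reason`.
#' @examples
#' exact_wilcoxon_signed_rank(c(1, -1))$p.value       # 1 (symmetry)
#' exact_wilcoxon_signed_rank(c(1, 2, 3, 4, 5))$p.value  # 0.0625
#' @export
exact_wilcoxon_signed_rank <- function(deltas, exact_max_n = 20) {
  if (!is.numeric(deltas) || !length(deltas))
    stop_wnorm("exact_wilcoxon_signed_rank: 'deltas' must be non-empty numeric")
  if (any(!is.finite(deltas)))
    stop_wnorm("exact_wilcoxon_signed_rank: 'deltas' must be finite")
  d <- deltas[deltas != 0]
  n_zero <- length(deltas) - length(d)
  n <- length(d)
  if (n == 0L)
    return(structure(list(statistic = NA_real_, p.value = NA_real_,
                          n_used = 0L, n_zero = n_zero,
                          method = "not-available",
                          reason = "all paired differences are zero"),
                     class = "wilcoxon_exact"))
  r <- rank(abs(d))             # midranks under ties
  W <- sum(r[d > 0])
  if (n <= exact_max_n) {
    # Distribution of W over all 2^n sign assignments. Midranks are
    # multiples of 1/2, so work on doubled ranks to stay integral.
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    counts <- numeric(total + 1L)  # counts[s + 1] = #assignments with 2W = s
    counts[1L] <- 1
    for (rk in r2) {
      shifted <- c(numeric(rk), counts[seq_len(total + 1L - rk)])
      counts <- counts + shifted
    }
    w2 <- as.integer(round(2 * W))
    p_ge <- sum(counts[(w2 + 1L):(total + 1L)]) / 2^n
    p_le <- sum(counts[seq_len(w2 + 1L)]) / 2^n
    p <- min(1, 2 * min(p_ge, p_le))
    method <- "exact enumeration"
  } else {
    mu <- sum(r) / 2
    sd_w <- sqrt(sum(r^2) / 4)  # midrank variance; tie-corrected
    z <- (W - mu) / sd_w
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation (tie-corrected)"
  }
  structure(list(statistic = W, p.value = p, n_used = n, n_zero = n_zero,
                 method = method),
            class = "wilcoxon_exact")
}

#' @export
print.wilcoxon_exact <- function(x, ...) {
  cat("Exact Wilcoxon signed-rank test\n")
  if (identical(x$method, "not-available")) {
    cat(sprintf("  not available: %s\n", x$reason))
  } else {
    cat(sprintf("  W = %g, n used = %d (zeros dropped: %d)\n", x$statistic,
                x$n_used, x$n_zero))
    cat(sprintf("  two-sided p = %.6g (%s)\n", x$p.value, x$method))
  }
  invisible(x)
}

#' Smallest attainable two-sided exact signed-rank p-value
#'
#' For `n` non-zero, untied paired differences, the most extreme sign
#' assignment has one-sided probability `2^-n`, so the smallest two-sided
#' p is `min(1, 2^(1 - n))`. It first drops to 0.05 or below at n = 6
#' (0.03125); at n = 5 the floor is 0.0625, which is why comparisons on
#' fewer than 6 pairs can never reach significance at the 5% level.
#'
#' @param n Pair count(s), >= 1.
#' @return Smallest achievable two-sided p-value(s).
#' @export
min_attainable_p <- function(n) {
  if (any(!is.finite(n)) || any(n < 1) || any(n != round(n)))
    stop_wnorm("min_attainable_p: 'n' must be integer(s) >= 1")
  pmin(1, 2^(1 - n))
}

#' Progression of clinical scores by regional abnormality stratum
#'
#' Restricts to presymptomatic carriers of one gene, splits them per
#' (roi, modality) into baseline-normal and baseline-abnormal strata, and
#' compares baseline to 12-month scores within each stratum with the exact
#' Wilcoxon signed-rank test. Strata with fewer than 3 paired carriers are
#' excluded (no p-value); strata with 3-5 are tested but flagged
#' `caution_lt6`, since two-sided exact significance at the 5% level is
#' unattainable below n = 6.
#'
#' @param calls Baseline abnormality calls ([classify_wscores()] output or
#'   any data frame with `participant_id`, `roi`, `modality`, `label`).
#' @param pairs Paired changes from [pair_visits()].
#' @param participants Participant table with `participant_id`, `group`
#'   and either `stage` or `cdr_global` (baseline rows).
#' @param gene `"C9orf72"`, `"GRN"` or `"MAPT"`.
#' @param rois Optional character vector restricting the regions analysed;
#'   default: regions present in `calls` that the registry marks for
#'   progression analysis (whole structures and tracts, no subfields).
#' @param B,level,seed Bootstrap parameters for the mean-delta CI.
#' @return Data frame of class `progression_result`: `gene`, `roi`,
#'   `modality`, `stratum`, `n_pairs`, `mean_baseline`, `mean_followup`,
#'   `mean_delta`, `ci_lo`, `ci_hi`, `W`, `p_value`, `flag`
#'   (`ok` / `caution_lt6` / `excluded_lt3`).
#' @export
progression_by_roi <- function(calls, pairs, participants, gene,
                               rois = NULL, B = 1000, level = 0.95,
                               seed = NULL) {
  check_columns(calls, c("participant_id", "roi", "modality", "label"),
                "calls")
  check_columns(pairs, c("participant_id", "baseline", "month12", "delta"),
                "pairs")
  check_columns(participants, c("participant_id", "group"), "participants")
  gene <- match.arg(gene, c("C9orf72", "GRN", "MAPT"))
  if ("stage" %in% names(participants)) {
    stage <- participants[c("participant_id", "stage")]
  } else {
    stage <- stage_participants(participants)
  }
  eligible <- participants$participant_id[
    participants$group == gene &
      stage$stage[match(participants$participant_id,
                        stage$participant_id)] == "presymptomatic"]
  pr <- pairs[pairs$participant_id %in% eligible, , drop = FALSE]
  cl <- calls[calls$participant_id %in% eligible, , drop = FALSE]

  if (is.null(rois)) {
    reg <- roi_registry()
    rois <- intersect(unique(cl$roi),
                      reg$roi[reg$default_progression])
  }
  if (!length(rois)) stop_wnorm("progression_by_roi: empty ROI set")
  cl <- cl[cl$roi %in% rois, , drop = FALSE]
  cells <- unique(cl[c("roi", "modality")])
  cells <- cells[order(cells$modality, cells$roi), , drop = FALSE]

  res <- with_seed(seed, {
    rows <- list()
    for (i in seq_len(nrow(cells))) {
      for (stratum in c("normal", "abnormal")) {
        sel <- cl$roi == cells$roi[i] & cl$modality == cells$modality[i] &
          cl$label == stratum
        ids <- intersect(cl$participant_id[sel], pr$participant_id)
        d <- pr[match(ids, pr$participant_id), , drop = FALSE]
        n <- nrow(d)
        row <- data.frame(gene = gene, roi = cells$roi[i],
                          modality = cells$modality[i], stratum = stratum,
                          n_pairs = n, mean_baseline = NA_real_,
                          mean_followup = NA_real_, mean_delta = NA_real_,
                          ci_lo = NA_real_, ci_hi = NA_real_, W = NA_real_,
                          p_value = NA_real_, flag = "excluded_lt3",
                          stringsAsFactors = FALSE)
        if (n >= 3) {
          row$mean_baseline <- mean(d$baseline)
          row$mean_followup <- mean(d$month12)
          row$mean_delta <- mean(d$delta)
          ci <- bootstrap_percentile_ci(d$delta, B = B, level = level)
          row$ci_lo <- ci[["lo"]]; row$ci_hi <- ci[["hi"]]
          test <- exact_wilcoxon_signed_rank(d$delta)
          row$W <- test$statistic
          row$p_value <- test$p.value
          row$flag <- if (n < 6) "caution_lt6" else "ok"
        }
        rows[[length(rows) + 1L]] <- row
      }
    }
    do.call(rbind, rows)
  })
  rownames(res) <- NULL
  class(res) <- c("progression_result", "data.frame")
  res
}

#' @export
print.progression_result <- function(x, ...) {
  cat(sprintf("Progression by region (%s): %d strata\n",
              paste(unique(x$gene), collapse = ", "), nrow(x)))
  cat(sprintf("  excluded (n < 3): %d; caution (3 <= n < 6): %d\n",
              sum(x$flag == "excluded_lt3"), sum(x$flag == "caution_lt6")))
  sig <- !is.na(x$p_value) & x$p_value <= 0.05 & x$flag == "ok"
  cat(sprintf("  significant strata (p <= 0.05, n >= 6): %d\n", sum(sig)))
  print.data.frame(utils::head(as.data.frame(x), 10), digits = 3)
  if (nrow(x) > 10) cat(sprintf("  ... %d more row(s)\n", nrow(x) - 10))
  invisible(x)
}
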