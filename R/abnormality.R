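#' Classify a w-score as normal or abnormal
#'
#' Abnormality is one-tailed and modality-aware: grey matter volume and FA
#' degrade downward, so a w-score strictly below the (negative) cut is
#' abnormal; MD degrades upward, so a w-score strictly above the positive
#' cut is abnormal. A w-score exactly at the cut is normal. The default cut
#' is the 10th control percentile (|w| = 1.282).
#'
#' @param w Finite w-score(s).
#' @param modality `"volume"`, `"FA"` or `"MD"` (recycled or vectorised).
#' @param cut_percentile Control percentile in (0, 50) defining the cut.
#' @return Character vector `"normal"`/`"abnormal"`.
#' @examples
#' classify_wscore(-1.5, "volume")  # abnormal
#' classify_wscore(1.5, "MD")       # abnormal
#' classify_wscore(2.0, "FA")       # normal (wrong tail)
#' @export
classify_wscore <- function(w, modality, cut_percentile = 10) {
  if (any(!is.finite(w))) stop_wnorm("classify_wscore: 'w' must be finite")
  if (cut_percentile <= 0 || cut_percentile >= 50)
    stop_wnorm("classify_wscore: 'cut_percentile' must be in (0, 50)")
  known <- modality %in% c("volume", "FA", "MD")
  if (!all(known))
    stop_wnorm("classify_wscore: unknown modality: %s",
               paste(unique(modality[!known]), collapse = ", "))
  k <- max(length(w), length(modality))
  w <- rep_len(w, k)
  modality <- rep_len(modality, k)
  cut_w <- percentile_cutpoint(cut_percentile / 100)  # negative
  abn <- ifelse(modality == "MD", w > -cut_w, w < cut_w)
  ifelse(abn, "abnormal", "normal")
}

#' Classify every row of a w-score table
#'
#' @param wscores A `wscore_table` (or any data frame with
#'   `participant_id`, `roi`, `modality`, `wscore`).
#' @inheritParams classify_wscore
#' @return The input plus columns `cut_percentile`, `cut_w` (signed,
#'   direction-aware) and `label`.
#' @export
classify_wscores <- function(wscores, cut_percentile = 10) {
  check_columns(wscores, c("participant_id", "roi", "modality", "wscore"),
                "wscores")
  cut_w <- percentile_cutpoint(cut_percentile / 100)
  out <- wscores
  out$cut_percentile <- cut_percentile
  out$cut_w <- ifelse(out$modality == "MD", -cut_w, cut_w)
  out$label <- classify_wscore(out$wscore, out$modality, cut_percentile)
  out
}

#' Non-parametric percentile bootstrap CI for a mean
#'
#' Resamples the sample with replacement `B` times, takes the mean of each
#' replicate, and returns the `(1 - level)/2` and `1 - (1 - level)/2`
#' empirical percentiles of those bootstrap means. With the defaults this
#' is the 95% percentile interval from 1000 replicates.
#'
#' @param values Numeric sample of length >= 2.
#' @param B Number of bootstrap replicates (>= 1).
#' @param level Confidence level in (0, 1).
#' @param seed Integer seed or `NULL` (uses the current RNG stream).
#' @return Named numeric vector `c(lo, hi)`.
#' @export
bootstrap_percentile_ci <- function(values, B = 1000, level = 0.95,
                                    seed = NULL) {
  n <- length(values)
  if (n < 2) stop_wnorm("bootstrap_percentile_ci: need at least 2 values")
  if (B < 1) stop_wnorm("bootstrap_percentile_ci: 'B' must be >= 1")
  if (level <= 0 || level >= 1)
    stop_wnorm("bootstrap_percentile_ci: 'level' must be in (0, 1)")
  means <- with_seed(seed, {
    idx <- sample.int(n, n * B, replace = TRUE)
    colMeans(matrix(values[idx], nrow = n, ncol = B))
  })
  alpha <- (1 - level) / 2
  ci <- stats::quantile(means, c(alpha, 1 - alpha), names = FALSE,
                        type = 7)
  stats::setNames(ci, c("lo", "hi"))
}

# One-sided tail probability of a mean w-score in the abnormal direction.
abnormal_tail_prob <- function(mean_w, modality) {
  ifelse(modality == "MD", stats::pnorm(mean_w, lower.tail = FALSE),
         stats::pnorm(mean_w))
}

# Percentile band from the abnormal-tail probability.
percentile_band <- function(tail_prob) {
  cut(tail_prob, breaks = c(-Inf, 0.025, 0.05, 0.10, 0.25, Inf),
      labels = c("<2.5th", "<5th", "<10th", "<25th", "not-abnormal"),
      right = TRUE)
}

#' Group-level percentile-band abnormality map
#'
#' For every (group, roi, modality) cell: the mean carrier w-score, its
#' non-parametric percentile bootstrap CI, a two-sided one-sample t-test
#' against 0, and a percentile band obtained by mapping the mean w-score
#' through the abnormal-tail standard-normal probability onto the bands
#' below the 2.5th, 5th, 10th and 25th control percentiles. The primary
#' significance rule is "bootstrap CI excludes 0"; the t-test p-value is
#' reported alongside.
#'
#' @param wscores A `wscore_table` (or data frame with `participant_id`,
#'   `roi`, `modality`, `wscore`).
#' @param groups Data frame `participant_id`, `group` (e.g. gene-by-stage
#'   labels). Participants missing from `groups` are dropped.
#' @param B,level,seed Bootstrap parameters; see
#'   [bootstrap_percentile_ci()].
#' @param p_adjust Multiple-testing correction for the t-test p-values
#'   across rows (`"none"`, the default, or any [stats::p.adjust] method
#'   such as `"BH"`); reported in `p_adj` without changing the primary
#'   CI-based flag.
#' @return Data frame of class `group_map` with one row per cell: `group`,
#'   `roi`, `modality`, `n`, `mean_w`, `ci_lo`, `ci_hi`, `t_p`, (`p_adj`),
#'   `tail_prob`, `band`, `significant`, `flag`. Cells with n < 2 carry NA
#'   intervals/tests and are flagged `"insufficient_n"`.
#' @export
group_abnormality_map <- function(wscores, groups, B = 1000, level = 0.95,
                                  seed = NULL, p_adjust = "none") {
  check_columns(wscores, c("participant_id", "roi", "modality", "wscore"),
                "wscores")
  check_columns(groups, c("participant_id", "group"), "groups")
  w <- wscores
  w$group <- groups$group[match(w$participant_id, groups$participant_id)]
  w <- w[!is.na(w$group), , drop = FALSE]
  if (!nrow(w)) stop_wnorm("group_abnormality_map: no scored participants matched 'groups'")
  key <- paste(w$group, w$modality, w$roi, sep = "\r")
  idx <- split(seq_len(nrow(w)), key)
  cells <- do.call(rbind, strsplit(names(idx), "\r", fixed = TRUE))
  cells <- data.frame(group = cells[, 1], modality = cells[, 2],
                      roi = cells[, 3], stringsAsFactors = FALSE)
  res <- with_seed(seed, {
    rows <- vector("list", nrow(cells))
    for (i in seq_len(nrow(cells))) {
      x <- w$wscore[idx[[i]]]
      n <- length(x)
      m <- mean(x)
      if (n >= 2) {
        ci <- bootstrap_percentile_ci(x, B = B, level = level)
        # a constant sample has no t-statistic; CI still informs the flag
        tp <- if (stats::sd(x) > 0) stats::t.test(x, mu = 0)$p.value
              else NA_real_
        flag <- "ok"
      } else {
        ci <- c(lo = NA_real_, hi = NA_real_); tp <- NA_real_
        flag <- "insufficient_n"
      }
      rows[[i]] <- data.frame(
        group = cells$group[i], roi = cells$roi[i],
        modality = cells$modality[i], n = n, mean_w = m,
        ci_lo = ci[["lo"]], ci_hi = ci[["hi"]], t_p = tp, flag = flag,
        stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })
  res$tail_prob <- abnormal_tail_prob(res$mean_w, res$modality)
  res$band <- as.character(percentile_band(res$tail_prob))
  res$significant <- !is.na(res$ci_lo) & (res$ci_lo > 0 | res$ci_hi < 0)
  if (!identical(p_adjust, "none"))
    res$p_adj <- stats::p.adjust(res$t_p, method = p_adjust)
  rownames(res) <- NULL
  class(res) <- c("group_map", "data.frame")
  res
}

#' @export
print.group_map <- function(x, ...) {
  cat(sprintf("Group abnormality map: %d cell(s), %d group(s)\n",
              nrow(x), length(unique(x$group))))
  abn <- x$band != "not-abnormal" & x$significant
  cat(sprintf("  significant abnormal cells: %d\n", sum(abn, na.rm = TRUE)))
  print.data.frame(utils::head(as.data.frame(x), 10), digits = 3)
  if (nrow(x) > 10) cat(sprintf("  ... %d more row(s)\n", nrow(x) - 10))
  invisible(x)
}

#' Heatmap of a group abnormality map
#'
#' Simple tabular heatmap of mean w-scores (regions x groups) for one
#' modality, colour-coded from abnormal (dark) to normal.
#'
#' @param x A `group_map`.
#' @param modality Modality to display.
#' @param ... Passed to [graphics::image].
#' @return `x`, invisibly.
#' @export
plot.group_map <- function(x, modality = "volume", ...) {
  sub <- x[x$modality == modality, , drop = FALSE]
  if (!nrow(sub)) stop_wnorm("plot.group_map: no rows with modality '%s'",
                             modality)
  rois <- sort(unique(sub$roi)); grps <- sort(unique(sub$group))
  z <- matrix(NA_real_, length(rois), length(grps),
              dimnames = list(rois, grps))
  z[cbind(match(sub$roi, rois), match(sub$group, grps))] <- sub$mean_w
  op <- graphics::par(mar = c(8, 10, 3, 2)); on.exit(graphics::par(op))
  graphics::image(seq_along(grps), seq_along(rois), t(z), axes = FALSE,
                  xlab = "", ylab = "",
                  main = sprintf("Mean w-score (%s)", modality),
                  col = grDevices::hcl.colors(21, "RdBu"),
                  zlim = c(-max(abs(z), na.rm = TRUE),
                           max(abs(z), na.rm = TRUE)), ...)
  graphics::axis(1, seq_along(grps), grps, las = 2, cex.axis = 0.7)
  graphics::axis(2, seq_along(rois), rois, las = 2, cex.axis = 0.6)
  invisible(x)
}
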