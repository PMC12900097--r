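# Segmentation evaluation: Dice similarity coefficient, relative volume
# difference, per-subject / per-tract aggregation with tract-size
# stratification, and the paired two-tailed Wilcoxon signed-rank test.

#' Dice similarity coefficient
#'
#' `2 |pred intersect gt| / (|pred| + |gt|)`. Two empty masks score 1 by
#' convention; exactly one empty mask scores 0. This keeps per-tract tables
#' defined for tracts absent from a subject.
#'
#' @param pred,gt binary masks of equal shape (any dimensionality).
#' @return value in \[0, 1\].
#' @export
dice_score <- function(pred, gt) {
  if (!all(dim(pred) == dim(gt)))
    stop("mask shapes differ", call. = FALSE)
  np <- sum(pred != 0)
  ng <- sum(gt != 0)
  if (np + ng == 0) return(1)
  2 * sum(pred != 0 & gt != 0) / (np + ng)
}

#' Relative volume difference
#'
#' Absolute volume difference normalized by the ground-truth volume:
#' `| |pred| - |gt| | / |gt|`. A size-agreement metric: 0 means matched
#' volumes, 1 means a total miss (or a doubling).
#'
#' @param pred,gt binary masks of equal shape; `gt` must be nonempty.
#' @return nonnegative value.
#' @export
rvd_score <- function(pred, gt) {
  if (!all(dim(pred) == dim(gt)))
    stop("mask shapes differ", call. = FALSE)
  ng <- sum(gt != 0)
  if (ng == 0)
    stop("RVD undefined for an empty ground-truth mask", call. = FALSE)
  abs(sum(pred != 0) - ng) / ng
}

# exact two-tailed p for the signed-rank statistic via the generating function
# of W+ over all 2^n sign patterns (ranks doubled so mid-ranks are integers)
wilcoxon_exact_p <- function(ranks, stat) {
  r2 <- as.integer(round(2 * ranks))
  maxw <- sum(r2)
  # counts[w + 1] = number of sign patterns with doubled W+ equal to w
  counts <- numeric(maxw + 1)
  counts[1] <- 1
  for (r in r2) {
    shifted <- c(numeric(r), counts[seq_len(maxw + 1 - r)])
    counts <- counts + shifted
  }
  wplus2 <- round(2 * stat)
  lo <- sum(counts[seq_len(wplus2 + 1)])            # P(W+ <= stat)
  hi <- sum(counts[(maxw - wplus2 + 1):(maxw + 1)]) # P(W+ >= maxw - stat)
  min(1, (lo + hi) / 2^length(ranks))
}

#' Paired two-tailed Wilcoxon signed-rank test
#'
#' Differences `a - b`; zero differences are dropped (classical signed-rank
#' treatment) and absolute differences are mid-ranked under ties. The
#' statistic is the smaller of the positive and negative rank sums. For 25 or
#' fewer nonzero differences the two-tailed p-value is exact over all `2^n`
#' sign patterns; above that a normal approximation with continuity and tie
#' corrections is used.
#'
#' @param a,b paired numeric vectors of equal length.
#' @return object of class `wilcoxon_result`: list(n_used, statistic,
#'   p_value, method).
#' @export
wilcoxon_signed_rank <- function(a, b) {
  if (length(a) != length(b) || length(a) < 1)
    stop("inputs must be paired vectors of equal length >= 1", call. = FALSE)
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    warning("all paired differences are zero; test degenerate", call. = FALSE)
    return(structure(list(n_used = 0L, statistic = 0, p_value = 1,
                          method = "degenerate"), class = "wilcoxon_result"))
  }
  rk <- rank(abs(d))          # mid-ranks under ties
  wpos <- sum(rk[d > 0])
  wneg <- sum(rk[d < 0])
  stat <- min(wpos, wneg)
  if (n <= 25) {
    p <- wilcoxon_exact_p(rk, min(wpos, wneg))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tcnt <- table(abs(d))   # tie correction over tied |d| groups
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tcnt^3 - tcnt) / 48
    z <- (stat - mu + 0.5) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(z))
    method <- "normal-approximation"
  }
  structure(list(n_used = as.integer(n), statistic = stat, p_value = p,
                 method = method),
            class = "wilcoxon_result")
}

#' @export
print.wilcoxon_result <- function(x, ...) {
  cat(sprintf("Wilcoxon signed-rank (%s): n = %d, statistic = %.1f, p = %.4g\n",
              x$method, x$n_used, x$statistic, x$p_value))
  invisible(x)
}

#' Evaluate prediction volumes against ground truth
#'
#' Computes Dice and RVD for every (subject, tract) pair, aggregate mean and
#' sample standard deviation per metric, and a tract-size stratification
#' mapping each tract's mean ground-truth volume to its mean Dice and RVD
#' across subjects. Tracts empty in the ground truth of a subject contribute
#' a defined Dice (empty-mask conventions) and are excluded from RVD.
#'
#' @param preds,gts paired lists of `tract_labels` with matching shapes and
#'   tract counts.
#' @return object of class `eval_result`: list(pairs, aggregates, by_tract).
#' @export
evaluate_dataset <- function(preds, gts) {
  if (length(preds) != length(gts) || length(preds) == 0)
    stop("prediction and ground-truth lists must be paired", call. = FALSE)
  rows <- list()
  for (s in seq_along(preds)) {
    pd <- if (inherits(preds[[s]], "tract_labels")) preds[[s]]$data else preds[[s]]
    gd <- if (inherits(gts[[s]], "tract_labels")) gts[[s]]$data else gts[[s]]
    if (!all(dim(pd) == dim(gd)))
      stop("subject ", s, ": prediction/ground-truth shapes differ",
           call. = FALSE)
    for (t in seq_len(dim(gd)[4])) {
      gv <- sum(gd[, , , t] != 0)
      rows[[length(rows) + 1L]] <- data.frame(
        subject = s, tract = t,
        dsc = dice_score(pd[, , , t], gd[, , , t]),
        rvd = if (gv > 0) rvd_score(pd[, , , t], gd[, , , t]) else NA_real_,
        gt_volume = gv)
    }
  }
  pairs <- do.call(rbind, rows)
  aggregates <- c(mean_dsc = mean(pairs$dsc),
                  sd_dsc = stats::sd(pairs$dsc),
                  mean_rvd = mean(pairs$rvd, na.rm = TRUE),
                  sd_rvd = stats::sd(pairs$rvd, na.rm = TRUE))
  by_tract <- do.call(rbind, lapply(split(pairs, pairs$tract), function(g)
    data.frame(tract = g$tract[1], mean_gt_volume = mean(g$gt_volume),
               mean_dsc = mean(g$dsc), mean_rvd = mean(g$rvd, na.rm = TRUE))))
  structure(list(pairs = pairs, aggregates = aggregates, by_tract = by_tract),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("eval_result: %d subject x tract pairs\n", nrow(x$pairs)))
  cat(sprintf("  Dice %.4f (sd %.4f) | RVD %.4f (sd %.4f)\n",
              x$aggregates["mean_dsc"], x$aggregates["sd_dsc"],
              x$aggregates["mean_rvd"], x$aggregates["sd_rvd"]))
  invisible(x)
}

#' Compare two prediction sets with the paired signed-rank test
#'
#' Flattens the per-(subject, tract) Dice (or RVD) tables of two evaluation
#' results and applies [wilcoxon_signed_rank()] to the paired values.
#'
#' @param eval_a,eval_b `eval_result`s over the same subjects and tracts.
#' @param metric `"dsc"` or `"rvd"`.
#' @return a `wilcoxon_result`.
#' @export
compare_predictions <- function(eval_a, eval_b, metric = c("dsc", "rvd")) {
  metric <- match.arg(metric)
  va <- eval_a$pairs[[metric]]
  vb <- eval_b$pairs[[metric]]
  keep <- !(is.na(va) | is.na(vb))
  wilcoxon_signed_rank(va[keep], vb[keep])
}
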