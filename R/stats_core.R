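#' Two-tailed p value from a t statistic
#'
#' @param t observed statistic.
#' @param df degrees of freedom (>= 1).
#' @return two-tailed p.
#' @export
p_from_t <- function(t, df) {
  if (any(df < 1)) stop("df must be >= 1")
  2 * stats::pt(abs(t), df, lower.tail = FALSE)
}

#' Paired t test across subjects
#'
#' Statistic on the per-subject differences \code{x - y}:
#' \eqn{t = \bar d / (s_d / \sqrt n)}, df = n - 1, two-tailed p.
#'
#' @param x,y per-subject values (equal length >= 2).
#' @return list of class \code{ms_test}: statistic, df, p, n.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- stats::complete.cases(x, y)
  d <- x[ok] - y[ok]
  n <- length(d)
  if (n < 2) stop("need >= 2 complete pairs")
  sdd <- stats::sd(d)
  if (sdd == 0) {
    if (all(d == 0))
      return(structure(list(statistic = 0, df = n - 1, p = 1, n = n),
                       class = "ms_test"))
    stop("zero-variance differences: t statistic undefined")
  }
  tstat <- mean(d) / (sdd / sqrt(n))
  structure(list(statistic = tstat, df = n - 1, p = p_from_t(tstat, n - 1),
                 n = n),
            class = "ms_test")
}

#' @export
print.ms_test <- function(x, ...) {
  cat(sprintf("t(%d) = %.3f, two-tailed p = %.4g (n = %d)\n",
              x$df, x$statistic, x$p, x$n))
  invisible(x)
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up procedure at level \code{q}; adjusted p values follow the
#' cumulative-minimum convention of \code{p.adjust(method = "BH")}.
#'
#' @param pvals vector of p values in [0, 1].
#' @param q FDR level (default 0.05).
#' @return list: \code{significant} logical mask, \code{p_adjusted}.
#' @export
bh_fdr <- function(pvals, q = 0.05) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stop("p values must lie in [0, 1]")
  padj <- stats::p.adjust(pvals, method = "BH")
  list(significant = !is.na(padj) & padj <= q, p_adjusted = padj)
}

#' Tabulate a behavioral trial log
#'
#' Counts and percentages of correct-aware / correct-unaware /
#' incorrect-aware / incorrect-unaware responses per ISI, overall accuracy,
#' RT means for the CA and CU conditions, and the ideal ISI: the ISI with
#' the most balanced CA/CU trial counts among ISIs where both conditions
#' reach \code{min_trials}.
#'
#' @param log data.frame with columns \code{ISI_ms}, \code{truth},
#'   \code{response}, \code{aware}, \code{RT_ms}
#'   (\code{\link{simulate_behavior_log}}).
#' @param min_trials minimum CA and CU count for an ISI to be eligible.
#' @return list of class \code{ms_behavior}: \code{by_isi} table,
#'   \code{overall_accuracy}, \code{rt_ms} (CA/CU means), \code{ideal_isi}.
#' @export
tabulate_behavior <- function(log, min_trials = 20) {
  if (!nrow(log)) stop("empty trial log")
  correct <- log$response == log$truth
  cat4 <- ifelse(correct, ifelse(log$aware, "CA", "CU"),
                 ifelse(log$aware, "IA", "IU"))
  isis <- sort(unique(log$ISI_ms))
  by_isi <- do.call(rbind, lapply(isis, function(isi) {
    sel <- log$ISI_ms == isi
    n <- sum(sel)
    cnt <- table(factor(cat4[sel], levels = c("CA", "CU", "IA", "IU")))
    data.frame(ISI_ms = isi, n = n, CA = cnt[["CA"]], CU = cnt[["CU"]],
               IA = cnt[["IA"]], IU = cnt[["IU"]],
               pct_CA = 100 * cnt[["CA"]] / n, pct_CU = 100 * cnt[["CU"]] / n,
               pct_IA = 100 * cnt[["IA"]] / n, pct_IU = 100 * cnt[["IU"]] / n,
               accuracy = 100 * mean(correct[sel]))
  }))
  eligible <- by_isi$CA >= min_trials & by_isi$CU >= min_trials
  if (!any(eligible))
    stop("no ISI has at least ", min_trials, " trials in both CA and CU")
  cand <- by_isi[eligible, ]
  ideal <- cand$ISI_ms[which.min(abs(cand$CA - cand$CU))]
  structure(list(
    by_isi = by_isi,
    overall_accuracy = 100 * mean(correct),
    rt_ms = c(CA = mean(log$RT_ms[cat4 == "CA"]),
              CU = mean(log$RT_ms[cat4 == "CU"])),
    ideal_isi = ideal), class = "ms_behavior")
}

#' @export
print.ms_behavior <- function(x, ...) {
  cat("<ms_behavior> overall accuracy ", sprintf("%.1f%%", x$overall_accuracy),
      "; ideal ISI ", x$ideal_isi, " ms\n", sep = "")
  print(x$by_isi[, c("ISI_ms", "n", "CA", "CU", "IA", "IU", "accuracy")],
        row.names = FALSE)
  cat(sprintf("mean RT: CA %.0f ms, CU %.0f ms\n", x$rt_ms[["CA"]],
              x$rt_ms[["CU"]]))
  invisible(x)
}
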