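#' One-sided rank-sum test of bait spectral counts against controls
#'
#' Wilcoxon--Mann--Whitney test of the alternative that the bait-side
#' spectral counts are stochastically greater than the control-side
#' counts, with mid-ranks for ties. When the pooled sample size is at most
#' \code{exact_cap} the p-value is exact: all \code{choose(n1 + n2, n1)}
#' assignments of group labels to the observed pooled values are
#' enumerated, which handles ties exactly (base R's exact path does not).
#' Larger samples use the normal approximation with tie and continuity
#' correction. If every observation is equal the p-value is 1.
#'
#' @param bait_scs,control_scs non-empty numeric vectors of spectral
#'   counts, zero-filled for runs without a detection.
#' @param alternative \code{"greater"} (default; bait enriched over
#'   control) or \code{"two.sided"}.
#' @param exact_cap largest pooled sample size for exact enumeration
#'   (default 12; the common 3-replicate + 6-control design has 9).
#' @return A list of class \code{ranksum_result} with \code{p_value},
#'   \code{u_statistic} (Mann--Whitney U of the bait side), \code{method}
#'   (\code{"exact_enumeration"} or \code{"normal_tie_corrected"}),
#'   \code{n_bait}, \code{n_control}.
#' @examples
#' ranksum_p(c(5, 6, 7), rep(0, 6))$p_value   # 1/84
#' @export
ranksum_p <- function(bait_scs, control_scs,
                      alternative = c("greater", "two.sided"),
                      exact_cap = 12L) {
  alternative <- match.arg(alternative)
  n1 <- length(bait_scs); n2 <- length(control_scs)
  if (n1 == 0 || n2 == 0)
    stop("both spectral-count vectors must be non-empty")
  pooled <- c(bait_scs, control_scs)
  r <- rank(pooled)                       # mid-ranks for ties
  w_obs <- sum(r[seq_len(n1)])
  u <- w_obs - n1 * (n1 + 1) / 2

  if (length(unique(pooled)) == 1L) {
    p <- 1
    method <- if (n1 + n2 <= exact_cap) "exact_enumeration"
              else "normal_tie_corrected"
  } else if (n1 + n2 <= exact_cap) {
    idx <- utils::combn(n1 + n2, n1)
    sums <- colSums(matrix(r[idx], nrow = n1))
    # tolerance guards mid-rank .5 arithmetic
    hi <- mean(sums >= w_obs - 1e-9)
    if (alternative == "greater") {
      p <- hi
    } else {
      lo <- mean(sums <= w_obs + 1e-9)
      p <- min(1, 2 * min(hi, lo))
    }
    method <- "exact_enumeration"
  } else {
    p <- suppressWarnings(
      stats::wilcox.test(bait_scs, control_scs,
                         alternative = alternative,
                         exact = FALSE, correct = TRUE)$p.value)
    method <- "normal_tie_corrected"
  }
  structure(list(p_value = min(max(p, 1e-16), 1),
                 u_statistic = u, method = method,
                 n_bait = n1, n_control = n2),
            class = "ranksum_result")
}

#' Calibrate a p-value into a per-pair false discovery rate
#'
#' Converts a single rank-sum p-value into a lower bound on the posterior
#' probability that the pair is a false (null) interaction, via the
#' \eqn{-e\,p\,\ln p} bound: for \eqn{p < 1/e},
#' \deqn{FDR = \frac{1}{1 + (-e\,p\,\ln p)^{-1}},}
#' and \eqn{FDR = 0.5} (the bound's supremum) for \eqn{p \ge 1/e}. The
#' result lies in \eqn{(0, 0.5]} and is non-decreasing and continuous in
#' \eqn{p}. This is a per-pair calibration of one p-value, not a
#' set-level multiple-testing procedure.
#'
#' @param p p-value(s) in (0, 1]; values below 1e-16 are clamped to that
#'   floor before taking the logarithm.
#' @return FDR value(s) in (0, 0.5].
#' @examples
#' fdr_from_p(exp(-1))  # 0.5
#' fdr_from_p(0.01)     # ~0.1113
#' @export
fdr_from_p <- function(p) {
  if (any(!is.finite(p) | p <= 0 | p > 1))
    stop("p must lie in (0, 1]")
  p <- pmax(p, 1e-16)
  ifelse(p >= exp(-1), 0.5,
         1 / (1 + 1 / (-exp(1) * p * log(p))))
}

#' Per-pair FDR from spectral-count evidence
#'
#' Composition of [ranksum_p()] and [fdr_from_p()] on a pair's zero-filled
#' replicate and control spectral counts.
#'
#' @param pair a \code{pair_evidence} object from
#'   [collect_pair_evidence()].
#' @param alternative,exact_cap passed to [ranksum_p()].
#' @return FDR in (0, 0.5].
#' @export
fdr_for_pair <- function(pair, alternative = "greater", exact_cap = 12L) {
  stopifnot(inherits(pair, "pair_evidence"))
  if (length(pair$sc_controls) == 0)
    stop("FDR computation requires negative-control runs")
  fdr_from_p(ranksum_p(pair$sc_replicates, pair$sc_controls,
                       alternative = alternative,
                       exact_cap = exact_cap)$p_value)
}
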