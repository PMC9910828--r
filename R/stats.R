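# Paired Wilcoxon signed-rank statistics with the common-language effect
# size r = W / (n(n+1)/2): the proportion of favorable signed ranks.

# Exact null distribution of W (sum of positive midranks) by convolution.
# Ranks are doubled so midranks become integers; returns P(W2 = 0..S) where
# W2 = 2W. Handles ties exactly (base dsignrank cannot).
signed_rank_exact_pmf <- function(ranks2) {
  S <- sum(ranks2)
  pmf <- numeric(S + 1)
  pmf[1] <- 1
  for (r in ranks2) {
    shifted <- c(numeric(r), pmf[seq_len(S + 1 - r)])
    pmf <- (pmf + shifted) / 2
  }
  pmf
}

#' Paired Wilcoxon signed-rank test
#'
#' Computes differences `x - y`, drops zero differences, midranks the
#' absolute differences, and reports `W` (the sum of ranks of positive
#' differences; half-integers possible under ties), the effect size
#' `r = W / (n(n+1)/2)`, and a two-sided p value. The p value is exact
#' (by convolution over the signed-rank null distribution, valid under
#' midrank ties) for `n <= exact_max`, and uses the normal approximation
#' with tie and continuity corrections otherwise.
#'
#' @param x,y Paired observations (e.g. per-participant values in the
#'   rewarded and non-rewarded conditions).
#' @param exact_max Largest n for which the exact p value is computed.
#' @return A `signed_rank_result`: `n` (pairs after dropping zeros), `W`,
#'   `r`, `p`, `method`.
#' @examples
#' signed_rank(c(5, 7, 9, 4, 8, 6), c(3, 2, 5, 1, 4, 2))
#' @export
signed_rank <- function(x, y, exact_max = 25) {
  if (length(x) != length(y)) stopf("x and y must have equal length")
  d <- x - y
  d <- d[!is.na(d) & d != 0]
  n <- length(d)
  if (n < 5) stopf("fewer than 5 non-zero paired differences (n = %d)", n)
  r_abs <- rank(abs(d))
  W <- sum(r_abs[d > 0])
  W_max <- n * (n + 1) / 2

  if (n <= exact_max) {
    ranks2 <- as.integer(round(2 * r_abs))
    pmf <- signed_rank_exact_pmf(ranks2)
    w2 <- as.integer(round(2 * W))
    p_le <- sum(pmf[seq_len(w2 + 1)])
    p_ge <- sum(pmf[(w2 + 1):length(pmf)])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- W_max / 2
    ties <- table(r_abs)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    cc <- sign(W - mu) * 0.5
    z <- (W - mu - cc) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation"
  }
  structure(list(n = n, W = W, r = W / W_max, p = p, method = method),
            class = "signed_rank_result")
}

#' @export
print.signed_rank_result <- function(x, ...) {
  pfmt <- if (x$p < 1e-3) sprintf("%.2e", x$p) else sprintf("%.3g", x$p)
  cat(sprintf("Wilcoxon signed-rank: W = %g, n = %d, r = %.2f, p = %s (%s)\n",
              x$W, x$n, x$r, pfmt, x$method))
  invisible(x)
}

#' Common-language effect size for the signed-rank statistic
#'
#' `r = W / (n(n+1)/2)`: the proportion of the maximal rank sum carried by
#' positive differences. `r = 1` when every difference favors the first
#' condition, `r = 0` when every difference favors the second, `r = 0.5`
#' when ranks balance.
#'
#' @param W Signed-rank statistic (sum of positive midranks).
#' @param n Number of non-zero paired differences.
#' @return Effect size in `[0, 1]`.
#' @examples
#' effect_size_r(136, 16)   # 1
#' effect_size_r(117.5, 17) # 0.768
#' @export
effect_size_r <- function(W, n) {
  W_max <- n * (n + 1) / 2
  if (any(W < 0 | W > W_max)) stopf("W must lie in [0, n(n+1)/2]")
  W / W_max
}

#' Per-participant median movement-time contrast
#'
#' For each participant, the median movement time over valid trials of the
#' conditions of interest is computed separately for rewarded and
#' non-rewarded trials; the paired differences (rewarded minus non-rewarded)
#' are tested across participants with the signed-rank test. Negative
#' differences mean faster movements under reward.
#'
#' @param dataset An `emg_dataset` (raw or processed).
#' @param conditions Optional selector restricting the trials of interest
#'   (reward excluded; it is the paired factor).
#' @return A list: `per_participant` data.frame (participant, median MT per
#'   reward condition, difference) and `test` (`signed_rank_result`).
#' @export
median_mt_contrast <- function(dataset, conditions = list()) {
  design <- dataset$design
  rows <- lapply(dataset$participants, function(p) {
    meds <- vapply(design$factors$reward, function(rw) {
      trs <- filter_trials(dataset$trials, c(conditions, list(reward = rw)), p)
      mts <- vapply(trs, function(tr) tr$mt %||% NA_real_, numeric(1))
      stats::median(mts[!is.na(mts)])
    }, numeric(1))
    data.frame(participant = p, mt_rewarded = meds[["rewarded"]],
               mt_nonrewarded = meds[["non_rewarded"]],
               diff = meds[["rewarded"]] - meds[["non_rewarded"]])
  })
  per <- do.call(rbind, rows)
  list(per_participant = per,
       test = signed_rank(per$mt_rewarded, per$mt_nonrewarded))
}
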