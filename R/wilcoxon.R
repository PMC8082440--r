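## Two-sided Wilcoxon signed-rank test with midranks for ties, exact null
## distribution by dynamic programming for n <= 25 and a tie-corrected
## normal approximation beyond. Implemented here (rather than wrapping
## stats::wilcox.test) because the exact path must handle ties via midranks
## and is oracle-tested against full sign-enumeration.

#' Two-sided Wilcoxon signed-rank test for paired samples
#'
#' Zero differences are discarded; tied absolute differences receive
#' midranks. For n <= `exact_max` the exact two-sided p-value is computed by
#' dynamic programming over the null distribution of the positive-rank sum
#' (doubled midranks are integers); otherwise a normal approximation with
#' tie correction and continuity correction is used.
#'
#' @param a,b paired numeric vectors of equal length.
#' @param exact_max largest effective n for the exact distribution.
#' @return list with `statistic` (positive-rank sum W+), `p_value`,
#'   `n_effective`, `method`, and `degenerate` (TRUE when all differences
#'   are zero; then p = 1).
#' @export
wilcoxon_signed_rank <- function(a, b, exact_max = 25L) {
  stopifnot(length(a) == length(b), length(a) >= 1)
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(list(statistic = 0, p_value = 1, n_effective = 0L,
                method = "degenerate", degenerate = TRUE))
  }
  r <- rank(abs(d)) # midranks
  w <- sum(r[d > 0])
  if (n <= exact_max) {
    # DP over doubled ranks (integers); counts[k+1] = #assignments with 2W = k
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    counts <- numeric(total + 1)
    counts[1] <- 1
    for (ri in r2) {
      shifted <- c(numeric(ri), counts[seq_len(total + 1 - ri)])
      counts <- counts + shifted
    }
    probs <- counts / 2^n
    w2 <- round(2 * w)
    p_le <- sum(probs[seq_len(w2 + 1)])
    p_ge <- sum(probs[(w2 + 1):(total + 1)])
    p <- min(1, 2 * min(p_le, p_ge))
    list(statistic = w, p_value = p, n_effective = n, method = "exact",
         degenerate = FALSE)
  } else {
    mu <- sum(r) / 2
    sig <- sqrt(sum(r^2) / 4) # midranks already absorb the tie correction
    z <- (w - mu - sign(w - mu) * 0.5) / sig
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    list(statistic = w, p_value = p, n_effective = n, method = "normal",
         degenerate = FALSE)
  }
}
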