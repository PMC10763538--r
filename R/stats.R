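# Shared statistical primitives.

#' Mann-Whitney U test with a tie-safe exact path
#'
#' Two-sample rank test used throughout the package. When both samples
#' have at most `exact_max` observations the p-value comes from full
#' enumeration of all arrangements of the pooled (average) ranks, which
#' stays exact in the presence of ties; otherwise `stats::wilcox.test` is
#' used (exact for small untied samples, tie-corrected normal
#' approximation with continuity correction beyond that).
#'
#' @param x,y Numeric samples.
#' @param alternative `"two.sided"`, `"greater"` (x tends larger) or
#'   `"less"`.
#' @param exact_max Enumeration cutoff per side.
#' @return A list with `statistic` (U for `x`) and `p.value`.
#' @export
mw_test <- function(x, y, alternative = c("two.sided", "greater", "less"),
                    exact_max = 10L) {
  alternative <- match.arg(alternative)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  nx <- length(x); ny <- length(y)
  if (nx == 0L || ny == 0L)
    stop_rnaivar("both samples must be nonempty", "empty_group")
  r <- rank(c(x, y))
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  if (nx <= exact_max && ny <= exact_max) {
    idx <- combn(nx + ny, nx)
    us <- colSums(matrix(r[idx], nrow = nx)) - nx * (nx + 1) / 2
    pg <- mean(us >= u - 1e-9)
    pl <- mean(us <= u + 1e-9)
    p <- switch(alternative,
                greater = pg, less = pl,
                two.sided = min(1, 2 * min(pg, pl)))
    return(list(statistic = u, p.value = p))
  }
  ties <- any(duplicated(c(x, y)))
  wt <- suppressWarnings(
    wilcox.test(x, y, alternative = alternative,
                exact = !ties && nx <= 50 && ny <= 50, correct = TRUE))
  list(statistic = unname(wt$statistic), p.value = wt$p.value)
}

# One-tailed (x > y) normal-approximation MW p-value, tie-corrected, with
# continuity correction; the fast path used inside the resampling loop
# where both sides are far above the exact cutoff.
.mw_p_greater_normal <- function(x, y) {
  nx <- length(x); ny <- length(y)
  z <- c(x, y)
  r <- rank(z)
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  n <- nx + ny
  tab <- table(z)
  tie_term <- sum(tab^3 - tab) / (n * (n - 1))
  sigma2 <- nx * ny / 12 * ((n + 1) - tie_term)
  if (sigma2 <= 0) return(1)
  pnorm((u - nx * ny / 2 - 0.5) / sqrt(sigma2), lower.tail = FALSE)
}

#' Exact upper-tail hypergeometric probability
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n) (population N with K
#' successes, n draws), by exact summation in log space.
#'
#' @param N Population size.
#' @param K Successes in the population.
#' @param n Number of draws.
#' @param k Observed successes (included in the tail).
#' @return The upper-tail probability.
#' @export
hypergeom_enrichment <- function(N, K, n, k) {
  if (!(k >= 0 && k <= n && n <= N && K >= 0 && K <= N && k <= K))
    stop_rnaivar("inconsistent hypergeometric counts", "invalid_counts")
  j <- k:min(n, K)
  p <- sum(exp(lchoose(K, j) + lchoose(N - K, n - j) - lchoose(N, n)))
  min(1, p)
}

#' Omega-squared effect sizes from a sequential ANOVA table
#'
#' omega^2 = (SS_term - df_term * MS_error) / (SS_total + MS_error),
#' reported unclipped (slightly negative values are possible under the
#' null).
#'
#' @param fit An `lm` fit.
#' @return A tibble `term`, `df`, `sumsq`, `omega_sq` (the residual row
#'   carries `NA` omega_sq).
#' @export
omega_sq <- function(fit) {
  at <- anova(fit)
  ss <- at[["Sum Sq"]]; df <- at[["Df"]]
  n <- nrow(at)
  ms_err <- ss[n] / df[n]
  ss_tot <- sum(ss)
  om <- (ss - df * ms_err) / (ss_tot + ms_err)
  om[n] <- NA_real_
  tibble(term = rownames(at), df = df, sumsq = ss, omega_sq = om)
}

#' Benjamini-Hochberg adjustment
#'
#' Thin wrapper over [stats::p.adjust()] kept as a named surface so the
#' adjustment used for the strain-wise FDR threshold is a single,
#' testable choice.
#'
#' @param p Numeric p-values.
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p) p.adjust(p, method = "BH")
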