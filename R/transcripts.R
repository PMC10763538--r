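# Per-embryo transcript-count analysis: treated-vs-control location and
# scale tests, excess-mass multimodality testing, and stage-adjusted
# ANCOVA with omega-squared effect sizes.

.filter_embryos <- function(counts, strain, stage_max) {
  out <- counts |> filter(.data$stage <= stage_max)
  if (!is.null(strain)) out <- out[out$strain == strain, ]
  out
}

#' Treated-vs-control tests on early-stage embryos
#'
#' Welch two-sample t-test on means, F-test on variances, and a
#' tie-corrected two-sided Mann-Whitney test, applied to transcript
#' counts of control vs RNAi-treated embryos up to `stage_max` (4 cells
#' by default, the early-embryo window).
#'
#' @param counts Tibble `embryo`, `strain`, `treatment`
#'   (`control`/`rnai`), `stage`, `count`.
#' @param strain Optional strain to subset to.
#' @param stage_max Maximum embryo stage retained.
#' @return A one-row tibble with group sizes, means, variances and the
#'   three p-values.
#' @export
compare_groups <- function(counts, strain = NULL, stage_max = 4) {
  d <- .filter_embryos(counts, strain, stage_max)
  x <- d$count[d$treatment == "control"]
  y <- d$count[d$treatment == "rnai"]
  if (length(x) < 2L || length(y) < 2L)
    stop_rnaivar("each group needs at least 2 embryos after the stage filter",
                 "empty_group")
  tt <- t.test(y, x)                       # Welch
  ft <- var.test(y, x)
  mw <- mw_test(y, x, "two.sided")
  tibble(n_control = length(x), n_rnai = length(y),
         mean_control = mean(x), mean_rnai = mean(y),
         var_control = var(x), var_rnai = var(y),
         t_p = tt$p.value, f_p = ft$p.value, mw_p = mw$p.value)
}

# Excess-mass values E(1, lambda) and E(2, lambda) for a grid of lambda.
# Over the alternating weight sequence (point mass 1/n, -lambda * gap,
# point mass, ...), E(1) is the maximum-sum subarray and E(2) the best
# pair of disjoint subarrays; both come from prefix-sum scans
# (best subarray ending at j = P_j - min(P_0..P_{j-1})), fully
# vectorized per lambda.
.excess_mass_scan <- function(xs, lambdas) {
  n <- length(xs)
  gaps <- diff(xs)
  m <- 2L * n - 1L
  w0 <- numeric(m)
  odd <- seq(1L, m, by = 2L)
  even <- if (n > 1L) seq(2L, m - 1L, by = 2L) else integer(0)
  w0[odd] <- 1 / n
  e1 <- e2 <- numeric(length(lambdas))
  for (i in seq_along(lambdas)) {
    w <- w0
    if (length(even)) w[even] <- -lambdas[i] * gaps
    P <- cumsum(w)
    left <- cummax(P - cummin(c(0, P[-m])))       # best in prefix 1..j
    Ps <- rev(cumsum(rev(w)))
    right <- rev(cummax(rev(Ps) - cummin(c(0, rev(Ps)[-m]))))
    e1[i] <- left[m]
    e2[i] <- if (m > 1L) max(left[-m] + right[-1L], left[m]) else left[m]
  }
  list(e1 = e1, e2 = e2)
}

.excess_mass_stat <- function(x, lambdas) {
  xs <- sort(x)
  sc <- .excess_mass_scan(xs, lambdas)
  max(sc$e2 - sc$e1)
}

# Piecewise-linear unimodal CDF closest in shape to the empirical CDF:
# greatest convex minorant left of the (kernel-estimated) mode, least
# concave majorant right of it.
.unimodal_cdf <- function(x, mode) {
  xs <- sort(x)
  n <- length(xs)
  px <- c(xs[1] - .Machine$double.eps * max(1, abs(xs[1])), xs)
  py <- c(0, seq_len(n) / n)
  keep <- !duplicated(px, fromLast = TRUE)  # collapse tied x to top F
  px <- px[keep]; py <- py[keep]
  iL <- max(1L, findInterval(mode, px))
  lower_hull <- function(xk, yk) {      # convex: slopes nondecreasing
    h <- integer(0)
    for (i in seq_along(xk)) {
      while (length(h) >= 2L) {
        a <- h[length(h) - 1L]; b <- h[length(h)]
        if ((yk[b] - yk[a]) * (xk[i] - xk[b]) >=
            (yk[i] - yk[b]) * (xk[b] - xk[a])) h <- h[-length(h)]
        else break
      }
      h <- c(h, i)
    }
    h
  }
  upper_hull <- function(xk, yk) {      # concave: slopes nonincreasing
    h <- integer(0)
    for (i in seq_along(xk)) {
      while (length(h) >= 2L) {
        a <- h[length(h) - 1L]; b <- h[length(h)]
        if ((yk[b] - yk[a]) * (xk[i] - xk[b]) <=
            (yk[i] - yk[b]) * (xk[b] - xk[a])) h <- h[-length(h)]
        else break
      }
      h <- c(h, i)
    }
    h
  }
  lidx <- seq_len(iL)
  ridx <- iL:length(px)
  hl <- lower_hull(px[lidx], py[lidx])
  hr <- upper_hull(px[ridx], py[ridx]) + iL - 1L
  kx <- c(px[lidx][hl], px[hr][-1])
  ky <- c(py[lidx][hl], py[hr][-1])
  keep2 <- !duplicated(kx)
  list(x = kx[keep2], y = ky[keep2])
}

.sample_unimodal <- function(cdf, n) {
  u <- runif(n)
  approx(cdf$y, cdf$x, xout = u, ties = "ordered", rule = 2)$y
}

#' Excess-mass test of bimodality
#'
#' Mueller-Sawitzki excess-mass statistic D = max over lambda of
#' (E(2, lambda) - E(1, lambda)), where E(m, lambda) is the maximal
#' excess probability mass attainable with m lambda-clusters; lambda is
#' scanned over a 50-point log-spaced grid spanning the kernel density
#' range. The p-value is calibrated by bootstrap under the best-fitting
#' unimodal rearrangement of the data (greatest-convex-minorant /
#' least-concave-majorant surgery on the empirical CDF around the
#' estimated mode), seeded for reproducibility.
#'
#' @param x Numeric sample (e.g. transcript counts of one strain and
#'   treatment); needs n >= 10 and at least 3 distinct values.
#' @param B Bootstrap replicates.
#' @param seed Integer seed.
#' @param n_lambda Grid size.
#' @return A list of class `rnai_bimodality`: `statistic`, `p_value`,
#'   `B`, `seed`.
#' @export
bimodality_test <- function(x, B = 500L, seed = 1L, n_lambda = 50L) {
  x <- x[!is.na(x)]
  if (length(x) < 10L)
    stop_rnaivar("need at least 10 observations", "invalid_design")
  if (length(unique(x)) < 3L)
    stop_rnaivar("degenerate (near-constant) data", "degenerate_data")
  bw <- tryCatch(stats::bw.SJ(x), error = function(e) stats::bw.nrd0(x))
  dens <- density(x, bw = bw)
  ymax <- max(dens$y)
  lambdas <- exp(seq(log(ymax / 100), log(ymax), length.out = n_lambda))
  obs <- .excess_mass_stat(x, lambdas)
  mode <- dens$x[which.max(dens$y)]
  cdf <- .unimodal_cdf(x, mode)
  # Bootstrap replicates reuse the lambda grid derived from the observed
  # sample; the grid is a fixed feature of the statistic, not re-estimated
  # under resampling.
  boot <- withr::with_seed(seed, {
    vapply(seq_len(B), function(b)
      .excess_mass_stat(.sample_unimodal(cdf, length(x)), lambdas),
      numeric(1))
  })
  structure(list(statistic = obs,
                 p_value = (1 + sum(boot >= obs)) / (B + 1),
                 B = B, seed = seed),
            class = "rnai_bimodality")
}

#' @export
print.rnai_bimodality <- function(x, ...) {
  cat(sprintf("Excess-mass test (2 vs 1 modes): D = %.4f, p = %.4g (B = %d)\n",
              x$statistic, x$p_value, x$B))
  invisible(x)
}

#' Stage-adjusted ANCOVA of transcript counts
#'
#' Fits the nested linear models `count ~ stage`,
#' `count ~ stage + treatment` and `count ~ stage * treatment` on
#' embryos up to `stage_max` (30 nuclei by default), reporting the
#' nested-F p-values for the treatment effect and for a change in slope,
#' omega-squared effect sizes per term of the full model (unclipped),
#' per-condition regression slopes and R-squared.
#'
#' @inheritParams compare_groups
#' @param stage_max Maximum embryo stage retained (wider window than the
#'   early-embryo tests).
#' @return An object of class `rnai_ancova`. Supports `tidy()`,
#'   `glance()` and `autoplot()`.
#' @export
ancova <- function(counts, strain = NULL, stage_max = 30) {
  d <- .filter_embryos(counts, strain, stage_max)
  d$treatment <- factor(d$treatment, levels = c("control", "rnai"))
  sizes <- d |> group_by(.data$treatment) |>
    summarise(n = n(), n_stage = n_distinct(.data$stage),
              .groups = "drop")
  if (nrow(sizes) < 2L || any(sizes$n < 3L))
    stop_rnaivar("need >= 3 embryos per condition", "invalid_design")
  if (any(sizes$n_stage < 2L))
    stop_rnaivar("a condition has a single stage value; slope inestimable",
                 "invalid_design")
  m_stage <- lm(count ~ stage, data = d)
  m_add <- lm(count ~ stage + treatment, data = d)
  m_int <- lm(count ~ stage * treatment, data = d)
  treatment_p <- anova(m_stage, m_add)$`Pr(>F)`[2]
  slope_p <- anova(m_add, m_int)$`Pr(>F)`[2]
  per_cond <- d |>
    group_by(.data$treatment) |>
    group_modify(function(g, key) {
      f <- lm(count ~ stage, data = g)
      tibble(intercept = unname(coef(f)[1]), slope = unname(coef(f)[2]),
             r_squared = summary(f)$r.squared)
    }) |> ungroup()
  structure(list(
    omega = omega_sq(m_int),
    treatment_p = treatment_p,
    slope_p = slope_p,
    per_condition = per_cond,
    models = list(stage = m_stage, add = m_add, interaction = m_int),
    data = d), class = "rnai_ancova")
}

#' @export
print.rnai_ancova <- function(x, ...) {
  cat("Stage-adjusted ANCOVA of transcript counts\n")
  cat(sprintf("  treatment effect p = %.4g; slope-change p = %.4g\n",
              x$treatment_p, x$slope_p))
  print(x$omega)
  print(x$per_condition)
  invisible(x)
}
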