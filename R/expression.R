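# Strain-wise expression variance and expression-matched resampling
# enrichment.

.counts_matrix <- function(counts) {
  m <- as.matrix(counts[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- counts[[1]]
  m
}

.check_samples <- function(counts, samples) {
  smp <- setdiff(names(counts), "gene")
  missing <- setdiff(smp, samples$sample)
  if (length(missing))
    stop_rnaivar(paste0("samples absent from sample sheet: ",
                        paste(missing, collapse = ", ")),
                 "sample_mismatch")
  samples$strain[match(smp, samples$sample)]
}

#' Drop genes with low total counts
#'
#' Removes genes whose total count across all samples is less than or
#' equal to `threshold` (default 10), preserving gene order otherwise.
#'
#' @param counts Tibble with a `gene` column followed by one integer
#'   column per sample.
#' @param threshold Total-count cutoff; genes with totals `<= threshold`
#'   are excluded.
#' @return The filtered counts tibble.
#' @export
filter_low_counts <- function(counts, threshold = 10) {
  tot <- rowSums(.counts_matrix(counts))
  out <- counts[tot > threshold, , drop = FALSE]
  if (nrow(out) == 0L)
    stop_rnaivar("all genes removed by the low-count filter",
                 "empty_result")
  out
}

#' Variance-stabilizing normalization (log2 scale)
#'
#' Computes per-sample size factors by the median-of-ratios method over
#' genes with a nonzero geometric mean, then returns
#' `log2(count / size_factor + 1)`. The contract of the transform is that
#' on negative-binomial data with constant dispersion the per-gene SD is
#' approximately independent of the per-gene mean rank; it does not claim
#' numeric equality with any external tool.
#'
#' @param counts Tibble with a `gene` column followed by sample columns.
#' @return A tibble of the same shape on the log2 scale, with the size
#'   factors in `attr(, "size_factors")`.
#' @export
normalize_vst <- function(counts) {
  m <- .counts_matrix(counts)
  if (ncol(m) < 2L)
    stop_rnaivar("need at least 2 samples", "invalid_design")
  if (any(m < 0)) stop_rnaivar("negative counts", "invalid_counts")
  if (any(colSums(m) == 0))
    stop_rnaivar("a sample has all-zero counts; size factor undefined",
                 "size_factor_error")
  pos <- rowSums(m == 0) == 0L
  if (!any(pos))
    stop_rnaivar("no gene with nonzero geometric mean", "size_factor_error")
  logref <- rowMeans(log(m[pos, , drop = FALSE]))
  sf <- exp(apply(log(m[pos, , drop = FALSE]) - logref, 2, median))
  v <- log2(sweep(m, 2, sf, "/") + 1)
  out <- bind_cols(tibble(gene = counts[[1]]), as_tibble(v))
  attr(out, "size_factors") <- sf
  out
}

#' Between-strain sum of squares per gene
#'
#' The strain term of a one-way ANOVA per gene:
#' SS = sum over strains of n_s * (mean_s - grand mean)^2, on the
#' normalized (variance-stabilized) values.
#'
#' @param norm Normalized expression tibble (`gene` + sample columns).
#' @param samples Sample sheet tibble (`sample`, `strain`).
#' @return A tibble `gene`, `strain_ss`.
#' @export
strain_variance <- function(norm, samples) {
  m <- .counts_matrix(norm)
  g <- .check_samples(norm, samples)
  if (length(unique(g)) < 2L)
    stop_rnaivar("need at least 2 strains", "invalid_design")
  bad <- rowSums(is.na(m)) > 0L
  if (any(bad)) warn(sprintf("%d gene(s) with missing values; SS set NA",
                             sum(bad)))
  ns <- as.vector(table(g)[unique(g)])
  gm <- t(rowsum(t(m), g)[unique(g), , drop = FALSE]) /
    rep(ns, each = nrow(m))
  grand <- rowMeans(m)
  ss <- rowSums(sweep((gm - grand)^2, 2, ns, "*"))
  ss[bad] <- NA_real_
  tibble(gene = norm[[1]], strain_ss = unname(ss))
}

#' Per-gene differential-expression stand-in test
#'
#' One-way ANOVA F-test of normalized expression across strains per gene,
#' with Benjamini-Hochberg adjustment and a significance flag at
#' FDR < `fdr_cut`. This is a documented stand-in for a count-model
#' likelihood-ratio test; the enrichment machinery also accepts
#' externally supplied flags.
#'
#' Genes with zero residual variance are flagged `degenerate` and get
#' p = 0 when the strain means differ (p = 1 when all values are
#' identical).
#'
#' @param norm Normalized expression tibble.
#' @param samples Sample sheet tibble.
#' @param fdr_cut FDR threshold for `de_flag`.
#' @return A tibble `gene`, `de_p`, `de_fdr`, `de_flag`, `degenerate`.
#' @export
de_test <- function(norm, samples, fdr_cut = 0.1) {
  m <- .counts_matrix(norm)
  g <- .check_samples(norm, samples)
  tabg <- table(g)
  if (any(tabg < 2L))
    stop_rnaivar("need at least 2 replicates per strain", "invalid_design")
  k <- length(tabg); n <- ncol(m)
  ns <- as.vector(tabg[unique(g)])
  gm <- t(rowsum(t(m), g)[unique(g), , drop = FALSE]) /
    rep(ns, each = nrow(m))
  grand <- rowMeans(m)
  ssb <- rowSums(sweep((gm - grand)^2, 2, ns, "*"))
  fitted <- gm[, match(g, unique(g)), drop = FALSE]
  ssw <- rowSums((m - fitted)^2)
  degenerate <- ssw < 1e-12
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  p <- unname(pf(f, k - 1, n - k, lower.tail = FALSE))
  p[degenerate] <- ifelse(ssb[degenerate] > 1e-12, 0, 1)
  fdr <- bh_adjust(p)
  tibble(gene = norm[[1]], de_p = p, de_fdr = fdr,
         de_flag = fdr < fdr_cut, degenerate = degenerate)
}

#' Per-gene variance table: normalization, strain SS, DE test
#'
#' Convenience pipeline: low-count filter, variance-stabilizing
#' normalization, per-gene mean expression and expression quantile
#' (average ranks for ties, scaled to (0, 1]), between-strain sum of
#' squares, and the DE stand-in test.
#'
#' @param counts Raw counts tibble (`gene` + sample columns).
#' @param samples Sample sheet tibble (`sample`, `strain`).
#' @param threshold Low-count filter cutoff.
#' @param fdr_cut FDR threshold for `de_flag`.
#' @return A tibble `gene`, `mean_expr`, `expr_quantile`, `strain_ss`,
#'   `de_p`, `de_fdr`, `de_flag`, `degenerate`.
#' @export
gene_variance_table <- function(counts, samples, threshold = 10,
                                fdr_cut = 0.1) {
  counts <- filter_low_counts(counts, threshold)
  norm <- normalize_vst(counts)
  mean_expr <- rowMeans(.counts_matrix(norm))
  tibble(gene = norm[[1]],
         mean_expr = mean_expr,
         expr_quantile = rank(mean_expr, ties.method = "average") /
           length(mean_expr)) |>
    left_join(strain_variance(norm, samples), by = "gene") |>
    left_join(de_test(norm, samples, fdr_cut), by = "gene")
}

#' Draw expression-matched null gene sets
#'
#' For each focal gene, the candidate pool is every non-focal gene whose
#' expression quantile lies within `window` of the focal gene's quantile
#' (one percentile by default). Each of the `B` null sets draws one pool
#' member uniformly (and independently) per focal gene.
#'
#' @param table Gene variance table from [gene_variance_table()].
#' @param focal Character vector of focal gene ids (subset of
#'   `table$gene`).
#' @param window Half-width on the `[0, 1]` quantile scale.
#' @param B Number of null sets.
#' @param seed Integer seed.
#' @return A `B` x `length(focal)` integer matrix of row indices into
#'   `table`, with attributes `genes` (the table's gene ids), `focal`,
#'   `window` and `seed`.
#' @export
match_expression_sets <- function(table, focal, window = 0.005,
                                  B = 10000L, seed = 1L) {
  if (B < 1L) stop_rnaivar("B must be >= 1", "invalid_design")
  fidx <- match(focal, table$gene)
  if (anyNA(fidx))
    stop_rnaivar("focal genes missing from table", "unknown_gene")
  q <- table$expr_quantile
  pools <- lapply(fidx, function(i) {
    pool <- which(abs(q - q[i]) <= window + 1e-12)
    pool <- setdiff(pool, fidx)
    if (length(pool) == 0L)
      stop_rnaivar(paste0("no expression-matched candidates for gene ",
                          table$gene[i]), "matching_failure")
    pool
  })
  withr::with_seed(seed, {
    idx <- vapply(pools, function(pool)
      pool[sample.int(length(pool), B, replace = TRUE)], integer(B))
  })
  if (B == 1L) idx <- matrix(idx, nrow = 1L)
  structure(idx, genes = table$gene, focal = focal, window = window,
            seed = seed, class = c("rnai_null_sets", class(idx)))
}

#' Expression-matched resampling enrichment of strain-wise variance
#'
#' Compares the focal set's median strain-wise sum of squares (and its
#' differentially-expressed proportion) against `B` expression-matched
#' null sets. For each null set it records the null median SS, optionally
#' a one-tailed Mann-Whitney test (focal SS values vs that null set's,
#' alternative focal > null) at level `alpha`, and the null set's DE
#' proportion. The permutation p-value follows the convention
#' `#(null >= observed) / B` (ties counted in the p-value), with the
#' add-one variant `(count + 1) / (B + 1)` always reported alongside; so
#' `frac_null_below + perm_p = 1` exactly.
#'
#' Also reports the exact upper-tail hypergeometric probability of the
#' focal set's DE enrichment against the genome-wide DE rate.
#'
#' @inheritParams match_expression_sets
#' @param alpha Level for the per-set Mann-Whitney tests.
#' @param mw_tests Run the per-set Mann-Whitney tests? (Skipping them
#'   speeds up large calibration runs that only need the medians.)
#' @param null_sets Optional pre-drawn sets from
#'   [match_expression_sets()].
#' @return An object of class `rnai_enrichment`; see [tidy_enrichment]
#'   methods, `glance()` and `autoplot()`.
#' @export
resampling_enrichment <- function(table, focal, B = 10000L,
                                  window = 0.005, seed = 1L,
                                  alpha = 0.05, mw_tests = TRUE,
                                  null_sets = NULL) {
  if (B < 1L) stop_rnaivar("B must be >= 1", "invalid_design")
  if (is.null(null_sets))
    null_sets <- match_expression_sets(table, focal, window, B, seed)
  B <- nrow(null_sets)
  fidx <- match(focal, table$gene)
  ss <- table$strain_ss
  flag <- table$de_flag
  focal_ss <- ss[fidx]
  obs_med <- median(focal_ss)
  null_ss <- matrix(ss[null_sets], nrow = B)
  null_med <- apply(null_ss, 1, median)
  ge <- sum(null_med >= obs_med)
  obs_de <- mean(flag[fidx])
  null_de <- rowMeans(matrix(flag[null_sets], nrow = B))
  ge_de <- sum(null_de >= obs_de)
  mw_sig <- if (mw_tests)
    sum(vapply(seq_len(B), function(b)
      .mw_p_greater_normal(focal_ss, null_ss[b, ]) < alpha,
      logical(1)))
  else NA_integer_
  structure(list(
    observed_median_ss = obs_med,
    null_median_ss = null_med,
    frac_null_below = mean(null_med < obs_med),
    perm_p_median = ge / B,
    perm_p_median_add1 = (ge + 1) / (B + 1),
    mw_significant_count = mw_sig,
    observed_de_prop = obs_de,
    null_de_prop = null_de,
    frac_null_deprop_below = mean(null_de < obs_de),
    perm_p_deprop = ge_de / B,
    perm_p_deprop_add1 = (ge_de + 1) / (B + 1),
    hypergeom_p = hypergeom_enrichment(
      N = nrow(table), K = sum(flag), n = length(focal),
      k = sum(flag[fidx])),
    B = B, alpha = alpha, seed = attr(null_sets, "seed"),
    window = attr(null_sets, "window"), focal = focal),
    class = "rnai_enrichment")
}

#' @export
print.rnai_enrichment <- function(x, ...) {
  cat("Expression-matched resampling enrichment\n")
  cat(sprintf("  focal set: %d genes; B = %d null sets (seed %s)\n",
              length(x$focal), x$B, format(x$seed)))
  cat(sprintf("  median strain SS: %.4g (null median below observed in %s/%d)\n",
              x$observed_median_ss,
              format(round(x$frac_null_below * x$B)), x$B))
  cat(sprintf("  perm p (median SS): %.3g  [add-one %.3g]\n",
              x$perm_p_median, x$perm_p_median_add1))
  if (!is.na(x$mw_significant_count))
    cat(sprintf("  one-tailed MW significant at alpha=%.2f: %d/%d\n",
                x$alpha, x$mw_significant_count, x$B))
  cat(sprintf("  DE proportion: %.3f (perm p %.3g, add-one %.3g)\n",
              x$observed_de_prop, x$perm_p_deprop, x$perm_p_deprop_add1))
  cat(sprintf("  hypergeometric DE enrichment p: %.3g\n", x$hypergeom_p))
  invisible(x)
}
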