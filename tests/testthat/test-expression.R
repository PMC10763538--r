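# Expression-variance module: filtering, normalization, per-gene strain
# SS, DE stand-in, expression-matched resampling.

two_strain_samples <- function(counts) {
  smp <- setdiff(names(counts), "gene")
  tibble::tibble(sample = smp,
                 strain = rep(c("A", "B"), each = length(smp) / 2))
}

test_that("low-count filter keeps exactly the genes above the cutoff", {
  counts <- tibble::tibble(gene = c("g1", "g2", "g3"),
                           s1 = c(4L, 5L, 0L), s2 = c(6L, 6L, 0L))
  expect_identical(filter_low_counts(counts)$gene, "g2")
  all_pos <- tibble::tibble(gene = c("g1", "g2"), s1 = c(1L, 2L))
  expect_identical(filter_low_counts(all_pos, threshold = 0), all_pos)
  expect_error(filter_low_counts(counts, threshold = 100),
               class = "empty_result")
})

test_that("forcing 100 of 18,589 genes below the cutoff retains 18,489", {
  m <- matrix(2L, nrow = 18589, ncol = 15)
  m[1:100, ] <- 0L
  counts <- dplyr::bind_cols(
    tibble::tibble(gene = sprintf("g%05d", 1:18589)),
    tibble::as_tibble(m, .name_repair = ~ sprintf("s%02d", 1:15)))
  expect_equal(nrow(filter_low_counts(counts)), 18489L)
})

test_that("size factors: identity on identical samples, ratio 2 on a doubled one", {
  counts <- tibble::tibble(gene = paste0("g", 1:50),
                           s1 = 10L + (1:50), s2 = 10L + (1:50))
  norm <- normalize_vst(counts)
  expect_equal(unname(attr(norm, "size_factors")), c(1, 1),
               tolerance = 1e-12)
  expect_equal(norm$s1, log2(counts$s1 + 1), tolerance = 1e-12)
  doubled <- tibble::tibble(gene = counts$gene, s1 = counts$s1,
                            s2 = counts$s1 * 2L)
  sf <- attr(normalize_vst(doubled), "size_factors")
  expect_equal(unname(sf[2] / sf[1]), 2, tolerance = 1e-12)
})

test_that("normalization is monotone within a sample", {
  set.seed(3)
  counts <- tibble::tibble(gene = paste0("g", 1:100),
                           s1 = rpois(100, 50) + 1L,
                           s2 = rpois(100, 80) + 1L)
  norm <- normalize_vst(counts)
  ord <- order(counts$s1)
  expect_true(all(diff(norm$s1[ord]) >= 0))
})

test_that("normalization errors are classed", {
  counts <- tibble::tibble(gene = c("g1", "g2"), s1 = c(1L, 2L),
                           s2 = c(0L, 0L))
  expect_error(normalize_vst(counts), class = "size_factor_error")
  expect_error(normalize_vst(tibble::tibble(gene = "g1", s1 = 5L)),
               class = "invalid_design")
})

test_that("strain SS: (1,1) vs (3,3) gives 4; equal means give 0", {
  norm <- tibble::tibble(gene = c("gA", "gB"),
                         a1 = c(1, 2), a2 = c(1, 2),
                         b1 = c(3, 2), b2 = c(3, 2))
  samples <- tibble::tibble(sample = c("a1", "a2", "b1", "b2"),
                            strain = c("A", "A", "B", "B"))
  ss <- strain_variance(norm, samples)
  expect_equal(ss$strain_ss, c(4, 0), tolerance = 1e-12)
})

test_that("strain SS agrees with a two-pass oracle on 100 random genes", {
  set.seed(4)
  ng <- 100
  norm <- dplyr::bind_cols(
    tibble::tibble(gene = paste0("g", seq_len(ng))),
    tibble::as_tibble(matrix(rnorm(ng * 9), ng,
                             dimnames = list(NULL, paste0("s", 1:9)))))
  samples <- tibble::tibble(sample = paste0("s", 1:9),
                            strain = rep(c("A", "B", "C"), each = 3))
  ss <- strain_variance(norm, samples)
  m <- as.matrix(norm[, -1])
  for (i in seq_len(ng)) {
    expect_equal(unname(ss$strain_ss[i]),
                 oracle_strain_ss(m[i, ], samples$strain),
                 tolerance = 1e-10)
  }
})

test_that("samples absent from the sheet raise a named error", {
  norm <- tibble::tibble(gene = "g1", a1 = 1, zz9 = 2)
  samples <- tibble::tibble(sample = "a1", strain = "A")
  expect_error(strain_variance(norm, samples), "zz9",
               class = "sample_mismatch")
})

test_that("DE stand-in flags degenerate genes and needs replicates", {
  norm <- tibble::tibble(gene = c("flat", "split"),
                         a1 = c(5, 1), a2 = c(5, 1),
                         b1 = c(5, 2), b2 = c(5, 2))
  samples <- tibble::tibble(sample = c("a1", "a2", "b1", "b2"),
                            strain = c("A", "A", "B", "B"))
  de <- de_test(norm, samples)
  expect_true(all(de$degenerate))
  expect_equal(de$de_p, c(1, 0))
  one_rep <- tibble::tibble(sample = c("a1", "a2", "b1", "b2"),
                            strain = c("A", "A", "B", "C"))
  expect_error(de_test(norm, one_rep), class = "invalid_design")
})

test_that("matched pools respect the quantile window", {
  ng <- 1000
  tbl <- tibble::tibble(gene = sprintf("g%04d", seq_len(ng)),
                        expr_quantile = seq_len(ng) / ng,
                        strain_ss = 1, de_flag = FALSE)
  sets <- match_expression_sets(tbl, focal = "g0500", window = 0.005,
                                B = 2000L, seed = 1L)
  drawn <- sort(unique(as.vector(sets)))
  expect_setequal(drawn, setdiff(495:505, 500))
})

test_that("with identical expression the pool is every non-focal gene", {
  ng <- 40
  tbl <- tibble::tibble(gene = paste0("g", seq_len(ng)),
                        expr_quantile = 1, strain_ss = 1,
                        de_flag = FALSE)
  sets <- match_expression_sets(tbl, focal = c("g1", "g2"), window = 0.005,
                                B = 3000L, seed = 1L)
  expect_setequal(sort(unique(as.vector(sets))), 3:ng)
})

test_that("matching is deterministic in the seed and fails loudly", {
  ng <- 200
  tbl <- tibble::tibble(gene = paste0("g", seq_len(ng)),
                        expr_quantile = seq_len(ng) / ng,
                        strain_ss = 1, de_flag = FALSE)
  s1 <- match_expression_sets(tbl, "g100", B = 50L, seed = 9L)
  s2 <- match_expression_sets(tbl, "g100", B = 50L, seed = 9L)
  expect_identical(s1, s2)
  # Isolated focal gene with an empty pool: error names the gene.
  tbl2 <- tbl
  tbl2$expr_quantile[1] <- 0.0001
  tbl2$expr_quantile[-1] <- seq(0.5, 1, length.out = ng - 1)
  expect_error(match_expression_sets(tbl2, "g1", window = 0.005, B = 10L),
               "g1", class = "matching_failure")
})

test_that("boundary permutation p-values: 0 with ties counted, 1/101 add-one", {
  ng <- 300
  set.seed(5)
  tbl <- tibble::tibble(gene = paste0("g", seq_len(ng)),
                        expr_quantile = seq_len(ng) / ng,
                        strain_ss = runif(ng), de_flag = FALSE)
  tbl$strain_ss[150] <- 100   # observed median exceeds every null median
  res <- resampling_enrichment(tbl, "g150", B = 100L, window = 0.05,
                               seed = 1L, mw_tests = FALSE)
  expect_equal(res$perm_p_median, 0)
  expect_equal(res$perm_p_median_add1, 1 / 101)
  expect_equal(res$frac_null_below, 1)
})

test_that("frac_null_below + perm_p_median = 1 exactly", {
  ng <- 400
  set.seed(6)
  tbl <- tibble::tibble(gene = paste0("g", seq_len(ng)),
                        expr_quantile = seq_len(ng) / ng,
                        strain_ss = rexp(ng),
                        de_flag = runif(ng) < 0.2)
  focal <- sample(tbl$gene, 15)
  res <- resampling_enrichment(tbl, focal, B = 200L, window = 0.05,
                               seed = 2L, mw_tests = FALSE)
  expect_identical(res$frac_null_below + res$perm_p_median, 1)
  expect_identical(res$frac_null_deprop_below + res$perm_p_deprop, 1)
  expect_equal(res$hypergeom_p,
               hypergeom_enrichment(ng, sum(tbl$de_flag), 15,
                                    sum(tbl$de_flag[tbl$gene %in% focal])))
})

test_that("gene_variance_table reports quantiles on (0, 1] with average ties", {
  cfg <- sim_config(seed = 13L, n_genes = 300L, focal_set_size = 10L)
  sim <- sim_counts(cfg)
  tbl <- gene_variance_table(sim$counts, sim$samples)
  expect_true(all(tbl$expr_quantile > 0 & tbl$expr_quantile <= 1))
  expect_equal(tbl$expr_quantile,
               rank(tbl$mean_expr, ties.method = "average") / nrow(tbl))
  expect_true(all(c("strain_ss", "de_p", "de_fdr", "de_flag") %in%
                    names(tbl)))
})
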