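# Population-genetic statistics and allele-fate classification.

test_that("pi closed cases: no segregating sites and the 2/2 site", {
  strains <- paste0("S", 1:4)
  empty <- tibble::tibble(gene = character(), chrom = character(),
                          pos = integer(), ref = character(),
                          alt = character(), impact = character(),
                          subtype = character(), filter_pass = logical(),
                          strain = character(), gt = character())
  expect_equal(as.numeric(gene_pi(empty, "g", 100, strains)), 0)
  # One biallelic site split 2/2 over 4 strains, L = 100:
  # (4/3) * (1 - 0.5) / 100.
  v <- tibble::tibble(gene = "g", chrom = "I", pos = 10L, ref = "A",
                      alt = "T", impact = "LOW",
                      subtype = "synonymous_variant", filter_pass = TRUE,
                      strain = c("S1", "S2"), gt = "alt")
  expect_equal(as.numeric(gene_pi(v, "g", 100, strains)),
               (4 / 3) * 0.5 / 100, tolerance = 1e-12)
})

test_that("pi matches the brute-force pairwise oracle on random tables", {
  set.seed(10)
  for (r in 1:100) {
    case <- random_allele_case()
    sparse <- sparse_from_dense(case$alleles, "g", case$positions)
    got <- as.numeric(gene_pi(sparse, "g", case$gene_length,
                              case$strains))
    want <- oracle_pi_dense(case$alleles, case$gene_length)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("pi skips sites with fewer than 2 called strains", {
  strains <- c("S1", "S2")
  v <- tibble::tibble(gene = "g", chrom = "I", pos = 5L, ref = "A",
                      alt = NA_character_, impact = NA_character_,
                      subtype = NA_character_, filter_pass = NA,
                      strain = "S1", gt = "missing")
  res <- gene_pi(v, "g", 100, strains)
  expect_equal(as.numeric(res), 0)
  expect_equal(attr(res, "skipped_sites"), 1L)
})

test_that("variants per kb: 4 MODERATE over 2 kb gives 2.0; multiallelic splits", {
  v <- tibble::tibble(gene = "g", chrom = "I", pos = c(1L, 2L, 3L, 4L),
                      ref = "A", alt = "T", impact = "MODERATE",
                      subtype = "missense_variant", filter_pass = TRUE,
                      strain = "S1", gt = "alt")
  out <- variants_per_kb(v, "g", 2000)
  expect_equal(out$per_kb[out$impact == "MODERATE"], 2.0)
  expect_equal(sum(out$n), 4L)
  none <- variants_per_kb(v[0, ], "g", 2000)
  expect_true(all(none$n == 0L))
  multi <- tibble::tibble(gene = "g", chrom = "I", pos = 7L, ref = "A",
                          alt = c("T", "G"),
                          impact = c("HIGH", "MODERATE"),
                          subtype = c("stop_gained", "missense_variant"),
                          filter_pass = TRUE,
                          strain = c("S1", "S2"), gt = "alt")
  mout <- variants_per_kb(multi, "g", 1000)
  expect_equal(mout$n[mout$impact == "HIGH"], 1L)
  expect_equal(mout$n[mout$impact == "MODERATE"], 1L)
})

test_that("allele summaries: constructed fixture fractions and carrier rule", {
  strains <- c("S1", "S2")
  gm <- tibble::tibble(gene = "g", length = 1000L)
  # S1 carries 12 diverged sites and misses 3 of L = 1000 -> 1.5%.
  v <- dplyr::bind_rows(
    tibble::tibble(gene = "g", chrom = "I", pos = 1:12, ref = "A",
                   alt = "T", impact = "HIGH", subtype = "stop_gained",
                   filter_pass = TRUE, strain = "S1", gt = "alt"),
    tibble::tibble(gene = "g", chrom = "I", pos = 13:15, ref = "A",
                   alt = NA_character_, impact = NA_character_,
                   subtype = NA_character_, filter_pass = NA,
                   strain = "S1", gt = "missing"))
  tab <- allele_summary_table(v, gm, strains)
  s1 <- tab[tab$strain == "S1", ]
  s2 <- tab[tab$strain == "S2", ]
  expect_equal(s1$frac_diverged_or_missing, 0.015, tolerance = 1e-12)
  expect_equal(s1$n_high_conf_high_impact, 12L)
  # S2 never carries the alt: the HIGH records do not count against it.
  expect_equal(s2$n_high_conf_high_impact, 0L)
  expect_equal(s2$n_diverged, 0L)
})

test_that("classification rules reproduce the threshold cases", {
  base <- tibble::tibble(gene = "g", strain = "S", n_sites = 1000L,
                         n_diverged = 0L, n_missing = 0L,
                         n_high_conf_high_impact = 0L, n_aa_subs = 0L,
                         frac_diverged = 0, frac_missing = 0,
                         frac_diverged_or_missing = 0)
  pseudo <- base |> dplyr::mutate(n_high_conf_high_impact = 1L,
                                  frac_diverged_or_missing = 0.012)
  expect_equal(classify_allele(pseudo)$label, "pseudogenized")
  fdiv <- base |> dplyr::mutate(n_aa_subs = 7L, frac_diverged = 0.015)
  expect_equal(classify_allele(fdiv)$label, "functional_diverged")
  missing80 <- base |> dplyr::mutate(frac_missing = 0.80)
  cm <- classify_allele(missing80)
  expect_equal(cm$label, "pseudogenized")
  expect_true(cm$possibly_missing)
  ref <- base |> dplyr::mutate(n_aa_subs = 3L, frac_diverged = 0.005)
  cr <- classify_allele(ref)
  expect_equal(cr$label, "reference_like")
  expect_false(cr$possibly_missing)
})

test_that("haplotype diversity closed forms", {
  strains4 <- paste0("S", 1:4)
  empty <- tibble::tibble(gene = character(), chrom = character(),
                          pos = integer(), ref = character(),
                          alt = character(), impact = character(),
                          subtype = character(), filter_pass = logical(),
                          strain = character(), gt = character())
  same <- haplotypes(empty, "g", strains4)
  expect_equal(same$n_haplotypes, 1L)
  expect_equal(same$haplotype_diversity, 0)
  # 4 strains, all distinct: H = (4/3)(1 - 4/16) = 1.
  v4 <- tibble::tibble(gene = "g", chrom = "I", pos = c(1L, 2L, 3L),
                       ref = "A", alt = "T", impact = "LOW",
                       subtype = "synonymous_variant", filter_pass = TRUE,
                       strain = c("S1", "S2", "S3"), gt = "alt")
  h4 <- haplotypes(v4, "g", strains4)
  expect_equal(h4$n_haplotypes, 4L)
  expect_equal(h4$haplotype_diversity, 1, tolerance = 1e-12)
  # 3 strains with haplotype frequencies (2,1): H = (3/2)(1 - 5/9) = 2/3.
  v3 <- tibble::tibble(gene = "g", chrom = "I", pos = 1L, ref = "A",
                       alt = "T", impact = "LOW",
                       subtype = "synonymous_variant", filter_pass = TRUE,
                       strain = c("S1", "S2"), gt = "alt")
  h3 <- haplotypes(v3, "g", paste0("S", 1:3))
  expect_equal(h3$haplotype_diversity, 2 / 3, tolerance = 1e-12)
})

test_that("haplotypes exclude missing strains and respect relabeling", {
  strains <- paste0("S", 1:5)
  v <- dplyr::bind_rows(
    tibble::tibble(gene = "g", chrom = "I", pos = c(1L, 2L), ref = "A",
                   alt = "T", impact = "LOW",
                   subtype = "synonymous_variant", filter_pass = TRUE,
                   strain = c("S1", "S2"), gt = "alt"),
    tibble::tibble(gene = "g", chrom = "I", pos = 3L, ref = "A",
                   alt = NA_character_, impact = NA_character_,
                   subtype = NA_character_, filter_pass = NA,
                   strain = "S5", gt = "missing"))
  h <- haplotypes(v, "g", strains)
  expect_equal(h$excluded, "S5")
  expect_equal(nrow(h$assignment), 4L)
  # Shuffling the roster order leaves the diversity and counts unchanged.
  h2 <- haplotypes(v, "g", rev(strains))
  expect_equal(h2$haplotype_diversity, h$haplotype_diversity)
  expect_equal(h2$n_haplotypes, h$n_haplotypes)
  # Hamming distances: S1 (alt at 1) vs S2 (alt at 2) differ at 2 sites.
  expect_equal(max(h$distances), 2L)
  expect_error(haplotypes(v, "g", c("S5", "S1")),
               class = "insufficient_strains")
})

test_that("hyperdivergent masking honors the BED half-open convention", {
  gm <- tibble::tibble(gene = c("gA", "gB"), chrom = "I",
                       start = c(100L, 250L), end = c(200L, 260L))
  # BED [200, 300) covers 1-based 201-300: gA (ends at 200) untouched,
  # gB flagged.
  mask <- tibble::tibble(chrom = "I", start = 200, end = 300)
  out <- exclude_hyperdiverse(gm, mask)
  expect_false(out$hyperdiverse[out$gene == "gA"])
  expect_true(out$hyperdiverse[out$gene == "gB"])
  empty <- exclude_hyperdiverse(gm, mask[0, ])
  expect_false(any(empty$hyperdiverse))
  expect_error(exclude_hyperdiverse(gm, tibble::tibble(chrom = "I",
                                                       start = 5,
                                                       end = 5)),
               class = "parse_error")
})

test_that("masking agrees with a brute-force overlap scan", {
  set.seed(11)
  gm <- tibble::tibble(gene = paste0("g", 1:50),
                       chrom = sample(c("I", "II"), 50, replace = TRUE),
                       start = sample(1:1000, 50))
  gm$end <- gm$start + sample(10:200, 50, replace = TRUE)
  mask <- tibble::tibble(chrom = sample(c("I", "II"), 10, replace = TRUE),
                         start = sample(0:900, 10))
  mask$end <- mask$start + sample(20:150, 10, replace = TRUE)
  out <- exclude_hyperdiverse(gm, mask)
  for (i in 1:50) {
    gene_bases <- gm$start[i]:gm$end[i]
    hit <- FALSE
    for (j in 1:10) {
      if (mask$chrom[j] != gm$chrom[i]) next
      mask_bases <- (mask$start[j] + 1):mask$end[j]   # 1-based view
      if (length(intersect(gene_bases, mask_bases))) hit <- TRUE
    }
    expect_equal(out$hyperdiverse[i], hit)
  }
})

test_that("geneset_compare enumerates small sets and guards overlap", {
  values <- tibble::tibble(gene = paste0("g", 1:5), value = 1:5)
  res <- geneset_compare(values, c("g1", "g2"), c("g3", "g4", "g5"))
  expect_equal(res$p_value, 0.2, tolerance = 1e-12)
  expect_equal(res$median_focal, 1.5)
  expect_equal(res$median_background, 4)
  expect_error(geneset_compare(values, "g1", c("g1", "g2")),
               class = "set_overlap")
  expect_error(geneset_compare(values, "gX", "g2"),
               class = "unknown_gene")
  expect_error(geneset_compare(values, character(), "g2"),
               class = "empty_group")
})

test_that("allele_fate_table aggregates per-gene counts and pi", {
  cfg <- sim_config(seed = 17L, n_popgen_genes = 6L,
                    n_popgen_strains = 15L)
  sv <- sim_variants(cfg)
  fate <- allele_fate_table(sv$variants, sv$gene_models, sv$strains)
  expect_equal(nrow(fate), 6L)
  expect_true(all(fate$pi >= 0))
  truth_counts <- sv$truth |>
    dplyr::group_by(gene) |>
    dplyr::summarise(
      n_pseudo = sum(expected_label == "pseudogenized"),
      n_fdiv = sum(expected_label == "functional_diverged"))
  merged <- dplyr::left_join(fate, truth_counts, by = "gene")
  expect_equal(merged$n_pseudogenized, merged$n_pseudo)
  expect_equal(merged$n_functional_diverged, merged$n_fdiv)
})
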