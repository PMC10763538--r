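# Per-gene diversity statistics and rule-based allele-fate classification
# from sparse population variant records.
#
# Variant tables are sparse and haploid: one row per non-reference call
# (gt = "alt") or missed call (gt = "missing"); strains without a row at a
# site implicitly carry the reference allele. Selfing isotypes justify the
# haploid treatment; heterozygous calls are converted to missing at read
# time.

.gene_variants <- function(variants, gene) {
  variants[!is.na(variants$gene) & variants$gene == gene, , drop = FALSE]
}

#' Per-site nucleotide diversity for one gene
#'
#' pi = (1/L) * sum over sites of (n_s / (n_s - 1)) * (1 - sum_a p_a^2),
#' where n_s counts strains with a called (non-missing) allele at the
#' site and p_a are allele frequencies among them. Monomorphic sites
#' contribute 0 and the denominator is the full gene length, so pi is a
#' per-site average. Sites with fewer than 2 called strains are skipped;
#' the skip count is attached as `attr(, "skipped_sites")`.
#'
#' @param variants Sparse variant tibble.
#' @param gene Gene id.
#' @param gene_length Gene length in bp.
#' @param strains Character vector: the full strain roster (needed to
#'   count implicit reference carriers).
#' @return Nucleotide diversity per site (numeric scalar).
#' @export
gene_pi <- function(variants, gene, gene_length, strains) {
  S <- length(strains)
  if (S < 2L) stop_rnaivar("need at least 2 strains", "invalid_design")
  v <- .gene_variants(variants, gene)
  if (nrow(v) == 0L) {
    return(structure(0, skipped_sites = 0L))
  }
  per_site <- v |>
    group_by(.data$pos) |>
    summarise(
      n_miss = n_distinct(.data$strain[.data$gt == "missing"]),
      sum_c2 = sum(table(.data$alt[.data$gt == "alt"])^2),
      n_alt = n_distinct(.data$strain[.data$gt == "alt"]),
      .groups = "drop") |>
    mutate(n_s = S - .data$n_miss,
           ref_n = pmax(.data$n_s - .data$n_alt, 0))
  usable <- per_site$n_s >= 2L
  skipped <- sum(!usable)
  ps <- per_site[usable, ]
  h <- with(ps, (n_s / (n_s - 1)) * (1 - (sum_c2 + ref_n^2) / n_s^2))
  structure(sum(h) / gene_length, skipped_sites = skipped)
}

#' Variant counts per kb by impact class
#'
#' Counts distinct variant records (site, alt allele) per impact class,
#' scaled to per-kb. A multiallelic site with alts of different classes
#' contributes one count to each class.
#'
#' @inheritParams gene_pi
#' @return A tibble `impact`, `n`, `per_kb` covering HIGH, MODERATE, LOW
#'   and MODIFIER.
#' @export
variants_per_kb <- function(variants, gene, gene_length) {
  if (gene_length <= 0) stop_rnaivar("gene_length must be > 0",
                                     "invalid_design")
  classes <- c("HIGH", "MODERATE", "LOW", "MODIFIER")
  v <- .gene_variants(variants, gene)
  v <- v[v$gt == "alt" & !is.na(v$impact), c("pos", "alt", "impact")]
  n <- v |> distinct() |> count(.data$impact)
  out <- tibble(impact = classes) |>
    left_join(n, by = "impact") |>
    mutate(n = tidyr::replace_na(.data$n, 0L),
           per_kb = .data$n * 1000 / gene_length)
  out
}

#' Allele summaries for every (gene, strain) cell
#'
#' Workhorse behind [summarize_allele()] and [classify_allele()]:
#' per-(gene, strain) counts of diverged sites, missed calls,
#' high-confidence HIGH-impact mutations carried, and MODERATE missense
#' substitutions carried, with the derived fractions over gene length.
#' Cells with no records are reference-identical (all zeros).
#'
#' A high-impact mutation is counted only when the strain carries the alt
#' allele and the record passed the variant filter (the high-confidence
#' flag).
#'
#' @param variants Sparse variant tibble.
#' @param gene_models Tibble `gene`, `length` (other columns ignored).
#' @param strains Full strain roster.
#' @return A tibble with one row per (gene, strain): counts `n_sites`,
#'   `n_diverged`, `n_missing`, `n_high_conf_high_impact`, `n_aa_subs`
#'   and fractions `frac_diverged`, `frac_missing`,
#'   `frac_diverged_or_missing`.
#' @export
allele_summary_table <- function(variants, gene_models, strains) {
  counted <- variants |>
    filter(.data$gene %in% gene_models$gene) |>
    group_by(.data$gene, .data$strain) |>
    summarise(
      n_diverged = n_distinct(.data$pos[.data$gt == "alt"]),
      n_missing = n_distinct(.data$pos[.data$gt == "missing"]),
      n_high_conf_high_impact = sum(
        .data$gt == "alt" & !is.na(.data$impact) &
          .data$impact == "HIGH" & !is.na(.data$filter_pass) &
          .data$filter_pass),
      n_aa_subs = sum(
        .data$gt == "alt" & !is.na(.data$impact) &
          .data$impact == "MODERATE" & !is.na(.data$subtype) &
          grepl("missense", .data$subtype)),
      .groups = "drop")
  tidyr::expand_grid(gene = gene_models$gene, strain = strains) |>
    left_join(counted, by = c("gene", "strain")) |>
    mutate(across(c("n_diverged", "n_missing", "n_high_conf_high_impact",
                    "n_aa_subs"),
                  ~ tidyr::replace_na(.x, 0L))) |>
    left_join(gene_models[, c("gene", "length")], by = "gene") |>
    rename(n_sites = "length") |>
    mutate(frac_diverged = .data$n_diverged / .data$n_sites,
           frac_missing = .data$n_missing / .data$n_sites,
           frac_diverged_or_missing =
             (.data$n_diverged + .data$n_missing) / .data$n_sites)
}

#' Summarize one strain's allele at one gene
#'
#' @inheritParams allele_summary_table
#' @param gene,strain The cell to summarize.
#' @param gene_length Gene length in bp.
#' @return One-row tibble; see [allele_summary_table()].
#' @export
summarize_allele <- function(variants, gene, strain, gene_length,
                             strains) {
  if (!strain %in% strains)
    stop_rnaivar(paste0("unknown strain: ", strain), "unknown_strain")
  allele_summary_table(variants,
                       tibble(gene = gene, length = gene_length),
                       strains) |>
    filter(.data$strain == !!strain)
}

#' Classify allele fates from summaries
#'
#' Rule-based fates: an allele is `pseudogenized` if it carries at least
#' one high-confidence high-impact mutation and at least 1% of sites are
#' diverged or missing relative to the reference, or if over 50% of sites
#' are missed calls; it is `functional_diverged` if it carries at least 5
#' amino-acid substitutions (MODERATE missense), at least 1% divergence
#' across sites, and no high-impact calls; otherwise it is
#' `reference_like`. Alleles with more than 75% of sites uncalled are
#' additionally flagged `possibly_missing` (such alleles may represent
#' missing genes; the flag implies the pseudogenized label).
#'
#' @param summary Tibble from [allele_summary_table()] (any number of
#'   rows).
#' @param thresholds Named list overriding the defaults
#'   `div_miss = 0.01`, `miss_pseudo = 0.50`, `aa_subs = 5`,
#'   `divergence = 0.01`, `possibly_missing = 0.75`.
#' @return `summary` with `label` and `possibly_missing` columns added.
#' @export
classify_allele <- function(summary, thresholds = list()) {
  th <- utils::modifyList(
    list(div_miss = 0.01, miss_pseudo = 0.50, aa_subs = 5,
         divergence = 0.01, possibly_missing = 0.75),
    thresholds)
  summary |>
    mutate(
      label = case_when(
        (.data$n_high_conf_high_impact >= 1 &
           .data$frac_diverged_or_missing >= th$div_miss) |
          .data$frac_missing > th$miss_pseudo ~ "pseudogenized",
        .data$n_aa_subs >= th$aa_subs &
          .data$frac_diverged >= th$divergence &
          .data$n_high_conf_high_impact == 0 ~ "functional_diverged",
        .default = "reference_like"),
      possibly_missing = .data$frac_missing > th$possibly_missing)
}

#' Per-gene allele-fate counts across the population
#'
#' Mirrors a per-gene summary table: for each gene, nucleotide
#' diversity, the number of strains with functionally diverged alleles,
#' pseudogenized alleles, and possibly-missing alleles.
#'
#' @inheritParams allele_summary_table
#' @param thresholds Passed to [classify_allele()].
#' @return A tibble `gene`, `pi`, `n_functional_diverged`,
#'   `n_pseudogenized`, `n_possibly_missing`.
#' @export
allele_fate_table <- function(variants, gene_models, strains,
                              thresholds = list()) {
  cls <- allele_summary_table(variants, gene_models, strains) |>
    classify_allele(thresholds)
  pis <- vapply(seq_len(nrow(gene_models)), function(i)
    as.numeric(gene_pi(variants, gene_models$gene[i],
                       gene_models$length[i], strains)),
    numeric(1))
  cls |>
    group_by(.data$gene) |>
    summarise(
      n_functional_diverged = sum(.data$label == "functional_diverged"),
      n_pseudogenized = sum(.data$label == "pseudogenized"),
      n_possibly_missing = sum(.data$possibly_missing),
      .groups = "drop") |>
    left_join(tibble(gene = gene_models$gene, pi = pis), by = "gene") |>
    select("gene", "pi", everything())
}

#' Collapse strains into haplotypes at one gene
#'
#' Strains with any missed call at the gene are excluded (and reported).
#' Remaining strains are collapsed by identical allele vectors over the
#' gene's variant sites; haplotype diversity is the small-sample
#' corrected probability that two sampled haplotypes differ,
#' H = (n / (n - 1)) * (1 - sum p_i^2). A Hamming distance matrix between
#' the distinct haplotypes is returned (network layout is out of scope).
#'
#' @inheritParams gene_pi
#' @return An object of class `rnai_haplotypes`: a list with
#'   `assignment` (tibble `strain`, `haplotype`), `n_haplotypes`,
#'   `haplotype_diversity`, `distances` (matrix), `excluded` (strains
#'   dropped for missingness).
#' @export
haplotypes <- function(variants, gene, strains) {
  v <- .gene_variants(variants, gene)
  excluded <- unique(v$strain[v$gt == "missing"])
  usable <- setdiff(strains, excluded)
  n <- length(usable)
  if (n < 2L)
    stop_rnaivar("fewer than 2 strains with complete calls",
                 "insufficient_strains")
  carried <- v[v$gt == "alt" & v$strain %in% usable,
               c("pos", "alt", "strain")]
  sites <- sort(unique(carried$pos))
  sig <- vapply(usable, function(s) {
    rows <- carried[carried$strain == s, ]
    if (nrow(rows) == 0L) return("")
    paste(sprintf("%d:%s", rows$pos[order(rows$pos)],
                  rows$alt[order(rows$pos)]), collapse = ";")
  }, character(1))
  hap_levels <- unique(sig)
  hap_id <- match(sig, hap_levels)
  freq <- tabulate(hap_id, length(hap_levels)) / n
  H <- if (length(hap_levels) == 1L) 0
       else (n / (n - 1)) * (1 - sum(freq^2))
  # Hamming distances over variant sites between distinct haplotypes.
  allele_at <- function(h, p) {
    rows <- strsplit(h, ";")[[1]]
    if (length(rows) == 0L || identical(h, "")) return(rep("ref",
                                                           length(p)))
    kv <- do.call(rbind, strsplit(rows, ":"))
    out <- rep("ref", length(p))
    out[match(as.integer(kv[, 1]), p)] <- kv[, 2]
    out
  }
  k <- length(hap_levels)
  d <- matrix(0L, k, k,
              dimnames = list(paste0("hap", seq_len(k)),
                              paste0("hap", seq_len(k))))
  if (k > 1L && length(sites) > 0L) {
    mat <- vapply(hap_levels, allele_at, character(length(sites)),
                  p = sites)
    mat <- matrix(mat, nrow = length(sites))
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      d[i, j] <- d[j, i] <- sum(mat[, i] != mat[, j])
    }
  }
  structure(list(
    assignment = tibble(strain = usable,
                        haplotype = paste0("hap", hap_id)),
    n_haplotypes = length(hap_levels),
    haplotype_diversity = H,
    distances = d,
    excluded = excluded), class = "rnai_haplotypes")
}

#' @export
print.rnai_haplotypes <- function(x, ...) {
  cat(sprintf("%d haplotypes over %d strains (H = %.4f); %d excluded\n",
              x$n_haplotypes, nrow(x$assignment),
              x$haplotype_diversity, length(x$excluded)))
  invisible(x)
}

#' Flag and exclude genes overlapping hyperdivergent intervals
#'
#' Genes (1-based inclusive spans) are flagged when they overlap any
#' masked interval (BED convention: 0-based half-open). When the mask
#' carries a `strain` column the flag is strain-aware: overlap in any
#' strain flags the gene.
#'
#' @param gene_models Tibble `gene`, `chrom`, `start`, `end`.
#' @param mask Tibble `chrom`, `start`, `end` (0-based half-open),
#'   optional `strain`.
#' @return `gene_models` with a logical `hyperdiverse` column added.
#' @export
exclude_hyperdiverse <- function(gene_models, mask) {
  if (nrow(mask) > 0 &&
      (!all(c("chrom", "start", "end") %in% names(mask)) ||
       any(!is.finite(mask$start)) || any(!is.finite(mask$end)) ||
       any(mask$end <= mask$start)))
    stop_rnaivar("malformed mask interval", "parse_error")
  hits <- gene_models |>
    inner_join(mask, by = "chrom", suffix = c("", ".mask"),
               relationship = "many-to-many") |>
    filter(.data$start <= .data$end.mask,            # gene_start <= bed_end
           .data$end >= .data$start.mask + 1) |>     # gene_end >= bed_start+1
    distinct(.data$gene)
  gene_models |>
    mutate(hyperdiverse = .data$gene %in% hits$gene)
}

#' Compare a per-gene statistic between a focal set and the background
#'
#' Two-sided, tie-corrected Mann-Whitney comparison of a per-gene
#' statistic (nucleotide diversity, variants per kb, ...) between a
#' focal gene set and a background set, with exact enumeration when both
#' sides have at most 10 genes.
#'
#' @param values Tibble `gene`, `value`.
#' @param focal,background Character vectors of gene ids.
#' @param include_focal Allow the background to contain focal genes
#'   (otherwise overlap is an error).
#' @return A one-row tibble: medians, test p-value and set sizes.
#' @export
geneset_compare <- function(values, focal, background,
                            include_focal = FALSE) {
  if (length(focal) == 0L || length(background) == 0L)
    stop_rnaivar("both sets must be nonempty", "empty_group")
  if (!include_focal && length(intersect(focal, background)))
    stop_rnaivar("focal and background sets overlap", "set_overlap")
  vf <- values$value[match(focal, values$gene)]
  vb <- values$value[match(background, values$gene)]
  if (anyNA(vf) || anyNA(vb))
    stop_rnaivar("genes missing from values table", "unknown_gene")
  mt <- mw_test(vf, vb, "two.sided")
  tibble(median_focal = median(vf), median_background = median(vb),
         statistic = mt$statistic, p_value = mt$p.value,
         n_focal = length(vf), n_background = length(vb))
}
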