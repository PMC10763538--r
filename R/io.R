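# Readers and writers for the external formats, with coordinate
# conventions centralized here: VCF positions are 1-based inclusive, BED
# intervals 0-based half-open, and all internal gene spans 1-based
# inclusive.
#
# Writers embed the producing seed/parameter set as `# key=value` header
# comments; readers skip `#` lines.

.write_meta <- function(path, meta) {
  if (length(meta))
    writeLines(sprintf("# %s=%s", names(meta),
                       vapply(meta, function(v)
                         paste(format(v), collapse = ","), character(1))),
               path)
}

.append_tsv <- function(x, path, meta) {
  .write_meta(path, meta)
  readr::write_tsv(x, path, append = length(meta) > 0,
                   col_names = TRUE)
}

#' Read a gene x sample counts TSV
#'
#' Expects a header row, a gene-id first column and one integer column
#' per sample. Non-integer cells raise a parse error naming the row and
#' column.
#'
#' @param path TSV path.
#' @return Counts tibble (`gene` + sample columns).
#' @export
read_counts <- function(path) {
  x <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                       progress = FALSE)
  names(x)[1] <- "gene"
  for (j in seq(2, ncol(x))) {
    v <- x[[j]]
    if (!is.numeric(v))
      stop_rnaivar(sprintf("non-numeric counts in column %s", names(x)[j]),
                   "parse_error")
    bad <- which(is.na(v) | v < 0 | v != floor(v))
    if (length(bad))
      stop_rnaivar(sprintf("non-integer count at row %d, column %s",
                           bad[1], names(x)[j]), "parse_error")
    x[[j]] <- as.integer(v)
  }
  x
}

#' Read a sample sheet TSV (`sample`, `strain`)
#' @param path TSV path.
#' @return Tibble `sample`, `strain`.
#' @export
read_samples <- function(path) {
  x <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                       progress = FALSE)
  if (!all(c("sample", "strain") %in% names(x)))
    stop_rnaivar("sample sheet needs sample and strain columns",
                 "parse_error")
  x[, c("sample", "strain")]
}

#' Read a focal gene list (one id per line)
#' @param path File path.
#' @return Character vector of gene ids.
#' @export
read_focal_genes <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Read gene models (`gene`, `chrom`, `start`, `end`; 1-based inclusive)
#' @param path TSV path.
#' @return Tibble with a derived `length` column.
#' @export
read_gene_models <- function(path) {
  x <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                       progress = FALSE)
  need <- c("gene", "chrom", "start", "end")
  if (!all(need %in% names(x)))
    stop_rnaivar("gene models need gene, chrom, start, end columns",
                 "parse_error")
  if (any(x$end < x$start))
    stop_rnaivar("gene end before start", "parse_error")
  x$length <- as.integer(x$end - x$start + 1)
  x
}

#' Read a BED mask of hyperdivergent intervals (0-based half-open)
#'
#' Columns: chrom, start, end, optional strain. Malformed intervals
#' raise a parse error with the offending line number.
#'
#' @param path BED path.
#' @return Tibble `chrom`, `start`, `end` (+ `strain` if present).
#' @export
read_mask <- function(path) {
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) & !startsWith(lines, "#") &
    !startsWith(lines, "track")
  rows <- strsplit(lines[keep], "\t")
  lineno <- which(keep)
  out <- purrr::map2(rows, lineno, function(f, i) {
    if (length(f) < 3L)
      stop_rnaivar(sprintf("malformed BED interval at line %d", i),
                   "parse_error")
    s <- suppressWarnings(as.numeric(f[2]))
    e <- suppressWarnings(as.numeric(f[3]))
    if (is.na(s) || is.na(e) || e <= s)
      stop_rnaivar(sprintf("malformed BED interval at line %d", i),
                   "parse_error")
    tibble(chrom = f[1], start = s, end = e,
           strain = if (length(f) >= 4L) f[4] else NA_character_)
  }) |> bind_rows()
  if (nrow(out) == 0L)
    return(tibble(chrom = character(), start = numeric(),
                  end = numeric()))
  if (all(is.na(out$strain))) out$strain <- NULL
  out
}

# Map one genotype string to "ref", "alt<i>" or "missing" (haploid view;
# heterozygous calls become missing with a warning).
.haploidize <- function(gt) {
  a <- strsplit(gsub("\\|", "/", gt), "/")
  vapply(a, function(al) {
    al <- al[al != ""]
    if (length(al) == 0L || all(al == ".")) return("missing")
    u <- unique(al)
    if (length(u) > 1L) return("het")
    u
  }, character(1))
}

#' Read population variants into the sparse table
#'
#' Accepts either a VCF (with SnpEff-style `ANN` annotations; FILTER is
#' captured as the high-confidence flag) or the package's simplified
#' variant TSV dialect: columns `gene`, `chrom`, `pos`, `ref`, `alt`,
#' `impact`, `subtype`, `filter`, then one genotype column per strain
#' with codes `0` (reference), `1` (carries this row's alt) and `.`
#' (missed call).
#'
#' Records are mapped to genes by span overlap against `gene_models`;
#' records outside any gene are retained with `gene = NA` and counted in
#' `attr(, "unassigned")`. Heterozygous calls are treated as missing
#' with a warning. Multiallelic VCF records yield one row per alt
#' allele.
#'
#' @param path VCF or TSV path.
#' @param gene_models Tibble from [read_gene_models()].
#' @return A list: `variants` (sparse long tibble), `strains` (roster).
#' @export
read_variants <- function(path, gene_models) {
  first <- readLines(path, n = 1L)
  if (grepl("\\.vcf$", path) || startsWith(first, "##fileformat=VCF"))
    .read_variants_vcf(path, gene_models)
  else .read_variants_tsv(path, gene_models)
}

.assign_gene <- function(tbl, gene_models) {
  gidx <- rep(NA_integer_, nrow(tbl))
  for (i in seq_len(nrow(gene_models))) {
    hit <- tbl$chrom == gene_models$chrom[i] &
      tbl$pos >= gene_models$start[i] & tbl$pos <= gene_models$end[i]
    gidx[hit & is.na(gidx)] <- i
  }
  tbl$gene <- gene_models$gene[gidx]
  tbl
}

.read_variants_tsv <- function(path, gene_models) {
  x <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                       progress = FALSE)
  fixed <- c("gene", "chrom", "pos", "ref", "alt", "impact", "subtype",
             "filter")
  if (!all(fixed %in% names(x)))
    stop_rnaivar("variant TSV missing dialect columns", "parse_error")
  strains <- setdiff(names(x), fixed)
  long <- x |>
    mutate(across(all_of(strains), as.character)) |>
    tidyr::pivot_longer(all_of(strains), names_to = "strain",
                        values_to = "code") |>
    mutate(code = as.character(.data$code)) |>
    filter(.data$code != "0")
  het <- long$code %in% c("0/1", "1/0", "0|1", "1|0")
  if (any(het)) {
    warn(sprintf("%d heterozygous call(s) treated as missing", sum(het)))
    long$code[het] <- "."
  }
  out <- long |>
    mutate(gt = ifelse(.data$code == ".", "missing", "alt"),
           filter_pass = ifelse(.data$gt == "alt",
                                .data$filter == "PASS", NA),
           alt = ifelse(.data$gt == "alt", .data$alt, NA_character_),
           impact = ifelse(.data$gt == "alt", .data$impact,
                           NA_character_),
           subtype = ifelse(.data$gt == "alt", .data$subtype,
                            NA_character_)) |>
    select("gene", "chrom", "pos", "ref", "alt", "impact", "subtype",
           "filter_pass", "strain", "gt") |>
    distinct()
  unassigned <- sum(is.na(out$gene))
  structure(list(variants = out, strains = strains),
            unassigned = unassigned)
}

.read_variants_vcf <- function(path, gene_models) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  ann <- vcfR::extract.info(vcf, element = "ANN")
  strains <- colnames(gt)
  miss_ann <- FALSE
  recs <- purrr::map(seq_len(nrow(fix)), function(i) {
    alts <- strsplit(fix$ALT[i], ",")[[1]]
    ann_i <- if (!is.null(ann) && !is.na(ann[i]))
      strsplit(ann[i], ",")[[1]] else character(0)
    ann_fields <- strsplit(ann_i, "\\|")
    ann_allele <- vapply(ann_fields, function(f) f[1] %||% "",
                         character(1))
    calls <- .haploidize(gt[i, ])
    het <- calls == "het"
    calls[het] <- "missing"
    pos <- as.integer(fix$POS[i])
    rows <- list()
    miss_strains <- strains[calls == "missing"]
    if (length(miss_strains))
      rows <- c(rows, list(tibble(
        chrom = fix$CHROM[i], pos = pos, ref = fix$REF[i],
        alt = NA_character_, impact = NA_character_,
        subtype = NA_character_, filter_pass = NA,
        strain = miss_strains, gt = "missing")))
    for (ai in seq_along(alts)) {
      carriers <- strains[calls == as.character(ai)]
      if (!length(carriers)) next
      af <- ann_fields[which(ann_allele == alts[ai])]
      if (length(af) == 0L) {
        impact <- "MODIFIER"; subtype <- NA_character_
        miss_ann <<- TRUE
      } else {
        impact <- af[[1]][3] %||% "MODIFIER"
        subtype <- af[[1]][2] %||% NA_character_
      }
      rows <- c(rows, list(tibble(
        chrom = fix$CHROM[i], pos = pos, ref = fix$REF[i],
        alt = alts[ai], impact = impact, subtype = subtype,
        filter_pass = fix$FILTER[i] %in% c("PASS", "."),
        strain = carriers, gt = "alt")))
    }
    c(n_het = sum(het), rows)
  })
  n_het <- sum(vapply(recs, function(r) r$n_het, numeric(1)))
  if (n_het > 0)
    warn(sprintf("%d heterozygous call(s) treated as missing", n_het))
  if (miss_ann) warn("records without ANN assigned impact MODIFIER")
  out <- bind_rows(purrr::map(recs, function(r) bind_rows(r[-1])))
  out <- .assign_gene(out, gene_models)
  out <- out[, c("gene", "chrom", "pos", "ref", "alt", "impact",
                 "subtype", "filter_pass", "strain", "gt")]
  structure(list(variants = out, strains = strains),
            unassigned = sum(is.na(out$gene)))
}

#' Write a counts matrix (or any tibble) as TSV with metadata comments
#'
#' @param x Tibble to write.
#' @param path Output path.
#' @param meta Named list embedded as `# key=value` header comments
#'   (seeds and parameters of the producing run).
#' @return `path`, invisibly.
#' @export
write_tsv_meta <- function(x, path, meta = list()) {
  .append_tsv(x, path, meta)
  invisible(path)
}

#' Write a sparse variant table in the simplified TSV dialect
#'
#' One row per distinct alt record (plus one all-missing row for sites
#' observed only as missed calls); genotype columns hold `0`, `1` or
#' `.`.
#'
#' @param variants Sparse long variant tibble.
#' @param strains Full strain roster (becomes the genotype columns).
#' @param path Output path.
#' @param meta Metadata comments, as in [write_tsv_meta()].
#' @return `path`, invisibly.
#' @export
write_variants_tsv <- function(variants, strains, path, meta = list()) {
  alt_rows <- variants |> filter(.data$gt == "alt") |>
    distinct(.data$gene, .data$chrom, .data$pos, .data$ref, .data$alt,
             .data$impact, .data$subtype, .data$filter_pass)
  miss <- variants |> filter(.data$gt == "missing")
  miss_only <- miss |>
    anti_join(alt_rows, by = c("gene", "chrom", "pos")) |>
    distinct(.data$gene, .data$chrom, .data$pos, .data$ref) |>
    mutate(alt = NA_character_, impact = NA_character_,
           subtype = NA_character_, filter_pass = NA)
  rows <- bind_rows(alt_rows, miss_only) |>
    arrange(.data$chrom, .data$pos, .data$alt)
  carriers <- variants |> filter(.data$gt == "alt")
  gtm <- matrix("0", nrow(rows), length(strains),
                dimnames = list(NULL, strains))
  key <- paste(rows$gene, rows$pos, rows$alt)
  ckey <- paste(carriers$gene, carriers$pos, carriers$alt)
  hit <- match(ckey, key)
  gtm[cbind(hit, match(carriers$strain, strains))] <- "1"
  mkey_rows <- paste(rows$gene, rows$pos)
  mkey <- paste(miss$gene, miss$pos)
  for (r in which(mkey_rows %in% mkey)) {
    ms <- miss$strain[mkey == mkey_rows[r]]
    gtm[r, match(ms, strains)] <- "."
  }
  out <- bind_cols(
    rows |> mutate(filter = ifelse(is.na(.data$filter_pass), ".",
                                   ifelse(.data$filter_pass, "PASS",
                                          "FAIL"))) |>
      select("gene", "chrom", "pos", "ref", "alt", "impact", "subtype",
             "filter"),
    as_tibble(gtm))
  .append_tsv(out, path, meta)
  invisible(path)
}

#' Write a BED mask (0-based half-open)
#' @param mask Tibble `chrom`, `start`, `end` (+ optional `strain`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  cols <- intersect(c("chrom", "start", "end", "strain"), names(mask))
  readr::write_tsv(mask[, cols], path, col_names = FALSE)
  invisible(path)
}
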