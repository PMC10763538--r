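# Independent brute-force oracles used by the unit and acceptance tests.
# These deliberately avoid the package's own vectorized code paths.

# Nucleotide diversity from a dense strain x site allele matrix
# (characters; NA = missed call): per site, the fraction of differing
# unordered pairs among called strains, summed and divided by the gene
# length. Sites with < 2 called strains are skipped.
oracle_pi_dense <- function(alleles, gene_length) {
  total <- 0
  for (j in seq_len(ncol(alleles))) {
    a <- alleles[, j]
    a <- a[!is.na(a)]
    ns <- length(a)
    if (ns < 2L) next
    diff_pairs <- 0L
    for (i1 in seq_len(ns - 1L)) for (i2 in (i1 + 1L):ns) {
      if (a[i1] != a[i2]) diff_pairs <- diff_pairs + 1L
    }
    total <- total + diff_pairs / choose(ns, 2)
  }
  total / gene_length
}

# Convert a dense allele matrix (rownames = strains, "ref"/alt bases/NA)
# into the package's sparse long variant tibble for one gene.
sparse_from_dense <- function(alleles, gene, positions) {
  rows <- list()
  for (j in seq_len(ncol(alleles))) {
    for (s in rownames(alleles)) {
      a <- alleles[s, j]
      if (is.na(a)) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          gene = gene, chrom = "I", pos = positions[j], ref = "A",
          alt = NA_character_, impact = NA_character_,
          subtype = NA_character_, filter_pass = NA,
          strain = s, gt = "missing")
      } else if (a != "ref") {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          gene = gene, chrom = "I", pos = positions[j], ref = "A",
          alt = a, impact = "LOW", subtype = "synonymous_variant",
          filter_pass = TRUE, strain = s, gt = "alt")
      }
    }
  }
  if (length(rows) == 0L) {
    return(tibble::tibble(gene = character(), chrom = character(),
                          pos = integer(), ref = character(),
                          alt = character(), impact = character(),
                          subtype = character(), filter_pass = logical(),
                          strain = character(), gt = character()))
  }
  dplyr::bind_rows(rows)
}

# Random dense allele table for the pi oracle property test.
random_allele_case <- function(max_strains = 8L, max_sites = 50L) {
  S <- sample(2:max_strains, 1)
  L <- sample(20:200, 1)
  n_sites <- sample(0:min(max_sites, L), 1)
  strains <- sprintf("S%02d", seq_len(S))
  positions <- if (n_sites > 0) sort(sample.int(L, n_sites)) else integer(0)
  alleles <- matrix("ref", nrow = S, ncol = n_sites,
                    dimnames = list(strains, NULL))
  for (j in seq_len(n_sites)) {
    for (i in seq_len(S)) {
      u <- runif(1)
      if (u < 0.15) alleles[i, j] <- NA_character_
      else if (u < 0.50) alleles[i, j] <- sample(c("C", "G", "T"), 1)
    }
  }
  list(alleles = alleles, strains = strains, positions = positions,
       gene_length = L)
}

# Two-pass per-gene between-strain sum of squares, one gene at a time.
oracle_strain_ss <- function(values, groups) {
  grand <- mean(values)
  ss <- 0
  for (g in unique(groups)) {
    v <- values[groups == g]
    ss <- ss + length(v) * (mean(v) - grand)^2
  }
  ss
}

# Exact hypergeometric upper tail by full enumeration of all C(N, n)
# draws from a population of K successes (only feasible for N <= 12).
oracle_hypergeom_enum <- function(N, K, n, k) {
  pop <- c(rep(1L, K), rep(0L, N - K))
  draws <- utils::combn(N, n)
  hits <- apply(draws, 2, function(idx) sum(pop[idx]))
  mean(hits >= k)
}

# Brute-force excess-mass values: over the alternating weight sequence
# (1/n at each sorted point, -lambda * gap between), the best single
# contiguous segment sum (E1) and the best sum of at most two disjoint
# segments (E2), by exhaustive search.
oracle_excess_mass <- function(xs, lambda) {
  n <- length(xs)
  m <- 2L * n - 1L
  w <- numeric(m)
  w[seq(1L, m, by = 2L)] <- 1 / n
  if (n > 1L) w[seq(2L, m - 1L, by = 2L)] <- -lambda * diff(xs)
  seg <- matrix(-Inf, m, m)
  for (i in seq_len(m)) for (j in i:m) seg[i, j] <- sum(w[i:j])
  e1 <- max(seg)
  e2 <- e1
  for (i in seq_len(m)) for (j in i:m) {
    if (j + 2L <= m) {
      for (i2 in (j + 2L):m) for (j2 in i2:m) {
        e2 <- max(e2, seg[i, j] + seg[i2, j2])
      }
    }
  }
  list(e1 = e1, e2 = e2)
}

# Benjamini-Hochberg by the textbook definition.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj_sorted <- rev(cummin(rev(p[o] * m / seq_len(m))))
  out <- numeric(m)
  out[o] <- pmin(1, adj_sorted)
  out
}
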