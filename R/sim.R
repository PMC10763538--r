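#' Simulation configuration for synthetic study data
#'
#' Builds the configuration object consumed by the `sim_*()` generators.
#' Defaults emulate the designs of the study the package supports: a
#' 5-strain x 3-replicate bulk RNA-seq experiment over 18,589 genes with a
#' 61-gene focal set; a 403-isotype population variant table; plate-based
#' embryonic-lethality assays with 100-200 embryos per plate; and
#' per-embryo transcript counts that decline with embryonic stage, with
#' knockdown and on/off mixture regimes.
#'
#' Effect-size knobs that no experimental design fixes (strain-effect SDs,
#' negative-binomial dispersion, intra-plate correlation) are calibration
#' defaults, not estimates of any real data set.
#'
#' @param seed Integer seed. Each generator draws from its own stream,
#'   derived as `seed + <stage offset>`, so adding one stage never perturbs
#'   another stage's draws.
#' @param n_genes,n_strains,n_reps_per_strain RNA-seq design.
#' @param focal_set_size Number of focal (RNAi-pathway-like) genes.
#' @param baseline_log_mean_range Range (log2 scale) for per-gene baseline
#'   mean counts.
#' @param strain_sd_background,strain_sd_focal SD (log2 units) of
#'   per-(gene,strain) expression effects for background and focal genes.
#' @param nb_dispersion Negative-binomial dispersion; variance =
#'   mean + dispersion * mean^2.
#' @param n_popgen_strains,n_popgen_genes Population variant design.
#' @param gene_length_range Range (bp) for simulated gene lengths.
#' @param scenario_mix Named proportions over the allele-fate scenarios
#'   `conserved`, `pseudogenized`, `functional_diverged`,
#'   `possibly_missing`, `sub_threshold`; must sum to 1.
#' @param plate_design Tibble with columns `genotype`, `n_plates`,
#'   `n_embryos_mean` for the plate assays.
#' @param true_props Named vector of true dead-embryo proportions per
#'   genotype.
#' @param overdispersion_rho Intra-plate correlation of the beta-binomial
#'   plate counts; 0 degenerates exactly to binomial.
#' @param onoff_mix Named list, strain -> c(p_on, prop_on, prop_off), for
#'   strains whose per-worm response is stochastic on/off.
#' @param lifespan_design Tibble with columns `strain`, `n_worms`,
#'   `logit_intercept`, `logit_slope_per_h`, `worm_sd` for the
#'   reproductive-lifespan assays.
#' @param lifespan_ages Age-interval midpoints (hours).
#' @param lifespan_embryos_mean Mean embryos laid per worm per interval.
#' @param transcript_regimes Tibble with columns `strain`, `treatment`,
#'   `intercept`, `slope_per_stage`, `knockdown_factor`, `mix_weight`.
#' @param transcript_stage_range Range of embryo stages (nuclei).
#' @param n_embryos_per_regime Embryos drawn per (strain, treatment).
#'
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 18589L,
                       n_strains = 5L,
                       n_reps_per_strain = 3L,
                       focal_set_size = 61L,
                       baseline_log_mean_range = c(0, 12),
                       strain_sd_background = 0.2,
                       strain_sd_focal = 0.6,
                       nb_dispersion = 0.05,
                       n_popgen_strains = 403L,
                       n_popgen_genes = 62L,
                       gene_length_range = c(500L, 5000L),
                       scenario_mix = c(conserved = 0.70,
                                        pseudogenized = 0.08,
                                        functional_diverged = 0.08,
                                        possibly_missing = 0.04,
                                        sub_threshold = 0.10),
                       plate_design = tibble(
                         genotype = c("parent", "f1_ppw1", "f1_del"),
                         n_plates = 8L,
                         n_embryos_mean = 150),
                       true_props = c(parent = 0.05, f1_ppw1 = 0.60,
                                      f1_del = 0.05),
                       overdispersion_rho = 0.1,
                       onoff_mix = list(),
                       lifespan_design = tibble(
                         strain = c("CB4856", "QX1211"),
                         n_worms = 8L,
                         logit_intercept = c(-5, -4),
                         logit_slope_per_h = c(0.05, 0.04),
                         worm_sd = c(0.3, 0.3)),
                       lifespan_ages = seq(12, 96, by = 12),
                       lifespan_embryos_mean = 60,
                       transcript_regimes = tibble(
                         strain = rep(c("N2", "CB4856", "QX1211"), each = 2),
                         treatment = rep(c("control", "rnai"), 3),
                         intercept = 650,
                         slope_per_stage = -15,
                         knockdown_factor = c(1, 0.05, 1, 1, 1, 0.05),
                         mix_weight = c(0, 1, 0, 0, 0, 0.3)),
                       transcript_stage_range = c(1L, 30L),
                       n_embryos_per_regime = 40L) {
  cfg <- list(
    seed = as.integer(seed),
    n_genes = as.integer(n_genes),
    n_strains = as.integer(n_strains),
    n_reps_per_strain = as.integer(n_reps_per_strain),
    focal_set_size = as.integer(focal_set_size),
    baseline_log_mean_range = baseline_log_mean_range,
    strain_sd_background = strain_sd_background,
    strain_sd_focal = strain_sd_focal,
    nb_dispersion = nb_dispersion,
    n_popgen_strains = as.integer(n_popgen_strains),
    n_popgen_genes = as.integer(n_popgen_genes),
    gene_length_range = as.integer(gene_length_range),
    scenario_mix = scenario_mix,
    plate_design = as_tibble(plate_design),
    true_props = true_props,
    overdispersion_rho = overdispersion_rho,
    onoff_mix = onoff_mix,
    lifespan_design = as_tibble(lifespan_design),
    lifespan_ages = lifespan_ages,
    lifespan_embryos_mean = lifespan_embryos_mean,
    transcript_regimes = as_tibble(transcript_regimes),
    transcript_stage_range = as.integer(transcript_stage_range),
    n_embryos_per_regime = as.integer(n_embryos_per_regime))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  counts <- c(cfg$n_genes, cfg$n_strains, cfg$n_reps_per_strain,
              cfg$focal_set_size, cfg$n_popgen_strains, cfg$n_popgen_genes,
              cfg$n_embryos_per_regime)
  if (any(counts < 1L))
    stop_rnaivar("all design counts must be >= 1", "invalid_config")
  if (any(cfg$gene_length_range <= 0L))
    stop_rnaivar("gene lengths must be positive", "invalid_config")
  if (cfg$nb_dispersion <= 0)
    stop_rnaivar("nb_dispersion must be > 0", "invalid_config")
  if (cfg$overdispersion_rho < 0 || cfg$overdispersion_rho >= 1)
    stop_rnaivar("overdispersion_rho must be in [0, 1)", "invalid_config")
  if (any(cfg$true_props < 0 | cfg$true_props > 1))
    stop_rnaivar("true_props must be in [0, 1]", "invalid_config")
  need <- c("conserved", "pseudogenized", "functional_diverged",
            "possibly_missing", "sub_threshold")
  if (!all(need %in% names(cfg$scenario_mix)))
    stop_rnaivar("scenario_mix must cover all five scenarios",
                 "invalid_config")
  if (abs(sum(cfg$scenario_mix) - 1) > 1e-8)
    stop_rnaivar("scenario_mix must sum to 1", "invalid_config")
  if (cfg$focal_set_size >= cfg$n_genes)
    stop_rnaivar("focal_set_size must be smaller than n_genes",
                 "invalid_config")
  invisible(cfg)
}

# Stage offsets for the per-generator RNG streams.
.sim_stage_seed <- function(cfg, stage) {
  cfg$seed + c(counts = 1L, variants = 2L, penetrance = 3L,
               transcripts = 4L)[[stage]]
}

.strain_names <- function(n) {
  if (n == 5L) c("N2", "CB4856", "QX1211", "JU1088", "EG4348")
  else sprintf("strain%02d", seq_len(n))
}

#' Simulate a gene x sample RNA-seq count matrix with a variance-inflated
#' focal set
#'
#' Counts are negative-binomial with a per-gene baseline mean drawn
#' log-uniformly, a per-(gene, strain) log2-fold effect drawn with SD
#' `strain_sd_background` (or `strain_sd_focal` for the focal genes), and a
#' fixed dispersion (variance = mean + dispersion * mean^2).
#'
#' @param config A [sim_config()].
#' @return A list with `counts` (tibble, `gene` column then one column per
#'   sample), `samples` (tibble `sample`, `strain`) and `truth` (tibble
#'   `gene`, `strain_sd`, `focal`).
#' @export
sim_counts <- function(config) {
  validate_sim_config(config)
  if (config$n_strains < 2L)
    stop_rnaivar("need at least 2 strains", "invalid_design")
  withr::with_seed(.sim_stage_seed(config, "counts"), {
    ng <- config$n_genes
    strains <- .strain_names(config$n_strains)
    samples <- tibble(
      sample = paste0(rep(strains, each = config$n_reps_per_strain), "_r",
                      rep(seq_len(config$n_reps_per_strain),
                          config$n_strains)),
      strain = rep(strains, each = config$n_reps_per_strain))
    genes <- sprintf("g%05d", seq_len(ng))
    focal <- genes %in% sample(genes, config$focal_set_size)
    sdv <- ifelse(focal, config$strain_sd_focal, config$strain_sd_background)
    base <- 2^runif(ng, config$baseline_log_mean_range[1],
                    config$baseline_log_mean_range[2])
    eff <- matrix(rnorm(ng * config$n_strains, sd = sdv), nrow = ng)
    mu <- base * 2^eff[, match(samples$strain, strains), drop = FALSE]
    cnt <- matrix(rnbinom(length(mu), mu = mu, size = 1 / config$nb_dispersion),
                  nrow = ng, dimnames = list(NULL, samples$sample))
    counts <- bind_cols(tibble(gene = genes), as_tibble(cnt))
    list(counts = counts, samples = samples,
         truth = tibble(gene = genes, strain_sd = sdv, focal = focal))
  })
}

#' Simulate a sparse population variant table with known allele-fate
#' scenarios
#'
#' Each (gene, strain) cell realizes one of five scenarios so that it
#' satisfies, by construction, the quantitative definition of its fate
#' label: `pseudogenized` carries at least one high-confidence HIGH-impact
#' variant plus >= 1% diverged-or-missing sites; `functional_diverged`
#' carries >= 5 MODERATE missense substitutions, >= 1% divergence and no
#' HIGH-impact call; `possibly_missing` has > 75% of sites uncalled;
#' `sub_threshold` sits below every threshold; `conserved` is identical to
#' the reference.
#'
#' The table is sparse: only non-reference (alt-carrying or missing) calls
#' are recorded; strains absent at a site implicitly carry the reference
#' allele.
#'
#' @param config A [sim_config()].
#' @return A list with `variants` (sparse long tibble), `gene_models`
#'   (tibble `gene`, `chrom`, `start`, `end`, `length`), `strains`
#'   (character) and `truth` (tibble `gene`, `strain`, `scenario`,
#'   `expected_label`, `expected_possibly_missing`).
#' @export
sim_variants <- function(config) {
  validate_sim_config(config)
  withr::with_seed(.sim_stage_seed(config, "variants"), {
    ngene <- config$n_popgen_genes
    strains <- sprintf("ST%03d", seq_len(config$n_popgen_strains))
    len <- sample(config$gene_length_range[1]:config$gene_length_range[2],
                  ngene, replace = TRUE)
    start <- cumsum(c(1L, head(len, -1) + 1000L))
    gene_models <- tibble(
      gene = sprintf("rnai%03d", seq_len(ngene)),
      chrom = sample(c("I", "II", "III", "IV", "V", "X"), ngene,
                     replace = TRUE),
      start = start, end = start + len - 1L, length = len)
    scen <- names(config$scenario_mix)
    cells <- tidyr::expand_grid(gene = gene_models$gene, strain = strains)
    cells$scenario <- sample(scen, nrow(cells), replace = TRUE,
                             prob = config$scenario_mix)
    gm <- gene_models[match(cells$gene, gene_models$gene), ]
    bases <- c("A", "C", "G", "T")

    recs <- purrr::pmap(
      list(cells$gene, cells$strain, cells$scenario, gm$chrom, gm$start,
           gm$length),
      function(gene, strain, scenario, chrom, gstart, L) {
        min_div <- ceiling(0.01 * L)   # sites needed to clear 1% divergence
        n_high <- 0L; n_mod <- 0L; n_low <- 0L; n_miss <- 0L
        if (scenario == "conserved") {
          return(NULL)
        } else if (scenario == "sub_threshold") {
          n_mod <- sample(0:4, 1)
          n_low <- sample(0:max(0, min_div - 2L - n_mod), 1)
          n_miss <- sample(0:1, 1)
          if (n_mod + n_low + n_miss == 0L) return(NULL)
        } else if (scenario == "functional_diverged") {
          n_mod <- sample(5:12, 1)
          n_low <- max(0L, min_div - n_mod) + sample(0:5, 1)
        } else if (scenario == "pseudogenized") {
          n_high <- sample(1:3, 1)
          n_low <- max(0L, min_div - n_high) + sample(0:5, 1)
          n_miss <- sample(0:3, 1)
        } else if (scenario == "possibly_missing") {
          n_miss <- ceiling(0.78 * L)
          n_high <- sample(0:1, 1)
        }
        tot <- n_high + n_mod + n_low + n_miss
        pos <- gstart + sample.int(L, tot) - 1L
        impact <- rep(c("HIGH", "MODERATE", "LOW", NA_character_),
                      c(n_high, n_mod, n_low, n_miss))
        subtype <- rep(c(NA, "missense_variant", "synonymous_variant", NA),
                       c(n_high, n_mod, n_low, n_miss))
        subtype[seq_len(n_high)] <- sample(c("frameshift_variant",
                                             "stop_gained"), n_high,
                                           replace = TRUE)
        gt <- rep(c("alt", "missing"), c(n_high + n_mod + n_low, n_miss))
        ref <- sample(bases, tot, replace = TRUE)
        alt <- ifelse(gt == "alt",
                      bases[(match(ref, bases) + sample(1:3, tot,
                                                        replace = TRUE) - 1L)
                            %% 4L + 1L],
                      NA_character_)
        tibble(gene = gene, chrom = chrom, pos = pos, ref = ref, alt = alt,
               impact = impact, subtype = subtype,
               filter_pass = ifelse(gt == "alt", TRUE, NA),
               strain = strain, gt = gt)
      })
    variants <- bind_rows(recs)
    truth <- cells |>
      mutate(
        expected_label = dplyr::case_match(
          .data$scenario,
          c("conserved", "sub_threshold") ~ "reference_like",
          "functional_diverged" ~ "functional_diverged",
          c("pseudogenized", "possibly_missing") ~ "pseudogenized"),
        expected_possibly_missing = .data$scenario == "possibly_missing")
    list(variants = variants, gene_models = gene_models, strains = strains,
         truth = truth)
  })
}

# Beta-binomial plate draws parameterized by (mean p, correlation rho);
# rho = 0 degenerates exactly to binomial.
.rbetabinom <- function(n_trials, p, rho) {
  if (p <= 0) return(rep(0L, length(n_trials)))
  if (p >= 1) return(as.integer(n_trials))
  pp <- if (rho == 0) rep(p, length(n_trials))
        else rbeta(length(n_trials), p * (1 - rho) / rho,
                   (1 - p) * (1 - rho) / rho)
  rbinom(length(n_trials), n_trials, pp)
}

#' Simulate plate-level embryonic-lethality records
#'
#' In `"plates"` mode, per-plate dead counts are beta-binomial with mean
#' `true_props[genotype]` and intra-plate correlation `overdispersion_rho`;
#' genotypes listed in `onoff_mix` instead draw each plate's worm as
#' Bernoulli(p_on) and use `prop_on` or `prop_off` as its lethality. In
#' `"lifespan"` mode, per-worm, per-age-interval counts follow a
#' logistic-in-age mean with a per-worm random intercept.
#'
#' @param config A [sim_config()].
#' @param mode `"plates"` or `"lifespan"`.
#' @return A tibble of penetrance records: `plate`, `genotype`, `dead`,
#'   `hatched`, plus `worm` and `age_h` in lifespan mode.
#' @export
sim_penetrance <- function(config, mode = c("plates", "lifespan")) {
  validate_sim_config(config)
  mode <- match.arg(mode)
  if (mode == "plates" && nrow(config$plate_design) == 0L)
    stop_rnaivar("plate_design is empty", "invalid_config")
  withr::with_seed(.sim_stage_seed(config, "penetrance"), {
    if (mode == "plates") {
      out <- purrr::pmap(config$plate_design,
        function(genotype, n_plates, n_embryos_mean) {
          n <- pmax(1L, rpois(n_plates, n_embryos_mean))
          oo <- config$onoff_mix[[genotype]]
          if (!is.null(oo)) {
            on <- rbinom(n_plates, 1L, oo[[1]]) == 1L
            dead <- .rbetabinom(n, 1, 0) * 0L
            dead[on] <- rbinom(sum(on), n[on], oo[[2]])
            dead[!on] <- rbinom(sum(!on), n[!on], oo[[3]])
          } else {
            dead <- .rbetabinom(n, config$true_props[[genotype]],
                                config$overdispersion_rho)
          }
          tibble(genotype = genotype, dead = as.integer(dead),
                 hatched = as.integer(n - dead))
        }) |> bind_rows()
      out$plate <- sprintf("plate%03d", seq_len(nrow(out)))
      out[, c("plate", "genotype", "dead", "hatched")]
    } else {
      out <- purrr::pmap(config$lifespan_design,
        function(strain, n_worms, logit_intercept, logit_slope_per_h,
                 worm_sd) {
          oo <- config$onoff_mix[[strain]]
          purrr::map(seq_len(n_worms), function(w) {
            worm_eff <- rnorm(1, 0, worm_sd)
            on <- if (is.null(oo)) TRUE else rbinom(1, 1, oo[[1]]) == 1L
            n <- pmax(1L, rpois(length(config$lifespan_ages),
                                config$lifespan_embryos_mean))
            p <- if (on)
              plogis(logit_intercept + logit_slope_per_h *
                       config$lifespan_ages + worm_eff)
            else rep(if (is.null(oo)) 0 else oo[[3]],
                     length(config$lifespan_ages))
            tibble(genotype = strain,
                   worm = sprintf("%s_w%02d", strain, w),
                   age_h = config$lifespan_ages,
                   dead = rbinom(length(n), n, p),
                   hatched = NA_integer_, n = n)
          }) |> bind_rows()
        }) |> bind_rows()
      out$hatched <- as.integer(out$n - out$dead)
      out$n <- NULL
      out$plate <- sprintf("plate%04d", seq_len(nrow(out)))
      out[, c("plate", "genotype", "worm", "age_h", "dead", "hatched")]
    }
  })
}

#' Simulate per-embryo transcript counts
#'
#' Control counts are negative-binomial with mean
#' `intercept + slope_per_stage * stage` (floored at 1, with a warning when
#' a negative mean is requested). Treated counts come from a two-component
#' mixture: with probability `mix_weight` an embryo's mean is scaled by
#' `knockdown_factor` (the responsive component), otherwise it matches the
#' control regime. `mix_weight = 1` models a uniformly responsive strain;
#' intermediate weights model stochastic on/off responses.
#'
#' @param config A [sim_config()].
#' @return A tibble `embryo`, `strain`, `treatment`, `stage`, `count`,
#'   `knocked` (ground-truth mixture component).
#' @export
sim_transcripts <- function(config) {
  validate_sim_config(config)
  withr::with_seed(.sim_stage_seed(config, "transcripts"), {
    warned <- FALSE
    out <- purrr::pmap(config$transcript_regimes,
      function(strain, treatment, intercept, slope_per_stage,
               knockdown_factor, mix_weight) {
        n <- config$n_embryos_per_regime
        stage <- sample(config$transcript_stage_range[1]:
                          config$transcript_stage_range[2], n,
                        replace = TRUE)
        mu <- intercept + slope_per_stage * stage
        if (any(mu < 1) && !warned) {
          warn("requested mean below 1; flooring at 1")
          warned <<- TRUE
        }
        mu <- pmax(mu, 1)
        knocked <- if (treatment == "rnai")
          rbinom(n, 1, mix_weight) == 1L else rep(FALSE, n)
        mu[knocked] <- pmax(mu[knocked] * knockdown_factor, 1)
        tibble(strain = strain, treatment = treatment, stage = stage,
               count = rnbinom(n, mu = mu, size = 1 / config$nb_dispersion),
               knocked = knocked)
      }) |> bind_rows()
    out$embryo <- sprintf("emb%04d", seq_len(nrow(out)))
    out[, c("embryo", "strain", "treatment", "stage", "count", "knocked")]
  })
}
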