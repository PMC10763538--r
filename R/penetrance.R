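# Quasibinomial penetrance models, pairwise contrasts, lifespan linear
# models, and complementation-pattern calling.

.check_penetrance <- function(records) {
  need <- c("genotype", "dead", "hatched")
  if (!all(need %in% names(records)))
    stop_rnaivar("records need genotype, dead, hatched columns",
                 "invalid_records")
  if (any(records$dead + records$hatched < 1))
    stop_rnaivar("each plate needs at least one embryo", "invalid_records")
  records
}

#' Quasibinomial GLM of embryonic-lethality penetrance
#'
#' Plate-level dead/hatched counts are bound as a single binomial
#' response and modeled on the logit scale with a free dispersion
#' parameter: standard errors are scaled by sqrt(phi) with
#' phi = Pearson chi-squared / residual df. Complete separation (a
#' genotype whose plates are all-dead or all-hatched) is detected and
#' flagged; the fitted proportion for such a genotype is reported at the
#' bound 0.5 / (n + 1) (or its complement), where n is the genotype's
#' embryo total.
#'
#' @param records Tibble with columns `plate`, `genotype`, `dead`,
#'   `hatched` (one row per plate).
#' @return An object of class `penetrance_fit` with the underlying
#'   `glm`, dispersion `phi`, and a `fitted` tibble of per-genotype
#'   proportions with t-based 95% intervals. Supports `tidy()`,
#'   `glance()` and `autoplot()`.
#' @export
fit_penetrance <- function(records) {
  records <- .check_penetrance(records)
  if (nrow(records) < 2L)
    stop_rnaivar("need at least 2 plates", "invalid_design")
  df <- records
  df$genotype <- factor(df$genotype)
  k <- nlevels(df$genotype)
  form <- if (k > 1L) cbind(dead, hatched) ~ genotype
          else cbind(dead, hatched) ~ 1
  fit <- glm(form, family = quasibinomial(), data = df)
  if (fit$df.residual < 1L)
    stop_rnaivar("no residual degrees of freedom: dispersion undefined",
                 "dispersion_undefined")
  phi <- sum(residuals(fit, type = "pearson")^2) / fit$df.residual
  per <- df |>
    group_by(.data$genotype) |>
    summarise(n_plates = n(), dead = sum(.data$dead),
              hatched = sum(.data$hatched), .groups = "drop") |>
    mutate(n = .data$dead + .data$hatched,
           separated = .data$dead == 0L | .data$hatched == 0L)
  # Per-genotype logit estimates/SEs from the cell-means parameterization.
  cm <- if (k > 1L)
    glm(cbind(dead, hatched) ~ 0 + genotype, family = quasibinomial(),
        data = df)
  else fit   # intercept-only fit already is the cell mean
  eta <- unname(coef(cm))
  se <- unname(sqrt(diag(vcov(cm)) / summary(cm)$dispersion * phi))
  tcrit <- qt(0.975, fit$df.residual)
  per$prop <- plogis(eta)
  per$prop_lo <- plogis(eta - tcrit * se)
  per$prop_hi <- plogis(eta + tcrit * se)
  bound <- 0.5 / (per$n + 1)
  per$prop[per$separated & per$dead == 0L] <-
    bound[per$separated & per$dead == 0L]
  per$prop[per$separated & per$hatched == 0L] <-
    1 - bound[per$separated & per$hatched == 0L]
  structure(list(glm = fit, phi = phi, fitted = per,
                 separation = any(per$separated),
                 converged = fit$converged, data = df),
            class = "penetrance_fit")
}

#' @export
print.penetrance_fit <- function(x, ...) {
  cat(sprintf(
    "Quasibinomial penetrance fit: %d genotypes, %d plates, phi = %.3f%s\n",
    nlevels(x$data$genotype), nrow(x$data), x$phi,
    if (x$separation) " [separation flagged]" else ""))
  print(x$fitted[, c("genotype", "n_plates", "n", "prop", "prop_lo",
                     "prop_hi", "separated")])
  invisible(x)
}

.stars <- function(p) {
  cut(p, c(-Inf, 0.001, 0.01, 0.05, Inf),
      labels = c("***", "**", "*", ""))
}

#' All pairwise genotype contrasts with family-wise adjustment
#'
#' Tukey-style all-pairs contrasts on the logit scale, with t statistics
#' scaled by the quasibinomial dispersion. The `single_step` adjustment
#' uses the joint max-|t| distribution over the fitted coefficient
#' covariance (via multcomp); `bonferroni` and `none` are deterministic
#' alternatives. With only two genotypes the adjusted p equals the
#' unadjusted p.
#'
#' @param fit A [fit_penetrance()] object.
#' @param adjust `"single_step"`, `"bonferroni"` or `"none"`.
#' @param seed Seed for the randomized multivariate-t quadrature behind
#'   the single-step adjustment (makes the p-values reproducible).
#' @return A tibble `contrast`, `estimate` (logit difference), `se`,
#'   `statistic`, `p_adj`, `stars`.
#' @export
pairwise_contrasts <- function(fit,
                               adjust = c("single_step", "bonferroni",
                                          "none"),
                               seed = 1L) {
  adjust <- match.arg(adjust)
  if (nlevels(fit$data$genotype) < 2L)
    stop_rnaivar("need at least 2 genotypes", "invalid_design")
  gl <- multcomp::glht(fit$glm,
                       linfct = multcomp::mcp(genotype = "Tukey"))
  type <- switch(adjust, single_step = "single-step",
                 bonferroni = "bonferroni", none = "none")
  sm <- withr::with_seed(seed,
    summary(gl, test = multcomp::adjusted(type = type)))
  tibble(contrast = names(sm$test$coefficients),
         estimate = unname(sm$test$coefficients),
         se = unname(sm$test$sigma),
         statistic = unname(sm$test$tstat),
         p_adj = pmin(1, unname(sm$test$pvalues)),
         stars = as.character(.stars(pmin(1, unname(sm$test$pvalues)))))
}

#' Linear model of penetrance over reproductive lifespan
#'
#' Ordinary least squares on the plate-level dead proportion with main
#' effects of strain and age, their interaction, and individual worm
#' nested within strain, with sequential (type I) F tests in that order.
#' The response is the raw proportion (not a GLM); heteroscedasticity is
#' accepted and documented.
#'
#' @param records Tibble with `genotype` (strain), `worm`, `age_h`,
#'   `dead`, `hatched` (one row per plate/interval).
#' @return An object of class `lifespan_fit` with the `lm`, a sequential
#'   ANOVA tibble and a full-rank flag. Supports `tidy()` and
#'   `glance()`.
#' @export
fit_lifespan_model <- function(records) {
  records <- .check_penetrance(records)
  if (!all(c("worm", "age_h") %in% names(records)))
    stop_rnaivar("records need worm and age_h columns", "invalid_records")
  df <- records |>
    mutate(prop = .data$dead / (.data$dead + .data$hatched),
           genotype = factor(.data$genotype),
           worm = factor(.data$worm))
  if (nlevels(df$genotype) < 2L)
    stop_rnaivar("need at least 2 strains", "invalid_design")
  fit <- lm(prop ~ genotype + age_h + genotype:age_h + worm, data = df)
  if (fit$df.residual < 1L)
    stop_rnaivar("confounded design: no residual degrees of freedom",
                 "rank_error")
  at <- anova(fit)
  structure(list(
    lm = fit,
    anova = tibble(term = rownames(at), df = at$Df,
                   sumsq = at$`Sum Sq`, statistic = at$`F value`,
                   p_value = at$`Pr(>F)`),
    full_rank = !anyNA(coef(fit)),
    aliased = names(coef(fit))[is.na(coef(fit))]),
    class = "lifespan_fit")
}

#' Reduced lifespan model (age and worm only) for one strain
#'
#' @param records As in [fit_lifespan_model()].
#' @param genotype The strain to subset to.
#' @return A `lifespan_fit`-like object for the model
#'   `prop ~ age_h + worm`.
#' @export
fit_lifespan_reduced <- function(records, genotype) {
  records <- .check_penetrance(records)
  df <- records |>
    filter(.data$genotype == !!genotype) |>
    mutate(prop = .data$dead / (.data$dead + .data$hatched),
           worm = factor(.data$worm))
  if (nrow(df) == 0L) stop_rnaivar("unknown genotype", "unknown_genotype")
  fit <- lm(prop ~ age_h + worm, data = df)
  at <- anova(fit)
  structure(list(
    lm = fit,
    anova = tibble(term = rownames(at), df = at$Df,
                   sumsq = at$`Sum Sq`, statistic = at$`F value`,
                   p_value = at$`Pr(>F)`),
    aliased = names(coef(fit))[is.na(coef(fit))]),
    class = "lifespan_fit")
}

#' @export
print.lifespan_fit <- function(x, ...) {
  cat("Lifespan penetrance linear model\n")
  print(x$anova)
  invisible(x)
}

#' Call the complementation pattern from a three-genotype experiment
#'
#' Given penetrance estimates and adjusted pairwise p-values for the
#' parent strain (P), the F1 carrying a functional copy of the rescuing
#' Argonaute (H+), and the F1 carrying its deletion (Hdel), calls one of
#' four patterns:
#' \itemize{
#'   \item `no_rescue`: neither F1 significantly exceeds P;
#'   \item `ppw1_dependent_rescue`: H+ exceeds both P and Hdel
#'     (both significant);
#'   \item `ppw1_dependent_suppression`: Hdel significantly exceeds both
#'     H+ and P;
#'   \item `ppw1_independent_rescue`: both F1s significantly exceed P
#'     and do not differ from each other.
#' }
#' When rules conflict or none applies cleanly, the call is resolved in
#' the listed priority order and flagged ambiguous.
#'
#' @param fit A [fit_penetrance()] object over the three genotypes.
#' @param contrasts Output of [pairwise_contrasts()] on the same fit.
#' @param roles Named character vector mapping `parent`, `f1_plus`,
#'   `f1_del` to genotype labels.
#' @param alpha Significance level for the pattern rules.
#' @return A one-row tibble: `pattern`, `ambiguous`, the three estimated
#'   proportions and the three adjusted p-values.
#' @export
classify_complementation <- function(fit, contrasts, roles,
                                     alpha = 0.05) {
  need <- c("parent", "f1_plus", "f1_del")
  if (!all(need %in% names(roles)))
    stop_rnaivar("roles must name parent, f1_plus, f1_del",
                 "invalid_roles")
  props <- setNames(fit$fitted$prop, as.character(fit$fitted$genotype))
  if (!all(roles %in% names(props)))
    stop_rnaivar("a role genotype is missing from the fit",
                 "unknown_genotype")
  pair_p <- function(a, b) {
    hit <- contrasts$contrast %in% c(paste(a, "-", b), paste(b, "-", a))
    if (!any(hit)) stop_rnaivar("missing pairwise contrast",
                                "missing_contrast")
    contrasts$p_adj[which(hit)[1]]
  }
  sig_gt <- function(a, b)
    props[[a]] > props[[b]] && pair_p(a, b) < alpha
  P <- roles[["parent"]]; Hp <- roles[["f1_plus"]]; Hd <- roles[["f1_del"]]
  cand <- c(
    no_rescue = !sig_gt(Hp, P) && !sig_gt(Hd, P),
    ppw1_dependent_rescue = sig_gt(Hp, P) && sig_gt(Hp, Hd),
    ppw1_dependent_suppression = sig_gt(Hd, Hp) && sig_gt(Hd, P),
    ppw1_independent_rescue = sig_gt(Hp, P) && sig_gt(Hd, P) &&
      pair_p(Hp, Hd) >= alpha)
  if (sum(cand) == 1L) {
    pattern <- names(cand)[cand]; ambiguous <- FALSE
  } else if (sum(cand) > 1L) {
    pattern <- names(cand)[which(cand)[1]]; ambiguous <- TRUE
  } else {
    pattern <- "no_rescue"; ambiguous <- TRUE
  }
  tibble(pattern = pattern, ambiguous = ambiguous,
         prop_parent = props[[P]], prop_f1_plus = props[[Hp]],
         prop_f1_del = props[[Hd]],
         p_plus_vs_parent = pair_p(Hp, P),
         p_del_vs_parent = pair_p(Hd, P),
         p_plus_vs_del = pair_p(Hp, Hd))
}
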