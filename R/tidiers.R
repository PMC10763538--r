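# broom-style tidiers for the package's fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.penetrance_fit <- function(x, ...) {
  sm <- summary(x$glm)$coefficients
  tibble(term = rownames(sm), estimate = sm[, 1], std_error = sm[, 2],
         statistic = sm[, 3], p_value = sm[, 4])
}

#' @export
glance.penetrance_fit <- function(x, ...) {
  tibble(phi = x$phi, df_residual = x$glm$df.residual,
         n_plates = nrow(x$data),
         n_genotypes = nlevels(x$data$genotype),
         separation = x$separation, converged = x$converged)
}

#' @export
tidy.lifespan_fit <- function(x, ...) x$anova

#' @export
glance.lifespan_fit <- function(x, ...) {
  sm <- summary(x$lm)
  tibble(r_squared = sm$r.squared, adj_r_squared = sm$adj.r.squared,
         df_residual = x$lm$df.residual,
         full_rank = length(x$aliased) == 0L)
}

#' @export
tidy.rnai_enrichment <- function(x, ...) {
  tibble(null_median_ss = x$null_median_ss,
         null_de_prop = x$null_de_prop)
}

#' @export
glance.rnai_enrichment <- function(x, ...) {
  tibble(observed_median_ss = x$observed_median_ss,
         frac_null_below = x$frac_null_below,
         perm_p_median = x$perm_p_median,
         perm_p_median_add1 = x$perm_p_median_add1,
         mw_significant_count = x$mw_significant_count,
         observed_de_prop = x$observed_de_prop,
         frac_null_deprop_below = x$frac_null_deprop_below,
         perm_p_deprop = x$perm_p_deprop,
         hypergeom_p = x$hypergeom_p, B = x$B)
}

#' @export
tidy.rnai_ancova <- function(x, ...) x$omega

#' @export
glance.rnai_ancova <- function(x, ...) {
  pc <- x$per_condition
  tibble(treatment_p = x$treatment_p, slope_p = x$slope_p,
         slope_control = pc$slope[pc$treatment == "control"],
         slope_rnai = pc$slope[pc$treatment == "rnai"],
         r2_control = pc$r_squared[pc$treatment == "control"],
         r2_rnai = pc$r_squared[pc$treatment == "rnai"])
}

#' @export
tidy.rnai_bimodality <- function(x, ...) {
  tibble(statistic = x$statistic, p_value = x$p_value, B = x$B)
}
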