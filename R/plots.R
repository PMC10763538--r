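# ggplot2 visualizations for the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_histogram geom_vline
#'   geom_point geom_errorbar geom_jitter geom_line geom_abline labs
#'   position_jitter facet_wrap
#' @export
ggplot2::autoplot

#' @export
autoplot.rnai_enrichment <- function(object, ...) {
  ggplot(tibble(null_median_ss = object$null_median_ss),
         aes(x = .data$null_median_ss)) +
    geom_histogram(bins = 60, fill = "grey70", colour = "grey40") +
    geom_vline(xintercept = object$observed_median_ss,
               colour = "firebrick", linewidth = 0.8) +
    labs(x = "median strain-wise SS of expression-matched null sets",
         y = "null sets",
         title = sprintf("focal median SS above %.1f%% of %d null sets",
                         100 * object$frac_null_below, object$B))
}

#' @export
autoplot.penetrance_fit <- function(object, ...) {
  obs <- object$data |>
    mutate(prop = .data$dead / (.data$dead + .data$hatched))
  ggplot(object$fitted, aes(x = .data$genotype)) +
    geom_jitter(data = obs, aes(y = .data$prop), width = 0.1,
                alpha = 0.5, colour = "grey40") +
    geom_point(aes(y = .data$prop), colour = "firebrick", size = 2) +
    geom_errorbar(aes(ymin = .data$prop_lo, ymax = .data$prop_hi),
                  width = 0.15, colour = "firebrick") +
    labs(x = NULL, y = "proportion of dead embryos")
}

#' @export
autoplot.rnai_ancova <- function(object, ...) {
  pc <- object$per_condition
  ggplot(object$data,
         aes(x = .data$stage, y = .data$count,
             colour = .data$treatment)) +
    geom_point(alpha = 0.6) +
    geom_abline(data = pc,
                aes(intercept = .data$intercept, slope = .data$slope,
                    colour = .data$treatment)) +
    labs(x = "embryo stage (nuclei)", y = "transcript count")
}

#' Plot per-worm penetrance trajectories over reproductive lifespan
#'
#' One line per worm: the proportion of dead embryos per age interval.
#'
#' @param records Lifespan penetrance records (`genotype`, `worm`,
#'   `age_h`, `dead`, `hatched`).
#' @return A ggplot object.
#' @export
plot_lifespan <- function(records) {
  d <- records |>
    mutate(prop = .data$dead / (.data$dead + .data$hatched))
  ggplot(d, aes(x = .data$age_h, y = .data$prop, group = .data$worm)) +
    geom_line(alpha = 0.5) +
    geom_point(size = 0.8) +
    facet_wrap(~genotype) +
    labs(x = "age (h)", y = "proportion of dead embryos")
}
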