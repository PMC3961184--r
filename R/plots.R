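#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_col geom_hline
#'   geom_abline geom_errorbar geom_vline labs scale_x_log10 theme_minimal
#'   position_dodge geom_line stat_function
#' @export
ggplot2::autoplot

#' Volcano plot of a contrast table
#'
#' Log2 fold-change against -log10 q for one comparison, with the q
#' threshold marked.
#'
#' @param contrasts output of [add_fdr()].
#' @param comparison comparison id to plot (default: first present).
#' @param alpha q threshold line, default 0.05.
#' @return a ggplot.
#' @export
plot_volcano <- function(contrasts, comparison = NULL, alpha = 0.05) {
  comparison <- comparison %||% contrasts$comparison[[1]]
  dat <- contrasts[contrasts$comparison == comparison & !is.na(contrasts$q), ]
  ggplot(dat, aes(log2FC, -log10(q))) +
    geom_point(alpha = 0.4, size = 0.8) +
    geom_hline(yintercept = -log10(alpha), linetype = 2, colour = "red") +
    labs(x = expression(log[2] ~ "fold-change"),
         y = expression(-log[10] ~ "q"),
         title = comparison) +
    theme_minimal()
}

#' TaqMan endpoint scatterplot with genotype calls
#'
#' VIC (glycine label) against FAM (serine label) fluorescence, coloured by
#' call, with the 1:1 dye-balance diagonal.
#'
#' @param calls output of [call_genotypes()].
#' @return a ggplot.
#' @export
plot_taqman <- function(calls) {
  ggplot(calls, aes(vic_dR_from(calls), fam_dR_from(calls))) +
    geom_point(aes(colour = call)) +
    geom_abline(slope = 1, intercept = 0, linetype = 2) +
    labs(x = "VIC dR (119G)", y = "FAM dR (119S)") +
    theme_minimal()
}

## calls carry angle/total_signal, reconstruct channels for plotting
vic_dR_from <- function(calls) calls$total_signal / (1 + tan(deg2rad(calls$angle)))
fam_dR_from <- function(calls) calls$total_signal - vic_dR_from(calls)

#' Bar chart of pooled bioassay mortalities
#'
#' @param summary output of [mortality_summary()] grouped by `insecticide`
#'   and `pbo` (and optionally `season`).
#' @return a ggplot.
#' @export
plot_mortality <- function(summary) {
  ggplot(summary, aes(insecticide, mortality, fill = pbo)) +
    geom_col(position = position_dodge(width = 0.9), width = 0.8) +
    geom_errorbar(aes(ymin = lower, ymax = upper),
                  position = position_dodge(width = 0.9), width = 0.2) +
    labs(y = "mortality (pooled)", x = NULL, fill = "PBO") +
    theme_minimal()
}

#' Dose-response plot of an LC50 fit
#'
#' Observed survival against dose (log10 axis) with the fitted line over
#' the partial-response range and the LC50 marked.
#'
#' @param object an `lc50_fit`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot lc50_fit
#' @export
autoplot.lc50_fit <- function(object, ...) {
  a <- object$intercept; b <- -object$slope
  ggplot(object$data, aes(dose, survival)) +
    geom_point() +
    stat_function(fun = function(d) pmin(pmax(a + b * log10(d), 0), 1),
                  colour = "steelblue") +
    geom_vline(xintercept = object$lc50, linetype = 2, colour = "red") +
    geom_hline(yintercept = 0.5, linetype = 3) +
    scale_x_log10() +
    labs(x = "dose (µg/vial)", y = "survival") +
    theme_minimal()
}
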