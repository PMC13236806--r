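# ggplot2 views of the main result types.

#' @importFrom ggplot2 ggplot aes geom_point geom_errorbar geom_errorbarh
#'   geom_abline geom_hline geom_boxplot labs theme_minimal autoplot
NULL

#' Scatter plot of an MR fit
#'
#' SNP-exposure effects (x) against SNP-outcome effects (y) with +/- 1 SE
#' error bars and the selected causal estimate as a line through the origin
#' (Egger fits additionally show their intercept line).
#'
#' @param object an `mr_result` from [rucker_select()].
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot mr_result
#' @export
autoplot.mr_result <- function(object, ...) {
  d <- object$pairs
  e <- object$estimate
  intercept <- if (object$method == "egger") object$egger_intercept[["value"]] else 0
  ggplot(d, aes(x = .data$gamma, y = .data$Gamma)) +
    geom_errorbar(aes(ymin = .data$Gamma - .data$se_Gamma,
                      ymax = .data$Gamma + .data$se_Gamma), width = 0) +
    geom_errorbarh(aes(xmin = .data$gamma - .data$se_gamma,
                       xmax = .data$gamma + .data$se_gamma), height = 0) +
    geom_point() +
    geom_abline(intercept = intercept, slope = e$theta, colour = "blue") +
    labs(x = "SNP effect on methylation (M-value per allele)",
         y = "SNP effect on outcome (log-odds per allele)",
         title = sprintf("%s (%s): %s OR = %.2f [%.2f, %.2f]",
                         object$cpg, object$tissue, object$method,
                         e$or_value, e$ci_low, e$ci_high)) +
    theme_minimal()
}

#' @export
plot.mr_result <- function(x, ...) print(autoplot.mr_result(x, ...))

#' Bland-Altman plot of methylation stability
#'
#' Per-probe difference between time points against the mean of means, with
#' the across-probe mean difference and limits of agreement.
#'
#' @param stab output of [stability()].
#' @param highlight optional probe ids drawn in red.
#' @return A ggplot.
#' @export
plot_bland_altman <- function(stab, highlight = NULL) {
  ba <- attr(stab, "bland_altman")
  p <- ggplot(stab, aes(x = .data$mean_of_means, y = .data$diff)) +
    geom_point(alpha = 0.7) +
    geom_hline(yintercept = ba$mean_diff, linetype = 1) +
    geom_hline(yintercept = c(ba$loa_low, ba$loa_high), linetype = 2) +
    labs(x = "Mean methylation across time points (%)",
         y = "Difference, time 2 - time 1 (%)") +
    theme_minimal()
  if (!is.null(highlight)) {
    p <- p + geom_point(data = dplyr::filter(stab, .data$probe_id %in% highlight),
                        colour = "red")
  }
  p
}

#' Boxplot of baseline methylation by follow-up HbA1c tertile
#'
#' @param M baseline `methyl_matrix`.
#' @param pheno phenotype tibble with `hba1c_followup`.
#' @param probe probe id to plot.
#' @return A ggplot.
#' @export
plot_methylation_tertiles <- function(M, pheno, probe) {
  ph <- dplyr::filter(pheno, .data$sample_id %in% rownames(M$values),
                      !is.na(.data$hba1c_followup))
  v <- M$values[ph$sample_id, probe]
  if (M$scale == "m_value") v <- beta_from_mvalue(v)
  d <- tibble(tertile = factor(tertile_split(ph$hba1c_followup)),
              beta = 100 * v)
  ggplot(d, aes(x = .data$tertile, y = .data$beta)) +
    geom_boxplot() +
    labs(x = "Follow-up HbA1c tertile", y = "Baseline methylation (%)",
         title = probe) +
    theme_minimal()
}
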