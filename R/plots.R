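#' Trending plot of simulated pool concentrations across the chain
#'
#' Distributions of the simulated pool concentration of one CQA at every
#' unit operation in process order, with observed manufacturing runs
#' overlaid when supplied — the visual plausibility check of the
#' integrated model.
#'
#' @param sim an `ipm_simulation`.
#' @param cqa CQA name.
#' @param observed optional long-format run table (`run`, `uo`, `cqa`,
#'   `conc`).
#' @return A ggplot object.
#' @export
plot_trending <- function(sim, cqa, observed = NULL) {
  d <- dimnames(sim$pool_conc)
  df <- data.frame(uo = factor(rep(d[[2]], each = sim$n_cycles),
                               levels = d[[2]]),
                   conc = as.vector(sim$pool_conc[, , cqa]))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = uo, y = conc)) +
    ggplot2::geom_violin(fill = "grey85", colour = "grey40") +
    ggplot2::labs(x = "unit operation (process order)",
                  y = sprintf("%s pool specific concentration", cqa),
                  title = sprintf("IPM trending: %s (%d cycles)", cqa,
                                  sim$n_cycles)) +
    ggplot2::theme_minimal()
  if (!is.null(observed)) {
    od <- observed[observed$cqa == cqa, ]
    od$uo <- factor(od$uo, levels = d[[2]])
    p <- p + ggplot2::geom_point(data = od, colour = "firebrick", size = 2)
  }
  p
}

#' Overlay sensitivity curves of all parameters for one CQA
#'
#' Curves are drawn on the relative screening range (set point coded 0,
#' half screening width coded 1) so parameters with different native
#' units are comparable at a glance.
#'
#' @param curves list of `ipm_psa_curve` objects.
#' @param cqa CQA name.
#' @param critical_ooa horizontal reference level, in percent.
#' @return A ggplot object.
#' @export
plot_psa_overlay <- function(curves, cqa, critical_ooa = 5) {
  df <- do.call(rbind, lapply(curves, function(cv)
    data.frame(parameter = cv$parameter$name,
               coded = relative_screening_range(cv$grid, cv$parameter),
               ooa = cv$ooa[, cqa])))
  ggplot2::ggplot(df, ggplot2::aes(x = coded, y = ooa,
                                   colour = parameter)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::geom_hline(yintercept = critical_ooa, linetype = 2) +
    ggplot2::labs(x = "relative screening range (set point = 0)",
                  y = "OOA at drug substance (%)",
                  title = sprintf("Sensitivity of %s", cqa)) +
    ggplot2::theme_minimal()
}

#' Sensitivity plot of one parameter across all CQAs, with PAR shading
#'
#' @param curve an `ipm_psa_curve`.
#' @param par_result optional `ipm_par` for the same parameter; its range
#'   is shaded.
#' @param critical_ooa horizontal reference level, in percent.
#' @return A ggplot object.
#' @export
plot_psa_parameter <- function(curve, par_result = NULL, critical_ooa = 5) {
  cqas <- colnames(curve$ooa)
  df <- data.frame(grid = rep(curve$grid, length(cqas)),
                   cqa = rep(cqas, each = length(curve$grid)),
                   ooa = as.vector(curve$ooa))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = grid, y = ooa,
                                        colour = cqa))
  if (!is.null(par_result) && !is.na(par_result$par_low))
    p <- p + ggplot2::annotate("rect", xmin = par_result$par_low,
                               xmax = par_result$par_high,
                               ymin = -Inf, ymax = Inf,
                               alpha = 0.15, fill = "grey40")
  p + ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::geom_hline(yintercept = critical_ooa, linetype = 2) +
    ggplot2::geom_vline(xintercept = curve$parameter$set_point,
                        linetype = 3) +
    ggplot2::labs(x = sprintf("%s (native units)", curve$parameter$name),
                  y = "OOA at drug substance (%)",
                  title = sprintf("PSA: %s", curve$parameter$name)) +
    ggplot2::theme_minimal()
}

#' Bar chart of FMEA severity rankings per parameter and CQA
#'
#' @param assessments list of `ipm_severity` objects.
#' @return A ggplot object.
#' @export
plot_severity <- function(assessments) {
  df <- do.call(rbind, lapply(assessments, `[[`, "by_cqa"))
  ggplot2::ggplot(df, ggplot2::aes(x = parameter, y = ranking,
                                   fill = cqa)) +
    ggplot2::geom_col(position = ggplot2::position_dodge()) +
    ggplot2::labs(x = NULL, y = "FMEA severity ranking",
                  title = "Automated FMEA severity rankings") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

utils::globalVariables(c("uo", "conc", "coded", "ooa", "parameter", "cqa",
                         "grid", "ranking"))
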