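#' Ranking rubric for the FMEA severity linearization
#'
#' Maps the worst-case ratio of CQA slope to critical slope onto an FMEA
#' severity rank.  The default four-band rubric assigns rank 10 (a CPP)
#' when the ratio is at least 0.8, 7 in `[0.5, 0.8)`, 3 in `[0.3, 0.5)`
#' and 1 below 0.3; lower band bounds are inclusive.  Other scales can be
#' supplied as long as thresholds are strictly decreasing, so the bands
#' partition `[0, Inf)`.
#'
#' @param thresholds strictly decreasing positive lower band bounds.
#' @param ranks severity ranks, one per band plus one for the residual
#'   band below the smallest threshold, in decreasing severity order.
#' @return An object of class `ipm_ranking_bands`.
#' @export
ranking_bands <- function(thresholds = c(0.8, 0.5, 0.3),
                          ranks = c(10, 7, 3, 1)) {
  assert_that(length(ranks) == length(thresholds) + 1L,
              "need one rank per band plus the residual band")
  assert_that(all(diff(thresholds) < 0),
              "thresholds must be strictly decreasing (bands may not overlap)")
  assert_that(all(thresholds > 0), "thresholds must be positive")
  assert_that(all(diff(ranks) < 0), "ranks must be strictly decreasing")
  structure(list(thresholds = as.numeric(thresholds),
                 ranks = as.numeric(ranks)),
            class = "ipm_ranking_bands")
}

band_rank <- function(ratio, bands) {
  for (i in seq_along(bands$thresholds))
    if (ratio >= bands$thresholds[i]) return(bands$ranks[i])
  bands$ranks[length(bands$ranks)]
}

edge_ooa <- function(curve, cqa, side) {
  i <- if (side == "low") 1L else nrow(curve$ooa)
  curve$ooa[i, cqa]
}

side_span <- function(curve, side) {
  p <- curve$parameter
  sr <- if (side == "low") p$sr_low else p$sr_high
  sr - p$set_point  # negative on the low side
}

#' Critical-effect slope of a sensitivity curve
#'
#' The maximum allowable impact of the parameter on the CQA per native
#' unit: the slope of the line from the set-point OOA to the critical OOA
#' level at the screening-range edge,
#' `(critical_ooa - OOA_SP) / (SR_side - SP)`.
#'
#' @param curve an `ipm_psa_curve`.
#' @param cqa CQA name.
#' @param side `"low"` or `"high"` side of the set point.
#' @param critical_ooa allowed OOA level in percent (default 5, roughly
#'   two standard deviations of a centred normal population).
#' @return Slope in percent OOA per native unit, or `NA` when the set
#'   point coincides with the screening edge on that side (one-sided
#'   assessment).
#' @export
critical_slope <- function(curve, cqa, side = c("low", "high"),
                           critical_ooa = 5) {
  side <- match.arg(side)
  span <- side_span(curve, side)
  if (span == 0) return(NA_real_)
  unname((critical_ooa - curve$set_point_ooa[[cqa]]) / span)
}

#' CQA slope of a sensitivity curve
#'
#' The simulated impact of the parameter on the CQA per native unit: the
#' slope of the line from the set-point OOA to the simulated OOA at the
#' screening-range edge, `(OOA_SR - OOA_SP) / (SR_side - SP)`.
#'
#' @inheritParams critical_slope
#' @return Slope in percent OOA per native unit, or `NA` when the side is
#'   inapplicable.
#' @export
cqa_slope <- function(curve, cqa, side = c("low", "high")) {
  side <- match.arg(side)
  span <- side_span(curve, side)
  if (span == 0) return(NA_real_)
  unname((edge_ooa(curve, cqa, side) - curve$set_point_ooa[[cqa]]) / span)
}

side_ratio <- function(m_cqa, m_crit, direction) {
  # direction: +1 on the high side, -1 on the low side.  A critical slope
  # whose sign does not point away from the set point means the set-point
  # OOA already meets or exceeds the critical level: rank 10 by design.
  if (is.na(m_cqa) || is.na(m_crit)) return(NA_real_)
  if (m_crit * direction <= 0) return(Inf)
  max(0, m_cqa / m_crit)
}

#' Assign an FMEA severity ranking from the slope ratio
#'
#' Per applicable side, the ratio of the CQA slope to the critical slope
#' is formed (beneficial directions, where OOA falls towards the edge,
#' floor at 0); the worst-case (larger-ratio) side is ranked with the
#' rubric.  A CQA slope equal to or exceeding the critical slope — or a
#' set point already at or above the critical OOA level — maps to the
#' highest rank by design.
#'
#' @param m_cqa_low,m_cqa_high CQA slopes per side (`NA` = inapplicable).
#' @param m_crit_low,m_crit_high critical slopes per side.
#' @param bands an [ranking_bands()] rubric.
#' @return A list with `pct_ref` (worst-case ratio), `worst_side` and
#'   `ranking`.
#' @export
assign_ranking <- function(m_cqa_low, m_cqa_high, m_crit_low, m_crit_high,
                           bands = ranking_bands()) {
  r_low <- side_ratio(m_cqa_low, m_crit_low, -1)
  r_high <- side_ratio(m_cqa_high, m_crit_high, +1)
  if (is.na(r_low) && is.na(r_high))
    stop_data("both sides inapplicable: set point coincides with both screening edges")
  worst_side <- if (is.na(r_high) || (!is.na(r_low) && r_low >= r_high))
    "low" else "high"
  pct_ref <- if (worst_side == "low") r_low else r_high
  ranking <- if (is.infinite(pct_ref)) bands$ranks[1L] else
    band_rank(pct_ref, bands)
  list(pct_ref = pct_ref, worst_side = worst_side, ranking = ranking)
}

#' Assess the FMEA severity of one parameter from its sensitivity curve
#'
#' Computes per-CQA critical and CQA slopes on both sides of the set
#' point, assigns per-CQA rankings via [assign_ranking()] and takes the
#' worst-case CQA ranking as the parameter's final ranking; rank equal to
#' the top of the rubric designates the parameter a CPP.
#'
#' @param curve an `ipm_psa_curve` covering all CQAs.
#' @param critical_ooa critical OOA level in percent.
#' @param bands an [ranking_bands()] rubric.
#' @return An object of class `ipm_severity`: a list with `parameter`,
#'   `by_cqa` (data frame of slopes, ratios and rankings), `final_ranking`
#'   and `is_cpp`.
#' @export
assess_parameter <- function(curve, critical_ooa = 5,
                             bands = ranking_bands()) {
  cqas <- colnames(curve$ooa)
  assert_that(length(cqas) >= 1, "curve covers no CQA")
  rows <- lapply(cqas, function(q) {
    mc_l <- cqa_slope(curve, q, "low")
    mc_h <- cqa_slope(curve, q, "high")
    cr_l <- critical_slope(curve, q, "low", critical_ooa)
    cr_h <- critical_slope(curve, q, "high", critical_ooa)
    a <- assign_ranking(mc_l, mc_h, cr_l, cr_h, bands)
    data.frame(parameter = curve$parameter$name, cqa = q,
               m_cqa_low = mc_l, m_cqa_high = mc_h,
               m_critical_low = cr_l, m_critical_high = cr_h,
               ratio_low = side_ratio(mc_l, cr_l, -1),
               ratio_high = side_ratio(mc_h, cr_h, +1),
               worst_side = a$worst_side, pct_ref = a$pct_ref,
               ranking = a$ranking)
  })
  by_cqa <- do.call(rbind, rows)
  final <- max(by_cqa$ranking)
  structure(list(parameter = curve$parameter$name, by_cqa = by_cqa,
                 final_ranking = final,
                 is_cpp = final == bands$ranks[1L],
                 critical_ooa = critical_ooa),
            class = "ipm_severity")
}

#' @export
print.ipm_severity <- function(x, ...) {
  cat(sprintf("FMEA severity for '%s': final ranking %g%s\n", x$parameter,
              x$final_ranking, if (x$is_cpp) " (CPP)" else ""))
  df <- x$by_cqa[, c("cqa", "ratio_low", "ratio_high", "worst_side",
                     "pct_ref", "ranking")]
  df[, 2:3] <- round(df[, 2:3], 4)
  df$pct_ref <- round(df$pct_ref, 4)
  print(df, row.names = FALSE)
  invisible(x)
}
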