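#' Derive the proven acceptable range of a parameter
#'
#' The PAR is the contiguous sub-interval of the screening range,
#' containing the set point, on which every CQA's simulated
#' drug-substance OOA stays at or below the critical level.  Moving
#' outward from the set point on each side, the first interval between
#' adjacent curve points whose endpoints straddle the critical level is
#' located and the crossing interpolated linearly; the most restrictive
#' crossing over all CQAs becomes the PAR limit on that side.  If no CQA
#' crosses, the full screening range is acceptable.  If the set-point OOA
#' itself exceeds the critical level for any CQA the PAR is undefined.
#'
#' @param curve an `ipm_psa_curve` covering all CQAs.
#' @param critical_ooa accepted OOA level in percent (default 5).
#' @param smooth if `TRUE`, apply isotonic (monotone away from the set
#'   point) smoothing to each side of each CQA curve before crossing
#'   detection; off by default to reproduce the plain procedure.
#' @return An object of class `ipm_par`: `parameter`, `crossings` (per-CQA
#'   data frame of low/high crossing points, `NA` when absent), `par_low`,
#'   `par_high`, `classification` (one of `"full range acceptable"`,
#'   `"restriction low"`, `"restriction high"`, `"restriction both"`,
#'   `"undefined"`) and `impacted_cqas` (CQAs whose crossings set the
#'   final limits).
#' @export
find_par <- function(curve, critical_ooa = 5, smooth = FALSE) {
  assert_that(inherits(curve, "ipm_psa_curve"), "curve must be an ipm_psa_curve")
  p <- curve$parameter
  cqas <- colnames(curve$ooa)
  sp <- p$set_point
  tol <- 1e-9 * max(1, p$sr_high - p$sr_low)

  side_crossing <- function(x, y, direction) {
    # x, y ordered moving outward from the set point (x[1] = sp)
    if (smooth && length(y) > 1L) y <- stats::isoreg(seq_along(y), y)$yf
    for (i in seq_len(length(x) - 1L)) {
      if (y[i] <= critical_ooa && y[i + 1L] > critical_ooa) {
        return(x[i] + (critical_ooa - y[i]) / (y[i + 1L] - y[i]) *
                 (x[i + 1L] - x[i]))
      }
    }
    NA_real_
  }

  undefined <- any(curve$set_point_ooa[cqas] > critical_ooa)
  rows <- lapply(cqas, function(q) {
    # augment the grid with the dedicated set-point evaluation
    gx <- curve$grid; gy <- curve$ooa[, q]
    keep <- abs(gx - sp) > tol
    xs <- c(gx[keep], sp); ys <- c(gy[keep], curve$set_point_ooa[[q]])
    o <- order(xs); xs <- xs[o]; ys <- ys[o]
    i_sp <- which(abs(xs - sp) <= tol)[1L]
    lo <- if (i_sp > 1L)
      side_crossing(rev(xs[1:i_sp]), rev(ys[1:i_sp]), -1) else NA_real_
    hi <- if (i_sp < length(xs))
      side_crossing(xs[i_sp:length(xs)], ys[i_sp:length(xs)], +1) else NA_real_
    data.frame(cqa = q, low = lo, high = hi)
  })
  crossings <- do.call(rbind, rows)

  if (undefined) {
    res <- list(parameter = p$name, crossings = crossings,
                par_low = NA_real_, par_high = NA_real_,
                classification = "undefined",
                impacted_cqas = cqas[curve$set_point_ooa[cqas] > critical_ooa],
                critical_ooa = critical_ooa)
    return(structure(res, class = "ipm_par"))
  }
  par_low <- if (all(is.na(crossings$low))) p$sr_low else
    max(crossings$low, na.rm = TRUE)
  par_high <- if (all(is.na(crossings$high))) p$sr_high else
    min(crossings$high, na.rm = TRUE)
  rl <- par_low > p$sr_low + tol
  rh <- par_high < p$sr_high - tol
  classification <- if (rl && rh) "restriction both" else
    if (rl) "restriction low" else if (rh) "restriction high" else
      "full range acceptable"
  impacted <- unique(c(
    crossings$cqa[!is.na(crossings$low) & abs(crossings$low - par_low) <= tol & rl],
    crossings$cqa[!is.na(crossings$high) & abs(crossings$high - par_high) <= tol & rh]))
  structure(list(parameter = p$name, crossings = crossings,
                 par_low = par_low, par_high = par_high,
                 classification = classification,
                 impacted_cqas = impacted, critical_ooa = critical_ooa),
            class = "ipm_par")
}

#' @export
print.ipm_par <- function(x, ...) {
  cat(sprintf("PAR for '%s' at %g%% OOA: %s\n", x$parameter,
              x$critical_ooa, x$classification))
  if (!is.na(x$par_low))
    cat(sprintf("  range [%g, %g]", x$par_low, x$par_high))
  if (length(x$impacted_cqas))
    cat(sprintf("  binding CQA(s): %s", paste(x$impacted_cqas, collapse = ", ")))
  cat("\n")
  invisible(x)
}
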