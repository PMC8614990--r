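#' Construct a parameter sensitivity curve object
#'
#' Container for the out-of-acceptance results of a one-at-a-time grid
#' scan of a parameter across its screening range, plus the dedicated
#' set-point evaluation that anchors the severity-slope calculations.
#' Normally produced by [run_psa()]; exposed so curves can also be built
#' from analytic OOA functions in tests and oracles.
#'
#' @param parameter an [process_parameter()].
#' @param grid strictly increasing equidistant values from `sr_low` to
#'   `sr_high`.
#' @param ooa numeric matrix, `length(grid)` rows x one column per CQA, of
#'   OOA percentages.
#' @param set_point_ooa named vector of OOA percentages at the set point.
#' @param n_per_point Monte-Carlo cycles per grid point (or `NA` for
#'   analytic curves).
#' @param seed master seed (or `NA`).
#' @return An object of class `ipm_psa_curve`.
#' @export
psa_curve <- function(parameter, grid, ooa, set_point_ooa,
                      n_per_point = NA_integer_, seed = NA_integer_) {
  assert_that(inherits(parameter, "ipm_parameter"),
              "parameter must be an ipm_parameter")
  assert_that(length(grid) >= 2, "grid needs >= 2 points")
  d <- diff(grid)
  assert_that(all(d > 0), "grid must be strictly increasing")
  assert_that(max(d) - min(d) <= 1e-8 * max(abs(grid)),
              "grid must be equidistant")
  tol <- 1e-8 * max(1, abs(parameter$sr_high - parameter$sr_low))
  assert_that(abs(grid[1] - parameter$sr_low) <= tol &&
              abs(grid[length(grid)] - parameter$sr_high) <= tol,
              "grid must span [sr_low, sr_high]")
  ooa <- as.matrix(ooa)
  assert_that(nrow(ooa) == length(grid), "ooa must have one row per grid point")
  assert_that(!is.null(colnames(ooa)), "ooa columns must be named by CQA")
  assert_that(all(ooa >= 0 & ooa <= 100), "ooa values must lie in [0, 100]")
  assert_that(all(colnames(ooa) %in% names(set_point_ooa)),
              "set_point_ooa must cover every CQA column")
  structure(list(parameter = parameter, grid = as.numeric(grid), ooa = ooa,
                 set_point_ooa = set_point_ooa[colnames(ooa)],
                 n_per_point = n_per_point, seed = seed),
            class = "ipm_psa_curve")
}

#' @export
print.ipm_psa_curve <- function(x, ...) {
  cat(sprintf("PSA curve for '%s': %d grid points over [%g, %g], set point %g\n",
              x$parameter$name, length(x$grid), x$parameter$sr_low,
              x$parameter$sr_high, x$parameter$set_point))
  df <- data.frame(grid = x$grid, round(x$ooa, 3), check.names = FALSE)
  print(df, row.names = FALSE)
  cat("set-point OOA (%):\n"); print(round(x$set_point_ooa, 3))
  invisible(x)
}

#' Run a grid-based parameter sensitivity analysis
#'
#' The parameter's screening range is divided into `grid_size` equidistant
#' points (endpoints inclusive).  At each point the parameter is fixed
#' while all others vary within their normal operating ranges, the full
#' Monte-Carlo simulation is run, and the per-CQA drug-substance OOA is
#' recorded.  The exact set point is evaluated as an additional dedicated
#' run because the severity slopes are anchored there.  Per-point seeds
#' are derived deterministically from the master seed, the parameter name
#' and the grid index, so curves are reproducible and points independent.
#'
#' @param chain an [process_chain()].
#' @param parameter name of the parameter to scan.
#' @param grid_size number of grid points (>= 2).
#' @param n Monte-Carlo cycles per grid point.
#' @param rng_seed master seed.
#' @param gamma confidence level for [ooa_probability()].
#' @return An `ipm_psa_curve` (see [psa_curve()]).
#' @export
run_psa <- function(chain, parameter, grid_size = 10L, n = 1000L,
                    rng_seed = 1L, gamma = 0.95) {
  if (grid_size < 2L) stop_config("grid_size must be >= 2")
  p <- chain$parameters[[parameter]]
  if (is.null(p)) stop_config(sprintf("unknown parameter '%s'", parameter))
  in_model <- any(vapply(chain$unit_operations, function(uo) {
    any(vapply(uo$models, function(e) {
      !is.null(e$doe) && parameter %in% unlist(e$doe$terms)
    }, logical(1)))
  }, logical(1)))
  if (!in_model)
    warning(sprintf("parameter '%s' appears in no DoE model; the curve is flat by construction",
                    parameter))
  grid <- seq(p$sr_low, p$sr_high, length.out = grid_size)
  ooa <- matrix(NA_real_, grid_size, length(chain$cqas),
                dimnames = list(NULL, names(chain$cqas)))
  for (i in seq_len(grid_size)) {
    sim <- run_ipm(chain, n = n, fixed_parameter = parameter,
                   fixed_value = grid[i],
                   rng_seed = derive_seed(rng_seed, parameter, i),
                   gamma = gamma)
    ooa[i, ] <- sim$ooa
  }
  sp_sim <- run_ipm(chain, n = n, fixed_parameter = parameter,
                    fixed_value = p$set_point,
                    rng_seed = derive_seed(rng_seed, parameter, "sp"),
                    gamma = gamma)
  psa_curve(p, grid, ooa, sp_sim$ooa, n_per_point = as.integer(n),
            seed = as.integer(rng_seed))
}

#' Code a parameter value onto the relative screening range
#'
#' Affine recoding of a native-unit value so that the manufacturing set
#' point maps to 0 and one half screening-range width maps to 1:
#' `(x - set_point) / ((sr_high - sr_low) / 2)`.  The image always lies in
#' `[-2, 2]`; in the extreme case where the set point coincides with a
#' screening-range limit the range is coded `[-2, 0]` (or `[0, 2]`).
#' Useful for overlaying sensitivity curves of parameters with different
#' native units.
#'
#' @param x value(s) within the parameter's screening range.
#' @param p an [process_parameter()].
#' @return Coded value(s).
#' @export
relative_screening_range <- function(x, p) {
  half <- (p$sr_high - p$sr_low) / 2
  if (half <= 0) stop_domain("zero-width screening range")
  assert_that(all(x >= p$sr_low - 1e-12 & x <= p$sr_high + 1e-12),
              "x must lie within the screening range")
  (x - p$set_point) / half
}
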