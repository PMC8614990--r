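# Closed-form (delta-method-free) moment propagation for a chain whose
# clearance models are known exactly.  Serves as the independent oracle the
# Monte-Carlo engine is checked against and as the "true" curve in
# end-to-end recovery tests.

# derivative of the expected clearance wrt one parameter, by central
# finite difference at the given settings (exact for linear terms)
clearance_deriv <- function(entry, settings, slc, pname) {
  x <- settings[pname]
  eps <- 1e-6 * max(1, abs(x))
  up <- settings; up[pname] <- x + eps
  dn <- settings; dn[pname] <- x - eps
  f <- function(s) {
    P <- matrix(as.numeric(s), nrow = 1, dimnames = list(NULL, names(s)))
    clearance_vec(entry, P, slc, 1L)
  }
  (f(up) - f(dn)) / (2 * eps)
}

#' Analytic drug-substance moments of a chain at fixed settings
#'
#' Treats the drug-substance concentration as a product of independent
#' factors: the normal starting concentration and, per unit operation, the
#' clearance with variance contributed by (a) process-parameter variation
#' within the NOR through the DoE model coefficients and (b) the model's
#' residual noise.  For independent factors the product mean and variance
#' are exact (`E[prod] = prod E`, `E[prod^2] = prod E[X^2]`); the
#' specific-load-concentration feedback of load models is evaluated on the
#' deterministic set-point trajectory, so its variance contribution is
#' neglected (second-order).
#'
#' @param chain an [process_chain()].
#' @param settings named settings vector; defaults to all set points.
#' @param fixed_parameter name of a parameter held fixed (its NOR variance
#'   is excluded), or `NULL`.
#' @return A data frame with one row per CQA: `cqa`, `mean`, `sd`.
#' @export
analytic_ds_moments <- function(chain, settings = NULL,
                                fixed_parameter = NULL) {
  pars <- chain$parameters
  if (is.null(settings))
    settings <- vapply(pars, `[[`, numeric(1), "set_point")
  sds <- vapply(pars, function(p) (p$nor_high - p$nor_low) / 6, numeric(1))
  if (!is.null(fixed_parameter)) sds[fixed_parameter] <- 0
  P <- matrix(as.numeric(settings), nrow = 1,
              dimnames = list(NULL, names(settings)))
  out <- lapply(names(chain$cqas), function(qn) {
    q <- chain$cqas[[qn]]
    m <- q$start_mean; e2 <- q$start_mean^2 + q$start_sd^2
    conc <- q$start_mean
    for (uo in chain$unit_operations) {
      entry <- uo$models[[qn]]
      ck <- clearance_vec(entry, P, conc, 1L)
      vpar <- 0
      if (!is.null(entry) && !is.null(entry$doe)) {
        for (pn in unique(unlist(entry$doe$terms))) {
          if (sds[pn] > 0)
            vpar <- vpar + (clearance_deriv(entry, settings, conc, pn) *
                              sds[pn])^2
        }
      }
      vk <- vpar + model_noise_sd(entry)^2
      m <- m * ck
      e2 <- e2 * (ck^2 + vk)
      conc <- conc * ck
    }
    data.frame(cqa = qn, mean = m, sd = sqrt(max(0, e2 - m^2)))
  })
  do.call(rbind, out)
}

#' Analytic out-of-acceptance sensitivity curve
#'
#' The closed-form counterpart of [run_psa()]: at each grid point the
#' scanned parameter is fixed, the drug-substance mean and standard
#' deviation are propagated analytically (see [analytic_ds_moments()]),
#' the standard deviation is inflated by the same upper chi-square
#' confidence factor an `n_ref`-cycle Monte-Carlo estimate would apply,
#' and OOA is read off the normal tails.  Used as the ground-truth curve
#' in recovery tests.
#'
#' @param chain an [process_chain()] with known (true) coefficients.
#' @param parameter name of the parameter to scan.
#' @param grid_size number of equidistant grid points.
#' @param n_ref reference sample size for the standard-deviation
#'   inflation, matching the Monte-Carlo run being emulated.
#' @param gamma confidence level of the inflation.
#' @return An `ipm_psa_curve`.
#' @export
analytic_ooa_curve <- function(chain, parameter, grid_size = 10L,
                               n_ref = 1000L, gamma = 0.95) {
  p <- chain$parameters[[parameter]]
  if (is.null(p)) stop_config(sprintf("unknown parameter '%s'", parameter))
  infl <- sqrt((n_ref - 1) / stats::qchisq(1 - gamma, df = n_ref - 1))
  base <- vapply(chain$parameters, `[[`, numeric(1), "set_point")
  eval_at <- function(x) {
    s <- base; s[parameter] <- x
    mom <- analytic_ds_moments(chain, s, fixed_parameter = parameter)
    vapply(seq_len(nrow(mom)), function(i) {
      q <- chain$cqas[[mom$cqa[i]]]
      sstar <- mom$sd[i] * infl
      if (sstar == 0) {
        out <- (!is.na(q$lsl) && mom$mean[i] <= q$lsl) ||
          (!is.na(q$usl) && mom$mean[i] >= q$usl)
        return(if (out) 100 else 0)
      }
      lo <- if (!is.na(q$lsl) && is.finite(q$lsl))
        stats::pnorm((q$lsl - mom$mean[i]) / sstar) else 0
      hi <- if (!is.na(q$usl) && is.finite(q$usl))
        stats::pnorm((q$usl - mom$mean[i]) / sstar, lower.tail = FALSE) else 0
      100 * (lo + hi)
    }, numeric(1), USE.NAMES = FALSE)
  }
  grid <- seq(p$sr_low, p$sr_high, length.out = grid_size)
  ooa <- t(vapply(grid, eval_at, numeric(length(chain$cqas))))
  colnames(ooa) <- names(chain$cqas)
  sp <- stats::setNames(eval_at(p$set_point), names(chain$cqas))
  psa_curve(p, grid, ooa, sp)
}
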