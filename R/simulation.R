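#' Sample process-parameter settings for Monte-Carlo simulation
#'
#' Each parameter is drawn i.i.d. normal with mean equal to its set point
#' and standard deviation equal to one sixth of its normal operating range
#' width (the NOR is interpreted as +/- 3 standard deviations around the
#' set point).  One parameter may be held fixed at a grid value, as the
#' sensitivity analysis requires.
#'
#' @param chain an [process_chain()].
#' @param n number of Monte-Carlo cycles (rows).
#' @param fixed_parameter,fixed_value optionally hold this parameter
#'   constant at `fixed_value`; the value must lie within the parameter's
#'   screening range.
#' @param rng_seed integer seed; draws are reproducible from it.
#' @return An `n x p` numeric matrix with one named column per parameter.
#' @export
sample_parameters <- function(chain, n, fixed_parameter = NULL,
                              fixed_value = NULL, rng_seed = 1L) {
  assert_that(n >= 1, "n must be >= 1")
  set.seed(rng_seed)
  .sample_parameters(chain, n, fixed_parameter, fixed_value)
}

.sample_parameters <- function(chain, n, fixed_parameter = NULL,
                               fixed_value = NULL) {
  pars <- chain$parameters
  if (!is.null(fixed_parameter)) {
    p <- pars[[fixed_parameter]]
    if (is.null(p))
      stop_config(sprintf("unknown parameter '%s'", fixed_parameter))
    if (fixed_value < p$sr_low || fixed_value > p$sr_high)
      stop_domain(sprintf("fixed value %g outside screening range [%g, %g] of '%s'",
                          fixed_value, p$sr_low, p$sr_high, fixed_parameter))
  }
  out <- matrix(NA_real_, n, length(pars),
                dimnames = list(NULL, names(pars)))
  for (p in pars) {
    if (!is.null(fixed_parameter) && p$name == fixed_parameter) {
      out[, p$name] <- fixed_value
    } else {
      out[, p$name] <- stats::rnorm(n, p$set_point, (p$nor_high - p$nor_low) / 6)
    }
  }
  out
}

#' Parametric out-of-acceptance probability of a sample
#'
#' Fits a normal distribution to the sample and returns the probability
#' (in percent) of falling at or outside the acceptance limits,
#' `100 * [Phi((lsl - xbar)/s*) + 1 - Phi((usl - xbar)/s*)]`, where `s*`
#' is the upper one-sided `gamma` confidence limit of the standard
#' deviation, `s* = s * sqrt((n - 1) / chisq_quantile(1 - gamma, n - 1))`.
#' The inflation makes OOA estimates from very small samples (e.g. a
#' handful of manufacturing runs) conservatively comparable with
#' large in-silico samples.
#'
#' @param values numeric sample (>= 2 values) of drug-substance results.
#' @param lsl,usl acceptance limits; `NA` (or `-Inf`/`Inf`) marks an
#'   absent limit, at least one must be given.
#' @param gamma confidence level for the standard-deviation limit.
#' @return OOA probability in percent, in `[0, 100]`.
#' @export
ooa_probability <- function(values, lsl = NA_real_, usl = NA_real_,
                            gamma = 0.95) {
  n <- length(values)
  if (n < 2L) stop_data("need >= 2 values to estimate OOA")
  if (is.na(lsl) && is.na(usl))
    stop_config("at least one acceptance limit must be given")
  if (is.na(lsl)) lsl <- -Inf
  if (is.na(usl)) usl <- Inf
  xbar <- mean(values)
  s <- stats::sd(values)
  if (s == 0) return(if (xbar <= lsl || xbar >= usl) 100 else 0)
  sstar <- s * sqrt((n - 1) / stats::qchisq(1 - gamma, df = n - 1))
  lo <- if (is.finite(lsl)) stats::pnorm((lsl - xbar) / sstar) else 0
  hi <- if (is.finite(usl)) stats::pnorm((usl - xbar) / sstar,
                                         lower.tail = FALSE) else 0
  100 * (lo + hi)
}

model_noise_sd <- function(entry) {
  if (is.null(entry)) return(0)
  switch(entry$type,
    doe = entry$doe$rmse,
    load = entry$load$rmse,
    # when both models are present the DoE model is the primary predictor
    # and its residual scale drives the sampled prediction variation
    both = entry$doe$rmse,
    fixed = entry$sc_sd)
}

#' Run the integrated process model Monte-Carlo simulation
#'
#' Per cycle: starting concentrations are drawn from each CQA's normal
#' start distribution, parameter settings from their NOR-based normals
#' (see [sample_parameters()]), and clearance noise per modelled unit
#' operation and CQA as mean-zero normal with the model's residual
#' standard error (the set-point standard deviation for fixed-clearance
#' cells).  Concentrations are propagated multiplicatively through the
#' chain and out-of-acceptance probabilities at drug substance are
#' computed with [ooa_probability()].
#'
#' @param chain an [process_chain()].
#' @param n number of Monte-Carlo cycles.
#' @param fixed_parameter,fixed_value optionally hold one parameter at a
#'   grid value (used by the sensitivity analysis).
#' @param rng_seed integer seed driving all draws.
#' @param gamma confidence level passed to [ooa_probability()].
#' @return An object of class `ipm_simulation` with elements `n_cycles`,
#'   `pool_conc` (cycles x unit operations x CQAs array), `ds_values`
#'   (cycles x CQAs matrix), `ooa` (named percent vector), `seed`,
#'   `clamp_count` and `gamma`.
#' @export
run_ipm <- function(chain, n = 1000L, fixed_parameter = NULL,
                    fixed_value = NULL, rng_seed = 1L, gamma = 0.95) {
  assert_that(n >= 2, "n must be >= 2")
  uos <- chain$unit_operations
  cqa_names <- names(chain$cqas)
  K <- length(uos)
  set.seed(rng_seed)
  start <- sapply(cqa_names, function(nm) {
    q <- chain$cqas[[nm]]
    stats::rnorm(n, q$start_mean, q$start_sd)
  })
  start <- matrix(pmax(start, .Machine$double.eps), n, length(cqa_names),
                  dimnames = list(NULL, cqa_names))
  P <- .sample_parameters(chain, n, fixed_parameter, fixed_value)
  pool <- array(NA_real_, dim = c(n, K, length(cqa_names)),
                dimnames = list(NULL, names(uos), cqa_names))
  clamp <- 0L
  conc <- start
  for (k in seq_len(K)) {
    uo <- uos[[k]]
    for (j in seq_along(cqa_names)) {
      cqa <- cqa_names[j]
      entry <- uo$models[[cqa]]
      sc <- clearance_vec(entry, P, conc[, j], n)
      nsd <- model_noise_sd(entry)
      if (nsd > 0) sc <- sc + stats::rnorm(n, 0, nsd)
      v <- conc[, j] * sc
      if (any(!is.finite(v)))
        stop(sprintf("non-finite concentration at unit operation '%s', CQA '%s', cycle %d",
                     uo$name, cqa, which(!is.finite(v))[1L]))
      neg <- v < 0
      if (any(neg)) { clamp <- clamp + sum(neg); v[neg] <- 0 }
      conc[, j] <- v
      pool[, k, j] <- v
    }
  }
  ds <- conc
  ooa <- vapply(cqa_names, function(nm) {
    q <- chain$cqas[[nm]]
    ooa_probability(ds[, nm], q$lsl, q$usl, gamma)
  }, numeric(1))
  structure(list(n_cycles = as.integer(n), pool_conc = pool,
                 ds_values = ds, ooa = ooa, seed = as.integer(rng_seed),
                 clamp_count = as.integer(clamp), gamma = gamma,
                 cqas = chain$cqas),
            class = "ipm_simulation")
}

#' @export
print.ipm_simulation <- function(x, ...) {
  cat(sprintf("IPM Monte-Carlo simulation: %d cycles (seed %d, gamma %.2f)\n",
              x$n_cycles, x$seed, x$gamma))
  cat("Drug-substance OOA (%):\n")
  print(round(x$ooa, 3))
  if (x$clamp_count > 0)
    cat(sprintf("note: %d concentration(s) clamped at 0\n", x$clamp_count))
  invisible(x)
}

#' Compare a simulation against observed manufacturing runs
#'
#' Plausibility check of the integrated model: per unit operation and CQA,
#' simulated pool mean/sd are set against the observed mean/sd, and the
#' simulated drug-substance OOA is set against the OOA computed from the
#' observed runs with the same parametric formula (where the small-n
#' standard-deviation inflation of [ooa_probability()] is material).
#'
#' @param sim an `ipm_simulation` result.
#' @param observed long-format data frame of observed runs with columns
#'   `run`, `uo`, `cqa`, `conc` (pool specific concentrations per unit
#'   operation).
#' @param gamma confidence level for the observed-data OOA.
#' @return A list of class `ipm_plausibility` with `by_uo_cqa` (data frame
#'   of means/sds) and `ooa` (data frame of simulated vs observed OOA).
#' @export
plausibility_report <- function(sim, observed, gamma = sim$gamma) {
  if (!is.data.frame(observed) || nrow(observed) == 0L)
    stop_config("observed run table is empty")
  need <- c("run", "uo", "cqa", "conc")
  assert_that(all(need %in% names(observed)),
              "observed table needs columns run, uo, cqa, conc")
  cqa_names <- dimnames(sim$pool_conc)[[3]]
  uo_names <- dimnames(sim$pool_conc)[[2]]
  bad <- setdiff(unique(observed$cqa), cqa_names)
  if (length(bad))
    stop_config(sprintf("observed CQA(s) %s absent from the chain",
                        paste(sQuote(bad), collapse = ", ")))
  rows <- list()
  for (u in uo_names) for (q in cqa_names) {
    obs <- observed$conc[observed$uo == u & observed$cqa == q]
    rows[[length(rows) + 1L]] <- data.frame(
      uo = u, cqa = q,
      sim_mean = mean(sim$pool_conc[, u, q]),
      sim_sd = stats::sd(sim$pool_conc[, u, q]),
      obs_mean = if (length(obs)) mean(obs) else NA_real_,
      obs_sd = if (length(obs) > 1L) stats::sd(obs) else NA_real_,
      n_obs = length(obs))
  }
  by_uo_cqa <- do.call(rbind, rows)
  last_uo <- uo_names[length(uo_names)]
  ooa <- do.call(rbind, lapply(cqa_names, function(q) {
    lim <- sim$cqas[[q]]
    obs_ds <- observed$conc[observed$uo == last_uo & observed$cqa == q]
    data.frame(cqa = q, sim_ooa = unname(sim$ooa[q]),
               obs_ooa = if (length(obs_ds) >= 2L)
                 ooa_probability(obs_ds, lim$lsl, lim$usl, gamma)
               else NA_real_,
               n_obs = length(obs_ds))
  }))
  structure(list(by_uo_cqa = by_uo_cqa, ooa = ooa), class = "ipm_plausibility")
}

#' @export
print.ipm_plausibility <- function(x, ...) {
  cat("IPM plausibility check (simulated vs observed)\n")
  print(x$ooa, row.names = FALSE)
  invisible(x)
}
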