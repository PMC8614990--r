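#' Default model-availability pattern of the synthetic process
#'
#' An 8 unit-operation x 4 CQA character matrix over
#' `{"doe", "load", "both", "fixed", "none"}` mirroring a typical
#' monoclonal-antibody downstream chain: capture (CAP), acid treatment
#' (AT), depth filtration (DF), anion- and cation-exchange chromatography
#' (AEX, CEX), viral filtration (VF), ultra-diafiltration (UFDF) and drug
#' substance (DS), tracking three impurities and one product attribute.
#' Every cell type the fitting and simulation code distinguishes occurs at
#' least once; VF and DS are pure pass-through steps.
#'
#' @return Character matrix with unit-operation rows and CQA columns.
#' @export
default_availability <- function() {
  uo <- c("CAP", "AT", "DF", "AEX", "CEX", "VF", "UFDF", "DS")
  cqa <- c("CQA1_imp", "CQA2_imp", "CQA3_imp", "CQA1_prod")
  m <- matrix("none", length(uo), length(cqa), dimnames = list(uo, cqa))
  m["CAP", ] <- c("doe", "doe", "none", "doe")
  m["AT", ]  <- c("both", "doe", "doe", "doe")
  m["DF", ]  <- c("none", "none", "load", "none")
  m["AEX", ] <- c("doe", "both", "both", "doe")
  m["CEX", ] <- c("both", "doe", "doe", "doe")
  m["UFDF", ] <- c("load", "load", "none", "none")
  m
}

#' Specification of a synthetic ground-truth process
#'
#' Collects the knobs of the synthetic process generator.  Defaults
#' emulate a capable monoclonal-antibody downstream process: 8 unit
#' operations, 4 CQAs (three impurities cleared stepwise, one product
#' attribute with near-unit yield), NOR half-widths of 5% of the set
#' point, screening ranges three times as wide, impurity clearances drawn
#' in `[0.3, 0.7]`, screening-edge clearance effects up to 0.12, residual
#' noise (RMSE) up to 0.012 on the clearance scale, 4% starting-
#' concentration coefficient of variation, and drug-substance acceptance
#' limits placed 4 analytic standard deviations from the set-point mean
#' (a capable process).
#'
#' @param availability unit-operation x CQA availability matrix, see
#'   [default_availability()].
#' @param n_params_per_uo process parameters created for each unit
#'   operation that carries a DoE model.
#' @param nor_rel_halfwidth NOR half-width as a fraction of the set point.
#' @param sr_factor screening-range half-width as a multiple of the NOR
#'   half-width (floored at 1% of the set point so the screening range
#'   never degenerates).
#' @param clearance_range_imp,clearance_range_prod set-point clearance
#'   ranges for impurity and product CQAs.
#' @param effect_range absolute clearance change when a parameter moves
#'   from set point to a screening edge (sign randomized).
#' @param load_delta_range relative clearance change when the specific
#'   load concentration doubles relative to its set-point mean.
#' @param rmse_range residual standard error range of the true models.
#' @param start_means starting specific concentrations per CQA.
#' @param start_cv coefficient of variation of the starting concentration.
#' @param limit_sigmas distance of acceptance limits from the analytic
#'   set-point drug-substance mean, in analytic standard deviations.
#' @param rng_seed integer seed making the generated truth reproducible.
#' @return An object of class `ipm_synth_spec`.
#' @export
synthetic_spec <- function(availability = default_availability(),
                           n_params_per_uo = 2L,
                           nor_rel_halfwidth = 0.05,
                           sr_factor = 3,
                           clearance_range_imp = c(0.3, 0.7),
                           clearance_range_prod = c(0.92, 0.99),
                           effect_range = c(0.02, 0.12),
                           load_delta_range = c(-0.08, 0.08),
                           rmse_range = c(0.004, 0.012),
                           start_means = c(100, 80, 60, 100),
                           start_cv = 0.04,
                           limit_sigmas = 4,
                           rng_seed = 1L) {
  assert_that(is.matrix(availability) && !is.null(dimnames(availability)),
              "availability must be a named unit-operation x CQA matrix")
  assert_that(all(availability %in% c("doe", "load", "both", "fixed", "none")),
              "availability cells must be doe/load/both/fixed/none")
  unmodelled <- colnames(availability)[
    colSums(availability != "none") == 0L]
  if (length(unmodelled))
    stop_config(sprintf("CQA(s) %s have no modelled unit operation",
                        paste(sQuote(unmodelled), collapse = ", ")))
  assert_that(length(start_means) == ncol(availability),
              "start_means must have one entry per CQA")
  structure(list(availability = availability,
                 n_params_per_uo = as.integer(n_params_per_uo),
                 nor_rel_halfwidth = nor_rel_halfwidth,
                 sr_factor = sr_factor,
                 clearance_range_imp = clearance_range_imp,
                 clearance_range_prod = clearance_range_prod,
                 effect_range = effect_range,
                 load_delta_range = load_delta_range,
                 rmse_range = rmse_range,
                 start_means = start_means, start_cv = start_cv,
                 limit_sigmas = limit_sigmas,
                 rng_seed = as.integer(rng_seed)),
            class = "ipm_synth_spec")
}

runif1 <- function(range) stats::runif(1, range[1], range[2])

#' Generate a ground-truth process chain
#'
#' Builds a [process_chain()] with known coefficients from a
#' [synthetic_spec()].  Set-point clearances, screening-edge effects, load
#' slopes and residual noise are drawn once from the spec's ranges
#' (reproducibly from its seed); acceptance limits are then placed
#' relative to the analytic drug-substance distribution at set point so
#' the generated process is capable by construction.
#'
#' @param spec an [synthetic_spec()].
#' @return A list with `chain` (the true [process_chain()]) and `truth`
#'   (the spec, set-point clearance matrix, deterministic drug-substance
#'   trajectory and analytic drug-substance moments) enabling recovery
#'   tests.
#' @export
make_chain <- function(spec = synthetic_spec()) {
  set.seed(spec$rng_seed)
  av <- spec$availability
  uo_names <- rownames(av); cqa_names <- colnames(av)
  is_prod <- grepl("prod", cqa_names)

  params <- list()
  for (u in uo_names) {
    if (!any(av[u, ] %in% c("doe", "both"))) next
    for (i in seq_len(spec$n_params_per_uo)) {
      sp <- stats::runif(1, 2, 10)
      nor_half <- spec$nor_rel_halfwidth * sp
      sr_half <- max(spec$sr_factor * nor_half, 0.01 * sp)
      params[[length(params) + 1L]] <- process_parameter(
        name = sprintf("%s_P%d", u, i), uo = u, set_point = sp,
        nor_low = sp - nor_half, nor_high = sp + nor_half,
        sr_low = sp - sr_half, sr_high = sp + sr_half)
    }
  }
  pnames <- vapply(params, `[[`, character(1), "name")
  puos <- vapply(params, `[[`, character(1), "uo")

  conc <- stats::setNames(spec$start_means, cqa_names)
  c0_mat <- matrix(1, length(uo_names), length(cqa_names),
                   dimnames = dimnames(av))
  uos <- list()
  for (k in seq_along(uo_names)) {
    u <- uo_names[k]
    upars <- params[puos == u]
    models <- list()
    for (j in seq_along(cqa_names)) {
      q <- cqa_names[j]
      type <- av[u, q]
      if (type == "none") next
      c0 <- if (is_prod[j]) runif1(spec$clearance_range_prod) else
        runif1(spec$clearance_range_imp)
      rmse <- runif1(spec$rmse_range)
      mk_doe <- function() {
        beta <- vapply(upars, function(p) {
          eff <- runif1(spec$effect_range) * sample(c(-1, 1), 1)
          eff / ((p$sr_high - p$sr_low) / 2)
        }, numeric(1))
        sp_vals <- vapply(upars, `[[`, numeric(1), "set_point")
        doe_model(uo = u, cqa = q,
                  terms = vapply(upars, `[[`, character(1), "name"),
                  beta = beta, beta0 = c0 - sum(beta * sp_vals),
                  rmse = rmse,
                  n_runs = length(upars) + 3L, n_params = length(upars))
      }
      mk_load <- function() {
        slcm <- conc[[q]]
        delta <- runif1(spec$load_delta_range)
        load_model(uo = u, cqa = q, beta_slc = c0 * delta / slcm,
                   beta0 = c0 * (1 - delta), rmse = rmse,
                   mean_slc_doe = slcm)
      }
      models[[q]] <- switch(type,
        doe = mk_doe(),
        load = mk_load(),
        both = list(mk_doe(), mk_load()),
        fixed = fixed_clearance(c0, rmse))
      c0_mat[u, q] <- c0
      conc[[q]] <- conc[[q]] * c0
    }
    uos[[length(uos) + 1L]] <- unit_operation(u, order = k, models = models)
  }

  provisional <- lapply(seq_along(cqa_names), function(j)
    quality_attribute(cqa_names[j],
                      kind = if (is_prod[j]) "product" else "impurity",
                      usl = spec$start_means[j] * 10,
                      start_mean = spec$start_means[j],
                      start_sd = spec$start_cv * spec$start_means[j]))
  chain0 <- process_chain(uos, params, provisional)
  mom <- analytic_ds_moments(chain0)
  cqas <- lapply(seq_along(cqa_names), function(j) {
    m <- mom$mean[j]; s <- mom$sd[j]
    if (s == 0) s <- 0.05 * m  # degenerate (noise-free) spec fallback
    quality_attribute(cqa_names[j],
                      kind = if (is_prod[j]) "product" else "impurity",
                      lsl = if (is_prod[j]) m - spec$limit_sigmas * s else NA,
                      usl = m + spec$limit_sigmas * s,
                      start_mean = spec$start_means[j],
                      start_sd = spec$start_cv * spec$start_means[j])
  })
  chain <- process_chain(uos, params, cqas)
  list(chain = chain,
       truth = list(spec = spec, clearance = c0_mat, det_ds = conc,
                    ds_moments = analytic_ds_moments(chain)))
}

# deterministic specific load concentration entering each unit operation
# at set point, per CQA
set_point_slc <- function(chain) {
  sp <- vapply(chain$parameters, `[[`, numeric(1), "set_point")
  start <- vapply(chain$cqas, `[[`, numeric(1), "start_mean")
  res <- propagate(chain, sp, start)
  K <- nrow(res$pool)
  slc <- rbind(start, res$pool[-K, , drop = FALSE])
  rownames(slc) <- rownames(res$pool)
  slc
}

#' Generate DoE datasets from the true chain
#'
#' For every unit operation carrying a DoE model, builds a two-level full
#' factorial in that unit operation's parameters at the screening-range
#' edges, replicated and augmented with centre points at the set point.
#' Measured specific clearances equal the true model prediction (at the
#' set-point specific load concentration, which is recorded in the
#' `SLC_<cqa>` columns) plus `N(0, rmse)` noise.
#'
#' @param chain the true [process_chain()] from [make_chain()].
#' @param rng_seed integer seed.
#' @param replicates factorial replicates (>= 1).
#' @param center_points centre-point runs at the set point.
#' @return Named list (by unit operation) of DoE run data frames.
#' @export
generate_doe_data <- function(chain, rng_seed = 1L, replicates = 2L,
                              center_points = 3L) {
  set.seed(rng_seed)
  slc_all <- set_point_slc(chain)
  out <- list()
  for (uo in chain$unit_operations) {
    has_doe <- vapply(uo$models, function(e) !is.null(e$doe), logical(1))
    if (!any(has_doe)) next
    upars <- Filter(function(p) p$uo == uo$name, chain$parameters)
    lv <- lapply(upars, function(p) c(p$sr_low, p$sr_high))
    names(lv) <- vapply(upars, `[[`, character(1), "name")
    fact <- as.matrix(expand.grid(lv))
    design <- fact[rep(seq_len(nrow(fact)), replicates), , drop = FALSE]
    if (center_points > 0L) {
      ctr <- matrix(rep(vapply(upars, `[[`, numeric(1), "set_point"),
                        each = center_points),
                    center_points, length(upars),
                    dimnames = list(NULL, colnames(fact)))
      design <- rbind(design, ctr)
    }
    if (nrow(design) <= length(upars))
      stop_data(sprintf("design for '%s' smaller than its parameter count", uo$name))
    df <- as.data.frame(design)
    for (q in names(uo$models)[has_doe]) {
      entry <- uo$models[[q]]
      slc <- slc_all[uo$name, q]
      mu <- doe_predict_vec(entry$doe, design)
      df[[paste0("SLC_", q)]] <- rep(slc, nrow(design))
      df[[paste0("SC_", q)]] <- mu + stats::rnorm(nrow(design), 0, entry$doe$rmse)
    }
    rownames(df) <- NULL
    out[[uo$name]] <- df
  }
  out
}

#' Generate load-model datasets from the true chain
#'
#' For every unit operation and CQA carrying a load model, simulates runs
#' whose specific load concentration is spread uniformly around the
#' set-point trajectory value, with the measured clearance equal to the
#' true load-model prediction plus residual noise.  Emulates the mix of
#' scales and loads a set-point run collection provides.
#'
#' @param chain the true [process_chain()].
#' @param rng_seed integer seed.
#' @param n runs per dataset.
#' @param spread half-width of the relative SLC spread.
#' @return Named list keyed `"<uo>.<cqa>"` of data frames with
#'   `SLC_<cqa>` and `SC_<cqa>` columns.
#' @export
generate_load_data <- function(chain, rng_seed = 1L, n = 8L, spread = 0.3) {
  set.seed(rng_seed)
  slc_all <- set_point_slc(chain)
  out <- list()
  for (uo in chain$unit_operations) {
    for (q in names(uo$models)) {
      entry <- uo$models[[q]]
      if (is.null(entry$load)) next
      slc0 <- slc_all[uo$name, q]
      slc <- slc0 * (1 + stats::runif(n, -spread, spread))
      sc <- load_predict(entry$load, slc) +
        stats::rnorm(n, 0, entry$load$rmse)
      df <- data.frame(slc, sc)
      names(df) <- paste0(c("SLC_", "SC_"), q)
      out[[paste(uo$name, q, sep = ".")]] <- df
    }
  }
  out
}

#' Simulate manufacturing runs at set point
#'
#' Full stochastic propagation (starting-concentration, NOR parameter and
#' clearance-noise draws) of `n` runs at manufacturing conditions,
#' returned as the long-format run table [plausibility_report()] consumes.
#'
#' @param chain an [process_chain()].
#' @param n number of runs (>= 1).
#' @param rng_seed integer seed.
#' @return Data frame with columns `run`, `uo`, `cqa`, `conc`.
#' @export
generate_manufacturing_runs <- function(chain, n = 5L, rng_seed = 1L) {
  assert_that(n >= 1, "n must be >= 1")
  sim <- run_ipm(chain, n = max(2L, as.integer(n)), rng_seed = rng_seed)
  pool <- sim$pool_conc[seq_len(n), , , drop = FALSE]
  d <- dimnames(pool)
  data.frame(
    run = rep(seq_len(n), times = length(d[[2]]) * length(d[[3]])),
    uo = rep(rep(d[[2]], each = n), times = length(d[[3]])),
    cqa = rep(d[[3]], each = n * length(d[[2]])),
    conc = as.vector(pool))
}

#' Refit a chain's models from generated datasets
#'
#' Replaces every DoE and load model of a (true or template) chain by
#' models fitted from the supplied datasets with [fit_doe_model()] (AIC
#' selection over all main-effect subsets of the unit operation's
#' parameters) and [fit_load_model()].  For combined cells the fitted
#' load model's `mean_slc_doe` anchor is overwritten with the mean SLC of
#' the DoE runs, as the combined prediction requires.  Fixed-clearance
#' cells are retained unchanged.
#'
#' @param chain chain providing the structure (parameters, CQAs,
#'   availability).
#' @param doe_data named list of DoE data frames from
#'   [generate_doe_data()] (or read from CSV).
#' @param load_data named list of load data frames from
#'   [generate_load_data()].
#' @return A list with `chain` (the fitted [process_chain()]) and
#'   `diagnostics` (long data frame of per-model diagnostics).
#' @export
fit_chain_models <- function(chain, doe_data, load_data = list()) {
  diags <- list()
  add_diag <- function(uo, cqa, kind, d) {
    diags[[length(diags) + 1L]] <<- data.frame(
      uo = uo, cqa = cqa, model = kind, r2_adj = d$r2_adj, q2 = d$q2,
      rmse = d$rmse, aic = d$aic)
  }
  new_uos <- lapply(chain$unit_operations, function(uo) {
    mains <- names(Filter(function(p) p$uo == uo$name, chain$parameters))
    models <- list()
    for (q in names(uo$models)) {
      entry <- uo$models[[q]]
      fitted_doe <- NULL; fitted_load <- NULL
      if (!is.null(entry$doe)) {
        d <- doe_data[[uo$name]]
        if (is.null(d))
          stop_config(sprintf("no DoE dataset for unit operation '%s'", uo$name))
        f <- fit_doe_model(d, uo$name, q, main_effects = mains)
        fitted_doe <- f$model
        add_diag(uo$name, q, "doe", f$diagnostics)
      }
      if (!is.null(entry$load)) {
        ld <- load_data[[paste(uo$name, q, sep = ".")]]
        if (is.null(ld))
          stop_config(sprintf("no load dataset for '%s', CQA '%s'", uo$name, q))
        f <- fit_load_model(ld, uo$name, q)
        fitted_load <- f$model
        add_diag(uo$name, q, "load", f$diagnostics)
      }
      models[[q]] <- switch(entry$type,
        doe = fitted_doe,
        load = fitted_load,
        both = {
          fitted_load$mean_slc_doe <-
            mean(doe_data[[uo$name]][[paste0("SLC_", q)]])
          list(fitted_doe, fitted_load)
        },
        fixed = fixed_clearance(entry$sc_mean, entry$sc_sd))
    }
    unit_operation(uo$name, uo$order, models)
  })
  list(chain = process_chain(unname(new_uos), unname(chain$parameters),
                             unname(chain$cqas)),
       diagnostics = do.call(rbind, diags))
}
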