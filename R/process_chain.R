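#' Define a process parameter
#'
#' A process parameter (pCPP) of one unit operation, described in native
#' units by its manufacturing set point, its normal operating range (NOR,
#' the band of routine uncontrolled variation) and its screening range (the
#' wider experimentally explored span used by the sensitivity analysis).
#'
#' @param name parameter identifier, unique within the chain.
#' @param uo identifier of the unit operation the parameter belongs to.
#' @param set_point manufacturing set point (native units).
#' @param nor_low,nor_high normal operating range bounds.
#' @param sr_low,sr_high screening range bounds; must bracket the NOR.
#' @return An object of class `ipm_parameter`.
#' @export
process_parameter <- function(name, uo, set_point, nor_low, nor_high,
                              sr_low, sr_high) {
  for (v in list(set_point, nor_low, nor_high, sr_low, sr_high))
    assert_that(is_scalar_num(v), sprintf("parameter '%s': bounds must be finite numbers", name))
  assert_that(sr_low < sr_high,
              sprintf("parameter '%s': screening range has zero width", name))
  assert_that(sr_low <= nor_low && nor_low <= set_point &&
              set_point <= nor_high && nor_high <= sr_high,
              sprintf("parameter '%s': require sr_low <= nor_low <= set_point <= nor_high <= sr_high", name))
  structure(list(name = as.character(name), uo = as.character(uo),
                 set_point = set_point, nor_low = nor_low,
                 nor_high = nor_high, sr_low = sr_low, sr_high = sr_high),
            class = "ipm_parameter")
}

#' Define a critical quality attribute
#'
#' A CQA is a product property (an impurity or a desired product attribute)
#' carrying an acceptance limit at drug substance.  Its starting specific
#' concentration entering the first unit operation is modelled as normal.
#'
#' @param name CQA identifier.
#' @param kind `"impurity"` or `"product"`.
#' @param lsl,usl lower/upper acceptance limit at drug substance; use `NA`
#'   for an absent limit (at least one must be finite).
#' @param start_mean,start_sd normal distribution of the starting specific
#'   concentration (`start_mean > 0`, `start_sd >= 0`).
#' @return An object of class `ipm_cqa`.
#' @export
quality_attribute <- function(name, kind = c("impurity", "product"),
                              lsl = NA_real_, usl = NA_real_,
                              start_mean, start_sd) {
  kind <- match.arg(kind)
  lsl <- as.numeric(lsl); usl <- as.numeric(usl)
  assert_that((!is.na(lsl) && is.finite(lsl)) || (!is.na(usl) && is.finite(usl)),
              sprintf("CQA '%s': at least one acceptance limit must be finite", name))
  if (!is.na(lsl) && !is.na(usl))
    assert_that(lsl < usl, sprintf("CQA '%s': lsl must be < usl", name))
  assert_that(is_scalar_num(start_mean) && start_mean > 0,
              sprintf("CQA '%s': start_mean must be > 0", name))
  assert_that(is_scalar_num(start_sd) && start_sd >= 0,
              sprintf("CQA '%s': start_sd must be >= 0", name))
  structure(list(name = as.character(name), kind = kind, lsl = lsl, usl = usl,
                 start_mean = start_mean, start_sd = start_sd),
            class = "ipm_cqa")
}

normalize_terms <- function(terms) {
  # main effects may be given as a character vector; derived terms
  # (interactions, quadratics) as named list entries of component parameters
  if (is.character(terms)) terms <- stats::setNames(as.list(terms), terms)
  if (is.null(names(terms)) && length(terms))
    names(terms) <- vapply(terms, paste, character(1), collapse = ":")
  lapply(terms, as.character)
}

#' DoE regression model of specific clearance
#'
#' A linear model of a unit operation's specific clearance for one CQA as a
#' function of its process-parameter settings, `SC = beta0 + sum(beta * PP)`.
#' Interaction or quadratic terms are declared as named derived terms whose
#' value is the product of the listed parameter columns.
#'
#' @param uo,cqa identifiers of the unit operation and quality attribute.
#' @param terms character vector of parameter names (main effects) or a
#'   named list mapping a term name to the parameter names whose product
#'   forms the regressor.
#' @param beta numeric coefficients, one per term, in term order.
#' @param beta0 intercept.
#' @param rmse residual standard error of the fit (noise scale used by the
#'   Monte-Carlo engine).
#' @param n_runs,n_params number of runs the model was fitted on and number
#'   of model terms; `n_runs > n_params >= 1`.
#' @return An object of class `ipm_doe_model`.
#' @export
doe_model <- function(uo, cqa, terms, beta, beta0, rmse,
                      n_runs = length(beta) + 2L, n_params = length(beta)) {
  terms <- normalize_terms(terms)
  assert_that(length(beta) == length(terms), "beta length must match terms")
  assert_that(is_scalar_num(rmse) && rmse >= 0, "rmse must be >= 0")
  assert_that(n_params >= 1 && n_runs > n_params,
              "require n_runs > n_params >= 1")
  structure(list(uo = as.character(uo), cqa = as.character(cqa),
                 terms = terms, beta = stats::setNames(as.numeric(beta), names(terms)),
                 beta0 = as.numeric(beta0), rmse = rmse,
                 n_runs = as.integer(n_runs), n_params = as.integer(n_params)),
            class = "ipm_doe_model")
}

#' Load (specific load concentration) model of specific clearance
#'
#' A unifactorial linear model `SC = beta0 + beta_slc * SLC` describing a
#' unit operation's clearance of a CQA as a function of the specific load
#' concentration entering it; this is the link that lets variation travel
#' across unit operations.
#'
#' @param uo,cqa identifiers.
#' @param beta_slc slope on the specific load concentration.
#' @param beta0 intercept.
#' @param rmse residual standard error.
#' @param mean_slc_doe arithmetic mean SLC over the runs the companion DoE
#'   model was fitted on; anchor of the multiplicative correction when both
#'   model types are present.
#' @return An object of class `ipm_load_model`.
#' @export
load_model <- function(uo, cqa, beta_slc, beta0, rmse, mean_slc_doe) {
  assert_that(is_scalar_num(rmse) && rmse >= 0, "rmse must be >= 0")
  assert_that(is_scalar_num(mean_slc_doe) && mean_slc_doe > 0,
              "mean_slc_doe must be > 0")
  structure(list(uo = as.character(uo), cqa = as.character(cqa),
                 beta_slc = as.numeric(beta_slc), beta0 = as.numeric(beta0),
                 rmse = rmse, mean_slc_doe = mean_slc_doe),
            class = "ipm_load_model")
}

#' Fixed set-point clearance estimated from manufacturing runs
#'
#' For unit operations with no regression model but reproducible set-point
#' data, the clearance is modelled as `N(sc_mean, sc_sd^2)`.
#'
#' @param sc_mean mean specific clearance observed at set point.
#' @param sc_sd standard deviation across set-point runs (`>= 0`).
#' @return An object of class `ipm_fixed_clearance`.
#' @export
fixed_clearance <- function(sc_mean, sc_sd = 0) {
  assert_that(is_scalar_num(sc_mean), "sc_mean must be a number")
  assert_that(is_scalar_num(sc_sd) && sc_sd >= 0, "sc_sd must be >= 0")
  structure(list(sc_mean = sc_mean, sc_sd = sc_sd),
            class = "ipm_fixed_clearance")
}

normalize_model_entry <- function(m, uo_name, cqa_name) {
  if (is.null(m)) return(NULL)
  if (inherits(m, "ipm_doe_model")) return(list(type = "doe", doe = m))
  if (inherits(m, "ipm_load_model")) return(list(type = "load", load = m))
  if (inherits(m, "ipm_fixed_clearance"))
    return(list(type = "fixed", sc_mean = m$sc_mean, sc_sd = m$sc_sd))
  if (is.list(m)) {
    doe <- Filter(function(x) inherits(x, "ipm_doe_model"), m)
    ld  <- Filter(function(x) inherits(x, "ipm_load_model"), m)
    if (length(doe) == 1L && length(ld) == 1L)
      return(list(type = "both", doe = doe[[1L]], load = ld[[1L]]))
  }
  stop_config(sprintf(
    "unit operation '%s', CQA '%s': model entry must be a doe_model, load_model, fixed_clearance, or list(doe_model, load_model)",
    uo_name, cqa_name))
}

#' Define a unit operation
#'
#' One processing step of the downstream chain.  `models` maps CQA names to
#' the clearance model used in simulation: a [doe_model()], a
#' [load_model()], a `list(doe_model, load_model)` combination, or a
#' [fixed_clearance()].  A CQA with no entry is passed through unchanged
#' (clearance exactly 1, zero noise).
#'
#' @param name unit operation identifier.
#' @param order 1-based position in the chain.
#' @param models named list keyed by CQA name (may be empty).
#' @return An object of class `ipm_uo`.
#' @export
unit_operation <- function(name, order, models = list()) {
  assert_that(is_scalar_num(order) && order == round(order) && order >= 1,
              sprintf("unit operation '%s': order must be a positive integer", name))
  if (length(models))
    assert_that(!is.null(names(models)) && all(nzchar(names(models))),
                sprintf("unit operation '%s': models must be named by CQA", name))
  models <- stats::setNames(
    lapply(seq_along(models),
           function(i) normalize_model_entry(models[[i]], name, names(models)[i])),
    names(models))
  structure(list(name = as.character(name), order = as.integer(order),
                 models = models),
            class = "ipm_uo")
}

#' Assemble a process chain
#'
#' Validates and assembles the in-silico process: ordered unit operations,
#' the process parameters they use and the CQAs being tracked.  Every DoE
#' model term must resolve to a declared parameter of the same unit
#' operation and every model's CQA to a declared quality attribute; unit
#' operation orders must form a contiguous permutation `1..K`.
#'
#' @param unit_operations list of [unit_operation()] objects.
#' @param parameters list of [process_parameter()] objects.
#' @param cqas list of [quality_attribute()] objects.
#' @return An object of class `ipm_chain`; unit operations are stored
#'   sorted by `order`.
#' @export
process_chain <- function(unit_operations, parameters, cqas) {
  assert_that(length(unit_operations) >= 1, "chain needs >= 1 unit operation")
  ord <- unname(vapply(unit_operations, `[[`, integer(1), "order"))
  assert_that(identical(sort(ord), seq_along(unit_operations)),
              "unit operation orders must be a contiguous permutation 1..K")
  unit_operations <- unit_operations[order(ord)]
  uo_names <- vapply(unit_operations, `[[`, character(1), "name")
  assert_that(!anyDuplicated(uo_names), "duplicate unit operation names")
  par_names <- vapply(parameters, `[[`, character(1), "name")
  assert_that(!anyDuplicated(par_names), "duplicate parameter names")
  cqa_names <- vapply(cqas, `[[`, character(1), "name")
  assert_that(!anyDuplicated(cqa_names), "duplicate CQA names")
  par_uo <- stats::setNames(vapply(parameters, `[[`, character(1), "uo"), par_names)
  for (uo in unit_operations) {
    for (cqa in names(uo$models)) {
      if (!cqa %in% cqa_names)
        stop_config(sprintf("unit operation '%s': model CQA '%s' is not a declared quality attribute",
                            uo$name, cqa))
      entry <- uo$models[[cqa]]
      if (!is.null(entry$doe)) {
        comps <- unique(unlist(entry$doe$terms))
        miss <- setdiff(comps, par_names)
        if (length(miss))
          stop_config(sprintf("unit operation '%s': DoE term parameter(s) %s not declared",
                              uo$name, paste(sQuote(miss), collapse = ", ")))
        wrong <- comps[par_uo[comps] != uo$name]
        if (length(wrong))
          stop_config(sprintf("unit operation '%s': DoE term parameter(s) %s belong to another unit operation",
                              uo$name, paste(sQuote(wrong), collapse = ", ")))
      }
    }
  }
  structure(list(unit_operations = stats::setNames(unit_operations, uo_names),
                 parameters = stats::setNames(parameters, par_names),
                 cqas = stats::setNames(cqas, cqa_names)),
            class = "ipm_chain")
}

#' @export
print.ipm_chain <- function(x, ...) {
  cat(sprintf("Integrated process model chain: %d unit operations, %d parameters, %d CQAs\n",
              length(x$unit_operations), length(x$parameters), length(x$cqas)))
  for (uo in x$unit_operations) {
    types <- vapply(uo$models, `[[`, character(1), "type")
    cat(sprintf("  %d. %-6s %s\n", uo$order, uo$name,
                if (length(types)) paste(names(types), types, sep = ":", collapse = "  ")
                else "(pass-through)"))
  }
  invisible(x)
}

# evaluate model terms (products of parameter columns) on an n x p settings
# matrix with named columns; returns n x n_terms matrix
eval_terms <- function(terms, P) {
  out <- matrix(NA_real_, nrow(P), length(terms),
                dimnames = list(NULL, names(terms)))
  for (j in seq_along(terms)) {
    comps <- terms[[j]]
    miss <- setdiff(comps, colnames(P))
    if (length(miss))
      stop_config(sprintf("missing parameter setting for term component '%s'", miss[1L]))
    v <- rep(1, nrow(P))
    for (cp in comps) v <- v * P[, cp]
    out[, j] <- v
  }
  out
}

doe_predict_vec <- function(m, P) {
  drop(eval_terms(m$terms, P) %*% m$beta) + m$beta0
}

load_predict <- function(m, slc) m$beta0 + m$beta_slc * slc

# vectorized expected clearance for one normalized model entry;
# P: n x p named settings matrix, slc: length-n vector (or NULL)
clearance_vec <- function(entry, P, slc, n) {
  if (is.null(entry)) return(rep(1, n))
  switch(entry$type,
    doe = doe_predict_vec(entry$doe, P),
    load = {
      if (any(slc <= 0)) stop_domain("slc must be > 0 when a load model is present")
      load_predict(entry$load, slc)
    },
    both = {
      if (any(slc <= 0)) stop_domain("slc must be > 0 when a load model is present")
      ref <- load_predict(entry$load, entry$load$mean_slc_doe)
      doe_predict_vec(entry$doe, P) * load_predict(entry$load, slc) / ref
    },
    fixed = rep(entry$sc_mean, n),
    stop_config("unknown model entry type"))
}

#' Predict the expected specific clearance of a unit operation
#'
#' Deterministic mean clearance for one CQA at given parameter settings and
#' specific load concentration.  DoE-only cells use the linear DoE
#' prediction; load-only cells the load-model prediction; cells with both
#' models multiply the DoE prediction by the ratio of the load prediction
#' at the current SLC to the load prediction at the DoE-mean SLC; fixed
#' cells return the set-point mean; unmodelled cells return 1
#' (pass-through).
#'
#' @param uo an [unit_operation()].
#' @param cqa CQA name.
#' @param pp_settings named numeric vector of parameter settings; must
#'   cover every term of the unit operation's DoE model, if any.
#' @param slc specific load concentration entering the unit operation;
#'   required (and `> 0`) when a load model is configured.
#' @return Expected specific clearance (dimensionless multiplicative ratio).
#' @export
predict_clearance <- function(uo, cqa, pp_settings = numeric(), slc = NULL) {
  entry <- uo$models[[cqa]]
  if (is.null(entry)) return(1)
  P <- matrix(as.numeric(pp_settings), nrow = 1,
              dimnames = list(NULL, names(pp_settings)))
  if (entry$type %in% c("load", "both")) {
    if (is.null(slc)) stop_domain("slc is required when a load model is present")
  }
  clearance_vec(entry, P, slc, 1L)
}

#' Propagate concentrations through the chain to drug substance
#'
#' Deterministic (or externally randomized) propagation: for each unit
#' operation in order, the pool specific concentration equals the incoming
#' concentration times `(predicted clearance + noise draw)`; the pool of
#' unit operation `k` is the load of `k + 1`, and the drug-substance value
#' is the pool of the last unit operation.  Negative intermediate
#' concentrations are clamped to zero and counted.
#'
#' @param chain an [process_chain()].
#' @param pp_settings named numeric vector of settings for all parameters
#'   used by DoE models.
#' @param start_conc named numeric vector of starting concentrations, one
#'   per CQA (positive).
#' @param noise_draws optional `K x C` matrix (unit operations x CQAs,
#'   dimnames matching the chain) of additive clearance noise; `NULL`
#'   means zero noise.
#' @return A list with `pool` (`K x C` matrix of pool concentrations),
#'   `ds` (named drug-substance vector) and `clamp_count`.
#' @export
propagate <- function(chain, pp_settings, start_conc, noise_draws = NULL) {
  uos <- chain$unit_operations
  cqa_names <- names(chain$cqas)
  assert_that(all(cqa_names %in% names(start_conc)),
              "start_conc must cover every CQA")
  if (any(start_conc[cqa_names] <= 0))
    stop_domain("start_conc must be positive")
  K <- length(uos)
  pool <- matrix(NA_real_, K, length(cqa_names),
                 dimnames = list(names(uos), cqa_names))
  P <- matrix(as.numeric(pp_settings), nrow = 1,
              dimnames = list(NULL, names(pp_settings)))
  clamp <- 0L
  conc <- start_conc[cqa_names]
  for (k in seq_len(K)) {
    uo <- uos[[k]]
    for (cqa in cqa_names) {
      eps <- if (is.null(noise_draws)) 0 else noise_draws[uo$name, cqa]
      sc <- clearance_vec(uo$models[[cqa]], P, conc[cqa], 1L) + eps
      val <- conc[cqa] * sc
      if (val < 0) { val <- 0; clamp <- clamp + 1L }
      conc[cqa] <- val
      pool[k, cqa] <- val
    }
  }
  if (clamp > 0L)
    warning(sprintf("%d negative pool concentration(s) clamped to 0", clamp))
  list(pool = pool, ds = conc, clamp_count = clamp)
}
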