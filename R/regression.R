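#' Model diagnostics for a fitted clearance model
#'
#' @param fit an `lm` fit.
#' @return A list of class `ipm_diagnostics` with `r2_adj`, `q2` (from
#'   leave-one-out PRESS via the hat matrix), `rmse` (residual standard
#'   error), `partial_p` (two-sided t-test p-values per term, intercept
#'   excluded), `aic` and `residuals`.
#' @keywords internal
model_diagnostics <- function(fit) {
  sm <- summary(fit)
  res <- stats::residuals(fit)
  h <- stats::hatvalues(fit)
  press <- sum((res / (1 - h))^2)
  y <- stats::model.response(stats::model.frame(fit))
  sstot <- sum((y - mean(y))^2)
  q2 <- if (sstot > 0) 1 - press / sstot else NA_real_
  cf <- sm$coefficients
  pp <- cf[rownames(cf) != "(Intercept)", "Pr(>|t|)", drop = TRUE]
  if (length(pp)) names(pp) <- rownames(cf)[rownames(cf) != "(Intercept)"]
  structure(list(r2_adj = sm$adj.r.squared, q2 = q2, rmse = sm$sigma,
                 partial_p = pp, aic = stats::AIC(fit),
                 residuals = unname(res)),
            class = "ipm_diagnostics")
}

default_candidates <- function(main_effects, interactions = list(),
                               max_size = length(main_effects)) {
  main_effects <- normalize_terms(main_effects)
  interactions <- normalize_terms(interactions)
  sets <- list(list())  # intercept-only
  idx <- seq_along(main_effects)
  for (k in seq_len(min(max_size, length(main_effects)))) {
    for (sel in utils::combn(idx, k, simplify = FALSE))
      sets <- c(sets, list(main_effects[sel]))
  }
  if (length(interactions)) {
    # interactions are offered on top of the full main-effect sets that
    # contain their components (weak heredity is not enforced beyond that)
    extra <- lapply(sets[-1L], function(s) {
      ok <- vapply(interactions,
                   function(tm) all(tm %in% unlist(s)), logical(1))
      if (any(ok)) c(s, interactions[ok]) else NULL
    })
    sets <- c(sets, Filter(Negate(is.null), extra))
  }
  sets
}

fit_one_candidate <- function(X, y) {
  df <- as.data.frame(X)
  df$.y <- y
  if (ncol(X)) {
    qrX <- qr(cbind(1, X))
    if (qrX$rank < ncol(X) + 1L) {
      keep <- qrX$pivot[seq_len(qrX$rank)]
      drop_cols <- setdiff(seq_len(ncol(X) + 1L), keep) - 1L
      stop_data(sprintf("rank-deficient design: collinear term(s) %s",
                        paste(sQuote(colnames(X)[drop_cols]), collapse = ", ")))
    }
  }
  fm <- if (ncol(X)) stats::as.formula(paste(
    ".y ~", paste(sprintf("`%s`", colnames(X)), collapse = " + ")))
  else .y ~ 1
  stats::lm(fm, data = df)
}

#' Fit a DoE clearance model by AIC-based candidate selection
#'
#' Fits every candidate term set by ordinary least squares on raw (native
#' unit) settings and returns the candidate with the lowest Akaike
#' information criterion, together with its diagnostics.
#'
#' @param data a data frame of DoE runs: one column per parameter (native
#'   units) plus a response column `SC_<cqa>` and, optionally, load columns
#'   `SLC_<cqa>`.
#' @param uo unit operation identifier recorded on the model.
#' @param cqa CQA name; the response column is `SC_<cqa>`.
#' @param candidate_terms either a list of term sets (each a character
#'   vector / named list as in [doe_model()]) or `NULL`, in which case all
#'   subsets of `main_effects` (plus declared `interactions` when their
#'   components are present) are considered, including the intercept-only
#'   model.
#' @param main_effects,interactions used to build the default candidate
#'   pool when `candidate_terms` is `NULL`.
#' @param max_size largest main-effect subset considered.
#' @return A list with `model` (an [doe_model()]) and `diagnostics`
#'   (see [model_diagnostics()]).
#' @export
fit_doe_model <- function(data, uo, cqa, candidate_terms = NULL,
                          main_effects = NULL, interactions = list(),
                          max_size = Inf) {
  ycol <- paste0("SC_", cqa)
  if (!ycol %in% names(data))
    stop_data(sprintf("response column '%s' not found", ycol))
  if (is.null(candidate_terms)) {
    if (is.null(main_effects))
      stop_config("either candidate_terms or main_effects must be given")
    candidate_terms <- default_candidates(main_effects, interactions,
                                          min(max_size, length(main_effects)))
  }
  candidate_terms <- lapply(candidate_terms, normalize_terms)
  y <- data[[ycol]]
  n <- length(y)
  p_max <- max(vapply(candidate_terms, length, integer(1)))
  if (n < p_max + 2L)
    stop_data(sprintf("need >= %d runs to fit %d-term candidates, got %d",
                      p_max + 2L, p_max, n))
  best <- NULL
  for (terms in candidate_terms) {
    X <- eval_terms(terms, as.matrix(data[, unique(unlist(terms)), drop = FALSE]))
    if (anyNA(X) || anyNA(y)) stop_data("missing values in model columns")
    fit <- fit_one_candidate(X, y)
    aic <- stats::AIC(fit)
    if (is.null(best) || aic < best$aic - 1e-12)
      best <- list(terms = terms, fit = fit, aic = aic)
  }
  diag <- model_diagnostics(best$fit)
  cf <- stats::coef(best$fit)
  beta <- if (length(best$terms)) unname(cf[-1L]) else numeric(0)
  n_params <- max(1L, length(best$terms))
  model <- doe_model(uo = uo, cqa = cqa,
                     terms = if (length(best$terms)) best$terms else
                       stats::setNames(list(character(0)), "(none)"),
                     beta = if (length(best$terms)) beta else 0,
                     beta0 = unname(cf[1L]), rmse = diag$rmse,
                     n_runs = n, n_params = n_params)
  # an intercept-only winner is encoded as a single all-ones "(none)" term
  # with zero coefficient so the prediction contract stays uniform
  list(model = model, diagnostics = diag)
}

#' Fit a load (SLC) clearance model
#'
#' Single-predictor OLS of the specific clearance `SC_<cqa>` on the
#' specific load concentration `SLC_<cqa>`; at least three rows with three
#' distinct SLC values are required.  The mean SLC over the fitted rows is
#' recorded as the anchor for the combined DoE-and-load prediction.
#'
#' @param data data frame with columns `SC_<cqa>` and `SLC_<cqa>`.
#' @param uo unit operation identifier recorded on the model.
#' @param cqa CQA name.
#' @return A list with `model` (an [load_model()]) and `diagnostics`.
#' @export
fit_load_model <- function(data, uo, cqa) {
  ycol <- paste0("SC_", cqa); xcol <- paste0("SLC_", cqa)
  for (cl in c(ycol, xcol))
    if (!cl %in% names(data)) stop_data(sprintf("column '%s' not found", cl))
  y <- data[[ycol]]; x <- data[[xcol]]
  if (anyNA(x) || anyNA(y)) stop_data("missing values in model columns")
  if (length(unique(x)) < 3L)
    stop_data("need >= 3 distinct SLC values to estimate the load slope")
  fit <- stats::lm(y ~ x, data = data.frame(x = x, y = y))
  diag <- model_diagnostics(fit)
  cf <- stats::coef(fit)
  model <- load_model(uo = uo, cqa = cqa, beta_slc = unname(cf[2L]),
                      beta0 = unname(cf[1L]), rmse = diag$rmse,
                      mean_slc_doe = mean(x))
  list(model = model, diagnostics = diag)
}
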