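model_entry_to_list <- function(entry) {
  if (is.null(entry)) return(NULL)
  out <- list(type = entry$type)
  if (!is.null(entry$doe)) {
    d <- entry$doe
    out$doe <- list(terms = d$terms, beta = as.list(d$beta), beta0 = d$beta0,
                    rmse = d$rmse, n_runs = d$n_runs, n_params = d$n_params)
  }
  if (!is.null(entry$load)) {
    l <- entry$load
    out$load <- list(beta_slc = l$beta_slc, beta0 = l$beta0, rmse = l$rmse,
                     mean_slc_doe = l$mean_slc_doe)
  }
  if (entry$type == "fixed") {
    out$sc_mean <- entry$sc_mean; out$sc_sd <- entry$sc_sd
  }
  out
}

list_to_model_entry <- function(x, uo, cqa) {
  mk_doe <- function() doe_model(uo, cqa, terms = lapply(x$doe$terms, unlist),
                                 beta = unlist(x$doe$beta),
                                 beta0 = x$doe$beta0, rmse = x$doe$rmse,
                                 n_runs = x$doe$n_runs,
                                 n_params = x$doe$n_params)
  mk_load <- function() load_model(uo, cqa, beta_slc = x$load$beta_slc,
                                   beta0 = x$load$beta0, rmse = x$load$rmse,
                                   mean_slc_doe = x$load$mean_slc_doe)
  switch(x$type,
    doe = mk_doe(),
    load = mk_load(),
    both = list(mk_doe(), mk_load()),
    fixed = fixed_clearance(x$sc_mean, x$sc_sd),
    stop_config(sprintf("unknown model type '%s' in config", x$type)))
}

#' Write a process chain to a JSON configuration file
#'
#' Serializes parameters (set point, NOR, screening range), CQAs (kind,
#' acceptance limits, start distribution) and per-unit-operation model
#' coefficients at full precision; [read_chain_json()] reproduces an
#' equivalent chain field by field.
#'
#' @param chain an [process_chain()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_chain_json <- function(chain, path) {
  doc <- list(
    parameters = lapply(unname(chain$parameters), function(p)
      p[c("name", "uo", "set_point", "nor_low", "nor_high",
          "sr_low", "sr_high")]),
    cqas = lapply(unname(chain$cqas), function(q)
      list(name = q$name, kind = q$kind,
           lsl = if (is.na(q$lsl)) NULL else q$lsl,
           usl = if (is.na(q$usl)) NULL else q$usl,
           start_mean = q$start_mean, start_sd = q$start_sd)),
    unit_operations = lapply(unname(chain$unit_operations), function(uo)
      list(name = uo$name, order = uo$order,
           models = lapply(uo$models, model_entry_to_list))))
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                              null = "null"), path)
  invisible(path)
}

#' Read a process chain from a JSON configuration file
#'
#' @param path file written by [write_chain_json()] (or hand-authored to
#'   the same schema).
#' @return An [process_chain()].
#' @export
read_chain_json <- function(path) {
  if (!file.exists(path)) stop_config(sprintf("config file '%s' not found", path))
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  params <- lapply(doc$parameters, function(p)
    process_parameter(p$name, p$uo, p$set_point, p$nor_low, p$nor_high,
                      p$sr_low, p$sr_high))
  cqas <- lapply(doc$cqas, function(q)
    quality_attribute(q$name, q$kind, lsl = q$lsl %||% NA_real_,
                      usl = q$usl %||% NA_real_,
                      start_mean = q$start_mean, start_sd = q$start_sd))
  uos <- lapply(doc$unit_operations, function(u) {
    models <- lapply(names(u$models), function(q)
      list_to_model_entry(u$models[[q]], u$name, q))
    names(models) <- names(u$models)
    unit_operation(u$name, u$order, models)
  })
  process_chain(uos, params, cqas)
}

#' Export simulation cycles as long-format CSV
#'
#' One row per cycle x unit operation x CQA with the pool concentration;
#' drug-substance values are the rows of the last unit operation.
#'
#' @param sim an `ipm_simulation`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
export_simulation_csv <- function(sim, path) {
  d <- dimnames(sim$pool_conc)
  n <- sim$n_cycles; K <- length(d[[2]]); C <- length(d[[3]])
  df <- data.frame(cycle = rep(seq_len(n), K * C),
                   uo = rep(rep(d[[2]], each = n), C),
                   cqa = rep(d[[3]], each = n * K),
                   conc = as.vector(sim$pool_conc))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export a simulation summary as JSON
#'
#' @param sim an `ipm_simulation`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
export_simulation_json <- function(sim, path) {
  doc <- list(n_cycles = sim$n_cycles, seed = sim$seed, gamma = sim$gamma,
              clamp_count = sim$clamp_count, ooa_percent = as.list(sim$ooa))
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' Export sensitivity curves as long-format CSV
#'
#' One row per parameter x evaluation point x CQA, carrying the native
#' grid value, its relative-screening-range coding and the OOA percent;
#' the dedicated set-point evaluations are flagged in `point_type`.
#'
#' @param curves list of `ipm_psa_curve` objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
export_psa_csv <- function(curves, path) {
  rows <- lapply(curves, function(cv) {
    cqas <- colnames(cv$ooa)
    g <- data.frame(
      parameter = cv$parameter$name,
      point_type = "grid",
      grid_value = rep(cv$grid, length(cqas)),
      coded_value = rep(relative_screening_range(cv$grid, cv$parameter),
                        length(cqas)),
      cqa = rep(cqas, each = length(cv$grid)),
      ooa_percent = as.vector(cv$ooa),
      n_per_point = cv$n_per_point, seed = cv$seed)
    s <- data.frame(
      parameter = cv$parameter$name,
      point_type = "set_point",
      grid_value = cv$parameter$set_point,
      coded_value = 0,
      cqa = cqas,
      ooa_percent = as.numeric(cv$set_point_ooa[cqas]),
      n_per_point = cv$n_per_point, seed = cv$seed)
    rbind(g, s)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read sensitivity curves back from CSV
#'
#' @param path CSV written by [export_psa_csv()].
#' @param chain the chain supplying parameter metadata.
#' @return Named list of `ipm_psa_curve` objects.
#' @export
read_psa_csv <- function(path, chain) {
  if (!file.exists(path)) stop_config(sprintf("PSA file '%s' not found", path))
  df <- utils::read.csv(path)
  lapply(split(df, df$parameter)[unique(df$parameter)], function(d) {
    p <- chain$parameters[[d$parameter[1]]]
    if (is.null(p))
      stop_config(sprintf("parameter '%s' in PSA file absent from chain",
                          d$parameter[1]))
    g <- d[d$point_type == "grid", ]
    s <- d[d$point_type == "set_point", ]
    cqas <- unique(g$cqa)
    grid <- sort(unique(g$grid_value))
    ooa <- sapply(cqas, function(q) {
      gq <- g[g$cqa == q, ]
      gq$ooa_percent[order(gq$grid_value)]
    })
    psa_curve(p, grid, ooa, stats::setNames(s$ooa_percent, s$cqa),
              n_per_point = d$n_per_point[1], seed = d$seed[1])
  })
}

#' Export FMEA severity assessments as CSV
#'
#' @param assessments list of `ipm_severity` objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
export_severity_csv <- function(assessments, path) {
  rows <- lapply(assessments, function(a) {
    df <- a$by_cqa
    df$final_ranking <- a$final_ranking
    df$is_cpp <- a$is_cpp
    df
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Export proven-acceptable-range results as CSV
#'
#' One row per parameter mirroring a control-strategy summary table:
#' unit operation, parameter, classification, final range and the CQAs
#' whose crossings bind it.
#'
#' @param results list of `ipm_par` objects.
#' @param chain chain supplying the unit operation of each parameter.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
export_par_csv <- function(results, chain, path) {
  rows <- lapply(results, function(r) {
    data.frame(uo = chain$parameters[[r$parameter]]$uo,
               parameter = r$parameter,
               classification = r$classification,
               par_low = r$par_low, par_high = r$par_high,
               critical_ooa = r$critical_ooa,
               impacted_cqas = paste(r$impacted_cqas, collapse = ";"))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

write_datasets_csv <- function(doe_data, load_data, mfg, dir) {
  for (u in names(doe_data))
    utils::write.csv(doe_data[[u]], file.path(dir, sprintf("doe_%s.csv", u)),
                     row.names = FALSE)
  for (k in names(load_data))
    utils::write.csv(load_data[[k]], file.path(dir, sprintf("load_%s.csv", k)),
                     row.names = FALSE)
  if (!is.null(mfg))
    utils::write.csv(mfg, file.path(dir, "manufacturing_runs.csv"),
                     row.names = FALSE)
  invisible(dir)
}

read_datasets_csv <- function(dir) {
  doe_files <- list.files(dir, "^doe_.*\\.csv$", full.names = TRUE)
  load_files <- list.files(dir, "^load_.*\\.csv$", full.names = TRUE)
  doe <- stats::setNames(lapply(doe_files, utils::read.csv),
                         sub("^doe_(.*)\\.csv$", "\\1", basename(doe_files)))
  ld <- stats::setNames(lapply(load_files, utils::read.csv),
                        sub("^load_(.*)\\.csv$", "\\1", basename(load_files)))
  mfg_path <- file.path(dir, "manufacturing_runs.csv")
  mfg <- if (file.exists(mfg_path)) utils::read.csv(mfg_path) else NULL
  list(doe = doe, load = ld, mfg = mfg)
}
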