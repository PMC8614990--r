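# fixtures built in code: tiny chains exercising each model-cell type

# chain of fixed deterministic clearances for a single CQA
fixed_chain <- function(clearances, start_mean = 100, start_sd = 0,
                        usl = 1e6) {
  uos <- lapply(seq_along(clearances), function(k)
    unit_operation(sprintf("UO%d", k), order = k,
                   models = list(imp = fixed_clearance(clearances[k], 0))))
  process_chain(uos,
                parameters = list(process_parameter("p1", "UO1", 5, 4.9, 5.1,
                                                    4.5, 5.5)),
                cqas = list(quality_attribute("imp", "impurity", usl = usl,
                                              start_mean = start_mean,
                                              start_sd = start_sd)))
}

# pure pass-through chain: DS distribution equals the start distribution
pass_chain <- function(K = 3, start_mean = 50, start_sd = 2,
                       lsl = NA, usl = NA) {
  if (is.na(lsl) && is.na(usl)) {
    lsl <- start_mean - 2 * start_sd
    usl <- start_mean + 2 * start_sd
  }
  uos <- lapply(seq_len(K), function(k)
    unit_operation(sprintf("UO%d", k), order = k))
  process_chain(uos,
                parameters = list(process_parameter("p1", "UO1", 5, 4.9, 5.1,
                                                    4.5, 5.5)),
                cqas = list(quality_attribute("imp", "impurity", lsl = lsl,
                                              usl = usl,
                                              start_mean = start_mean,
                                              start_sd = start_sd)))
}

# one-parameter, one-UO chain whose DoE model rises linearly in the
# parameter toward an upper-limited impurity
mono_chain <- function(beta = 0.1, beta0 = 0.2, rmse = 0.01,
                       sp = 5, nor_half = 0.25, sr_half = 1,
                       start_mean = 100, start_sd = 3, usl = 75) {
  p <- process_parameter("x", "UO1", sp, sp - nor_half, sp + nor_half,
                         sp - sr_half, sp + sr_half)
  m <- doe_model("UO1", "imp", terms = "x", beta = beta, beta0 = beta0,
                 rmse = rmse)
  process_chain(list(unit_operation("UO1", 1, models = list(imp = m))),
                parameters = list(p),
                cqas = list(quality_attribute("imp", "impurity", usl = usl,
                                              start_mean = start_mean,
                                              start_sd = start_sd)))
}

# build a sensitivity curve from an analytic OOA function of the native
# grid value (used to test slope and crossing logic exactly)
fn_curve <- function(p, f, grid_size = 10, cqa = "imp") {
  grid <- seq(p$sr_low, p$sr_high, length.out = grid_size)
  ooa <- matrix(vapply(grid, f, numeric(1)), ncol = 1,
                dimnames = list(NULL, cqa))
  psa_curve(p, grid, ooa,
            stats::setNames(f(p$set_point), cqa))
}

centered_param <- function(sp = 5, sr_half = 2, nor_half = 0.5,
                           name = "x", uo = "UO1") {
  process_parameter(name, uo, sp, sp - nor_half, sp + nor_half,
                    sp - sr_half, sp + sr_half)
}
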