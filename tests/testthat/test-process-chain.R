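test_that("constructors enforce the declared invariants", {
  expect_error(process_parameter("p", "U", 5, 4.9, 5.1, 5.05, 5.5),
               "sr_low <= nor_low")
  expect_error(process_parameter("p", "U", 5, 5, 5, 5, 5), "zero width")
  expect_error(quality_attribute("q", "impurity", start_mean = 1,
                                 start_sd = 0),
               "acceptance limit")
  expect_error(quality_attribute("q", "impurity", lsl = 2, usl = 1,
                                 start_mean = 1, start_sd = 0),
               "lsl must be <")
  expect_error(quality_attribute("q", "impurity", usl = 1, start_mean = -1,
                                 start_sd = 0), "start_mean")
  expect_error(doe_model("U", "q", "x", beta = 0.1, beta0 = 0, rmse = -1),
               "rmse")
  expect_error(load_model("U", "q", 0.1, 0, rmse = 0.1, mean_slc_doe = 0),
               "mean_slc_doe")
})

test_that("process_chain validates order contiguity and term resolution", {
  p <- process_parameter("x", "UO1", 5, 4.5, 5.5, 4, 6)
  q <- quality_attribute("imp", "impurity", usl = 10, start_mean = 5,
                         start_sd = 1)
  m <- doe_model("UO1", "imp", "x", beta = 0.1, beta0 = 0.3, rmse = 0.01)
  uo1 <- unit_operation("UO1", 1, models = list(imp = m))
  expect_s3_class(process_chain(list(uo1), list(p), list(q)), "ipm_chain")
  # non-contiguous orders
  expect_error(process_chain(list(unit_operation("UO1", 2)), list(p),
                             list(q)), "contiguous")
  # term referencing an undeclared parameter
  m2 <- doe_model("UO1", "imp", "ghost", beta = 0.1, beta0 = 0.3,
                  rmse = 0.01)
  expect_error(
    process_chain(list(unit_operation("UO1", 1, models = list(imp = m2))),
                  list(p), list(q)),
    "ghost")
  # term parameter belonging to another unit operation
  p2 <- process_parameter("y", "UO2", 1, 0.9, 1.1, 0.5, 1.5)
  m3 <- doe_model("UO1", "imp", "y", beta = 0.1, beta0 = 0.3, rmse = 0.01)
  expect_error(
    process_chain(list(unit_operation("UO1", 1, models = list(imp = m3))),
                  list(p, p2), list(q)),
    "another unit operation")
  # model CQA must resolve
  expect_error(
    process_chain(list(unit_operation("UO1", 1,
                                      models = list(other = m))),
                  list(p), list(q)),
    "not a declared quality attribute")
})

test_that("predict_clearance covers every model-cell type", {
  doe <- doe_model("UO1", "imp", "x", beta = 0.1, beta0 = 0.5, rmse = 0.01)
  ld <- load_model("UO1", "imp", beta_slc = 0.05, beta0 = 0.4, rmse = 0.01,
                   mean_slc_doe = 4)
  uo_both <- unit_operation("UO1", 1, models = list(imp = list(doe, ld)))
  # hand evaluation: SC_PP = 0.5 + 0.1*2 = 0.7; load at slc 8 = 0.8;
  # load at DoE-mean slc 4 = 0.6; combined = 0.7 * 0.8 / 0.6
  expect_equal(predict_clearance(uo_both, "imp", c(x = 2), slc = 8),
               0.7 * 0.8 / 0.6)
  # identity case: slc at the DoE mean reduces the combination to the DoE
  # prediction, to machine precision
  expect_equal(predict_clearance(uo_both, "imp", c(x = 2), slc = 4), 0.7,
               tolerance = 1e-15)
  # intercept-only DoE model
  doe0 <- doe_model("UO1", "imp", "x", beta = 0, beta0 = 0.8, rmse = 0)
  uo_doe <- unit_operation("UO1", 1, models = list(imp = doe0))
  expect_equal(predict_clearance(uo_doe, "imp", c(x = 123)), 0.8)
  # load-only, fixed and pass-through cells
  uo_load <- unit_operation("UO1", 1, models = list(imp = ld))
  expect_equal(predict_clearance(uo_load, "imp", slc = 2), 0.5)
  uo_fix <- unit_operation("UO1", 1,
                           models = list(imp = fixed_clearance(0.33)))
  expect_equal(predict_clearance(uo_fix, "imp"), 0.33)
  expect_equal(predict_clearance(unit_operation("UO1", 1), "imp"), 1)
  # errors: missing term setting, non-positive slc
  expect_error(predict_clearance(uo_doe, "imp", c(z = 1)),
               "missing parameter setting")
  expect_error(predict_clearance(uo_both, "imp", c(x = 2), slc = 0),
               "slc must be > 0")
  expect_error(predict_clearance(uo_both, "imp", c(x = 2)), "slc is required")
})

test_that("interaction terms multiply parameter columns", {
  m <- doe_model("UO1", "imp",
                 terms = list(x = "x", y = "y", `x:y` = c("x", "y")),
                 beta = c(0.1, 0.2, 0.05), beta0 = 0.1, rmse = 0)
  uo <- unit_operation("UO1", 1, models = list(imp = m))
  expect_equal(predict_clearance(uo, "imp", c(x = 2, y = 3)),
               0.1 + 0.1 * 2 + 0.2 * 3 + 0.05 * 6)
})

test_that("propagate multiplies clearances down the chain", {
  ch1 <- fixed_chain(0.5, start_mean = 10)
  expect_equal(unname(propagate(ch1, c(p1 = 5), c(imp = 10))$ds), 5)
  ch3 <- fixed_chain(c(0.5, 0.4, 0.9), start_mean = 100)
  res <- propagate(ch3, c(p1 = 5), c(imp = 100))
  expect_equal(unname(res$ds), 100 * 0.5 * 0.4 * 0.9)  # = 18
  expect_equal(unname(res$pool[, "imp"]), c(50, 20, 18))
  expect_equal(res$clamp_count, 0L)
  # identity chain returns the start concentration
  chp <- pass_chain(4)
  expect_equal(unname(propagate(chp, c(p1 = 5), c(imp = 7))$ds), 7)
  expect_error(propagate(ch1, c(p1 = 5), c(imp = -1)), "positive")
})

test_that("negative clearance draws are clamped to zero and flagged", {
  ch <- fixed_chain(c(0.5, 0.5), start_mean = 10)
  nd <- matrix(0, 2, 1, dimnames = list(c("UO1", "UO2"), "imp"))
  nd["UO1", "imp"] <- -0.8  # clearance 0.5 - 0.8 < 0
  expect_warning(res <- propagate(ch, c(p1 = 5), c(imp = 10), nd),
                 "clamped")
  expect_equal(unname(res$ds), 0)
  expect_equal(res$clamp_count, 1L)
})

test_that("parameter storage order never changes predictions", {
  m <- doe_model("UO1", "imp", c("a", "b"), beta = c(0.2, -0.1),
                 beta0 = 0.5, rmse = 0)
  uo <- unit_operation("UO1", 1, models = list(imp = m))
  s1 <- c(a = 1.5, b = 2.5)
  expect_identical(predict_clearance(uo, "imp", s1),
                   predict_clearance(uo, "imp", rev(s1)))
  pa <- process_parameter("a", "UO1", 1.5, 1, 2, 0.5, 2.5)
  pb <- process_parameter("b", "UO1", 2.5, 2, 3, 1.5, 3.5)
  q <- quality_attribute("imp", "impurity", usl = 100, start_mean = 10,
                         start_sd = 0)
  ch_ab <- process_chain(list(uo), list(pa, pb), list(q))
  ch_ba <- process_chain(list(uo), list(pb, pa), list(q))
  expect_equal(propagate(ch_ab, s1, c(imp = 10))$ds,
               propagate(ch_ba, s1, c(imp = 10))$ds)
})
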