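# a curve with prescribed set-point and edge OOA values on a centred
# parameter (set point 5, screening half-range 2)
slope_curve <- function(ooa_sp, ooa_low, ooa_high, cqa = "imp") {
  p <- centered_param(sp = 5, sr_half = 2)
  fn_curve(p, function(x) {
    if (x <= 5) ooa_sp + (ooa_low - ooa_sp) * (5 - x) / 2
    else ooa_sp + (ooa_high - ooa_sp) * (x - 5) / 2
  }, grid_size = 9, cqa = cqa)  # odd count: set point is a grid node
}

test_that("critical_slope implements the hand-derived examples", {
  # OOA_SP = 1%, SP = 5, SR_high = 7: (5 - 1) / 2 = 2 %OOA per unit
  cv <- slope_curve(1, 1, 9)
  expect_equal(critical_slope(cv, "imp", "high"), 2)
  expect_equal(critical_slope(cv, "imp", "low"), -2)
  # numerator vanishes when the set point sits at the critical level
  cv5 <- slope_curve(5, 5, 5)
  expect_equal(critical_slope(cv5, "imp", "high"), 0)
  expect_equal(critical_slope(cv5, "imp", "low"), 0)
  # set point on the screening edge: that side is inapplicable
  pe <- process_parameter("x", "UO1", 3, 3, 3.1, 3, 7)
  cve <- fn_curve(pe, function(x) 1 + x / 10)
  expect_true(is.na(critical_slope(cve, "imp", "low")))
  expect_false(is.na(critical_slope(cve, "imp", "high")))
})

test_that("cqa_slope measures the simulated OOA change per unit", {
  # OOA_SP = 1%, OOA at SR_high = 9%, half-range 2: slope 4
  cv <- slope_curve(1, 1, 9)
  expect_equal(cqa_slope(cv, "imp", "high"), 4)
  expect_equal(cqa_slope(cv, "imp", "low"), 0)
  # flat curve: zero on both sides
  flat <- slope_curve(2, 2, 2)
  expect_equal(cqa_slope(flat, "imp", "high"), 0)
  expect_equal(cqa_slope(flat, "imp", "low"), 0)
  # OOA decreasing towards the edge: negative (beneficial) slope
  down <- slope_curve(3, 3, 1)
  expect_lt(cqa_slope(down, "imp", "high"), 0)
})

test_that("assign_ranking reproduces the rubric bands and boundaries", {
  r <- function(ratio) {
    # construct slopes with the requested high-side ratio
    assign_ranking(m_cqa_low = 0, m_cqa_high = ratio * 2,
                   m_crit_low = -2, m_crit_high = 2)$ranking
  }
  expect_equal(r(0.9), 10)
  expect_equal(r(0.6), 7)
  expect_equal(r(0.4), 3)
  expect_equal(r(0.1), 1)
  # boundary values: lower band bounds inclusive
  expect_equal(r(0.8), 10)
  expect_equal(r(0.5), 7)
  expect_equal(r(0.3), 3)
  # CQA slope equal to the critical slope: ratio 1, highest rank
  expect_equal(r(1), 10)
})

test_that("worst-case side selection and by-design rule", {
  a <- assign_ranking(m_cqa_low = -1.2, m_cqa_high = 0.4,
                      m_crit_low = -2, m_crit_high = 2)
  expect_equal(a$worst_side, "low")
  expect_equal(a$pct_ref, 0.6)
  expect_equal(a$ranking, 7)
  # beneficial directions floor at zero
  b <- assign_ranking(m_cqa_low = 1, m_cqa_high = -1,
                      m_crit_low = -2, m_crit_high = 2)
  expect_equal(b$pct_ref, 0)
  expect_equal(b$ranking, 1)
  # set-point OOA at/above the critical level: critical slope direction
  # flips and the rank is 10 by design
  cv <- slope_curve(7, 7, 9)
  sv <- assess_parameter(cv)
  expect_equal(sv$final_ranking, 10)
  expect_true(sv$is_cpp)
  # both sides inapplicable is an error
  expect_error(assign_ranking(NA, NA, NA, NA), "inapplicable")
})

test_that("rankings are invariant under affine reparameterization of units", {
  cv <- slope_curve(1, 2, 8)
  sv <- assess_parameter(cv)
  # rescale the parameter axis by 40 and shift: slopes change, ratios do not
  p2 <- process_parameter("x", "UO1", 5 * 40 + 3, 4.5 * 40 + 3, 5.5 * 40 + 3,
                          3 * 40 + 3, 7 * 40 + 3)
  cv2 <- psa_curve(p2, cv$grid * 40 + 3, cv$ooa, cv$set_point_ooa)
  sv2 <- assess_parameter(cv2)
  expect_equal(sv2$by_cqa$pct_ref, sv$by_cqa$pct_ref, tolerance = 1e-12)
  expect_equal(sv2$by_cqa$ranking, sv$by_cqa$ranking)
})

test_that("rubric bands partition the non-negative ratios", {
  bands <- ranking_bands()
  set.seed(31)
  for (ratio in c(0, stats::runif(200, 0, 2), 5, 100)) {
    hits <- sum(vapply(seq_along(bands$ranks), function(i) {
      lo <- if (i <= length(bands$thresholds)) bands$thresholds[i] else 0
      hi <- if (i == 1L) Inf else bands$thresholds[i - 1L]
      ratio >= lo && ratio < hi
    }, logical(1)))
    expect_equal(hits, 1L)
  }
  # monotone non-decreasing rank in the ratio
  rk <- vapply(seq(0, 1.5, by = 0.01), function(x)
    assign_ranking(0, x * 2, -2, 2)$ranking, numeric(1))
  expect_true(all(diff(rk) >= 0))
})

test_that("assess_parameter takes the worst-case CQA ranking as final", {
  p <- centered_param(sp = 5, sr_half = 2)
  mk <- function(edge) {
    grid <- seq(3, 7, length.out = 5)
    vapply(grid, function(x) 1 + (edge - 1) * abs(x - 5) / 2, numeric(1))
  }
  # per-CQA edge OOA values chosen to land in each rubric band: with
  # critical slope (5-1)/2 = 2 the ratio is (edge-1)/4
  ooa <- cbind(q1 = mk(1.5), q2 = mk(2.6), q3 = mk(9.5), q4 = mk(4))
  cv <- psa_curve(p, seq(3, 7, length.out = 5), ooa,
                  c(q1 = 1, q2 = 1, q3 = 1, q4 = 1))
  sv <- assess_parameter(cv)
  expect_equal(stats::setNames(sv$by_cqa$ranking, sv$by_cqa$cqa),
               c(q1 = 1, q2 = 3, q3 = 10, q4 = 7))
  expect_equal(sv$final_ranking, 10)
  expect_true(sv$is_cpp)
  # single CQA: final equals that CQA's ranking
  sv1 <- assess_parameter(slope_curve(1, 1, 3))
  expect_equal(sv1$final_ranking, sv1$by_cqa$ranking[1])
})

test_that("custom ranking scales are honoured and validated", {
  bands <- ranking_bands(thresholds = c(1, 0.5), ranks = c(9, 5, 1))
  expect_equal(assign_ranking(0, 1.2 * 2, -2, 2, bands = bands)$ranking, 9)
  expect_equal(assign_ranking(0, 0.7 * 2, -2, 2, bands = bands)$ranking, 5)
  expect_error(ranking_bands(c(0.5, 0.8), c(10, 7, 1)), "decreasing")
  expect_error(ranking_bands(c(0.8, 0.5), c(10, 7)), "residual band")
})
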