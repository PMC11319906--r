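test_that("index formulas reproduce hand-computed values", {
  expect_equal(bmi(100, 2.0), 25.0)
  expect_equal(round(bmi(74.04, 1.698), 2), 25.68)
  expect_equal(waist_height_ratio(85, 1.70), 0.5)
  expect_equal(round(waist_height_ratio(89.69, 1.698), 4), 0.5282)
  expect_equal(conicity_index(109, 100, 1.0), 1.0)
  expect_equal(round(conicity_index(89.69, 74.04, 1.698), 4), 1.2461)
  expect_equal(round(conicity_index(96, 79, 1.698), 4), 1.2912)
  expect_equal(body_adiposity_index(100, 1.0), 82.0)
  expect_equal(round(body_adiposity_index(102.98, 1.698), 2), 28.54)
  expect_equal(round(body_adiposity_index(102.98, 1.698, hip_unit = "m"), 2),
               -17.53)
  expect_equal(abdominal_volume_index(100, 100), 20.0)
  expect_equal(round(abdominal_volume_index(89.69, 102.98), 3), 16.212)
  expect_equal(round(abdominal_volume_index(105.18, 108.22), 3), 22.132)
  expect_equal(round(body_roundness_index(89.69, 1.698), 3), 3.903)
  expect_equal(round(body_roundness_index(89.69, 1.698, constant = 365.2), 3),
               4.903)
  expect_equal(weight_adjusted_waist_index(100, 100), 10.0)
  expect_equal(round(weight_adjusted_waist_index(96, 79), 4), 10.8008)
  expect_equal(round(weight_adjusted_waist_index(105.18, 84.40), 3), 11.449)
  expect_equal(lipid_accumulation_product(65, 1.9, "male")[1], 0.0)
  expect_equal(lipid_accumulation_product(58, 2.2, "female")[1], 0.0)
  expect_equal(lipid_accumulation_product(96, 1.9, "male")[1], 58.9)
  expect_equal(cardiometabolic_index(1.3, 1.3, 85, 1.70), 0.5)
  expect_equal(round(cardiometabolic_index(1.8, 1.2, 90, 1.70), 4), 0.7941)
  expect_equal(atherogenic_index(1.4, 1.4), 0.0)
  expect_equal(round(atherogenic_index(2.0, 1.0), 5), 0.30103)
})

test_that("non-positive inputs raise domain errors", {
  expect_error(bmi(0, 1.7), "positive")
  expect_error(waist_height_ratio(90, 0), "positive")
  expect_error(conicity_index(-1, 70, 1.7), "positive")
  expect_error(cardiometabolic_index(1.8, 0, 90, 1.70), "positive")
  expect_error(atherogenic_index(-2, 1), "positive")
  expect_error(lipid_accumulation_product(96, 1.9, "unknown"), "sex")
})

test_that("BRI limit and eccentricity domain behave as derived", {
  # waist -> 0 limit tends to C - 365.5 = -1.3 under the standard constant
  expect_equal(body_roundness_index(1e-8, 1.7), 364.2 - 365.5,
               tolerance = 1e-6)
  # waist circumference implying a semi-axis beyond half the height errors
  expect_error(body_roundness_index(600, 1.7), "height")
})

test_that("every index matches the independent arithmetic transcription on
          1000 random valid inputs", {
  d <- random_inputs(1000, seed = 7)
  rel <- function(a, b) max(abs(a - b) / pmax(abs(b), 1e-300))
  expect_lt(rel(bmi(d$weight, d$height), oracle$bmi(d$weight, d$height)), 1e-12)
  expect_lt(rel(waist_height_ratio(d$waist, d$height),
                oracle$whtr(d$waist, d$height)), 1e-12)
  expect_lt(rel(conicity_index(d$waist, d$weight, d$height),
                oracle$ci(d$waist, d$weight, d$height)), 1e-12)
  expect_lt(rel(body_adiposity_index(d$hip, d$height),
                oracle$bai_cm(d$hip, d$height)), 1e-12)
  expect_lt(rel(body_adiposity_index(d$hip, d$height, hip_unit = "m"),
                oracle$bai_m(d$hip, d$height)), 1e-12)
  expect_lt(rel(abdominal_volume_index(d$waist, d$hip),
                oracle$avi(d$waist, d$hip)), 1e-12)
  expect_lt(rel(body_roundness_index(d$waist, d$height),
                oracle$bri(d$waist, d$height)), 1e-12)
  expect_lt(rel(weight_adjusted_waist_index(d$waist, d$weight),
                oracle$wwi(d$waist, d$weight)), 1e-12)
  expect_lt(rel(as.numeric(lipid_accumulation_product(d$waist, d$tg, d$sex)),
                oracle$lap(d$waist, d$tg, d$sex)), 1e-12)
  expect_lt(rel(cardiometabolic_index(d$tg, d$hdl, d$waist, d$height),
                oracle$cmi(d$tg, d$hdl, d$waist, d$height)), 1e-12)
  expect_lt(rel(atherogenic_index(d$tg, d$hdl),
                oracle$aip(d$tg, d$hdl)), 1e-12)
})

test_that("algebraic index properties hold on random inputs", {
  d <- random_inputs(1000, seed = 11)
  # CI equals WWI * sqrt(height) / 10.9 (both formulas collapse to it)
  ci <- conicity_index(d$waist, d$weight, d$height)
  wwi <- weight_adjusted_waist_index(d$waist, d$weight)
  expect_equal(ci, wwi * sqrt(d$height) / 10.9, tolerance = 1e-12)
  # AVI is homogeneous of degree 2 in (waist, hip)
  expect_equal(abdominal_volume_index(2 * d$waist, 2 * d$hip),
               4 * abdominal_volume_index(d$waist, d$hip), tolerance = 1e-12)
  # AIP antisymmetry and scale invariance
  expect_equal(atherogenic_index(d$tg, d$hdl),
               -atherogenic_index(d$hdl, d$tg), tolerance = 1e-12)
  expect_equal(atherogenic_index(3.7 * d$tg, 3.7 * d$hdl),
               atherogenic_index(d$tg, d$hdl), tolerance = 1e-12)
  # BRI strictly increasing in waist at fixed height
  w <- seq(55, 120, by = 0.5)
  expect_true(all(diff(body_roundness_index(w, 1.7)) > 0))
})

test_that("compute_indices composes the scalar operations over a cohort", {
  rec <- data.frame(weight = 74.04, height = 1.698, waist = 89.69,
                    hip = 102.98, sex = "male", tg = 1.9, hdl = 1.1)
  p <- compute_indices(rec)
  expect_equal(round(p$bmi, 2), 25.68)
  expect_equal(round(p$ci, 4), 1.2461)
  expect_equal(round(p$avi, 3), 16.212)
  expect_equal(round(p$bri, 3), 3.903)

  two <- rbind(rec, data.frame(weight = 79, height = 1.698, waist = 96,
                               hip = 106, sex = "female", tg = 1.4, hdl = 1.3))
  both <- compute_indices(two)
  for (ix in c("bmi", "whtr", "ci", "bai", "avi", "bri", "wwi", "lap",
               "cmi", "aip")) {
    expect_equal(both[[ix]][1], compute_indices(two[1, ])[[ix]])
    expect_equal(both[[ix]][2], compute_indices(two[2, ])[[ix]])
  }
})

test_that("missing lipids mark the lipid indices NA and keep body indices", {
  rec <- data.frame(weight = 74, height = 1.7, waist = 90, hip = 103,
                    sex = "male", tg = NA_real_, hdl = 1.1)
  p <- compute_indices(rec)
  expect_true(is.na(p$lap) && is.na(p$aip))
  expect_false(is.na(p$bmi) || is.na(p$avi))
  # cohort without lipid columns at all
  p2 <- compute_indices(rec[setdiff(names(rec), c("tg", "hdl"))])
  expect_true(all(is.na(c(p2$lap, p2$cmi, p2$aip))))
})

test_that("a record invalid for one index does not abort the cohort", {
  d <- data.frame(weight = c(74, 74), height = c(1.7, 1.7),
                  waist = c(90, -5), hip = c(103, 103),
                  sex = c("male", "male"), tg = c(1.9, 1.9),
                  hdl = c(1.1, 1.1))
  p <- compute_indices(d)
  expect_false(is.na(p$avi[1]))
  expect_true(is.na(p$avi[2]))
  expect_false(is.na(p$bmi[2]))  # weight/height still valid
})

test_that("negative LAP is kept and flagged by default, NA when disallowed", {
  v <- lipid_accumulation_product(60, 1.5, "male")
  expect_equal(v[1], -7.5)
  expect_true(attr(v, "negative"))
  v2 <- lipid_accumulation_product(60, 1.5, "male", allow_negative = FALSE)
  expect_true(is.na(v2[1]))
})

test_that("formula options are validated and recorded in the panel", {
  expect_error(formula_options(bri_constant = 400), "364.2")
  p <- compute_indices(make_cohort_df(3),
                       options = formula_options(bai_hip_unit = "m"))
  expect_equal(attr(p, "formula_options")$bai_hip_unit, "m")
  expect_true(all(p$bai < -17 & p$bai > -18))
})
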