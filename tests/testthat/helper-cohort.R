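# small in-code fixtures shared across test files

make_cohort_df <- function(n = 3) {
  data.frame(
    id = paste0("P", seq_len(n)),
    age = rep_len(c(25, 40, 55, 30, 62), n),
    sex = rep_len(c("male", "female"), n),
    weight = rep_len(c(74.04, 79.48, 84.40), n),
    height = rep_len(c(1.698, 1.70, 1.65), n),
    waist = rep_len(c(89.69, 97.18, 105.18), n),
    hip = rep_len(c(102.98, 106.26, 108.22), n),
    tg = rep_len(c(1.9, 1.4, 2.2), n),
    hdl = rep_len(c(1.1, 1.3, 0.9), n),
    energy = rep_len(c(2500, 3100, 3600), n),
    b1 = rep_len(c(1.8, 2.1, 2.4), n),
    b2 = rep_len(c(1.5, 1.8, 2.0), n),
    b3 = rep_len(c(28, 33, 38), n),
    b6 = rep_len(c(1.6, 2.0, 2.3), n),
    stringsAsFactors = FALSE
  )
}

write_cohort_csv <- function(d, path = tempfile(fileext = ".csv")) {
  utils::write.csv(d, path, row.names = FALSE)
  path
}

# independent plain-arithmetic transcriptions of the published index
# formulas, deliberately written without reference to the package functions
oracle <- list(
  bmi = function(w, h) w / h^2,
  whtr = function(wc, h) (wc / 100) / h,
  ci = function(wc, w, h) (wc / 100) / (0.109 * sqrt(w / h)),
  bai_cm = function(hc, h) hc / h^1.5 - 18,
  bai_m = function(hc, h) (hc / 100) / h^1.5 - 18,
  avi = function(wc, hc) (2 * wc * wc + 0.7 * (wc - hc) * (wc - hc)) / 1000,
  bri = function(wc, h, C = 364.2)
    C - 365.5 * sqrt(1 - ((wc / 100) / (2 * pi))^2 / (0.5 * h)^2),
  wwi = function(wc, w) wc / sqrt(w),
  lap = function(wc, tg, sex) (wc - ifelse(sex == "male", 65, 58)) * tg,
  cmi = function(tg, hdl, wc, h) (tg / hdl) * ((wc / 100) / h),
  aip = function(tg, hdl) log10(tg / hdl)
)

# random valid inputs on realistic adult ranges
random_inputs <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(
    weight = runif(n, 45, 130),
    height = runif(n, 1.45, 1.95),
    waist = runif(n, 60, 130),
    hip = runif(n, 80, 140),
    tg = runif(n, 0.4, 5),
    hdl = runif(n, 0.5, 2.5),
    sex = sample(c("male", "female"), n, replace = TRUE)
  )
}
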