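test_that("tertile summary reproduces the hand ANOVA and SEM oracles", {
  d <- data.frame(y = c(1, 2, 3, 4, 5, 6),
                  g = factor(rep(c("T1", "T2", "T3"), each = 2)))
  ts <- tertile_summary(d, "y", tertile = d$g)
  expect_equal(ts$mean, c(1.5, 3.5, 5.5))
  expect_equal(ts$n, c(2L, 2L, 2L))
  # SSB = 16, SSW = 1.5 -> F = (16/2) / (1.5/3) = 16 on (2, 3) df
  expect_equal(attr(ts, "F"), 16.0, tolerance = 1e-12)
  expect_equal(attr(ts, "df"), c(2, 3))
  expect_equal(attr(ts, "p"), stats::pf(16, 2, 3, lower.tail = FALSE),
               tolerance = 1e-12)
  # SEM of 1..4 is sd/sqrt(4)
  d2 <- data.frame(y = c(1:4, 8:11, 2:5),
                   g = factor(rep(c("T1", "T2", "T3"), each = 4)))
  ts2 <- tertile_summary(d2, "y", tertile = d2$g)
  expect_equal(round(ts2$sem[1], 4), 0.6455)
})

test_that("identical groups give F = 0 and p = 1; tiny groups warn", {
  d <- data.frame(y = rep(c(2, 4), 3),
                  g = factor(rep(c("T1", "T2", "T3"), each = 2)))
  ts <- tertile_summary(d, "y", tertile = d$g)
  expect_equal(attr(ts, "F"), 0, tolerance = 1e-12)
  expect_equal(attr(ts, "p"), 1, tolerance = 1e-12)
  d3 <- data.frame(y = c(1, 2, 3, 4, 5),
                   g = factor(c("T1", "T1", "T2", "T2", "T3")))
  expect_warning(ts3 <- tertile_summary(d3, "y", tertile = d3$g), "n < 2")
  expect_true(is.na(attr(ts3, "p")))
})

test_that("two-group ANOVA F equals the squared pooled-variance t statistic", {
  set.seed(5)
  for (i in 1:20) {
    a <- rnorm(sample(5:30, 1))
    b <- rnorm(sample(5:30, 1), mean = runif(1, -1, 1))
    d <- data.frame(y = c(a, b),
                    g = factor(rep(c("T1", "T2"), c(length(a), length(b)))))
    ts <- tertile_summary(d, "y", tertile = d$g)
    tt <- stats::t.test(a, b, var.equal = TRUE)
    expect_equal(attr(ts, "F"), unname(tt$statistic)^2, tolerance = 1e-10)
  }
})

test_that("stratified Pearson matches hand covariance and edge oracles", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_by_stratum(x, 2 * x)$r, 1.0, tolerance = 1e-12)
  expect_equal(pearson_by_stratum(x, -x + 10)$r, -1.0, tolerance = 1e-12)
  expect_equal(pearson_by_stratum(x, c(1, 3, 2, 4))$r, 0.8, tolerance = 1e-12)
  # brute-force sum-of-products agreement on random vectors, per stratum
  set.seed(13)
  for (i in 1:25) {
    n <- sample(10:100, 1)
    xi <- rnorm(n); yi <- rnorm(n)
    s <- sample(c("male", "female"), n, replace = TRUE)
    res <- pearson_by_stratum(xi, yi, s)
    brute <- function(u, v) {
      du <- u - sum(u) / length(u); dv <- v - sum(v) / length(v)
      sum(du * dv) / sqrt(sum(du^2) * sum(dv^2))
    }
    expect_equal(res$r[res$stratum == "total"], brute(xi, yi),
                 tolerance = 1e-12)
    expect_equal(res$r[res$stratum == "male"],
                 brute(xi[s == "male"], yi[s == "male"]), tolerance = 1e-12)
    # p via the t transform on n - 2 df
    r <- res$r[res$stratum == "total"]
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    expect_equal(res$p[res$stratum == "total"],
                 2 * stats::pt(-abs(tstat), n - 2), tolerance = 1e-10)
  }
})

test_that("degenerate strata are flagged rather than fatal", {
  # both the zero-variance stratum and the n = 1 stratum warn
  expect_warning(expect_warning(
    res <- pearson_by_stratum(c(1, 1, 1, 2), c(1, 2, 3, 4),
                              c("a", "a", "a", "b")),
    "undefined"), "undefined")
  expect_true(anyNA(res$r))
})

test_that("variance explained equals squared Pearson r in bivariate mode", {
  x <- c(1, 2, 3, 4)
  rc <- r2_change(c(1, 3, 2, 4), x)
  expect_equal(rc$r, 0.8, tolerance = 1e-12)
  expect_equal(rc$percent, 64, tolerance = 1e-12)
  expect_equal(r2_change(x, x)$percent, 100, tolerance = 1e-12)
  y_orth <- c(1, -1, -1, 1)  # exactly uncorrelated with x
  expect_equal(r2_change(y_orth, x)$percent, 0, tolerance = 1e-12)
  set.seed(3)
  xi <- rnorm(100); yi <- 0.4 * xi + rnorm(100)
  expect_equal(r2_change(yi, xi)$percent, 100 * cor(xi, yi)^2,
               tolerance = 1e-12)
})

test_that("nested mode reports the age/sex-partialled R-squared increment", {
  set.seed(8)
  n <- 200
  age <- sample(18:64, n, TRUE)
  sex <- sample(c("male", "female"), n, TRUE)
  x <- rnorm(n)
  y <- 0.05 * age + 0.3 * (sex == "male") + 0.2 * x + rnorm(n)
  rc <- r2_change(y, x, age = age, sex = sex, mode = "nested_age_sex")
  base <- summary(lm(y ~ age + factor(sex)))$r.squared
  full <- summary(lm(y ~ age + factor(sex) + x))$r.squared
  expect_equal(rc$percent, 100 * (full - base), tolerance = 1e-10)
  expect_equal(rc$percent_bivariate, 100 * cor(x, y)^2, tolerance = 1e-10)
  expect_error(r2_change(y, x, mode = "nested_age_sex"), "requires")
  # nutrient identical to a confounder is flagged as collinear
  expect_error(r2_change(y, age, age = age, sex = sex,
                         mode = "nested_age_sex"), "collinear")
})

test_that("demographic table gives mean (SD) with ANOVA and n (%) with
          chi-squared", {
  d <- data.frame(
    g = factor(rep(c("A", "B"), each = 30)),
    weight = c(rnorm(30, 70, 5), rnorm(30, 80, 5)),
    smoke = c(rep(c("yes", "no"), c(10, 20)), rep(c("yes", "no"), c(20, 10)))
  )
  tab <- demographic_table(d, group = "g", continuous = "weight",
                           categorical = "smoke")
  # 2x2 table (10,20 / 20,10): uncorrected chi-squared = 6.6667 on 1 df
  p_chi <- tab$p[tab$variable == "smoke"][1]
  expect_equal(p_chi, stats::pchisq(20 / 3, df = 1, lower.tail = FALSE),
               tolerance = 1e-10)
  p_aov <- tab$p[tab$variable == "weight"]
  expect_equal(p_aov,
               stats::anova(stats::aov(weight ~ g, data = d))[["Pr(>F)"]][1],
               tolerance = 1e-12)
  expect_equal(attr(tab, "tests")[["smoke"]], "chi-squared")
})

test_that("single-group demographic tables carry descriptives only", {
  d <- data.frame(g = factor(rep("A", 10)), weight = rnorm(10, 70, 5),
                  smoke = rep(c("yes", "no"), 5))
  tab <- demographic_table(d, group = "g", continuous = "weight",
                           categorical = "smoke")
  expect_true(all(is.na(tab$p)))
})

test_that("three equal-mean groups give ANOVA p = 1 on identical data", {
  d <- data.frame(y = rep(c(1, 2, 3), 3),
                  g = factor(rep(c("A", "B", "C"), each = 3)))
  tab <- demographic_table(d, group = "g", continuous = "y",
                           categorical = character(0))
  expect_equal(tab$p[1], 1, tolerance = 1e-12)
})

test_that("finite-population sample size reproduces the published design", {
  expect_equal(sample_size(5621970), 385L)
  expect_equal(sample_size(5621970, inflation = 0.10), 424L)
  # infinite-population closed form z^2 p (1-p) / E^2 = 384.16 -> 385
  expect_equal(sample_size(Inf), 385L)
  expect_error(sample_size(5621970, margin = 0), "margin")
})

test_that("required n is monotone in margin, confidence and population", {
  margins <- c(0.02, 0.03, 0.05, 0.1)
  ns <- vapply(margins, function(m) sample_size(1e6, margin = m), integer(1))
  expect_true(all(diff(ns) <= 0))
  confs <- c(0.80, 0.90, 0.95, 0.99)
  ns <- vapply(confs, function(cl) sample_size(1e6, confidence = cl),
               integer(1))
  expect_true(all(diff(ns) >= 0))
  pops <- c(1e3, 1e4, 1e6, 1e8)
  ns <- vapply(pops, sample_size, integer(1))
  expect_true(all(diff(ns) >= 0))
})
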