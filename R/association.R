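#' Tertile-wise index summary with one-way ANOVA
#'
#' Mean and SEM of an index within each tertile of an (energy-adjusted)
#' nutrient, with a two-tailed p-value from classic equal-variance one-way
#' ANOVA across the tertiles. Means and SEMs are computed on unrounded
#' values; rounding is a presentation concern.
#'
#' @param cohort A cohort processed by [compute_indices()] and
#'   [energy_adjust_cohort()], or any data frame holding the two columns.
#' @param index Name of the index column, e.g. `"avi"`.
#' @param nutrient Nutrient whose tertile column (`<nutrient>_tertile`) to
#'   group by, e.g. `"b1"`; alternatively supply `tertile` directly.
#' @param tertile Optional factor of tertile labels overriding `nutrient`.
#' @return Data frame with one row per tertile (`tertile`, `n`, `mean`,
#'   `sem`) and attributes `"p"` (ANOVA p-value), `"F"`, `"df"`.
#' @export
tertile_summary <- function(cohort, index, nutrient = NULL, tertile = NULL) {
  d <- as.data.frame(cohort)
  if (is.null(tertile)) {
    col <- paste0(nutrient, "_tertile")
    if (!col %in% names(d)) {
      stop("no column `", col, "`; run energy_adjust_cohort() first",
           call. = FALSE)
    }
    tertile <- d[[col]]
  }
  y <- d[[index]]
  ok <- !is.na(y) & !is.na(tertile)
  y <- y[ok]
  g <- factor(tertile[ok])
  if (nlevels(droplevels(g)) < 2) {
    stop("need at least two non-empty tertiles", call. = FALSE)
  }
  out <- data.frame(
    tertile = levels(g),
    n = as.integer(table(g)),
    mean = as.numeric(tapply(y, g, mean)),
    sem = as.numeric(tapply(y, g, function(v) sd(v) / sqrt(length(v)))),
    row.names = NULL
  )
  small <- out$n < 2
  if (any(small)) {
    warning("tertile(s) with n < 2: p-value undefined", call. = FALSE)
    attr(out, "p") <- NA_real_
  } else {
    a <- stats::anova(stats::aov(y ~ g))
    attr(out, "F") <- a[["F value"]][1]
    attr(out, "df") <- a[["Df"]]
    attr(out, "p") <- a[["Pr(>F)"]][1]
  }
  attr(out, "index") <- index
  attr(out, "nutrient") <- nutrient
  out
}

#' Pearson correlation, total and by stratum
#'
#' Pearson r with a two-tailed p-value from the t transform on n - 2 degrees
#' of freedom, computed for the pooled sample and within each stratum
#' (typically sex).
#'
#' @param x,y Numeric vectors.
#' @param strata Optional labels (e.g. sex); one result row per level is
#'   added after the `"total"` row.
#' @return Data frame with columns `stratum`, `n`, `r`, `p`. Strata with
#'   fewer than 3 complete pairs or zero variance get `NA` with a warning.
#' @export
#' @examples
#' pearson_by_stratum(1:10, (1:10)^2)
pearson_by_stratum <- function(x, y, strata = NULL) {
  one <- function(xi, yi, label) {
    ok <- !is.na(xi) & !is.na(yi)
    xi <- xi[ok]; yi <- yi[ok]
    if (length(xi) < 3 || sd(xi) == 0 || sd(yi) == 0) {
      warning("stratum `", label,
              "`: correlation undefined (n < 3 or zero variance)",
              call. = FALSE)
      return(data.frame(stratum = label, n = length(xi),
                        r = NA_real_, p = NA_real_))
    }
    ct <- stats::cor.test(xi, yi, method = "pearson", alternative = "two.sided")
    data.frame(stratum = label, n = length(xi),
               r = unname(ct$estimate), p = ct$p.value)
  }
  out <- one(x, y, "total")
  if (!is.null(strata)) {
    for (lv in levels(factor(strata))) {
      sel <- !is.na(strata) & strata == lv
      out <- rbind(out, one(x[sel], y[sel], lv))
    }
  }
  rownames(out) <- NULL
  out
}

#' Variance in an index explained by a nutrient
#'
#' In `"bivariate"` mode (default) this is the squared Pearson correlation
#' between index and nutrient, expressed as a percent: the R-squared of the
#' simple linear regression. In `"nested_age_sex"` mode it is the increment
#' in R-squared when the nutrient is added to a base model of age + sex,
#' with the p-value from the partial F test for that increment. Both modes
#' are always computed; `mode` selects which fills the headline columns.
#'
#' @param index Numeric index values.
#' @param nutrient Numeric (energy-adjusted) nutrient values.
#' @param age,sex Confounders, required for the nested mode.
#' @param mode `"bivariate"` or `"nested_age_sex"`.
#' @return One-row data frame: `r` (absolute Pearson r of the bivariate
#'   model), `r2`, `percent` (= 100 * r2 of the selected mode), `p`, `mode`,
#'   plus both mode-specific percents (`percent_bivariate`,
#'   `percent_nested`).
#' @export
#' @examples
#' set.seed(1)
#' x <- rnorm(100); y <- 0.3 * x + rnorm(100)
#' r2_change(y, x)
r2_change <- function(index, nutrient, age = NULL, sex = NULL,
                      mode = c("bivariate", "nested_age_sex")) {
  mode <- match.arg(mode)
  ok <- !is.na(index) & !is.na(nutrient)
  if (!is.null(age)) ok <- ok & !is.na(age)
  if (!is.null(sex)) ok <- ok & !is.na(sex)
  yi <- index[ok]; xi <- nutrient[ok]
  r <- cor(xi, yi)
  r2_biv <- r^2
  ct <- stats::cor.test(xi, yi)
  p_biv <- ct$p.value

  r2_nested <- NA_real_
  p_nested <- NA_real_
  if (!is.null(age) && !is.null(sex)) {
    a <- age[ok]; s <- factor(sex[ok])
    base <- lm(yi ~ a + s)
    full <- lm(yi ~ a + s + xi)
    if (any(is.na(coef(full)))) {
      bad <- names(coef(full))[is.na(coef(full))]
      stop("collinear predictors: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    r2_nested <- summary(full)$r.squared - summary(base)$r.squared
    p_nested <- stats::anova(base, full)[["Pr(>F)"]][2]
  } else if (mode == "nested_age_sex") {
    stop("nested_age_sex mode requires `age` and `sex`", call. = FALSE)
  }
  r2_sel <- if (mode == "bivariate") r2_biv else r2_nested
  p_sel <- if (mode == "bivariate") p_biv else p_nested
  data.frame(
    r = abs(r), r2 = r2_sel, percent = 100 * r2_sel, p = p_sel, mode = mode,
    percent_bivariate = 100 * r2_biv, percent_nested = 100 * r2_nested,
    n = length(yi)
  )
}

#' Demographic characteristics table by group
#'
#' Continuous variables are summarised as mean (SD) per group with a one-way
#' ANOVA p-value; categorical variables as n (%) per group (percent within
#' group) with an uncorrected chi-squared p-value. When the chi-squared
#' expectation includes a zero cell, Fisher's exact test is used instead and
#' the row flagged.
#'
#' @param cohort A `cohort_table` or data frame.
#' @param group Name of the grouping column (default `"age_group"`, created
#'   from `age` via [assign_age_group()] if absent).
#' @param continuous,categorical Character vectors of column names to
#'   summarise; defaults cover the standard schema columns that are present.
#' @return Data frame with one row per variable level, columns per group and
#'   a `p` column, plus attribute `"tests"` naming the test used per variable.
#' @export
demographic_table <- function(cohort, group = "age_group",
                              continuous = NULL, categorical = NULL) {
  d <- as.data.frame(cohort)
  if (!group %in% names(d)) {
    if (group == "age_group" && "age" %in% names(d)) {
      d$age_group <- assign_age_group(d$age)
    } else {
      stop("grouping column `", group, "` not found", call. = FALSE)
    }
  }
  g <- factor(d[[group]])
  if (is.null(continuous)) {
    continuous <- intersect(c("weight", "waist", "hip", "bmi"), names(d))
  }
  if (is.null(categorical)) {
    categorical <- intersect(
      c("sex", "education", "marital", "activity", "smoking"), names(d))
  }
  single <- nlevels(droplevels(g)) < 2
  rows <- list()
  tests <- character()
  for (v in continuous) {
    y <- d[[v]]
    cells <- tapply(y, g, function(x)
      sprintf("%.2f ± %.2f", mean(x, na.rm = TRUE), sd(x, na.rm = TRUE)))
    p <- NA_real_
    if (!single) {
      p <- stats::anova(stats::aov(y ~ g))[["Pr(>F)"]][1]
      tests[v] <- "anova"
    }
    rows[[v]] <- data.frame(variable = v, level = "",
                            t(as.matrix(cells)), p = p, check.names = FALSE)
  }
  for (v in categorical) {
    tab <- table(d[[v]], g)
    pct <- prop.table(tab, margin = 2) * 100
    p <- NA_real_
    if (!single && nrow(tab) > 1) {
      expct <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      if (any(expct == 0)) {
        p <- stats::fisher.test(tab, simulate.p.value = TRUE)$p.value
        tests[v] <- "fisher (zero expected cell)"
        warning("zero expected cell for `", v,
                "`; Fisher exact test used", call. = FALSE)
      } else {
        p <- suppressWarnings(
          stats::chisq.test(tab, correct = FALSE)$p.value)
        tests[v] <- "chi-squared"
      }
    }
    cells <- matrix(sprintf("%d (%.1f)", tab, pct), nrow = nrow(tab),
                    dimnames = dimnames(tab))
    rows[[v]] <- data.frame(variable = v, level = rownames(tab),
                            cells, p = c(p, rep(NA, nrow(tab) - 1)),
                            check.names = FALSE, row.names = NULL)
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(out, "tests") <- tests
  out
}

#' Finite-population sample size (margin-of-error design)
#'
#' Required sample size for estimating a proportion in a finite population:
#' with x = z^2 * p * (1 - p), n = ceiling(N * x / ((N - 1) * E^2 + x)),
#' where z is the two-sided normal quantile for the confidence level, p the
#' anticipated response distribution and E the margin of error. An optional
#' inflation (e.g. 10% for anticipated non-response) is applied as
#' ceiling(n * (1 + inflation)). Ceiling is used at both steps: a fractional
#' participant cannot be enrolled.
#'
#' @param population Population size N.
#' @param margin Margin of error E as a proportion (default 0.05).
#' @param confidence Confidence level (default 0.95).
#' @param response Anticipated response distribution p (default 0.5, the
#'   conservative maximum-variance choice).
#' @param inflation Proportional inflation applied after rounding (default 0).
#' @return Required sample size (integer).
#' @export
#' @examples
#' sample_size(5621970)                     # 385
#' sample_size(5621970, inflation = 0.10)   # 424
sample_size <- function(population, margin = 0.05, confidence = 0.95,
                        response = 0.5, inflation = 0) {
  if (margin <= 0 || margin >= 1) stop("`margin` must be in (0, 1)", call. = FALSE)
  if (confidence <= 0 || confidence >= 1) {
    stop("`confidence` must be in (0, 1)", call. = FALSE)
  }
  if (population < 1) stop("`population` must be positive", call. = FALSE)
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  x <- z^2 * response * (1 - response)
  n <- if (is.infinite(population)) {
    x / margin^2
  } else {
    population * x / ((population - 1) * margin^2 + x)
  }
  n <- ceiling(n)
  as.integer(ceiling(n * (1 + inflation)))
}
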