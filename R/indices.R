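#' Formula options for the index panel
#'
#' A handful of the published index formulas are ambiguous about units or
#' constants; these options pin down the conventions used and are recorded in
#' pipeline provenance so every reported number names the mode it was computed
#' under.
#'
#' @param bai_hip_unit Unit convention for the hip term of the body adiposity
#'   index: `"cm"` (the standard published formula, hip in centimetres) or
#'   `"m"` (hip expressed in metres, which yields values near -17.5 on typical
#'   adult anthropometry; offered for comparability with reports computed that
#'   way). Default `"cm"`.
#' @param bri_constant Leading constant of the body roundness index, either
#'   `364.2` (the standard published constant; default) or `365.2`.
#' @param allow_negative_lap If `TRUE` (default) negative lipid accumulation
#'   product values (waist below the sex-specific offset) are kept and flagged
#'   rather than truncated at zero, so group means stay unbiased.
#' @return An object of class `formula_options`.
#' @export
#' @examples
#' formula_options(bai_hip_unit = "m")
formula_options <- function(bai_hip_unit = c("cm", "m"),
                            bri_constant = 364.2,
                            allow_negative_lap = TRUE) {
  bai_hip_unit <- match.arg(bai_hip_unit)
  if (!bri_constant %in% c(364.2, 365.2)) {
    stop("`bri_constant` must be 364.2 (standard) or 365.2", call. = FALSE)
  }
  structure(
    list(bai_hip_unit = bai_hip_unit,
         bri_constant = bri_constant,
         allow_negative_lap = isTRUE(allow_negative_lap)),
    class = "formula_options"
  )
}

#' @export
print.formula_options <- function(x, ...) {
  cat("Index formula options\n",
      "  BAI hip unit:       ", x$bai_hip_unit, "\n",
      "  BRI constant:       ", format(x$bri_constant), "\n",
      "  negative LAP kept:  ", x$allow_negative_lap, "\n", sep = "")
  invisible(x)
}

check_positive <- function(..., .names = NULL) {
  vals <- list(...)
  nms <- if (is.null(.names)) names(vals) else .names
  for (i in seq_along(vals)) {
    v <- vals[[i]]
    bad <- !is.na(v) & v <= 0
    if (any(bad)) {
      stop(sprintf("`%s` must be strictly positive", nms[[i]]), call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Body mass index
#'
#' @param weight Body weight in kilograms.
#' @param height Standing height in metres.
#' @return BMI in kg/m^2.
#' @export
#' @examples
#' bmi(100, 2)
bmi <- function(weight, height) {
  check_positive(weight = weight, height = height)
  weight / height^2
}

#' Waist-to-height ratio
#'
#' @param waist Waist circumference in centimetres.
#' @inheritParams bmi
#' @return Dimensionless ratio (waist and height on the same length scale).
#' @export
#' @examples
#' waist_height_ratio(85, 1.70)
waist_height_ratio <- function(waist, height) {
  check_positive(waist = waist, height = height)
  (waist / 100) / height
}

#' Conicity index
#'
#' Waist circumference relative to the circumference of a cylinder with the
#' person's weight and height: CI = WC(m) / (0.109 * sqrt(weight / height)).
#'
#' @inheritParams waist_height_ratio
#' @inheritParams bmi
#' @return Dimensionless conicity index.
#' @export
#' @examples
#' conicity_index(waist = 89.69, weight = 74.04, height = 1.698)
conicity_index <- function(waist, weight, height) {
  check_positive(waist = waist, weight = weight, height = height)
  (waist / 100) / (0.109 * sqrt(weight / height))
}

#' Body adiposity index
#'
#' BAI = hip / height^1.5 - 18, a weight-free estimate of percent body fat.
#' The published formula takes hip in centimetres (`hip_unit = "cm"`); the
#' `"m"` mode divides hip by 100 first and produces values near -17.5 on
#' typical adult anthropometry.
#'
#' @param hip Hip circumference in centimetres.
#' @inheritParams bmi
#' @param hip_unit `"cm"` (standard) or `"m"`.
#' @return Body adiposity index.
#' @export
#' @examples
#' body_adiposity_index(102.98, 1.698)
#' body_adiposity_index(102.98, 1.698, hip_unit = "m")
body_adiposity_index <- function(hip, height, hip_unit = c("cm", "m")) {
  hip_unit <- match.arg(hip_unit)
  check_positive(hip = hip, height = height)
  h <- if (hip_unit == "m") hip / 100 else hip
  h / height^1.5 - 18
}

#' Abdominal volume index
#'
#' AVI = (2 * waist^2 + 0.7 * (waist - hip)^2) / 1000, with circumferences in
#' centimetres; a quadratic approximation of abdominal volume.
#'
#' @inheritParams waist_height_ratio
#' @inheritParams body_adiposity_index
#' @return Abdominal volume index (litre scale).
#' @export
#' @examples
#' abdominal_volume_index(89.69, 102.98)
abdominal_volume_index <- function(waist, hip) {
  check_positive(waist = waist, hip = hip)
  (2 * waist^2 + 0.7 * (waist - hip)^2) / 1000
}

#' Body roundness index
#'
#' BRI = C - 365.5 * sqrt(1 - (waist_m / (2*pi))^2 / (0.5 * height)^2), an
#' eccentricity transform of the body ellipse. The constant C defaults to the
#' standard 364.2; see [formula_options()].
#'
#' @inheritParams waist_height_ratio
#' @param constant Leading constant, 364.2 (default) or 365.2.
#' @return Body roundness index.
#' @export
#' @examples
#' body_roundness_index(89.69, 1.698)
body_roundness_index <- function(waist, height, constant = 364.2) {
  check_positive(waist = waist, height = height)
  r <- (waist / 100) / (2 * pi)
  ecc <- (r / (0.5 * height))^2
  bad <- !is.na(ecc) & ecc > 1
  if (any(bad)) {
    stop(sprintf(
      "waist/(2*pi) exceeds the semi-minor axis 0.5*height (ratio^2 = %.4g)",
      max(ecc[bad])), call. = FALSE)
  }
  constant - 365.5 * sqrt(1 - ecc)
}

#' Weight-adjusted waist index
#'
#' WWI = waist / sqrt(weight); central adiposity decoupled from overall mass.
#'
#' @inheritParams waist_height_ratio
#' @inheritParams bmi
#' @return WWI in cm/sqrt(kg).
#' @export
#' @examples
#' weight_adjusted_waist_index(100, 100)
weight_adjusted_waist_index <- function(waist, weight) {
  check_positive(waist = waist, weight = weight)
  waist / sqrt(weight)
}

#' Lipid accumulation product
#'
#' LAP = (waist - 65) * TG for males and (waist - 58) * TG for females, with
#' waist in centimetres and fasting triglycerides in mmol/L. Negative values
#' arise for very lean participants; by default they are kept (see
#' [formula_options()]).
#'
#' @inheritParams waist_height_ratio
#' @param tg Fasting triglycerides, mmol/L.
#' @param sex Character or factor coded `"male"` / `"female"` (recycled).
#' @param allow_negative Keep negative values (default) or replace with `NA`.
#' @return LAP in cm * mmol/L, with attribute `"negative"` flagging records
#'   below the sex-specific waist offset.
#' @export
#' @examples
#' lipid_accumulation_product(96, 1.9, "male")
lipid_accumulation_product <- function(waist, tg, sex, allow_negative = TRUE) {
  check_positive(waist = waist, tg = tg)
  sex <- as.character(sex)
  known <- is.na(sex) | sex %in% c("male", "female")
  if (!all(known)) {
    stop("`sex` must be coded \"male\" or \"female\"", call. = FALSE)
  }
  offset <- ifelse(sex == "male", 65, 58)
  out <- (waist - offset) * tg
  neg <- !is.na(out) & out < 0
  if (!allow_negative) out[neg] <- NA_real_
  attr(out, "negative") <- neg
  out
}

#' Cardiometabolic index
#'
#' CMI = (TG / HDL) * waist-to-height ratio.
#'
#' @inheritParams lipid_accumulation_product
#' @param hdl HDL cholesterol, mmol/L.
#' @inheritParams waist_height_ratio
#' @return Dimensionless cardiometabolic index.
#' @export
#' @examples
#' cardiometabolic_index(1.8, 1.2, 90, 1.70)
cardiometabolic_index <- function(tg, hdl, waist, height) {
  check_positive(tg = tg, hdl = hdl, waist = waist, height = height)
  (tg / hdl) * waist_height_ratio(waist, height)
}

#' Atherogenic index of plasma
#'
#' AIP = log10(TG / HDL) on molar concentrations; zero when TG equals HDL.
#'
#' @inheritParams cardiometabolic_index
#' @return AIP (log10 scale).
#' @export
#' @examples
#' atherogenic_index(2, 1)
atherogenic_index <- function(tg, hdl) {
  check_positive(tg = tg, hdl = hdl)
  log10(tg / hdl)
}

#' Convert lipid concentrations from mg/dL to mmol/L
#'
#' The index formulas take molar units. Conversion uses the molecular-weight
#' divisors 88.57 (triglycerides) and 38.67 (HDL cholesterol); it is never
#' applied implicitly.
#'
#' @param value Concentration in mg/dL.
#' @param lipid `"tg"` or `"hdl"`.
#' @return Concentration in mmol/L.
#' @export
#' @examples
#' lipid_to_mmol(150, "tg")
lipid_to_mmol <- function(value, lipid = c("tg", "hdl")) {
  lipid <- match.arg(lipid)
  value / switch(lipid, tg = 88.57, hdl = 38.67)
}

index_names <- function() {
  c("bmi", "whtr", "ci", "bai", "avi", "bri", "wwi", "lap", "cmi", "aip")
}

#' Compute the full index panel for a cohort
#'
#' Evaluates all ten body-composition and cardiometabolic indices per record.
#' Records missing lipid values get `NA` for LAP, CMI and AIP while the
#' anthropometric indices are still computed; a record whose anthropometry is
#' invalid for one index gets `NA` in that column only.
#'
#' @param data A `cohort_table` or data frame with columns `weight` (kg),
#'   `height` (m), `waist` (cm), `hip` (cm), `sex`, and optionally `tg`,
#'   `hdl` (mmol/L).
#' @param options A [formula_options()] object.
#' @return `data` with ten appended index columns (`bmi`, `whtr`, `ci`,
#'   `bai`, `avi`, `bri`, `wwi`, `lap`, `cmi`, `aip`) and attribute
#'   `"formula_options"` recording the conventions used.
#' @export
#' @examples
#' d <- data.frame(weight = 74.04, height = 1.698, waist = 89.69,
#'                 hip = 102.98, sex = "male", tg = 1.9, hdl = 1.1)
#' compute_indices(d)[, c("bmi", "ci", "avi")]
compute_indices <- function(data, options = formula_options()) {
  stopifnot(inherits(options, "formula_options"))
  d <- as.data.frame(data)
  need <- c("weight", "height", "waist", "hip", "sex")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  has_lipids <- all(c("tg", "hdl") %in% names(d))

  safe <- function(f, ...) {
    # per-record evaluation so one invalid record doesn't abort the cohort
    args <- list(...)
    n <- max(lengths(args))
    args <- lapply(args, rep_len, n)
    vapply(seq_len(n), function(i) {
      a <- lapply(args, `[[`, i)
      if (any(vapply(a[names(a) != "sex"], function(v) {
        is.na(v) || (is.numeric(v) && v <= 0)
      }, logical(1)))) {
        return(NA_real_)
      }
      tryCatch(as.numeric(do.call(f, a)), error = function(e) NA_real_)
    }, numeric(1))
  }

  d$bmi  <- safe(bmi, weight = d$weight, height = d$height)
  d$whtr <- safe(waist_height_ratio, waist = d$waist, height = d$height)
  d$ci   <- safe(conicity_index, waist = d$waist, weight = d$weight,
                 height = d$height)
  d$bai  <- safe(function(hip, height)
    body_adiposity_index(hip, height, hip_unit = options$bai_hip_unit),
    hip = d$hip, height = d$height)
  d$avi  <- safe(abdominal_volume_index, waist = d$waist, hip = d$hip)
  d$bri  <- safe(function(waist, height)
    body_roundness_index(waist, height, constant = options$bri_constant),
    waist = d$waist, height = d$height)
  d$wwi  <- safe(weight_adjusted_waist_index, waist = d$waist,
                 weight = d$weight)
  if (has_lipids) {
    d$lap <- safe(function(waist, tg, sex)
      lipid_accumulation_product(waist, tg, sex,
                                 allow_negative = options$allow_negative_lap),
      waist = d$waist, tg = d$tg, sex = as.character(d$sex))
    d$cmi <- safe(cardiometabolic_index, tg = d$tg, hdl = d$hdl,
                  waist = d$waist, height = d$height)
    d$aip <- safe(atherogenic_index, tg = d$tg, hdl = d$hdl)
  } else {
    d$lap <- d$cmi <- d$aip <- NA_real_
  }
  attr(d, "formula_options") <- options
  if (inherits(data, "cohort_table")) {
    d <- rebuild_cohort(d, data)
  }
  d
}
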