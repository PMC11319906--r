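#' @importFrom stats coef complete.cases cor lm quantile rnorm runif sd setNames
#' @importFrom utils read.csv write.csv
NULL

# canonical numeric fields every analysed record must carry
required_numeric <- function() {
  c("age", "weight", "height", "waist", "hip", "energy",
    "b1", "b2", "b3", "b6")
}

lipid_fields <- function() c("tg", "hdl")

#' Construct a cohort table
#'
#' A `cohort_table` is a validated data frame of per-participant records with
#' provenance and an exclusion log attached. Most users obtain one from
#' [read_cohort()] or [generate_cohort()] rather than calling this directly.
#'
#' @param data Data frame with one row per participant. Required columns:
#'   `id`, `age` (years), `sex` (`"male"`/`"female"`), `weight` (kg),
#'   `height` (m), `waist` (cm), `hip` (cm), `energy` (kcal/day), `b1`, `b2`,
#'   `b3`, `b6` (mg/day). Optional: `tg`, `hdl` (mmol/L) and categoricals.
#'   Unknown columns are preserved untouched.
#' @param provenance Named list describing where the data came from.
#' @param exclusion_log Data frame with columns `id`, `reason` recording rows
#'   removed during validation or exclusion.
#' @param validate Drop rows with missing/invalid required numerics (logged)?
#' @return A `cohort_table`.
#' @export
cohort_table <- function(data, provenance = list(source = "in-memory"),
                         exclusion_log = NULL, validate = TRUE) {
  d <- as.data.frame(data, stringsAsFactors = FALSE)
  if (is.null(d$id)) d$id <- seq_len(nrow(d))
  d$id <- as.character(d$id)
  if (anyDuplicated(d$id)) stop("participant ids must be unique", call. = FALSE)
  if (is.null(exclusion_log)) {
    exclusion_log <- data.frame(id = character(), reason = character(),
                                stringsAsFactors = FALSE)
  }
  miss <- setdiff(c(required_numeric(), "sex"), names(d))
  if (length(miss)) {
    stop("cohort is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  for (col in c(required_numeric(), lipid_fields())) {
    if (!is.null(d[[col]])) d[[col]] <- as.numeric(d[[col]])
  }
  d$sex <- as.character(d$sex)

  if (validate) {
    bad_reason <- rep(NA_character_, nrow(d))
    anth <- c("weight", "height", "waist", "hip")
    inc_anth <- !complete.cases(d[anth]) |
      d$weight <= 0 | d$waist <= 0 | d$hip <= 0 |
      d$height <= 0.5 | d$height >= 2.5
    inc_diet <- !complete.cases(d[c("energy", "b1", "b2", "b3", "b6")])
    bad_sex <- is.na(d$sex) | !d$sex %in% c("male", "female")
    bad_age <- is.na(d$age)
    bad_reason[which(inc_diet)] <- "incomplete dietary"
    bad_reason[which(inc_anth)] <- "incomplete anthropometric"
    bad_reason[which(bad_sex)] <- "sex not coded male/female"
    bad_reason[which(bad_age)] <- "missing age"
    drop <- !is.na(bad_reason)
    if (any(drop)) {
      exclusion_log <- rbind(exclusion_log, data.frame(
        id = d$id[drop], reason = bad_reason[drop], stringsAsFactors = FALSE))
      d <- d[!drop, , drop = FALSE]
      rownames(d) <- NULL
    }
  }
  structure(d, provenance = provenance, exclusion_log = exclusion_log,
            class = c("cohort_table", "data.frame"))
}

# reattach cohort_table metadata after a transforming step
rebuild_cohort <- function(d, template) {
  keep_or <- function(nm) {
    v <- attr(d, nm)
    if (is.null(v)) attr(template, nm) else v
  }
  structure(as.data.frame(d),
            provenance = attr(template, "provenance"),
            exclusion_log = attr(template, "exclusion_log"),
            formula_options = keep_or("formula_options"),
            adjusted = keep_or("adjusted"),
            tertile_cuts = keep_or("tertile_cuts"),
            ground_truth = attr(template, "ground_truth"),
            class = c("cohort_table", "data.frame"))
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("<cohort_table> %d participants, %d columns\n", nrow(x), ncol(x)))
  prov <- attr(x, "provenance")
  if (!is.null(prov$source)) cat("  source:", prov$source, "\n")
  xl <- attr(x, "exclusion_log")
  if (!is.null(xl) && nrow(xl)) {
    cat(sprintf("  %d record(s) excluded (see exclusion_log())\n", nrow(xl)))
  }
  print(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("  ...", nrow(x) - 6, "more rows\n")
  invisible(x)
}

#' Exclusion log of a cohort
#'
#' @param cohort A `cohort_table`.
#' @return Data frame with columns `id` and `reason`, one row per record
#'   removed during ingestion, validation, or [apply_exclusions()].
#' @export
exclusion_log <- function(cohort) {
  attr(cohort, "exclusion_log")
}

#' Read a cohort table from disk
#'
#' Reads a CSV (RFC-4180, header row) or SPSS `.sav` file into a validated
#' [cohort_table()]. Column names are mapped to the canonical schema via
#' `column_map`; heights reported in centimetres are converted to metres when
#' they exceed 3 (the conversion is recorded in provenance); lipids reported
#' in mg/dL must be declared via `lipid_unit` — no unit guessing is done for
#' lipids. Sex coding is never guessed: if the file does not already use
#' `"male"`/`"female"`, supply `sex_map`.
#'
#' @param path File path.
#' @param format `"csv"` or `"spss"`.
#' @param column_map Named character vector mapping file column names to
#'   canonical names, e.g. `c(WC_cm = "waist")`. Columns already canonically
#'   named need no entry; unknown columns are kept as-is.
#' @param sex_map Named vector mapping file sex codes to `"male"`/`"female"`,
#'   e.g. `c("1" = "male", "2" = "female")`.
#' @param lipid_unit `"mmol"` (default, no conversion) or `"mgdl"` (TG / 88.57,
#'   HDL / 38.67 applied on read).
#' @return A `cohort_table`; rows failing validation are excluded and logged.
#' @export
read_cohort <- function(path, format = c("csv", "spss"), column_map = NULL,
                        sex_map = NULL, lipid_unit = c("mmol", "mgdl")) {
  format <- match.arg(format)
  lipid_unit <- match.arg(lipid_unit)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- switch(format,
    csv = read.csv(path, stringsAsFactors = FALSE),
    spss = as.data.frame(foreign::read.spss(path, to.data.frame = TRUE,
                                            use.value.labels = FALSE))
  )
  names(d) <- trimws(names(d))
  if (!is.null(column_map)) {
    hit <- names(d) %in% names(column_map)
    names(d)[hit] <- unname(column_map[names(d)[hit]])
  }
  miss <- setdiff(c(required_numeric(), "sex"), names(d))
  if (length(miss)) {
    stop("input lacks required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  conv <- character()
  if (!is.null(d$height)) {
    h <- suppressWarnings(as.numeric(d$height))
    if (any(h > 3, na.rm = TRUE)) {       # heuristic: heights > 3 are cm
      d$height <- h / 100
      conv <- c(conv, "height cm->m")
    }
  }
  if (lipid_unit == "mgdl") {
    if (!is.null(d$tg)) d$tg <- lipid_to_mmol(as.numeric(d$tg), "tg")
    if (!is.null(d$hdl)) d$hdl <- lipid_to_mmol(as.numeric(d$hdl), "hdl")
    conv <- c(conv, "lipids mg/dL->mmol/L")
  }
  if (!is.null(sex_map)) {
    d$sex <- unname(sex_map[as.character(d$sex)])
  }
  cohort_table(d, provenance = list(source = path, format = format,
                                    conversions = conv))
}

#' Write a cohort table to CSV
#'
#' Numeric fields are written at full precision so a read/write round trip
#' reproduces them exactly.
#'
#' @param cohort A `cohort_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}

#' Standard exclusion ruleset
#'
#' Builds the ruleset applied by [apply_exclusions()]: analysis age span
#' (default 18-64 inclusive), complete anthropometry, and (optionally)
#' complete fasting lipids. Each rule is a predicate returning `TRUE` for
#' records to keep.
#'
#' @param age_range Inclusive analysis age span, default `c(18, 64)`.
#' @param require_lipids Exclude records missing TG or HDL? Default `TRUE`.
#' @return Named list of predicate functions.
#' @export
exclusion_rules <- function(age_range = c(18, 64), require_lipids = TRUE) {
  rules <- list(
    "age outside 18-64" = function(d) {
      !is.na(d$age) & d$age >= age_range[1] & d$age <= age_range[2]
    },
    "incomplete anthropometric" = function(d) {
      complete.cases(d[c("weight", "height", "waist", "hip")])
    }
  )
  names(rules)[1] <- sprintf("age outside %d-%d", age_range[1], age_range[2])
  if (require_lipids) {
    rules[["incomplete biochemical"]] <- function(d) {
      !is.na(d$tg) & !is.na(d$hdl) & d$tg > 0 & d$hdl > 0
    }
  }
  rules
}

#' Apply exclusion rules to a cohort
#'
#' Drops records failing any rule, appending one exclusion-log entry per
#' removed record naming the first rule it failed. Order of the surviving
#' records is preserved and the operation is idempotent.
#'
#' @param cohort A `cohort_table`.
#' @param rules Named list of predicates as built by [exclusion_rules()].
#' @return The filtered `cohort_table`.
#' @export
apply_exclusions <- function(cohort, rules = exclusion_rules()) {
  d <- as.data.frame(cohort)
  if (!("tg" %in% names(d))) d$tg <- NA_real_
  if (!("hdl" %in% names(d))) d$hdl <- NA_real_
  reason <- rep(NA_character_, nrow(d))
  for (nm in rev(names(rules))) {     # first failing rule wins
    keep <- rules[[nm]](d)
    keep[is.na(keep)] <- FALSE
    reason[!keep] <- nm
  }
  drop <- !is.na(reason)
  log <- attr(cohort, "exclusion_log")
  if (any(drop)) {
    log <- rbind(log, data.frame(id = d$id[drop], reason = reason[drop],
                                 stringsAsFactors = FALSE))
  }
  out <- as.data.frame(cohort)[!drop, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0) warning("all records excluded", call. = FALSE)
  structure(out, provenance = attr(cohort, "provenance"),
            exclusion_log = log,
            ground_truth = attr(cohort, "ground_truth"),
            class = c("cohort_table", "data.frame"))
}

#' Assign the analysis age group
#'
#' Groups are `20-34`, `35-44` and `45-65`, inclusive at both printed
#' endpoints. Ages 18-19 fall inside the enrolment span but below the first
#' printed group; they are absorbed into `20-34` by convention.
#'
#' @param age Integer ages in years, within 18-65.
#' @return Factor with levels `"20-34"`, `"35-44"`, `"45-65"`.
#' @export
#' @examples
#' assign_age_group(c(19, 34, 35, 64))
assign_age_group <- function(age) {
  if (any(is.na(age)) || any(age < 18 | age > 65)) {
    stop("age must be within 18-65", call. = FALSE)
  }
  cut(age, breaks = c(17, 34, 44, 65),
      labels = c("20-34", "35-44", "45-65"), right = TRUE)
}
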