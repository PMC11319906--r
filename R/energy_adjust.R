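#' Average two 24-hour dietary recalls
#'
#' Usual intake is estimated as the arithmetic mean of one weekday and one
#' weekend 24-hour recall, per nutrient and for energy. Participants with a
#' single recall are excluded by default; `policy = "use_single"` passes the
#' available recall through and flags the record instead.
#'
#' @param recall1,recall2 Numeric vectors (or data frames column-by-column) of
#'   per-participant intakes from each recall; `NA` marks a missing recall.
#' @param policy `"exclude"` (default) returns `NA` where either recall is
#'   missing; `"use_single"` returns the available value.
#' @return Numeric vector of mean intakes with attribute `"single_recall"`
#'   flagging participants lacking one recall.
#' @export
#' @examples
#' average_recalls(c(1, 2), c(3, 2))
average_recalls <- function(recall1, recall2,
                            policy = c("exclude", "use_single")) {
  policy <- match.arg(policy)
  if (is.data.frame(recall1)) {
    stopifnot(is.data.frame(recall2), identical(names(recall1), names(recall2)))
    out <- as.data.frame(Map(function(a, b) average_recalls(a, b, policy),
                             recall1, recall2))
    return(out)
  }
  if (any(recall1 < 0, na.rm = TRUE) || any(recall2 < 0, na.rm = TRUE)) {
    stop("intakes must be non-negative", call. = FALSE)
  }
  single <- xor(is.na(recall1), is.na(recall2))
  out <- (recall1 + recall2) / 2
  if (policy == "use_single") {
    out[single] <- ifelse(is.na(recall1[single]),
                          recall2[single], recall1[single])
  }
  attr(out, "single_recall") <- single
  out
}

#' Residual-method energy adjustment
#'
#' Regresses nutrient intake on total energy intake (ordinary least squares
#' with intercept) and returns residual + cohort mean nutrient intake: an
#' intake measure uncorrelated with energy, on the original mg/day scale,
#' with the cohort mean preserved.
#'
#' @param nutrient Numeric vector of nutrient intakes (mg/day).
#' @param energy Numeric vector of energy intakes (kcal/day), same length.
#' @return Numeric vector of energy-adjusted intakes.
#' @export
#' @examples
#' residual_adjust(c(1.2, 1.0, 2.0, 1.8), c(1800, 2400, 3000, 3600))
residual_adjust <- function(nutrient, energy) {
  if (length(nutrient) != length(energy)) {
    stop("`nutrient` and `energy` must have equal length", call. = FALSE)
  }
  ok <- !is.na(nutrient) & !is.na(energy)
  if (sum(ok) < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (sd(energy[ok]) == 0) {
    stop("energy intake has zero variance; slope undefined", call. = FALSE)
  }
  fit <- lm(nutrient ~ energy, subset = ok)
  out <- rep(NA_real_, length(nutrient))
  out[ok] <- stats::residuals(fit) + mean(nutrient[ok])
  out
}

#' Tertile cutpoints and labels
#'
#' Cutpoints are the 33rd and 66th percentiles computed by linear
#' interpolation between order statistics at position (n-1)p + 1
#' (`quantile type 7`). Labels: T1 strictly below the 33rd percentile, T2
#' between the two cutpoints inclusive, T3 strictly above the 66th.
#'
#' @param values Numeric vector, length >= 3.
#' @param probs The two cut probabilities, default `c(0.33, 0.66)`.
#' @return List with `cuts` (named vector `q33`, `q66`, plus attribute
#'   `"method"`) and `labels` (factor `T1`/`T2`/`T3`).
#' @export
#' @examples
#' tertile_cut(1:9)
tertile_cut <- function(values, probs = c(0.33, 0.66)) {
  ok <- !is.na(values)
  if (sum(ok) < 3) stop("need at least 3 values", call. = FALSE)
  q <- quantile(values[ok], probs = probs, type = 7, names = FALSE)
  if (q[1] > q[2]) stop("cutpoints out of order", call. = FALSE)
  labels <- factor(rep(NA_character_, length(values)),
                   levels = c("T1", "T2", "T3"))
  labels[ok] <- ifelse(values[ok] < q[1], "T1",
                       ifelse(values[ok] > q[2], "T3", "T2"))
  if (q[1] == q[2] && sd(values[ok]) == 0) {
    warning("all values identical; every record labelled T2", call. = FALSE)
  }
  cuts <- setNames(q, c("q33", "q66"))
  attr(cuts, "method") <- "linear interpolation, type 7, positions (n-1)p+1"
  list(cuts = cuts, labels = labels)
}

#' Energy-adjust nutrients across a cohort and assign tertiles
#'
#' Applies [residual_adjust()] to each nutrient against cohort energy intake,
#' then [tertile_cut()] to the adjusted values. Adjustment is computed on the
#' whole analysed cohort (one set of cutpoints, not within sex strata).
#'
#' @param cohort A `cohort_table` (post-exclusion).
#' @param nutrients Character vector of intake columns, default
#'   `c("b1", "b2", "b3", "b6")`.
#' @return The cohort with `<nutrient>_adj` and `<nutrient>_tertile` columns
#'   appended and attribute `"tertile_cuts"` (named list of cut vectors).
#' @export
energy_adjust_cohort <- function(cohort, nutrients = c("b1", "b2", "b3", "b6")) {
  d <- as.data.frame(cohort)
  miss <- setdiff(c(nutrients, "energy"), names(d))
  if (length(miss)) {
    stop("cohort lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  cuts <- list()
  for (nu in nutrients) {
    adj <- residual_adjust(d[[nu]], d$energy)
    tc <- tertile_cut(adj)
    d[[paste0(nu, "_adj")]] <- adj
    d[[paste0(nu, "_tertile")]] <- tc$labels
    cuts[[nu]] <- tc$cuts
  }
  attr(d, "tertile_cuts") <- cuts
  attr(d, "adjusted") <- nutrients
  if (inherits(cohort, "cohort_table")) d <- rebuild_cohort(d, cohort)
  d
}

#' Tertile cutpoints recorded on an adjusted cohort
#'
#' @param cohort A cohort processed by [energy_adjust_cohort()].
#' @return Named list of cut vectors (`q33`, `q66`) per nutrient.
#' @export
tertile_cuts <- function(cohort) {
  attr(cohort, "tertile_cuts")
}
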