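#' Liver-chemistry grading scales
#'
#' The six liver chemistries are graded on a CTCAE-style ordinal ladder.
#' Each scale is an ordered set of cutoffs in the analyte's own units; a
#' value is graded by counting how many cutoffs it exceeds (or, for
#' albumin, falls below).  The default cutoffs are multiples of the upper
#' limit of normal: bilirubin 1.5/2.25/4.5/15 mg/dL, AST and ALT
#' 35/105/175/700 IU/L, alkaline phosphatase 120/300/600/2400 IU/L,
#' INR 1.2/1.5/2.5 (unitless), and albumin 3.5/3/2 g/dL (low is worse).
#'
#' @name lf_scales
NULL

LF_ANALYTES <- c("BIL", "AST", "ALT", "ALKP", "INR", "ALB")

.default_scale_defs <- list(
  BIL  = list(cutoffs = c(1.5, 2.25, 4.5, 15), direction = "high_is_worse",
              units = "mg/dL"),
  AST  = list(cutoffs = c(35, 105, 175, 700), direction = "high_is_worse",
              units = "IU/L"),
  ALT  = list(cutoffs = c(35, 105, 175, 700), direction = "high_is_worse",
              units = "IU/L"),
  ALKP = list(cutoffs = c(120, 300, 600, 2400), direction = "high_is_worse",
              units = "IU/L"),
  INR  = list(cutoffs = c(1.2, 1.5, 2.5), direction = "high_is_worse",
              units = "unitless"),
  ALB  = list(cutoffs = c(3.5, 3, 2), direction = "low_is_worse",
              units = "g/dL")
)

#' Construct a grading scale for one liver chemistry
#'
#' @param analyte one of `"BIL"`, `"AST"`, `"ALT"`, `"ALKP"`, `"INR"`,
#'   `"ALB"`.
#' @param cutoffs ordered numeric grade boundaries; defaults to the
#'   CTCAE-style ladder for the analyte.  Must be strictly increasing for
#'   high-is-worse analytes and strictly decreasing for albumin.
#' @param direction `"high_is_worse"` or `"low_is_worse"`.
#' @param units unit label; inputs are validated against it, never
#'   converted.
#' @param scale_factor multiplier already applied to `cutoffs` (recorded
#'   for provenance; see [scale_cutoffs()]).
#' @return an object of class `lf_scale`.
#' @examples
#' grade_value(lf_scale("BIL"), 3.0)   # grade 2
#' @export
lf_scale <- function(analyte,
                     cutoffs = NULL,
                     direction = NULL,
                     units = NULL,
                     scale_factor = 1.0) {
  analyte <- match.arg(analyte, LF_ANALYTES)
  def <- .default_scale_defs[[analyte]]
  if (is.null(cutoffs)) cutoffs <- def$cutoffs
  if (is.null(direction)) direction <- def$direction
  if (is.null(units)) units <- def$units
  direction <- match.arg(direction, c("high_is_worse", "low_is_worse"))
  stopifnot(is.numeric(cutoffs), all(is.finite(cutoffs)),
            length(cutoffs) >= 1,
            is.numeric(scale_factor), length(scale_factor) == 1,
            scale_factor > 0)
  d <- diff(cutoffs)
  if (direction == "high_is_worse" && !all(d > 0))
    stop(analyte, ": cutoffs must be strictly increasing for high_is_worse")
  if (direction == "low_is_worse" && !all(d < 0))
    stop(analyte, ": cutoffs must be strictly decreasing for low_is_worse")
  structure(
    list(analyte = analyte, direction = direction, cutoffs = cutoffs,
         max_grade = length(cutoffs), units = units,
         scale_factor = scale_factor),
    class = "lf_scale")
}

#' Default grading scales for all six chemistries
#'
#' @param scale_factor common multiplier applied to every cutoff of every
#'   analyte, as used by the cutoff-scaling sensitivity analysis
#'   (0.7-1.3 in steps of 0.1).
#' @return named list of [lf_scale()] objects.
#' @export
default_scales <- function(scale_factor = 1.0) {
  sc <- lapply(LF_ANALYTES, lf_scale)
  names(sc) <- LF_ANALYTES
  if (scale_factor != 1.0)
    sc <- lapply(sc, scale_cutoffs, factor = scale_factor)
  sc
}

#' Multiply a scale's cutoffs by a sensitivity factor
#'
#' Every cutoff is multiplied by `factor`; direction and maximum grade are
#' unchanged and the factor is recorded on the returned scale.
#'
#' @param scale an [lf_scale()].
#' @param factor positive multiplier.
#' @return a new `lf_scale`.
#' @export
scale_cutoffs <- function(scale, factor) {
  stopifnot(inherits(scale, "lf_scale"))
  if (!is.numeric(factor) || length(factor) != 1 || !is.finite(factor) ||
      factor <= 0)
    stop("cutoff scale factor must be a positive number")
  lf_scale(scale$analyte, cutoffs = scale$cutoffs * factor,
           direction = scale$direction, units = scale$units,
           scale_factor = scale$scale_factor * factor)
}

#' Grade laboratory values on a scale
#'
#' For high-is-worse analytes a value is grade 0 when at or below the
#' first cutoff, grade k when strictly above the k-th cutoff and at or
#' below the (k+1)-th, and the maximum grade when strictly above the last
#' cutoff.  For albumin (low is worse) the inclusivity mirrors: grade 0 at
#' or above 3.5 g/dL, grade k when below the k-th cutoff and at or above
#' the (k+1)-th.
#'
#' @param scale an [lf_scale()].
#' @param value positive numeric vector of measurements in the scale's
#'   units.
#' @return integer vector of grades in `[0, max_grade]`.
#' @export
grade_value <- function(scale, value) {
  stopifnot(inherits(scale, "lf_scale"))
  if (!is.numeric(value) || any(!is.finite(value)) || any(value <= 0))
    stop(scale$analyte, ": lab values must be positive and finite")
  if (scale$direction == "high_is_worse") {
    g <- vapply(value, function(v) sum(v > scale$cutoffs), integer(1))
  } else {
    g <- vapply(value, function(v) sum(v < scale$cutoffs), integer(1))
  }
  as.integer(g)
}

#' Sample a laboratory value uniformly inside a grade band
#'
#' Inverse of [grade_value()] in distribution: the returned value grades
#' back to `grade` under `scale`.  Open-ended bands are bounded at twice
#' the outermost cutoff (or half of it on the low side) so every band has
#' finite width.
#'
#' @param scale an [lf_scale()].
#' @param grade integer grade(s) in `[0, max_grade]`.
#' @return numeric vector of values.
#' @export
sample_in_band <- function(scale, grade) {
  stopifnot(inherits(scale, "lf_scale"))
  if (any(grade < 0 | grade > scale$max_grade))
    stop(scale$analyte, ": grade outside [0, ", scale$max_grade, "]")
  cuts <- scale$cutoffs
  k <- scale$max_grade
  vapply(grade, function(g) {
    if (scale$direction == "high_is_worse") {
      lo <- if (g == 0) cuts[1] / 2 else cuts[g]
      hi <- if (g == k) 2 * cuts[k] else cuts[g + 1]
    } else {
      lo <- if (g == k) cuts[k] / 2 else cuts[g + 1]
      hi <- if (g == 0) 1.5 * cuts[1] else cuts[g]
    }
    # stay strictly inside the band so regrading is exact at boundaries
    lo + (hi - lo) * runif(1, min = 1e-6, max = 1 - 1e-6)
  }, numeric(1))
}

#' Composite liver-function score definitions
#'
#' `ALL6` sums the grades of all six chemistries (maximum 22), `ALL4`
#' restricts to BIL/AST/ALT/ALKP, and `ALL3` to BIL/AST/ALT — the two
#' substitutions used by the composite sensitivity analysis.
#'
#' @param name `"ALL6"`, `"ALL4"` or `"ALL3"`.
#' @param missing_policy `"require_complete"` (score is `NA` when any
#'   member grade is absent) or `"sum_available"` (sum the present
#'   members and flag incompleteness).
#' @return an object of class `composite_definition`.
#' @export
composite_definition <- function(name = c("ALL6", "ALL4", "ALL3"),
                                 missing_policy = c("require_complete",
                                                    "sum_available")) {
  name <- match.arg(name)
  missing_policy <- match.arg(missing_policy)
  members <- switch(name,
                    ALL6 = LF_ANALYTES,
                    ALL4 = c("BIL", "AST", "ALT", "ALKP"),
                    ALL3 = c("BIL", "AST", "ALT"))
  structure(list(name = name, members = members,
                 missing_policy = missing_policy),
            class = "composite_definition")
}

#' Composite score from per-analyte grades
#'
#' @param grades named integer vector (names are analytes) of grades for
#'   one patient at one time point; members absent from the vector or
#'   `NA` count as missing.
#' @param definition a [composite_definition()].
#' @return integer score with attribute `complete`; `NA` under
#'   `require_complete` when a member is missing.
#' @export
composite_score <- function(grades, definition = composite_definition("ALL6")) {
  stopifnot(inherits(definition, "composite_definition"))
  g <- grades[definition$members]
  names(g) <- definition$members
  for (a in definition$members) {
    ga <- g[[a]]
    if (!is.na(ga) && (ga < 0 || ga > length(.default_scale_defs[[a]]$cutoffs)))
      stop(a, ": grade ", ga, " outside the analyte's range")
  }
  present <- !is.na(g)
  complete <- all(present)
  if (!complete && definition$missing_policy == "require_complete")
    return(structure(NA_integer_, complete = FALSE))
  structure(as.integer(sum(g[present])), complete = complete)
}

#' Grade a long-format laboratory series
#'
#' Converts records (patient, time, analyte, value) to grade records.
#' Multiple tests of one analyte for one patient on the same calendar day
#' are collapsed to the single worst (highest) grade, because events are
#' defined per visit day.  Pre-treatment records (negative times) pass
#' through with their negative times.
#'
#' @param labs data.frame with columns `patient_id`, `time_months`,
#'   `analyte`, `value`, and optionally `unit`.
#' @param scales named list of [lf_scale()] objects (default
#'   [default_scales()]).
#' @return data.frame with columns `patient_id`, `time_months`,
#'   `analyte`, `grade`, sorted by patient, analyte, time.
#' @export
grade_series <- function(labs, scales = default_scales()) {
  req <- c("patient_id", "time_months", "analyte", "value")
  if (!all(req %in% names(labs)))
    stop("labs must have columns ", paste(req, collapse = ", "))
  if (nrow(labs) == 0)
    return(data.frame(patient_id = character(), time_months = numeric(),
                      analyte = character(), grade = integer(),
                      stringsAsFactors = FALSE))
  unknown <- setdiff(unique(labs$analyte), names(scales))
  if (length(unknown))
    stop("unknown analyte(s): ", paste(unknown, collapse = ", "))
  if ("unit" %in% names(labs)) {
    for (a in unique(labs$analyte)) {
      u <- unique(labs$unit[labs$analyte == a])
      bad <- setdiff(u, scales[[a]]$units)
      if (length(bad))
        stop(a, ": unit mismatch (got ", paste(bad, collapse = ", "),
             ", scale uses ", scales[[a]]$units, ")")
    }
  }
  grade <- integer(nrow(labs))
  for (a in unique(labs$analyte)) {
    idx <- labs$analyte == a
    grade[idx] <- grade_value(scales[[a]], labs$value[idx])
  }
  out <- data.frame(patient_id = labs$patient_id,
                    time_months = labs$time_months,
                    analyte = labs$analyte, grade = grade,
                    stringsAsFactors = FALSE)
  out$day <- visit_day(out$time_months)
  # worst grade per patient x analyte x day; keep the day's earliest time
  out <- out[order(out$patient_id, out$analyte, out$day,
                   -out$grade, out$time_months), ]
  key <- paste(out$patient_id, out$analyte, out$day, sep = "\r")
  out <- out[!duplicated(key), ]
  out$day <- NULL
  out <- out[order(out$patient_id, out$analyte, out$time_months), ]
  rownames(out) <- NULL
  out
}

#' @export
print.lf_scale <- function(x, ...) {
  cat(sprintf("<lf_scale %s (%s, %s)> cutoffs: %s  scale_factor: %g\n",
              x$analyte, x$units, x$direction,
              paste(signif(x$cutoffs, 6), collapse = ", "),
              x$scale_factor))
  invisible(x)
}

#' Serialize / deserialize grading scales as JSON
#'
#' @param scales named list of [lf_scale()] objects.
#' @param path file path.
#' @return `write_scales_json` invisibly returns `path`;
#'   `read_scales_json` returns the list of scales.
#' @export
write_scales_json <- function(scales, path) {
  x <- lapply(scales, function(s)
    list(analyte = s$analyte, direction = s$direction, cutoffs = s$cutoffs,
         units = s$units, scale_factor = s$scale_factor))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_scales_json
#' @export
read_scales_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- lapply(x, function(s)
    lf_scale(s$analyte, cutoffs = as.numeric(s$cutoffs),
             direction = s$direction, units = s$units,
             scale_factor = s$scale_factor))
  names(out) <- vapply(out, function(s) s$analyte, character(1))
  out
}
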