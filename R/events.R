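#' Pre-treatment reference grade
#'
#' The comparator for a patient's first post-treatment visit is the grade
#' of the latest pre-treatment test within one week before radiotherapy
#' completion (window open on the low side, closed at 0).  If none exists
#' the fallback is the latest test within the previous month; if that is
#' also empty the reference is missing and the first post-treatment visit
#' initializes the comparator without being event-eligible.
#'
#' @param pre_records data.frame of graded records (`time_months` <= 0,
#'   `grade`) for one patient and one analyte.
#' @param week_days width of the primary window in days (default 7).
#' @param fallback_months width of the fallback window in months
#'   (default 1); `NULL` disables the fallback.
#' @return integer grade, or `NA` when no reference test exists.
#' @export
reference_grade <- function(pre_records, week_days = 7, fallback_months = 1) {
  pre <- pre_records[pre_records$time_months <= 0, , drop = FALSE]
  if (nrow(pre) == 0) return(NA_integer_)
  pick <- function(lo) {
    w <- pre[pre$time_months > lo, , drop = FALSE]
    if (nrow(w) == 0) return(NA_integer_)
    as.integer(w$grade[which.max(w$time_months)])
  }
  g <- pick(-week_days / DAYS_PER_MONTH)
  if (is.na(g) && !is.null(fallback_months)) g <- pick(-fallback_months)
  g
}

.empty_events <- function() {
  data.frame(patient_id = character(), time_months = numeric(),
             scope = character(), prev_grade = integer(),
             new_grade = integer(), delta = integer(),
             synchronous = logical(), magnitude = character(),
             stringsAsFactors = FALSE)
}

#' Derive individual upgrade events for one patient and analyte
#'
#' An event occurs at a visit whose grade exceeds its comparator: the
#' pre-treatment reference for the first visit, the previous visit's
#' grade thereafter.  The event's delta is the full jump, so a
#' same-day jump of more than one grade is a single `>1-grade` event.
#'
#' @param series data.frame of post-treatment grade records
#'   (`patient_id`, `time_months` > 0, `grade`), sorted by time, one
#'   record per day.
#' @param reference integer reference grade or `NA`.
#' @param analyte scope label written on the events.
#' @return data.frame of events (possibly empty) with columns
#'   `patient_id`, `time_months`, `scope`, `prev_grade`, `new_grade`,
#'   `delta`, `synchronous` (`NA`, filled by [classify_synchrony()]),
#'   `magnitude`.
#' @export
derive_individual_events <- function(series, reference, analyte = "LF") {
  if (nrow(series) == 0) return(.empty_events())
  if (is.unsorted(series$time_months, strictly = TRUE))
    stop("series must be strictly sorted by time (one record per day)")
  comparator <- if (is.na(reference)) NA_integer_ else as.integer(reference)
  ev <- vector("list", nrow(series))
  nev <- 0
  for (j in seq_len(nrow(series))) {
    g <- as.integer(series$grade[j])
    if (!is.na(comparator) && g > comparator) {
      d <- g - comparator
      nev <- nev + 1
      ev[[nev]] <- data.frame(
        patient_id = series$patient_id[j],
        time_months = series$time_months[j], scope = analyte,
        prev_grade = comparator, new_grade = g, delta = d,
        synchronous = NA,
        magnitude = if (d > 1) "gt_one_grade" else "one_grade",
        stringsAsFactors = FALSE)
    }
    comparator <- g
  }
  if (nev == 0) return(.empty_events())
  out <- do.call(rbind, ev[seq_len(nev)])
  rownames(out) <- NULL
  out
}

#' Derive all individual events for a graded cohort series
#'
#' Splits a graded series (output of [grade_series()]) into pre- and
#' post-treatment parts, computes each patient-by-analyte reference grade
#' and applies [derive_individual_events()], then flags synchrony.
#'
#' @param graded data.frame from [grade_series()].
#' @param analytes analytes to derive events for (default: all present).
#' @inheritParams reference_grade
#' @return data.frame of individual events with synchrony flags.
#' @export
derive_events <- function(graded, analytes = NULL,
                          week_days = 7, fallback_months = 1) {
  if (is.null(analytes)) analytes <- unique(graded$analyte)
  pre <- graded[graded$time_months <= 0, , drop = FALSE]
  post <- graded[graded$time_months > 0, , drop = FALSE]
  out <- list()
  for (pid in unique(graded$patient_id)) {
    for (a in analytes) {
      s <- post[post$patient_id == pid & post$analyte == a, , drop = FALSE]
      if (nrow(s) == 0) next
      r <- reference_grade(
        pre[pre$patient_id == pid & pre$analyte == a, , drop = FALSE],
        week_days = week_days, fallback_months = fallback_months)
      out[[length(out) + 1]] <- derive_individual_events(s, r, analyte = a)
    }
  }
  ev <- if (length(out)) do.call(rbind, out) else .empty_events()
  classify_synchrony(ev)
}

#' Flag synchronous events
#'
#' An individual event is synchronous when another analyte also has an
#' event for the same patient on the same calendar day; otherwise it is a
#' single event.
#'
#' @param events data.frame of individual events.
#' @return the events with the `synchronous` column filled.
#' @export
classify_synchrony <- function(events) {
  if (nrow(events) == 0) return(events)
  day <- visit_day(events$time_months)
  key <- paste(events$patient_id, day, sep = "\r")
  nsame <- ave(seq_along(key), key, FUN = length)
  events$synchronous <- nsame > 1
  events
}

#' Combine same-day individual events into composite events
#'
#' One composite event is recognized per patient-day carrying at least
#' one member-analyte event.  Its delta is the sum of the member deltas
#' that day (`combine_rule = "sum"`, the default) or their maximum
#' (`"max"`); the magnitude class follows the composite delta, and the
#' event is synchronous when two or more member events co-occur.
#'
#' @param individual_events data.frame of individual events.
#' @param definition a [composite_definition()].
#' @param combine_rule `"sum"` or `"max"`.
#' @return data.frame of composite events (scope = the composite name);
#'   `prev_grade`/`new_grade` are `NA` for composite events.
#' @export
derive_combined_events <- function(individual_events,
                                   definition = composite_definition("ALL6"),
                                   combine_rule = c("sum", "max")) {
  combine_rule <- match.arg(combine_rule)
  ev <- individual_events[
    individual_events$scope %in% definition$members, , drop = FALSE]
  if (nrow(ev) == 0) return(.empty_events())
  day <- visit_day(ev$time_months)
  key <- paste(ev$patient_id, day, sep = "\r")
  split_idx <- split(seq_len(nrow(ev)), key)
  rows <- lapply(split_idx, function(ii) {
    d <- if (combine_rule == "sum") sum(ev$delta[ii]) else max(ev$delta[ii])
    data.frame(
      patient_id = ev$patient_id[ii[1]],
      time_months = min(ev$time_months[ii]),
      scope = definition$name,
      prev_grade = NA_integer_, new_grade = NA_integer_,
      delta = as.integer(d),
      synchronous = length(ii) >= 2,
      magnitude = if (d > 1) "gt_one_grade" else "one_grade",
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$patient_id, out$time_months), ]
  rownames(out) <- NULL
  out
}

#' Person-months of follow-up per patient for a scope
#'
#' Follow-up runs from radiotherapy completion (time 0) to the last
#' post-treatment visit carrying a test of the scope; censoring dates may
#' therefore differ between scopes.  A patient with no post-treatment
#' test of the scope contributes 0 person-months and is flagged
#' unobserved.
#'
#' @param visits data.frame with `patient_id`, `time_months`, `analyte`
#'   (graded or raw records; only times and analytes are used).
#' @param scope an analyte name or a [composite_definition()] (censored
#'   at the last visit carrying any member test).
#' @param patients optional patient ids to report (defaults to those in
#'   `visits`).
#' @return data.frame `patient_id`, `censor_time`, `person_months`,
#'   `observed`.
#' @export
person_months <- function(visits, scope, patients = NULL) {
  members <- if (inherits(scope, "composite_definition")) scope$members
             else scope
  if (is.null(patients)) patients <- unique(visits$patient_id)
  v <- visits[visits$analyte %in% members & visits$time_months > 0, ,
              drop = FALSE]
  last <- vapply(patients, function(pid) {
    tt <- v$time_months[v$patient_id == pid]
    if (length(tt) == 0) 0 else max(tt)
  }, numeric(1))
  data.frame(patient_id = patients, censor_time = last,
             person_months = last, observed = last > 0,
             stringsAsFactors = FALSE)
}

#' Stratified incidence rates
#'
#' Events per person-month within strata defined by a per-patient label
#' (baseline score value, gender, ...).  A stratum with zero
#' person-months has an undefined (`NA`) rate, not zero.
#'
#' @param events data.frame of events for one scope.
#' @param follow_up data.frame from [person_months()].
#' @param strata data.frame with `patient_id` and `stratum`.
#' @return data.frame `stratum`, `events`, `person_months`, `rate`.
#' @export
incidence_rates <- function(events, follow_up, strata) {
  fu <- merge(follow_up, strata, by = "patient_id")
  pm <- aggregate(person_months ~ stratum, data = fu, FUN = sum)
  if (nrow(events)) {
    ev <- merge(events, strata, by = "patient_id")
    cnt <- aggregate(cbind(events = ev$patient_id != ""), by =
                       list(stratum = ev$stratum), FUN = sum)
  } else {
    cnt <- data.frame(stratum = pm$stratum[0], events = integer())
  }
  out <- merge(pm, cnt, by = "stratum", all.x = TRUE)
  out$events[is.na(out$events)] <- 0L
  out$rate <- ifelse(out$person_months > 0,
                     out$events / out$person_months, NA_real_)
  out[order(out$stratum), c("stratum", "events", "person_months", "rate")]
}
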