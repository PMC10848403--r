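#' Build Andersen-Gill counting-process risk intervals
#'
#' A patient with event times t1 < ... < tk and censor time C contributes
#' intervals (0, t1], (t1, t2], ..., (tk, C] on the calendar (total-time)
#' scale; the trailing censored interval is omitted when the last event
#' falls on the censor-day visit.  Baseline covariates are carried on
#' every interval of the patient.
#'
#' @param events data.frame of events with `patient_id` and
#'   `time_months`; pass only the scope of interest.
#' @param follow_up data.frame from [person_months()] (`patient_id`,
#'   `censor_time`).
#' @param covariates data.frame keyed by `patient_id` with the model
#'   covariate columns; patients absent from it are dropped.
#' @param scope label recorded on the intervals.
#' @return data.frame with `cluster_id`, `start`, `stop`, `status`,
#'   `scope` and the covariate columns.
#' @export
build_intervals <- function(events, follow_up, covariates = NULL,
                            scope = "LF") {
  pats <- follow_up$patient_id[follow_up$censor_time > 0]
  rows <- lapply(pats, function(pid) {
    C <- follow_up$censor_time[follow_up$patient_id == pid][1]
    tt <- sort(events$time_months[events$patient_id == pid])
    if (length(tt)) {
      if (anyDuplicated(tt))
        stop(pid, ": duplicate event times within one patient and scope")
      if (max(tt) > C)
        stop(pid, ": event time ", max(tt), " after censor time ", C)
    }
    bounds <- unique(c(0, tt, C))
    data.frame(cluster_id = pid,
               start = bounds[-length(bounds)],
               stop = bounds[-1],
               status = as.integer(bounds[-1] %in% tt),
               scope = scope, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(cluster_id = character(), start = numeric(),
                      stop = numeric(), status = integer(),
                      scope = character(), stringsAsFactors = FALSE)
  if (!is.null(covariates)) {
    out <- merge(out, covariates, by.x = "cluster_id", by.y = "patient_id",
                 sort = FALSE)
    out <- out[order(out$cluster_id, out$start), ]
  }
  rownames(out) <- NULL
  out
}

#' Value of a constructed time-dependent covariate
#'
#' The extended Cox model uses cross-products of a baseline factor with a
#' transform of elapsed time, `x * g(t)` with `g(t) = t` months by
#' default.  The estimation engine evaluates this at every event time for
#' every subject at risk; no static interval expansion is performed.
#'
#' @param covariate_value baseline covariate value(s).
#' @param t time(s) in months since radiotherapy completion.
#' @param transform time transform `g` (default identity).
#' @return numeric `covariate_value * g(t)`.
#' @export
time_dependent_value <- function(covariate_value, t, transform = identity) {
  covariate_value * transform(t)
}
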