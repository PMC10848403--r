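#' Specify a counting-process Cox model
#'
#' @param fixed_terms character vector of time-fixed covariate columns.
#' @param td_terms constructed covariate-by-time terms: a character
#'   vector of covariate names (each paired with the identity time
#'   transform, `g(t) = t` months) or a named list mapping covariate
#'   names to transform functions.
#' @param ties `"efron"` (default) or `"breslow"` handling of event-time
#'   ties across patients.
#' @param cluster_by column identifying the patient cluster for the
#'   robust sandwich variance.
#' @param tol convergence tolerance on the change in log partial
#'   likelihood.
#' @param max_iter maximum Newton-Raphson iterations.
#' @return an object of class `cox_spec`.
#' @export
cox_spec <- function(fixed_terms, td_terms = list(),
                     ties = c("efron", "breslow"),
                     cluster_by = "cluster_id",
                     tol = 1e-9, max_iter = 50L) {
  ties <- match.arg(ties)
  stopifnot(tol > 0, max_iter >= 1)
  if (is.character(td_terms))
    td_terms <- setNames(rep(list(identity), length(td_terms)), td_terms)
  if (length(td_terms) && is.null(names(td_terms)))
    stop("td_terms must be named by covariate")
  structure(list(fixed_terms = as.character(fixed_terms),
                 td_terms = td_terms, ties = ties, cluster_by = cluster_by,
                 tol = tol, max_iter = as.integer(max_iter)),
            class = "cox_spec")
}

# Assemble the pieces the compiled core needs: fixed design, td base
# columns, unique event times and the transform values at those times.
# Complete-case: rows (hence whole patients, covariates being baseline)
# with any missing model covariate are excluded with a logged count.
.cox_design <- function(intervals, spec) {
  used <- unique(c(spec$fixed_terms, names(spec$td_terms)))
  miss <- setdiff(c(used, spec$cluster_by, "start", "stop", "status"),
                  names(intervals))
  if (length(miss))
    stop("intervals lack column(s): ", paste(miss, collapse = ", "))
  if (any(intervals$stop <= intervals$start))
    stop("intervals must satisfy stop > start")
  keep <- if (length(used))
    stats::complete.cases(intervals[, used, drop = FALSE])
  else rep(TRUE, nrow(intervals))
  excluded <- unique(intervals[[spec$cluster_by]][!keep])
  iv <- intervals[keep, , drop = FALSE]
  # a patient partially excluded would break interval contiguity
  iv <- iv[!(iv[[spec$cluster_by]] %in% excluded), , drop = FALSE]
  if (nrow(iv) == 0) stop("no complete-case intervals left")

  Xf <- if (length(spec$fixed_terms))
    as.matrix(iv[, spec$fixed_terms, drop = FALSE])
  else matrix(0, nrow(iv), 0)
  Xt <- if (length(spec$td_terms))
    as.matrix(iv[, names(spec$td_terms), drop = FALSE])
  else matrix(0, nrow(iv), 0)
  storage.mode(Xf) <- "double"; storage.mode(Xt) <- "double"

  etimes <- sort(unique(iv$stop[iv$status == 1]))
  gvals <- if (length(spec$td_terms))
    vapply(spec$td_terms, function(g) as.numeric(g(etimes)),
           numeric(length(etimes)))
  else matrix(0, length(etimes), 0)
  if (length(etimes) <= 1) gvals <- matrix(gvals, nrow = length(etimes))

  idx <- cox_risk_index(iv$start, iv$stop, as.integer(iv$status), etimes)

  list(iv = iv, Xf = Xf, Xt = Xt, etimes = etimes, gvals = gvals,
       ridx = idx$risk, didx = idx$death,
       cluster = iv[[spec$cluster_by]],
       terms = c(spec$fixed_terms,
                 if (length(spec$td_terms))
                   paste0(names(spec$td_terms), ":time")),
       n_excluded_clusters = length(excluded))
}

.cox_core_call <- function(ds, beta, ties, deriv) {
  cox_core(ds$Xf, ds$Xt, ds$gvals, ds$ridx, ds$didx,
           beta, identical(ties, "efron"), as.integer(deriv))
}

.cox_resid_call <- function(ds, beta, ties) {
  cox_resid(ds$Xf, ds$Xt, ds$gvals, ds$etimes, ds$ridx, ds$didx,
            as.numeric(beta), identical(ties, "efron"))
}

#' Log partial likelihood on counting-process data
#'
#' The risk set at an event time t consists of the intervals with
#' `start < t <= stop`; covariate-by-time terms are evaluated at t.
#' Tied event times across patients are handled by the Efron or Breslow
#' correction.
#'
#' @param beta coefficient vector (fixed terms first, then td terms).
#' @param intervals counting-process data from [build_intervals()].
#' @param spec a [cox_spec()].
#' @return the log partial likelihood (scalar).
#' @export
partial_loglik <- function(beta, intervals, spec) {
  ds <- .cox_design(intervals, spec)
  p <- ncol(ds$Xf) + ncol(ds$Xt)
  stopifnot(length(beta) == p)
  .cox_core_call(ds, as.numeric(beta), spec$ties, 0)$loglik
}

#' Gradient and information of the log partial likelihood
#'
#' @inheritParams partial_loglik
#' @return list with `loglik`, `grad` and `info` (observed information,
#'   the negated Hessian).
#' @export
partial_loglik_deriv <- function(beta, intervals, spec) {
  ds <- .cox_design(intervals, spec)
  .cox_core_call(ds, as.numeric(beta), spec$ties, 2)
}

#' Fit the Cox model by Newton-Raphson
#'
#' Maximizes the log partial likelihood with step-halving on
#' non-increase; convergence when the log-likelihood change drops below
#' `spec$tol`.  The model-based covariance is the inverse observed
#' information; confidence intervals and Wald tests use the
#' cluster-robust sandwich covariance (see [robust_covariance()]).
#'
#' @inheritParams partial_loglik
#' @param init optional starting coefficients (default 0).
#' @return an object of class `lfcox` with elements `beta`, `loglik`
#'   (null and maximized), `info`, `model_cov`, `robust_cov`, `hr`,
#'   `ci95_low`, `ci95_high`, `robust_se`, `wald_p`, `converged`,
#'   `n_events`, `n_intervals`, `n_clusters`, `n_excluded_clusters`.
#' @export
fit_cox <- function(intervals, spec, init = NULL) {
  ds <- .cox_design(intervals, spec)
  p <- ncol(ds$Xf) + ncol(ds$Xt)
  n_events <- sum(ds$iv$status == 1)
  if (n_events < 1) stop("no events in the data")
  clusters <- unique(ds$cluster)

  null_ll <- .cox_core_call(ds, numeric(p), spec$ties, 0)$loglik
  if (p == 0) {
    fit <- structure(list(
      beta = numeric(0), loglik = c(null = null_ll, max = null_ll),
      info = matrix(0, 0, 0), model_cov = matrix(0, 0, 0),
      robust_cov = matrix(0, 0, 0), hr = numeric(0),
      ci95_low = numeric(0), ci95_high = numeric(0),
      robust_se = numeric(0), wald_p = numeric(0),
      converged = TRUE, iterations = 0L, n_events = n_events,
      n_intervals = nrow(ds$iv), n_clusters = length(clusters),
      n_excluded_clusters = ds$n_excluded_clusters,
      terms = character(0), spec = spec, design = ds), class = "lfcox")
    return(fit)
  }

  # rank check at beta = 0: name the collinear terms rather than fail late
  info0 <- .cox_core_call(ds, numeric(p), spec$ties, 2)$info
  qr0 <- qr(info0)
  if (qr0$rank < p) {
    bad <- ds$terms[qr0$pivot[(qr0$rank + 1):p]]
    stop("design is rank deficient; collinear term(s): ",
         paste(bad, collapse = ", "))
  }

  beta <- if (is.null(init)) numeric(p) else as.numeric(init)
  ll <- .cox_core_call(ds, beta, spec$ties, 0)$loglik
  converged <- FALSE
  diverged <- FALSE
  iter <- 0L
  while (iter < spec$max_iter) {
    iter <- iter + 1L
    dd <- .cox_core_call(ds, beta, spec$ties, 2)
    step <- tryCatch(solve(dd$info, dd$grad), error = function(e) NULL)
    if (is.null(step)) { diverged <- TRUE; break }
    newbeta <- beta + step
    newll <- .cox_core_call(ds, newbeta, spec$ties, 0)$loglik
    nhalf <- 0
    while (is.na(newll) || newll < ll) {
      step <- step / 2
      newbeta <- beta + step
      newll <- .cox_core_call(ds, newbeta, spec$ties, 0)$loglik
      nhalf <- nhalf + 1
      if (nhalf > 30) break
    }
    if (is.na(newll) || newll < ll) { diverged <- TRUE; break }
    dll <- newll - ll
    beta <- newbeta
    ll <- newll
    if (any(abs(beta) > 15)) { diverged <- TRUE; break }
    if (dll < spec$tol) { converged <- TRUE; break }
  }

  final <- .cox_core_call(ds, beta, spec$ties, 2)
  model_cov <- tryCatch(solve(final$info), error = function(e)
    matrix(NA_real_, p, p))
  names(beta) <- ds$terms
  dimnames(model_cov) <- list(ds$terms, ds$terms)

  fit <- structure(list(
    beta = beta, loglik = c(null = null_ll, max = ll),
    info = final$info, model_cov = model_cov,
    robust_cov = NULL, hr = exp(beta),
    ci95_low = NULL, ci95_high = NULL, robust_se = NULL, wald_p = NULL,
    converged = converged && !diverged, iterations = iter,
    diagnostic = if (diverged)
      "possible monotone likelihood: coefficients diverging" else NULL,
    n_events = n_events, n_intervals = nrow(ds$iv),
    n_clusters = length(clusters),
    n_excluded_clusters = ds$n_excluded_clusters,
    terms = ds$terms, spec = spec, design = ds), class = "lfcox")

  rv <- robust_covariance(fit)
  fit$robust_cov <- rv
  rse <- sqrt(diag(rv))
  z <- qnorm(0.975)
  fit$robust_se <- rse
  fit$ci95_low <- exp(beta - z * rse)
  fit$ci95_high <- exp(beta + z * rse)
  fit$wald_p <- 2 * pnorm(-abs(beta / rse))
  fit
}

#' Cluster-robust sandwich covariance
#'
#' Computes `V (sum_g U_g U_g') V` where `V` is the inverse observed
#' information and `U_g` is the score residual summed over all intervals
#' of cluster (patient) g.  This is the variance used for every reported
#' confidence interval and Wald test, accounting for the within-patient
#' correlation of recurrent events.
#'
#' @param fit an [fit_cox()] result.
#' @param intervals,cluster_by optional replacement data / cluster
#'   column; defaults to the data the model was fitted on.
#' @return the robust covariance matrix.
#' @export
robust_covariance <- function(fit, intervals = NULL, cluster_by = NULL) {
  stopifnot(inherits(fit, "lfcox"))
  spec <- fit$spec
  if (!is.null(cluster_by)) spec$cluster_by <- cluster_by
  ds <- if (is.null(intervals)) fit$design else .cox_design(intervals, spec)
  p <- length(fit$beta)
  if (p == 0) return(matrix(0, 0, 0))
  if (length(unique(ds$cluster)) < 2)
    stop("robust variance undefined with a single cluster")
  res <- .cox_resid_call(ds, fit$beta, spec$ties)
  Ug <- rowsum(res$score, group = ds$cluster)
  V <- fit$model_cov
  rv <- V %*% crossprod(Ug) %*% V
  dimnames(rv) <- dimnames(V)
  rv
}

#' Schoenfeld-residual test of proportional hazards
#'
#' The Schoenfeld residual at each event is the covariate vector of the
#' event case minus the risk-set weighted mean at that time (with the
#' Efron tie adjustment averaged over the tie sub-steps).  Following the
#' Grambsch-Therneau scaling, proportional hazards is tested by
#' regressing the scaled residuals on a transform of event time; the
#' default transform is identity (months), consistent with the extended
#' model's covariate-by-time products.
#'
#' @param fit a converged [fit_cox()] result.
#' @param transform `"identity"` (default), `"rank"`, `"km"`, or a
#'   function of time.
#' @return an object of class `lfcox_zph`: a `table` with one row per
#'   term plus `GLOBAL` (`chisq`, `df`, `p`), the residuals and scaled
#'   residuals, and the transformed times.
#' @export
schoenfeld_test <- function(fit, transform = "identity") {
  stopifnot(inherits(fit, "lfcox"))
  if (!fit$converged) stop("fit did not converge")
  p <- length(fit$beta)
  ds <- fit$design
  m <- fit$n_events
  if (m < 2) stop("at least two events required")
  if (m <= p) stop("fewer events than model terms")
  res <- .cox_resid_call(ds, fit$beta, fit$spec$ties)
  R <- res$schoenfeld
  times <- res$schoenfeld_time
  tname <- if (is.function(transform)) "function" else transform
  g <- if (is.function(transform)) transform(times)
  else switch(match.arg(transform, c("identity", "rank", "km")),
              identity = times,
              rank = rank(times),
              km = .km_transform(ds, times))
  gc <- g - mean(g)
  V <- fit$model_cov
  u <- drop(crossprod(gc, R))              # p-vector
  denom <- sum(gc^2)
  Vu <- drop(V %*% u)
  chisq_term <- m * Vu^2 / (diag(V) * denom)
  chisq_global <- m * sum(u * Vu) / denom
  tab <- data.frame(
    chisq = c(chisq_term, chisq_global),
    df = c(rep(1, p), p),
    p = c(pchisq(chisq_term, 1, lower.tail = FALSE),
          pchisq(chisq_global, p, lower.tail = FALSE)),
    row.names = c(fit$terms, "GLOBAL"))
  scaled <- m * (R %*% V) + matrix(fit$beta, nrow(R), p, byrow = TRUE)
  colnames(R) <- colnames(scaled) <- fit$terms
  structure(list(table = tab, residuals = R, scaled_residuals = scaled,
                 time = times, gtime = g, transform = tname),
            class = "lfcox_zph")
}

# 1 - KM(t-) of time-to-any-event computed on the interval data; the
# conventional left-continuous Kaplan-Meier transform for the PH test.
.km_transform <- function(ds, times) {
  et <- ds$etimes
  nrisk <- vapply(et, function(t)
    sum(ds$iv$start < t & t <= ds$iv$stop), numeric(1))
  ndead <- vapply(et, function(t)
    sum(ds$iv$status == 1 & ds$iv$stop == t), numeric(1))
  km <- cumprod(1 - ndead / nrisk)
  kmleft <- c(1, km[-length(km)])
  1 - kmleft[match(times, et)]
}

#' Hazard ratio of a time-extended term at a given time
#'
#' For a term with a main coefficient and a `term:time` product
#' coefficient, the hazard ratio at time t is
#' `exp(beta_main + beta_td * t)`.
#'
#' @param fit an [fit_cox()] result containing both coefficients.
#' @param term the main-term name.
#' @param t time(s) in months, non-negative.
#' @return numeric hazard ratio(s).
#' @export
hr_at_time <- function(fit, term, t) {
  stopifnot(inherits(fit, "lfcox"))
  if (any(t < 0)) stop("t must be non-negative")
  td <- paste0(term, ":time")
  if (!(term %in% names(fit$beta)) || !(td %in% names(fit$beta)))
    stop("fit lacks main and/or time coefficients for ", term)
  exp(fit$beta[[term]] + fit$beta[[td]] * t)
}

#' Two-stage extended Cox fit
#'
#' Fits the proportional-hazards model, tests each term's PH assumption
#' on the Schoenfeld residuals, and for every term violating PH
#' (p < alpha) that also has a significant main effect (robust Wald
#' p < alpha) adds a covariate-by-time product and refits.
#'
#' @inheritParams partial_loglik
#' @param base_spec the PH-model [cox_spec()].
#' @param alpha significance level for both conditions (default 0.05).
#' @param transform time transform for the PH test and the added
#'   products.
#' @return list with `ph_fit`, `ph_test`, `extended_fit` (identical to
#'   `ph_fit` when no term qualifies) and `extended_terms`.
#' @export
two_stage_extended_fit <- function(intervals, base_spec, alpha = 0.05,
                                   transform = "identity") {
  ph_fit <- fit_cox(intervals, base_spec)
  ph_test <- schoenfeld_test(ph_fit, transform = transform)
  fixed <- base_spec$fixed_terms
  ptab <- ph_test$table[fixed, , drop = FALSE]
  qualify <- fixed[ptab$p < alpha & ph_fit$wald_p[fixed] < alpha]
  if (length(qualify) == 0)
    return(list(ph_fit = ph_fit, ph_test = ph_test,
                extended_fit = ph_fit, extended_terms = character(0)))
  td <- c(base_spec$td_terms,
          setNames(rep(list(identity), length(qualify)), qualify))
  spec2 <- cox_spec(base_spec$fixed_terms, td_terms = td,
                    ties = base_spec$ties, cluster_by = base_spec$cluster_by,
                    tol = base_spec$tol, max_iter = base_spec$max_iter)
  list(ph_fit = ph_fit, ph_test = ph_test,
       extended_fit = fit_cox(intervals, spec2),
       extended_terms = qualify)
}

#' Tidy coefficient table of a fitted model
#'
#' @param fit an [fit_cox()] result.
#' @return data.frame with term, coefficient, hazard ratio, robust SE,
#'   95% CI and robust Wald p-value.
#' @export
cox_table <- function(fit) {
  stopifnot(inherits(fit, "lfcox"))
  data.frame(term = fit$terms, coef = unname(fit$beta),
             hr = unname(fit$hr), robust_se = unname(fit$robust_se),
             ci95_low = unname(fit$ci95_low),
             ci95_high = unname(fit$ci95_high),
             p = unname(fit$wald_p), stringsAsFactors = FALSE)
}

#' @export
print.lfcox <- function(x, digits = 3, ...) {
  cat(sprintf(
    "Counting-process Cox fit (%s ties): %d events / %d intervals / %d patients\n",
    x$spec$ties, x$n_events, x$n_intervals, x$n_clusters))
  if (!x$converged) cat("WARNING: not converged.",
                        if (!is.null(x$diagnostic)) x$diagnostic, "\n")
  if (length(x$beta)) {
    tab <- cox_table(x)
    tab[-1] <- lapply(tab[-1], signif, digits)
    print(tab, row.names = FALSE)
  } else cat("(null model) loglik:", format(x$loglik[["max"]]), "\n")
  invisible(x)
}

#' @export
print.lfcox_zph <- function(x, digits = 4, ...) {
  cat("Proportional-hazards test (Schoenfeld residuals, transform:",
      x$transform, ")\n")
  print(signif(x$table, digits))
  invisible(x)
}
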