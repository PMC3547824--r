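#' Kaplan-Meier survival curve
#'
#' Product-limit estimate with Greenwood variance (via the survival
#' package); at tied times events precede censorings, the standard
#' convention. With no events the curve is identically 1 (warning).
#'
#' @param time follow-up times (> 0).
#' @param event 1 = event, 0 = censored.
#' @return list of class \code{"km_curve"}: \code{time}, \code{surv},
#'   \code{se} (Greenwood SE of S), \code{n_risk}, \code{n_event}, and the
#'   underlying \code{survfit} object.
#' @export
km_fit <- function(time, event) {
  if (any(time <= 0)) stop("times must be positive")
  if (!all(event %in% c(0, 1))) stop("event must be 0/1")
  if (sum(event) == 0) warning("no events: survival curve is identically 1")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, conf.type = "log")
  out <- list(time = fit$time, surv = fit$surv,
              se = fit$std.err * fit$surv,   # survfit std.err is on log scale
              n_risk = fit$n.risk, n_event = fit$n.event, fit = fit)
  class(out) <- "km_curve"
  out
}

#' Survival probability at given times
#'
#' Right-continuous step-function evaluation of a [km_fit()] curve.
#'
#' @param km a \code{"km_curve"}.
#' @param t times at which to evaluate.
#' @return numeric vector of survival probabilities.
#' @export
km_at <- function(km, t) {
  stats::stepfun(km$time, c(1, km$surv), right = FALSE)(t)
}

#' Two-group log-rank test
#'
#' Standard observed-minus-expected statistic over the pooled event times
#' (via \code{survival::survdiff}), with a chi-square reference on
#' (groups - 1) degrees of freedom.
#'
#' @param time follow-up times.
#' @param event 1 = event, 0 = censored.
#' @param group group labels (2 or more non-empty groups).
#' @return list with \code{chisq}, \code{df}, \code{p}.
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(group)
  if (any(table(group) == 0L)) stop("every group must contain subjects")
  if (sum(event) == 0) stop("need at least one event")
  fit <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- length(fit$n) - 1L
  list(chisq = fit$chisq, df = df,
       p = stats::pchisq(fit$chisq, df, lower.tail = FALSE))
}

#' Cumulative incidence under competing risks
#'
#' Aalen-Johansen estimator of the cause-specific cumulative incidence
#' \eqn{CIF_k(t) = \sum_{t_i \le t} \hat S(t_i^-) d_{k,i}/n_i} with
#' \eqn{\hat S} the all-cause Kaplan-Meier (via \code{cmprsk::cuminc}).
#'
#' @param time follow-up times.
#' @param status 0 = censored, positive integers = cause codes.
#' @param group optional group labels.
#' @return list of class \code{"cuminc_curves"}: \code{curves} (per
#'   group/cause: time, est, var), \code{tests} (Gray's test table when
#'   groups are given) and the raw \code{cmprsk} object.
#' @export
cuminc_fit <- function(time, status, group = NULL) {
  if (!all(status %in% c(0L, 1L, 2L))) stop("unknown cause code in status")
  if (is.null(group)) group <- rep(1L, length(time))
  fit <- cmprsk::cuminc(ftime = time, fstatus = status, group = group,
                        cencode = 0)
  tests <- if ("Tests" %in% names(fit)) fit$Tests else NULL
  curves <- fit[setdiff(names(fit), "Tests")]
  out <- list(curves = curves, tests = tests, fit = fit)
  class(out) <- "cuminc_curves"
  out
}

#' Cumulative incidence at given times
#'
#' @param ci a \code{"cuminc_curves"} object.
#' @param curve curve name, \code{"<group> <cause>"} as produced by
#'   \code{cmprsk::cuminc} (e.g. \code{"1 1"}).
#' @param t times at which to evaluate.
#' @return numeric vector of cumulative incidences.
#' @export
cuminc_at <- function(ci, curve, t) {
  cc <- ci$curves[[curve]]
  if (is.null(cc)) stop("no such curve: ", curve)
  # cmprsk returns a fine grid; take the running estimate at or before t
  vapply(t, function(tt) {
    i <- which(cc$time <= tt)
    if (length(i) == 0L) 0 else cc$est[max(i)]
  }, numeric(1L))
}

#' Gray's test for equality of cumulative incidence
#'
#' K-sample test of the cause-specific subdistribution hazards (rho = 0
#' weights), for the cause of interest, with a 1-df chi-square reference for
#' two groups.
#'
#' @param time follow-up times.
#' @param status 0 = censored, positive integers = cause codes.
#' @param group group labels.
#' @param cause cause of interest (default 1 = disease death).
#' @return list with \code{stat}, \code{p}.
#' @export
gray_test <- function(time, status, group, cause = 1) {
  if (!any(status == cause)) stop("no events of the target cause")
  fit <- cmprsk::cuminc(ftime = time, fstatus = status, group = group,
                        cencode = 0)
  tests <- fit$Tests
  row <- match(as.character(cause), rownames(tests))
  if (is.na(row)) stop("no test available for cause ", cause)
  list(stat = tests[row, "stat"], p = tests[row, "pv"])
}

#' Multivariable Cox proportional-hazards fit
#'
#' Partial-likelihood maximization with Efron tie handling (via
#' \code{survival::coxph}); reports per-covariate log-hazard coefficients,
#' hazard ratios with Wald 95% confidence intervals, and Wald p-values.
#' Non-convergence or monotone likelihood (separation) is flagged rather
#' than silently returned.
#'
#' @param covariates data.frame of covariates (factors or numerics).
#' @param time follow-up times.
#' @param event 1 = event, 0 = censored.
#' @param ties tie-handling method, \code{"efron"} (default, lower bias) or
#'   \code{"breslow"}.
#' @return list of class \code{"cox_fit"}: \code{table} (data.frame with
#'   term, coef, se, hr, lower, upper, p), \code{converged}, \code{fit}.
#' @export
cox_fit <- function(covariates, time, event, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  covariates <- as.data.frame(covariates)
  if (any(vapply(covariates, function(v) length(unique(v)) == 1L, logical(1L))))
    stop("constant covariate")
  if (sum(event) < ncol(covariates))
    stop("fewer events than covariates")
  dat <- cbind(covariates, .time = time, .event = event)
  flagged <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(.time, .event) ~ . - .time - .event,
                    data = dat, ties = ties,
                    control = survival::coxph.control(eps = 1e-9, iter.max = 100)),
    warning = function(w) {
      if (grepl("infinite|converge|beta may be infinite", conditionMessage(w)))
        flagged <<- TRUE
      invokeRestart("muffleWarning")
    })
  co <- summary(fit)$coefficients
  tab <- data.frame(term = rownames(co),
                    coef = co[, "coef"],
                    se = co[, "se(coef)"],
                    hr = exp(co[, "coef"]),
                    lower = exp(co[, "coef"] - 1.96 * co[, "se(coef)"]),
                    upper = exp(co[, "coef"] + 1.96 * co[, "se(coef)"]),
                    p = co[, "Pr(>|z|)"],
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- list(table = tab, converged = !flagged, fit = fit)
  class(out) <- "cox_fit"
  out
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("Cox proportional-hazards fit (Efron ties)\n")
  tab <- x$table
  tab$`HR (95% CI)` <- sprintf("%.2f (%.2f-%.2f)", tab$hr, tab$lower, tab$upper)
  print(tab[, c("term", "coef", "se", "HR (95% CI)", "p")], row.names = FALSE)
  if (!x$converged) cat("warning: possible non-convergence or separation\n")
  invisible(x)
}
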