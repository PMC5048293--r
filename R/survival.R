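# Match a per-sample vector (groups / covariate) to a survival table,
# dropping zero-time censored records with a warning.
align_survival <- function(surv, x) {
  stopifnot(inherits(surv, "survival_table") || is.data.frame(surv))
  if (!is.null(names(x))) {
    miss <- setdiff(surv$sample, names(x))
    if (length(miss)) {
      stop("no covariate/group value for sample(s): ",
           paste(utils::head(miss, 5L), collapse = ", "))
    }
    x <- x[surv$sample]
  } else if (length(x) != nrow(surv)) {
    stop("covariate length does not match the survival table")
  }
  drop <- surv$time == 0 & surv$event == 0
  if (any(drop)) {
    warning(sum(drop), " subject(s) with time 0 and no event dropped")
    surv <- surv[!drop, , drop = FALSE]
    x <- x[!drop]
  }
  list(surv = surv, x = x)
}

#' Kaplan-Meier curves per group
#'
#' Product-limit estimate of survival within each group; tied event times
#' decrement the curve simultaneously.
#'
#' @param surv a `survival_table`.
#' @param groups group label per sample (named by sample id, or in table
#'   order). Every label must be non-missing.
#' @return named list of `km_curve` data.frames (columns time, n_risk,
#'   n_event, n_censor, surv), one per group.
#' @export
km_estimate <- function(surv, groups) {
  al <- align_survival(surv, groups)
  g <- as.character(al$x)
  if (anyNA(g)) stop("unknown (missing) group label in survival table")
  ev <- tapply(al$surv$event, g, sum)
  if (any(ev == 0)) {
    warning("group(s) without any observed event: ",
            paste(names(ev)[ev == 0], collapse = ", "))
  }
  out <- lapply(sort(unique(g)), function(lev) {
    sub <- al$surv[g == lev, , drop = FALSE]
    fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = sub)
    curve <- data.frame(time = fit$time, n_risk = fit$n.risk,
                        n_event = fit$n.event, n_censor = fit$n.censor,
                        surv = fit$surv)
    class(curve) <- c("km_curve", "data.frame")
    attr(curve, "group") <- lev
    curve
  })
  names(out) <- sort(unique(g))
  out
}

#' Log-rank test between two score groups
#'
#' Observed-minus-expected events over the shared risk sets, with the
#' hypergeometric variance; the statistic is chi-square with one degree of
#' freedom under the null of equal hazards.
#'
#' @param surv a `survival_table`.
#' @param groups two-level group label per sample.
#' @return list with `chi2`, `p`, `df`, and observed/expected event counts
#'   per group.
#' @export
logrank_test <- function(surv, groups) {
  al <- align_survival(surv, groups)
  g <- droplevels(as.factor(al$x))
  if (nlevels(g) != 2L) stop("log-rank test needs exactly two groups")
  if (any(table(g) == 0L)) stop("one group is empty")
  if (sum(al$surv$event) == 0) stop("no observed events")
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ g,
                            data = cbind(al$surv, g = g))
  list(chi2 = unname(sd_$chisq),
       p = stats::pchisq(sd_$chisq, df = 1, lower.tail = FALSE), df = 1L,
       observed = sd_$obs, expected = sd_$exp)
}

#' Cox proportional-hazards estimate for one covariate
#'
#' Partial-likelihood fit (Efron tie handling) of the hazard ratio for a
#' binary group indicator or a continuous score; Wald 95% confidence
#' interval on the log-hazard scale.
#'
#' @param surv a `survival_table`.
#' @param covariate per-sample covariate (named by sample id or in table
#'   order). Binary factors estimate the second-vs-first-level hazard ratio;
#'   continuous covariates the per-unit hazard ratio.
#' @return object of class `cox_result`: list with `coef`, `hr`, `ci`
#'   (length-2), `p_wald`, `p_lrt`, `n`, `n_events`.
#' @export
cox_hr <- function(surv, covariate) {
  al <- align_survival(surv, covariate)
  x <- al$x
  if (is.factor(x) || is.character(x) || is.logical(x)) {
    f <- droplevels(as.factor(x))
    if (nlevels(f) != 2L) stop("binary covariate must have exactly two levels")
    x <- as.numeric(f) - 1
  }
  if (length(unique(x)) < 2L) stop("constant covariate")
  n_events <- sum(al$surv$event)
  if (n_events < 10L) warning("fewer than 10 events; estimates are unstable")
  dat <- data.frame(time = al$surv$time, event = al$surv$event, x = x)
  fit <- survival::coxph(survival::Surv(time, event) ~ x, data = dat,
                         ties = "efron")
  if (is.na(fit$coefficients) || !is.finite(fit$coefficients)) {
    stop("Cox fit did not converge to a finite coefficient")
  }
  beta <- unname(fit$coefficients)
  se <- sqrt(unname(fit$var[1L, 1L]))
  lrt_p <- stats::pchisq(2 * (fit$loglik[2L] - fit$loglik[1L]), df = 1,
                         lower.tail = FALSE)
  structure(list(coef = beta, hr = exp(beta),
                 ci = exp(beta + c(-1, 1) * stats::qnorm(0.975) * se),
                 se = se, p_wald = 2 * stats::pnorm(-abs(beta / se)),
                 p_lrt = lrt_p, n = nrow(dat), n_events = n_events),
            class = "cox_result")
}

#' @export
print.cox_result <- function(x, ...) {
  cat(sprintf("Cox PH: HR = %.3f (95%% CI %.3f-%.3f), Wald p = %.3g\n",
              x$hr, x$ci[1L], x$ci[2L], x$p_wald))
  cat(sprintf("  n = %d, events = %d, log HR = %.4f (se %.4f)\n",
              x$n, x$n_events, x$coef, x$se))
  invisible(x)
}
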