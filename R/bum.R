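#' Fit a beta-uniform mixture to a p-value distribution
#'
#' Models the p-value density as f(p) = lambda + (1 - lambda) a p^(a-1) with
#' lambda in [0, 1] and a in (0, 1]: a uniform null component plus a
#' spike-near-zero Beta(a, 1) signal component. The maximum-likelihood fit
#' yields an upper bound on the null proportion,
#' pi0_upper = lambda + (1 - lambda) a, from which FDR thresholds follow
#' ([bum_significant()]).
#'
#' Optimization is box-constrained quasi-Newton (L-BFGS-B) on
#' logit-transformed (lambda, a), restarted from a deterministic grid of
#' interior starts; the best converged solution is kept. A fit with a at the
#' upper boundary (a -> 1) makes the density flat regardless of lambda and is
#' flagged as non-identifiable with pi0_upper = 1.
#'
#' @param pvalues numeric vector of p-values in (0, 1]; at least 50.
#' @return object of class `bum_fit`: list with `lambda`, `a`, `pi0_upper`,
#'   `loglik`, `n`, `boundary` (logical).
#' @export
fit_bum <- function(pvalues) {
  p <- as.numeric(pvalues)
  if (length(p) < 50L) stop("need at least 50 p-values to fit the mixture")
  if (any(p <= 0 | p > 1) || anyNA(p)) stop("p-values must lie in (0, 1]")
  lp <- log(p)
  negll <- function(theta) {
    lambda <- stats::plogis(theta[1L])
    a <- stats::plogis(theta[2L])
    f <- lambda + (1 - lambda) * a * exp((a - 1) * lp)
    -sum(log(pmax(f, 1e-300)))
  }
  starts <- expand.grid(l = stats::qlogis(c(0.25, 0.5, 0.75, 0.9)),
                        a = stats::qlogis(c(0.05, 0.2, 0.5, 0.8)))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- try(stats::optim(as.numeric(starts[i, ]), negll,
                            method = "L-BFGS-B", lower = c(-12, -12),
                            upper = c(12, 12)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("BUM optimization failed from every start")
  lambda <- stats::plogis(best$par[1L])
  a <- stats::plogis(best$par[2L])
  boundary <- a > 1 - 1e-4 || lambda > 1 - 1e-4
  pi0 <- if (a > 1 - 1e-4) 1 else lambda + (1 - lambda) * a
  structure(list(lambda = lambda, a = a, pi0_upper = min(1, pi0),
                 loglik = -best$value, n = length(p), boundary = boundary),
            class = "bum_fit")
}

#' @export
print.bum_fit <- function(x, ...) {
  cat(sprintf("Beta-uniform mixture fit on %d p-values\n", x$n))
  cat(sprintf("  lambda = %.4f, a = %.4f, pi0 upper bound = %.4f\n",
              x$lambda, x$a, x$pi0_upper))
  cat(sprintf("  log-likelihood = %.2f%s\n", x$loglik,
              if (x$boundary) "  [boundary / non-identifiable fit]" else ""))
  invisible(x)
}

#' Plug-in FDR of a p-value threshold under a BUM fit
#'
#' FDR(tau) = pi0_upper * tau / F(tau), where
#' F(tau) = lambda tau + (1 - lambda) tau^a is the fitted CDF.
#'
#' @param fit a `bum_fit`.
#' @param tau threshold(s) in (0, 1].
#' @return estimated FDR at each `tau`.
#' @export
bum_fdr <- function(fit, tau) {
  stopifnot(inherits(fit, "bum_fit"))
  if (any(tau <= 0 | tau > 1)) stop("tau must lie in (0, 1]")
  F_tau <- fit$lambda * tau + (1 - fit$lambda) * tau^fit$a
  fit$pi0_upper * tau / F_tau
}

#' Significance call at a target FDR under a BUM fit
#'
#' Finds the largest threshold tau with plug-in FDR(tau) <= `fdr_target`
#' (FDR(tau) is monotone increasing in tau for a < 1, so tau has a closed
#' form) and flags p-values at or below it.
#'
#' @param fit a `bum_fit`.
#' @param pvalues p-values to threshold.
#' @param fdr_target target FDR in (0, 1).
#' @return list with `tau`, `significant` (logical mask), `count`.
#' @export
bum_significant <- function(fit, pvalues, fdr_target) {
  stopifnot(inherits(fit, "bum_fit"))
  if (fdr_target <= 0 || fdr_target >= 1) stop("fdr_target must be in (0, 1)")
  lambda <- fit$lambda
  a <- fit$a
  pi0 <- fit$pi0_upper
  if (fit$boundary && fit$a > 1 - 1e-4) {
    # flat density: FDR(tau) = pi0 for every tau
    tau <- if (fdr_target >= pi0) 1 else 0
  } else if (fdr_target >= bum_fdr(fit, 1)) {
    tau <- 1
  } else {
    ratio <- (pi0 / fdr_target - lambda) / (1 - lambda)
    tau <- if (ratio <= 0) 1 else min(1, ratio^(1 / (a - 1)))
  }
  mask <- pvalues <= tau
  list(tau = tau, significant = mask, count = sum(mask))
}
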