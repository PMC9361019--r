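#' Truncate follow-up at a horizon
#'
#' Implements a fixed-horizon (default 5-year) survival analysis window.
#' The default administratively censors records beyond the horizon (time
#' set to the horizon, event to 0); `method = "exclude"` instead drops
#' longer-followed patients, which induces selection bias but is kept
#' available because the two readings of a "within 5 years" rule differ.
#'
#' @param clinical data.frame with `time_months` and `event` columns.
#' @param horizon months of follow-up retained (default 60).
#' @param method `"censor"` (default) or `"exclude"`.
#' @return The truncated data.frame.
#' @export
truncateFollowup <- function(clinical, horizon = 60,
                             method = c("censor", "exclude")) {
  method <- match.arg(method)
  if (horizon <= 0) stop("horizon must be > 0")
  if (method == "exclude")
    return(clinical[clinical$time_months <= horizon, , drop = FALSE])
  over <- clinical$time_months > horizon
  clinical$event[over] <- 0L
  clinical$time_months[over] <- horizon
  clinical
}

#' Kaplan-Meier survival estimate
#'
#' Product-limit estimator with right censoring and Greenwood standard
#' errors, via [survival::survfit()].
#'
#' @param clinical data.frame with `time_months` and `event`.
#' @return data.frame with columns `time`, `n_risk`, `n_event`,
#'   `survival`, `greenwood_se`, one row per distinct observed time.
#' @export
kmEstimate <- function(clinical) {
  if (!nrow(clinical)) stop("domain error: no records")
  if (any(clinical$time_months < 0))
    stop("domain error: negative survival time")
  fit <- survival::survfit(
    survival::Surv(time_months, event) ~ 1,
    data = clinical, conf.type = "none")
  data.frame(
    time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
    survival = fit$surv,
    greenwood_se = fit$std.err * fit$surv   # survfit reports SE of log S
  )
}

#' Log-rank test between two groups
#'
#' Standard observed-minus-expected log-rank chi-square (df = 1), via
#' [survival::survdiff()].
#'
#' @param clinical data.frame with `time_months` and `event`.
#' @param group per-record group labels, exactly two levels.
#' @return list with `chisq`, `df` and `p`.
#' @export
logrankTest <- function(clinical, group) {
  group <- droplevels(as.factor(group))
  if (nlevels(group) != 2L)
    stop("domain error: exactly two groups required")
  if (sum(clinical$event) < 1L)
    stop("domain error: at least one event required")
  dat <- data.frame(time = clinical$time_months,
                    event = clinical$event, group = group)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = dat)
  list(chisq = unname(sd$chisq), df = 1L,
       p = stats::pchisq(sd$chisq, df = 1L, lower.tail = FALSE))
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood Newton-Raphson fit with Efron tie handling (the
#' conventional default), via [survival::coxph()]; Wald confidence
#' intervals and p-values per covariate.
#'
#' @param clinical data.frame with `time_months`, `event` and the
#'   covariate columns.
#' @param covariates character vector of covariate column names.
#' @param ties tie-handling method (default `"efron"`).
#' @return data.frame with one row per model term: `term`, `beta`,
#'   `hazard_ratio`, `ci_lower`, `ci_upper`, `wald_p`; attributes
#'   `converged` and `ties`.
#' @export
coxFit <- function(clinical, covariates, ties = "efron") {
  miss <- setdiff(covariates, colnames(clinical))
  if (length(miss))
    stop("covariate(s) not in table: ", paste(miss, collapse = ", "))
  for (cv in covariates) {
    v <- clinical[[cv]]
    if (length(unique(v)) < 2L)
      stop("domain error: covariate '", cv, "' is constant")
  }
  fml <- stats::as.formula(paste(
    "survival::Surv(time_months, event) ~",
    paste(covariates, collapse = " + ")))
  fit <- survival::coxph(fml, data = clinical, ties = ties,
                         control = survival::coxph.control(eps = 1e-10))
  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  if (anyNA(beta) || any(abs(beta) > 15))
    stop("non-convergence / monotone likelihood for covariate(s): ",
         paste(names(beta)[is.na(beta) | abs(beta) > 15], collapse = ", "))
  out <- data.frame(
    term = names(beta), beta = unname(beta),
    hazard_ratio = exp(unname(beta)),
    ci_lower = exp(unname(beta - 1.96 * se)),
    ci_upper = exp(unname(beta + 1.96 * se)),
    wald_p = 2 * stats::pnorm(abs(unname(beta / se)), lower.tail = FALSE),
    stringsAsFactors = FALSE
  )
  attr(out, "converged") <- TRUE
  attr(out, "ties") <- ties
  attr(out, "scoreTest") <- unname(fit$score)
  out
}
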