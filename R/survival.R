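# Survival association of derived groups: Kaplan-Meier estimates, log-rank
# tests, and multivariate Cox proportional-hazards regression. The
# estimators are delegated to the survival package; this module fixes the
# input contract (per-sample time/event plus group labels) and the output
# shape used by the pipeline.

check_records <- function(time, event) {
  if (any(!is.finite(time)) || any(time <= 0)) stop("survival times must be > 0")
  if (anyNA(event)) stop("event indicators must be TRUE/FALSE")
}

#' Kaplan-Meier estimates per group
#'
#' Product-limit estimator via [survival::survfit()]. The curve starts at 1,
#' is non-increasing, and drops to 0 only if the largest time in a group is
#' an event.
#'
#' @param time Positive survival times (months).
#' @param event Logical event indicators (`TRUE` = event observed).
#' @param group Per-sample group labels (single group if omitted).
#' @return Data frame with `group`, `time`, `n_risk`, `n_event`, `surv`.
#' @export
km_estimate <- function(time, event, group = NULL) {
  check_records(time, event)
  group <- if (is.null(group)) rep("all", length(time)) else as.character(group)
  if (any(table(factor(group)) == 0L) || length(time) == 0L) stop("empty group")
  fits <- lapply(split(seq_along(time), group), function(idx) {
    f <- survival::survfit(survival::Surv(time[idx], event[idx]) ~ 1)
    data.frame(time = f$time, n_risk = f$n.risk, n_event = f$n.event,
               surv = f$surv)
  })
  out <- do.call(rbind, Map(cbind, group = names(fits), fits))
  rownames(out) <- NULL
  out
}

#' Log-rank test between groups
#'
#' Standard log-rank chi-square via [survival::survdiff()] (discrete
#' hypergeometric variance at tied event times), with the p-value from the
#' chi-square tail on `k - 1` degrees of freedom.
#'
#' @inheritParams km_estimate
#' @param group Per-sample group labels (at least two non-empty groups).
#' @return List with `statistic`, `df`, `p_value`, `n_events`.
#' @export
logrank_test <- function(time, event, group) {
  check_records(time, event)
  group <- factor(group)
  if (nlevels(droplevels(group)) < 2) stop("need at least two non-empty groups")
  if (sum(event) == 0L) stop("no events observed")
  sd <- survival::survdiff(survival::Surv(time, as.integer(event)) ~ group)
  df <- length(sd$n) - 1L
  list(statistic = unname(sd$chisq), df = df,
       p_value = pchisq(sd$chisq, df, lower.tail = FALSE),
       n_events = sum(event))
}

#' Multivariate Cox proportional-hazards regression
#'
#' Maximum partial-likelihood fit via [survival::coxph()] (Efron handling of
#' tied event times). Rows with missing covariates are dropped listwise;
#' zero-variance covariates and non-convergence are reported as errors, not
#' masked.
#'
#' @inheritParams km_estimate
#' @param covariates Data frame of covariates (one row per sample); factors
#'   and numerics are passed through to the model formula.
#' @param conf_level Confidence level for hazard-ratio intervals; default
#'   0.95.
#' @return Data frame with one row per model term: `term`, `hr`, `lower`,
#'   `upper`, `p_value`, plus attributes `n` (rows used) and `n_events`.
#' @export
cox_multivariate <- function(time, event, covariates, conf_level = 0.95) {
  check_records(time, event)
  covariates <- as.data.frame(covariates)
  keep <- complete.cases(covariates) & is.finite(time) & !is.na(event)
  covariates <- covariates[keep, , drop = FALSE]
  time <- time[keep]; event <- event[keep]
  for (nm in names(covariates)) {
    v <- covariates[[nm]]
    if ((is.numeric(v) && sd(v) == 0) ||
        (!is.numeric(v) && length(unique(v)) < 2))
      stop("zero-variance covariate: ", nm)
  }
  dat <- cbind(data.frame(.time = time, .event = as.integer(event)),
               covariates)
  fml <- stats::as.formula(paste("survival::Surv(.time, .event) ~",
                                 paste(names(covariates), collapse = " + ")))
  fit <- survival::coxph(fml, data = dat, ties = "efron")
  if (!is.null(fit$info) && any(grepl("did not converge", fit$info)))
    stop("Cox model did not converge")
  s <- summary(fit, conf.int = conf_level)
  out <- data.frame(term = rownames(s$coefficients),
                    hr = s$conf.int[, "exp(coef)"],
                    lower = s$conf.int[, 3],
                    upper = s$conf.int[, 4],
                    p_value = s$coefficients[, "Pr(>|z|)"])
  rownames(out) <- NULL
  attr(out, "n") <- s$n
  attr(out, "n_events") <- s$nevent
  out
}
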