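#' Validate a per-patient survival table
#'
#' @param records data.frame with columns `patient_id`, `os_time` (months),
#'   `event` (1 = death observed), `sex` (0/1 or factor), `distance`
#'   (continuous compositional-shift covariate) and optionally
#'   `time_to_relapse`, `relapse_event`.
#' @return The validated data.frame.
#' @export
survival_records <- function(records) {
  need <- c("patient_id", "os_time", "event", "distance")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("survival records missing: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  if (any(records$os_time <= 0)) stop("survival times must be positive", call. = FALSE)
  if (!all(records$event %in% c(0, 1))) stop("event must be 0/1", call. = FALSE)
  records
}

#' Mean-split Kaplan-Meier comparison of compositional shift
#'
#' Splits patients into high (`distance > mean`) and low (`<= mean`)
#' groups and compares overall survival with the two-group log-rank test.
#' Kaplan-Meier curve points per group are returned for plotting.
#'
#' @param records See [survival_records()].
#' @param split `"mean"` (default) or `"median"`.
#' @return List with `groups` (factor per patient), `chisq`, `p_value`,
#'   `split_value` and `km` (data.frame of time, surv, group).
#' @export
mean_split_logrank <- function(records, split = c("mean", "median")) {
  records <- survival_records(records)
  split <- match.arg(split)
  cut <- if (split == "mean") mean(records$distance) else median(records$distance)
  grp <- factor(ifelse(records$distance > cut, "high", "low"),
                levels = c("low", "high"))
  if (any(table(grp) < 2L)) {
    stop(sprintf("mean split at %.4g leaves a group with < 2 patients", cut),
         call. = FALSE)
  }
  sd <- survival::survdiff(survival::Surv(os_time, event) ~ grp, data =
                             cbind(records, grp = grp))
  p <- pchisq(sd$chisq, df = 1, lower.tail = FALSE)
  fit <- survival::survfit(survival::Surv(os_time, event) ~ grp,
                           data = cbind(records, grp = grp))
  km <- data.frame(time = fit$time, surv = fit$surv,
                   group = rep(sub("^grp=", "", names(fit$strata)), fit$strata))
  list(groups = grp, chisq = unname(sd$chisq), p_value = p,
       split_value = cut, km = km)
}

#' Cox proportional-hazards model of outcome on compositional shift
#'
#' Partial-likelihood fit (Efron tie handling) of the hazard on the
#' continuous Aitchison-distance covariate, adjusting for patient sex.
#' The hazard ratio is per unit distance; its p-value is the Wald test.
#'
#' @param records See [survival_records()].
#' @param outcome `"os"` (overall survival, default) or `"relapse"`
#'   (time to relapse; needs `time_to_relapse` and `relapse_event`).
#' @param covariates Adjustment covariates (default `"sex"`); may be
#'   empty.
#' @return List with `hazard_ratio`, `coef`, `se`, `p_value`, `ci_lower`,
#'   `ci_upper` (95%, on the HR scale), `n`, `n_events` and the fitted
#'   `model`.
#' @export
cox_fit <- function(records, outcome = c("os", "relapse"),
                    covariates = "sex") {
  records <- survival_records(records)
  outcome <- match.arg(outcome)
  if (outcome == "os") {
    time <- records$os_time; event <- records$event
  } else {
    if (is.null(records$time_to_relapse)) {
      stop("records carry no time_to_relapse", call. = FALSE)
    }
    time <- records$time_to_relapse
    event <- records$relapse_event %||% rep(1, nrow(records))
  }
  for (cv in covariates) {
    if (is.null(records[[cv]])) stop("missing covariate '", cv, "'", call. = FALSE)
    if (length(unique(records[[cv]])) < 2L) {
      stop("covariate '", cv, "' is constant; drop it from the model", call. = FALSE)
    }
  }
  if (length(unique(records$distance)) < 2L) {
    stop("distance covariate is constant", call. = FALSE)
  }
  df <- cbind(records, .time = time, .event = event)
  fml <- stats::reformulate(c("distance", covariates),
                            response = "survival::Surv(.time, .event)")
  fit <- survival::coxph(fml, data = df, ties = "efron")
  sm <- summary(fit)
  co <- sm$coefficients["distance", ]
  ci <- sm$conf.int["distance", ]
  list(hazard_ratio = unname(co["exp(coef)"]), coef = unname(co["coef"]),
       se = unname(co["se(coef)"]), p_value = unname(co["Pr(>|z|)"]),
       ci_lower = unname(ci["lower .95"]), ci_upper = unname(ci["upper .95"]),
       n = sm$n, n_events = sm$nevent, model = fit)
}
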