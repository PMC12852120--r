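validate_surv <- function(time, event) {
  if (anyNA(time) || anyNA(event)) {
    stop("missing survival times or events", call. = FALSE)
  }
  if (any(time <= 0)) stop("survival times must be positive", call. = FALSE)
  if (!all(event %in% c(0, 1))) {
    stop("event flags must be 0/1", call. = FALSE)
  }
  invisible(NULL)
}

#' Kaplan-Meier estimate
#'
#' Product-limit estimator with Greenwood variance, via
#' `survival::survfit`. Subjects censored at an event time remain in the
#' at-risk set at that time.
#'
#' @param time Positive event/censoring times.
#' @param event 0/1 event indicators.
#' @return Object of class `tcms_km`: data frame `curve` with `time`,
#'   `n_risk`, `n_event`, `surv`, `std_err` (Greenwood), plus `median`.
#' @export
km_estimate <- function(time, event) {
  validate_surv(time, event)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  curve <- data.frame(time = fit$time, n_risk = fit$n.risk,
                      n_event = fit$n.event, surv = fit$surv,
                      std_err = fit$surv * fit$std.err)
  med <- unname(stats::quantile(fit, probs = 0.5)$quantile)
  structure(list(curve = curve, median = med, n = length(time),
                 n_events = sum(event)),
            class = "tcms_km")
}

#' @export
print.tcms_km <- function(x, ...) {
  cat(sprintf("<tcms_km> n=%d, events=%d, median=%s\n", x$n, x$n_events,
              format(x$median)))
  invisible(x)
}

#' Log-rank test
#'
#' Standard (O - E)^2 / V log-rank over two or more groups via
#' `survival::survdiff`; K groups give K - 1 degrees of freedom.
#'
#' @inheritParams km_estimate
#' @param group Group labels (2+ non-empty groups).
#' @return List with `chisq`, `df`, `p`.
#' @export
logrank_test <- function(time, event, group) {
  validate_surv(time, event)
  group <- as.factor(group)
  tab <- table(group)
  if (length(tab) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(tab == 0)) {
    stop("group(s) with zero subjects: ",
         paste(names(tab)[tab == 0], collapse = ", "), call. = FALSE)
  }
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- length(tab) - 1
  list(chisq = unname(sd$chisq), df = df,
       p = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood fit with Breslow tie handling (switchable). Covariates
#' may be numeric or categorical; a zero-variance covariate is an error, and
#' non-convergence or monotone likelihood (complete separation) is flagged
#' rather than silently returned.
#'
#' @inheritParams km_estimate
#' @param covariates Data frame (or vector) of covariates, one row per
#'   subject.
#' @param ties Tie handling, `"breslow"` (default) or `"efron"`.
#' @return Object of class `tcms_cox`: `coef` (log hazard ratios), `se`,
#'   `p` (Wald), `loglik` (partial log-likelihood at the solution), `score`
#'   (score test statistic; equals the log-rank statistic for a single
#'   binary covariate without ties), `converged`, `flagged` (TRUE on
#'   suspect estimates).
#' @export
cox_fit <- function(time, event, covariates, ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  validate_surv(time, event)
  if (sum(event) < 1) stop("need at least one event", call. = FALSE)
  if (!is.data.frame(covariates)) {
    covariates <- data.frame(x = covariates)
  }
  for (nm in names(covariates)) {
    v <- covariates[[nm]]
    if (length(unique(v)) < 2) {
      stop("zero-variance covariate: ", nm, call. = FALSE)
    }
  }
  dat <- cbind(data.frame(.time = time, .event = event), covariates)
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(sprintf("`%s`", names(covariates)), collapse = " + ")))
  flagged <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = dat, ties = ties),
    warning = function(w) {
      flagged <<- TRUE
      invokeRestart("muffleWarning")
    })
  s <- summary(fit)
  structure(list(coef = stats::coef(fit),
                 se = s$coefficients[, "se(coef)"],
                 p = s$coefficients[, "Pr(>|z|)"],
                 loglik = fit$loglik[2],
                 score = unname(fit$score),
                 converged = is.finite(fit$loglik[2]) &&
                   all(is.finite(stats::coef(fit))),
                 flagged = flagged),
            class = "tcms_cox")
}

#' @export
print.tcms_cox <- function(x, ...) {
  cat("<tcms_cox>", if (x$flagged) "(flagged)" else "", "\n")
  print(data.frame(coef = x$coef, HR = exp(x$coef), se = x$se, p = x$p))
  invisible(x)
}

#' Hotspot-cohort exclusion filter
#'
#' Restricts a clinical table to the cohort used for hotspot survival
#' comparisons: drops AIS/MIA patients, and drops stage-I patients who are
#' relapse-free and received no adjuvant therapy. All other patients are
#' retained.
#'
#' @param clinical Data frame with columns `stage` (values like "AIS",
#'   "MIA", "I"/"IA"/"IB", "II", "III", "IV"), `relapse` (0/1), `adjuvant`
#'   (0/1).
#' @return The retained rows of `clinical`.
#' @export
hotspot_cohort_filter <- function(clinical) {
  need <- c("stage", "relapse", "adjuvant")
  miss <- setdiff(need, names(clinical))
  if (length(miss) > 0) {
    stop("clinical table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  stage <- toupper(as.character(clinical$stage))
  is_ais_mia <- stage %in% c("AIS", "MIA", "AIS/MIA")
  is_stage1 <- stage %in% c("I", "IA", "IB")
  drop <- is_ais_mia |
    (is_stage1 & clinical$relapse == 0 & clinical$adjuvant == 0)
  clinical[!drop, , drop = FALSE]
}

#' Median split of a numeric marker
#'
#' "High" is strictly above the cohort median; ties at the median go to
#' "low". A constant vector cannot be split and is an error.
#'
#' @param x Numeric vector.
#' @return Factor with levels `low`, `high`.
#' @export
median_split <- function(x) {
  if (anyNA(x)) stop("missing values in marker", call. = FALSE)
  if (length(unique(x)) < 2) {
    stop("constant marker: median split is degenerate", call. = FALSE)
  }
  med <- stats::median(x)
  f <- factor(ifelse(x > med, "high", "low"), levels = c("low", "high"))
  if (length(unique(f)) < 2) {
    stop("degenerate median split: all values on one side", call. = FALSE)
  }
  f
}

#' Grouped survival comparison
#'
#' The bundle used for every subtype / biomarker comparison: per endpoint, a
#' KM curve per group, the log-rank test over all groups, and a Cox fit with
#' the group as a factor covariate (hazard ratios relative to the first
#' level).
#'
#' @param clinical Data frame with `<endpoint>_time` and `<endpoint>_event`
#'   columns (e.g. `os_time`, `os_event`).
#' @param group Group labels, one per row (2+ non-empty groups), or a
#'   numeric vector to be median-split.
#' @param endpoints Endpoints to analyze (default `c("os", "rfs")`,
#'   restricted to those whose columns are present).
#' @return Named list per endpoint: `km` (list of `tcms_km` per group),
#'   `logrank`, `cox`, `groups` (the group factor).
#' @export
compare_groups <- function(clinical, group, endpoints = c("os", "rfs")) {
  if (is.numeric(group)) group <- median_split(group)
  group <- droplevels(as.factor(group))
  if (length(group) != nrow(clinical)) {
    stop("group labels and clinical rows differ in length", call. = FALSE)
  }
  if (nlevels(group) < 2) {
    stop("need at least 2 groups", call. = FALSE)
  }
  endpoints <- endpoints[paste0(endpoints, "_time") %in% names(clinical)]
  if (length(endpoints) == 0) {
    stop("no endpoint time/event columns found", call. = FALSE)
  }
  out <- list()
  for (ep in endpoints) {
    tm <- clinical[[paste0(ep, "_time")]]
    evn <- clinical[[paste0(ep, "_event")]]
    km <- lapply(levels(group), function(g) {
      km_estimate(tm[group == g], evn[group == g])
    })
    names(km) <- levels(group)
    out[[ep]] <- list(
      km = km,
      logrank = logrank_test(tm, evn, group),
      cox = cox_fit(tm, evn, data.frame(group = group)),
      groups = group
    )
  }
  out
}
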