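#' @title Trial endpoint statistics
#' @description Response-rate summaries with exact (Clopper-Pearson) or Wald
#'   confidence intervals, the Kaplan-Meier product-limit estimator with
#'   Greenwood standard errors, the two-group log-rank test, univariate Cox
#'   proportional-hazards regression for a binary biomarker (Breslow tie
#'   handling, Newton-Raphson on the partial likelihood), and adverse-event
#'   tabulation.
#' @name endpoints
NULL

clopper_pearson <- function(x, n, level) {
  a <- 1 - level
  lower <- if (x == 0) 0 else stats::qbeta(a / 2, x, n - x + 1)
  upper <- if (x == n) 1 else stats::qbeta(1 - a / 2, x + 1, n - x)
  c(lower, upper)
}

wald_ci <- function(x, n, level) {
  p <- x / n
  z <- stats::qnorm(1 - (1 - level) / 2)
  se <- sqrt(p * (1 - p) / n)
  c(max(0, p - z * se), min(1, p + z * se))
}

#' Response-rate summary
#'
#' Tabulates CR/PR/SD/PD over an intent-to-treat denominator (all records,
#' including those with missing response assessment) and reports the CR
#' rate and overall response rate (CR + PR) with confidence intervals.
#'
#' @param response Character vector of `CR`, `PR`, `SD`, `PD` or `NA`.
#' @param ci_method `"clopper_pearson"` (exact, default) or `"wald"`.
#' @param level Confidence level (default 0.95).
#' @return List of class `response_summary` with counts, `cr_rate`, `orr`,
#'   and `cr_ci` / `orr_ci` (2-vectors).
#' @export
response_rates <- function(response, ci_method = c("clopper_pearson",
                                                   "wald"),
                           level = 0.95) {
  ci_method <- match.arg(ci_method)
  n <- length(response)
  if (n == 0) stop("no records", call. = FALSE)
  bad <- setdiff(unique(response[!is.na(response)]), RESPONSES)
  if (length(bad)) {
    stop("unknown response label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  counts <- table(factor(response, levels = RESPONSES))
  n_cr <- as.integer(counts["CR"])
  n_resp <- n_cr + as.integer(counts["PR"])
  ci_fun <- switch(ci_method, clopper_pearson = clopper_pearson,
                   wald = wald_ci)
  structure(list(n = n,
                 n_cr = n_cr,
                 n_pr = as.integer(counts["PR"]),
                 n_sd = as.integer(counts["SD"]),
                 n_pd = as.integer(counts["PD"]),
                 n_missing = sum(is.na(response)),
                 cr_rate = n_cr / n,
                 orr = n_resp / n,
                 cr_ci = ci_fun(n_cr, n, level),
                 orr_ci = ci_fun(n_resp, n, level),
                 ci_method = ci_method, level = level),
            class = "response_summary")
}

#' @export
print.response_summary <- function(x, ...) {
  cat(sprintf("n = %d  CR %d (%.1f%%, %s CI %.1f-%.1f%%)  ORR %d (%.1f%%, CI %.1f-%.1f%%)\n",
              x$n, x$n_cr, 100 * x$cr_rate, x$ci_method,
              100 * x$cr_ci[1], 100 * x$cr_ci[2],
              x$n_cr + x$n_pr, 100 * x$orr,
              100 * x$orr_ci[1], 100 * x$orr_ci[2]))
  cat(sprintf("SD %d  PD %d  not assessed %d\n", x$n_sd, x$n_pd,
              x$n_missing))
  invisible(x)
}

#' Kaplan-Meier product-limit estimate
#'
#' S(t) = prod over event times t_i <= t of (1 - d_i / n_i), with the
#' Greenwood variance estimate
#' `S(t)^2 * sum d_i / (n_i (n_i - d_i))`.
#'
#' @param times Nonnegative follow-up times (months).
#' @param events Logical/0-1 event indicators (TRUE = event, FALSE =
#'   censored).
#' @return List of class `km_estimate`: `time` (distinct event times),
#'   `n_risk`, `n_event`, `survival`, `greenwood_se`.
#' @export
km_estimate <- function(times, events) {
  if (length(times) != length(events)) {
    stop("times and events differ in length", call. = FALSE)
  }
  if (any(times < 0)) stop("negative survival time", call. = FALSE)
  events <- as.logical(events)
  et <- sort(unique(times[events]))
  n_risk <- vapply(et, function(t) sum(times >= t), numeric(1))
  n_event <- vapply(et, function(t) sum(times == t & events), numeric(1))
  frac <- 1 - n_event / n_risk
  surv <- cumprod(frac)
  gw_terms <- n_event / (n_risk * (n_risk - n_event))
  gw_terms[!is.finite(gw_terms)] <- Inf  # everyone at risk died at this time
  se <- surv * sqrt(cumsum(gw_terms))
  se[!is.finite(se)] <- NA_real_
  structure(list(time = et, n_risk = n_risk, n_event = n_event,
                 survival = surv, greenwood_se = se,
                 n = length(times)),
            class = "km_estimate")
}

#' Survival probability at a time point
#'
#' Right-continuous step convention: the value at `t` includes any drop at
#' `t` itself. Before the first event the survival is 1.
#'
#' @param estimate A `km_estimate`.
#' @param t Time point (months).
#' @return Survival probability in `[0, 1]`.
#' @export
survival_at <- function(estimate, t) {
  idx <- findInterval(t, estimate$time)
  ifelse(idx == 0, 1, estimate$survival[pmax(idx, 1)])
}

#' Two-group log-rank test
#'
#' Standard observed-minus-expected statistic over the pooled event times
#' with the hypergeometric variance, referred to a 1-df chi-square. With no
#' events in either group the statistic is 0 and p = 1 by convention.
#'
#' @param times_a,events_a Follow-up and event indicator, group A.
#' @param times_b,events_b Same, group B.
#' @return List with `chi_square`, `p`, `observed` (2-vector),
#'   `expected` (2-vector).
#' @export
logrank_test <- function(times_a, events_a, times_b, events_b) {
  if (length(times_a) == 0 || length(times_b) == 0) {
    stop("both groups must be nonempty", call. = FALSE)
  }
  times <- c(times_a, times_b)
  events <- as.logical(c(events_a, events_b))
  group <- rep(c(0L, 1L), c(length(times_a), length(times_b)))
  et <- sort(unique(times[events]))
  if (length(et) == 0) {
    return(list(chi_square = 0, p = 1,
                observed = c(0, 0), expected = c(0, 0)))
  }
  o_a <- e_a <- v <- 0
  for (t in et) {
    at_risk <- times >= t
    n_t <- sum(at_risk)
    n_a <- sum(at_risk & group == 0L)
    d_t <- sum(times == t & events)
    d_a <- sum(times == t & events & group == 0L)
    o_a <- o_a + d_a
    e_a <- e_a + d_t * n_a / n_t
    if (n_t > 1) {
      v <- v + d_t * (n_a / n_t) * (1 - n_a / n_t) * (n_t - d_t) / (n_t - 1)
    }
  }
  total_d <- sum(events)
  chi <- if (v > 0) (o_a - e_a)^2 / v else 0
  list(chi_square = chi,
       p = stats::pchisq(chi, df = 1, lower.tail = FALSE),
       observed = c(o_a, total_d - o_a),
       expected = c(e_a, total_d - e_a))
}

# Breslow partial log-likelihood, score and information for a single
# binary covariate; beta is the log hazard ratio.
breslow_loglik <- function(beta, times, events, x) {
  et <- sort(unique(times[events]))
  ll <- score <- info <- 0
  for (t in et) {
    at_risk <- times >= t
    d_ids <- times == t & events
    d <- sum(d_ids)
    s0 <- sum(exp(beta * x[at_risk]))
    s1 <- sum(x[at_risk] * exp(beta * x[at_risk]))
    s2 <- s1  # x binary: x^2 = x
    ll <- ll + beta * sum(x[d_ids]) - d * log(s0)
    score <- score + sum(x[d_ids]) - d * s1 / s0
    info <- info + d * (s2 / s0 - (s1 / s0)^2)
  }
  list(loglik = ll, score = score, info = info)
}

#' Univariate Cox regression for a binary covariate
#'
#' Maximises the Breslow partial likelihood by Newton-Raphson (converged
#' when |score| < 1e-8) and reports the hazard ratio with a Wald confidence
#' interval and p-value. Monotone likelihoods (complete separation of
#' events by the covariate) are detected and returned as a bounded estimate
#' with a warning.
#'
#' @param times Follow-up times.
#' @param events Event indicators.
#' @param covariate Binary (0/1 or logical) covariate per patient.
#' @param level Confidence level (default 0.95).
#' @param max_iter Newton-Raphson iteration cap.
#' @return List of class `cox_result`: `hr`, `ci`, `log_hr`, `se_log_hr`,
#'   `wald_p`, `converged`, `monotone`.
#' @export
cox_univariate <- function(times, events, covariate, level = 0.95,
                           max_iter = 50L) {
  x <- as.numeric(covariate)
  events <- as.logical(events)
  if (length(unique(x)) < 2) {
    stop("covariate is constant", call. = FALSE)
  }
  if (!all(x %in% c(0, 1))) {
    stop("covariate must be binary (0/1)", call. = FALSE)
  }
  if (sum(events) == 0) stop("no events in the data", call. = FALSE)

  beta <- 0
  converged <- FALSE
  for (i in seq_len(max_iter)) {
    g <- breslow_loglik(beta, times, events, x)
    if (abs(g$score) < 1e-8) {
      converged <- TRUE
      break
    }
    if (g$info <= 0) break
    step <- g$score / g$info
    step <- max(min(step, 2), -2)  # damp huge first steps
    beta <- beta + step
  }
  monotone <- FALSE
  if (abs(beta) > 15) {  # events fully separated by the covariate
    monotone <- TRUE
    beta <- sign(beta) * 15
    warning("monotone partial likelihood: hazard ratio estimate is ",
            "unbounded; returning a bounded value", call. = FALSE)
  }
  g <- breslow_loglik(beta, times, events, x)
  se <- 1 / sqrt(g$info)
  z <- stats::qnorm(1 - (1 - level) / 2)
  wald_z <- beta / se
  structure(list(hr = exp(beta),
                 ci = exp(c(beta - z * se, beta + z * se)),
                 log_hr = beta, se_log_hr = se,
                 wald_p = 2 * stats::pnorm(-abs(wald_z)),
                 converged = converged, monotone = monotone,
                 level = level),
            class = "cox_result")
}

#' @export
print.cox_result <- function(x, ...) {
  cat(sprintf("HR %.2f (%.0f%% CI %.2f-%.2f), p = %.3g%s\n",
              x$hr, 100 * x$level, x$ci[1], x$ci[2], x$wald_p,
              if (x$monotone) " [monotone likelihood]" else ""))
  invisible(x)
}

#' Adverse-event tabulation
#'
#' Per-event any-grade and grade >= 3 counts and rates, overall and by arm.
#'
#' @param ae Data.frame with columns `sample_id`, `event` (AE label),
#'   `grade` (integer 1-5) and optionally `arm`.
#' @param n_patients Denominator for rates (number treated); defaults to
#'   the number of distinct sample_ids in `ae`. May carry named elements
#'   per arm (and `all`) when the treated counts exceed the patients with
#'   any recorded event.
#' @return Data.frame with columns `arm`, `event`, `n_any`, `rate_any`,
#'   `n_grade3plus`, `rate_grade3plus`; overall rows have arm `"all"`.
#' @export
safety_table <- function(ae, n_patients = NULL) {
  if (nrow(ae) == 0) {
    return(data.frame(arm = character(), event = character(),
                      n_any = integer(), rate_any = numeric(),
                      n_grade3plus = integer(),
                      rate_grade3plus = numeric(),
                      stringsAsFactors = FALSE))
  }
  if (!all(ae$grade %in% 1:5)) {
    stop("adverse-event grade outside 1-5", call. = FALSE)
  }
  if (is.null(n_patients)) n_patients <- length(unique(ae$sample_id))
  denom_for <- function(arm_label, fallback) {
    if (!is.null(names(n_patients)) && arm_label %in% names(n_patients)) {
      unname(n_patients[arm_label])
    } else if (is.null(names(n_patients))) {
      if (arm_label == "all") n_patients else fallback
    } else {
      fallback
    }
  }
  tab_one <- function(df, arm_label, denom) {
    evs <- sort(unique(df$event))
    do.call(rbind, lapply(evs, function(e) {
      sub <- df[df$event == e, ]
      n_any <- length(unique(sub$sample_id))
      n_g3 <- length(unique(sub$sample_id[sub$grade >= 3]))
      data.frame(arm = arm_label, event = e, n_any = n_any,
                 rate_any = n_any / denom, n_grade3plus = n_g3,
                 rate_grade3plus = n_g3 / denom, stringsAsFactors = FALSE)
    }))
  }
  out <- tab_one(ae, "all", denom_for("all", length(unique(ae$sample_id))))
  if (!is.null(ae$arm)) {
    for (a in sort(unique(ae$arm))) {
      sub <- ae[ae$arm == a, ]
      out <- rbind(out,
                   tab_one(sub, a,
                           denom_for(a, length(unique(sub$sample_id)))))
    }
  }
  rownames(out) <- NULL
  out
}
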