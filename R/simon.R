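#' @title Simon two-stage phase II designs
#' @description Exact binomial computation of Simon two-stage designs with
#'   futility-only stopping: enrol `n1` patients, stop if responses are at
#'   or below `r1`, otherwise enrol to `n` and reject the null response rate
#'   if total responses exceed `r`. The search enumerates every admissible
#'   `(r1, n1, r, n)` up to `n_max` and returns the optimal design
#'   (minimum expected sample size under the null) or the minimax design
#'   (minimum `n`, then expected size).
#' @name trial_design
NULL

#' Lower binomial tail probability
#'
#' P(X <= k) for X ~ Binomial(n, p), accumulated from point masses so the
#' same backbone serves the design enumeration and its brute-force checks.
#'
#' @param k Number of successes (0 <= k <= n); may be < 0, giving 0.
#' @param n Number of trials.
#' @param p Success probability.
#' @return Probability.
#' @export
binomial_tail <- function(k, n, p) {
  if (p < 0 || p > 1) stop("p must lie in [0, 1]", call. = FALSE)
  if (k < 0) return(0)
  if (k >= n) return(1)
  sum(stats::dbinom(0:k, n, p))
}

#' Operating characteristics of a two-stage design
#'
#' For a design `(r1, n1, r, n)` and true response probability `p`:
#' the probability of early termination `pet = P(X1 <= r1)`, the rejection
#' probability `sum over x1 > r1 of P(X1 = x1) P(X2 > r - x1)`, and the
#' expected sample size `n1 + (1 - pet) (n - n1)`.
#'
#' @param design List or `two_stage_design` with `r1`, `n1`, `r`, `n`.
#' @param p True per-patient response probability.
#' @return List with `pet`, `reject_prob`, `expected_n`.
#' @export
design_oc <- function(design, p) {
  r1 <- design$r1; n1 <- design$n1; r <- design$r; n <- design$n
  stopifnot(r1 < n1, n1 <= n, r1 <= r, r <= n)
  pet <- binomial_tail(r1, n1, p)
  n2 <- n - n1
  x1 <- seq.int(r1 + 1L, n1)
  # P(X2 > r - x1): whole second stage certain to clear the bound once
  # x1 > r; binomial_tail handles r - x1 >= n2 giving tail 0.
  p_clear <- vapply(x1, function(x) 1 - binomial_tail(r - x, n2, p),
                    numeric(1))
  reject <- sum(stats::dbinom(x1, n1, p) * p_clear)
  list(pet = pet, reject_prob = reject, expected_n = n1 + (1 - pet) * n2)
}

new_two_stage_design <- function(r1, n1, r, n, spec, criterion) {
  oc0 <- design_oc(list(r1 = r1, n1 = n1, r = r, n = n), spec$p0)
  oc1 <- design_oc(list(r1 = r1, n1 = n1, r = r, n = n), spec$p1)
  structure(list(r1 = r1, n1 = n1, r = r, n = n,
                 attained_alpha = oc0$reject_prob,
                 attained_power = oc1$reject_prob,
                 pet0 = oc0$pet, en0 = oc0$expected_n,
                 p0 = spec$p0, p1 = spec$p1,
                 alpha = spec$alpha, beta = spec$beta,
                 criterion = criterion),
            class = "two_stage_design")
}

#' @export
print.two_stage_design <- function(x, ...) {
  cat(sprintf("Simon two-stage %s design  (p0=%.3g, p1=%.3g, alpha=%.3g, beta=%.3g)\n",
              x$criterion, x$p0, x$p1, x$alpha, x$beta))
  cat(sprintf("  stage 1: n1 = %d, stop for futility if responses <= %d (continue needs >= %d)\n",
              x$n1, x$r1, x$r1 + 1L))
  cat(sprintf("  overall: n = %d, reject H0 if responses > %d\n", x$n, x$r))
  cat(sprintf("  attained alpha = %.4f, power = %.4f, PET(p0) = %.4f, E[N|p0] = %.2f\n",
              x$attained_alpha, x$attained_power, x$pet0, x$en0))
  invisible(x)
}

#' Search for a Simon two-stage design
#'
#' Exact enumeration over all `(r1, n1, r, n)` with `n <= n_max`,
#' `0 <= r1 < n1 < n`, `r1 <= r < n`, keeping designs whose attained
#' one-sided type I error is at most `alpha` and attained power at least
#' `1 - beta`. The `optimal` criterion minimises the expected sample size
#' under the null; `minimax` minimises `n` first. Ties fall to smaller
#' `n`, then smaller `n1` (reproducible).
#'
#' The enumeration prunes with exact inequalities: attained power never exceeds the
#' probability of passing stage 1 under `p1`, and `en0` never falls below
#' `n1`, so whole branches that cannot beat the incumbent are skipped. For
#' each admissible `(r1, n1, n)` the smallest final bound `r` meeting the
#' alpha constraint is located by binary search (the type I error is
#' decreasing in `r`); that `r` maximises power among alpha-admissible
#' bounds, so one power check settles feasibility.
#'
#' @param p0 Null (uninteresting) response probability.
#' @param p1 Alternative response probability, p1 > p0.
#' @param alpha One-sided type I error bound.
#' @param beta Type II error bound (power = 1 - beta).
#' @param criterion `"optimal"` or `"minimax"`.
#' @param n_max Largest total sample size searched (default 120).
#' @return A `two_stage_design`.
#' @export
simon_search <- function(p0, p1, alpha = 0.05, beta = 0.20,
                         criterion = c("optimal", "minimax"),
                         n_max = 120L) {
  criterion <- match.arg(criterion)
  if (!(p0 > 0 && p1 < 1 && p0 < p1)) {
    stop("need 0 < p0 < p1 < 1", call. = FALSE)
  }
  if (!(alpha > 0 && alpha < 0.5 && beta > 0 && beta < 0.5)) {
    stop("need alpha and beta in (0, 0.5)", call. = FALSE)
  }
  spec <- list(p0 = p0, p1 = p1, alpha = alpha, beta = beta)

  best <- NULL
  best_key <- c(Inf, Inf, Inf)
  for (n in 2:n_max) {
    if (criterion == "minimax" && n > best_key[1]) break
    for (n1 in seq_len(n - 1)) {
      if (criterion == "optimal" && n1 > best_key[1]) break  # en0 >= n1
      n2 <- n - n1
      for (r1 in 0:(n1 - 1)) {
        pet1 <- stats::pbinom(r1, n1, p1)
        if (1 - pet1 < 1 - beta) break  # power <= P(continue | p1); worse for larger r1
        pet0 <- stats::pbinom(r1, n1, p0)
        en0 <- n1 + (1 - pet0) * n2
        if (criterion == "optimal" && en0 > best_key[1]) next
        x1 <- seq.int(r1 + 1L, n1)
        b0 <- stats::dbinom(x1, n1, p0)
        b1 <- stats::dbinom(x1, n1, p1)
        alpha_at <- function(r) sum(b0 * (1 - stats::pbinom(r - x1, n2, p0)))
        lo <- r1
        hi <- n - 1L
        if (alpha_at(lo) > alpha) {
          if (alpha_at(hi) > alpha) next
          while (lo < hi) {  # smallest r with type I error <= alpha
            mid <- (lo + hi) %/% 2L
            if (alpha_at(mid) <= alpha) hi <- mid else lo <- mid + 1L
          }
        }
        r <- lo
        pw <- sum(b1 * (1 - stats::pbinom(r - x1, n2, p1)))
        if (pw < 1 - beta) next
        key <- switch(criterion,
                      optimal = c(en0, n, n1),
                      minimax = c(n, en0, n1))
        better <- key[1] < best_key[1] ||
          (key[1] == best_key[1] && key[2] < best_key[2]) ||
          (key[1] == best_key[1] && key[2] == best_key[2] &&
           key[3] < best_key[3])
        if (better) {
          best <- list(r1 = r1, n1 = n1, r = r, n = n)
          best_key <- key
        }
      }
    }
  }
  if (is.null(best)) {
    stop("no feasible two-stage design with n <= ", n_max,
         " meets alpha = ", alpha, " and power = ", 1 - beta, call. = FALSE)
  }
  new_two_stage_design(best$r1, best$n1, best$r, best$n, spec, criterion)
}

#' Stage-1 continue/stop decision
#'
#' Continue to stage 2 exactly when stage-1 responses exceed the futility
#' bound `r1`; for the trial's design (`r1 = 8`, `n1 = 23`) this is the
#' "at least 9 responses to proceed" rule.
#'
#' @param design A `two_stage_design` (or list with `r1`, `n1`).
#' @param responses Observed stage-1 response count.
#' @return `"continue"` or `"stop_futility"`.
#' @export
stage1_decision <- function(design, responses) {
  if (responses < 0 || responses > design$n1) {
    stop("responses must lie in [0, n1]", call. = FALSE)
  }
  if (responses > design$r1) "continue" else "stop_futility"
}

#' Inflate an evaluable sample size for dropout
#'
#' Smallest enrolment `m` with `m (1 - dropout_rate) >= n_evaluable`,
#' i.e. `ceiling(n_evaluable / (1 - dropout_rate))`.
#'
#' @param n_evaluable Required evaluable patients.
#' @param dropout_rate Anticipated dropout proportion in `[0, 1)`.
#' @return Integer enrolment target.
#' @export
inflate_for_dropout <- function(n_evaluable, dropout_rate) {
  if (dropout_rate < 0 || dropout_rate >= 1) {
    stop("dropout_rate must lie in [0, 1)", call. = FALSE)
  }
  as.integer(ceiling(n_evaluable / (1 - dropout_rate)))
}
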