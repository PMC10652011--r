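#' Kaplan-Meier product-limit estimate
#'
#' `S(t) = prod_{t_i <= t} (1 - d_i / n_i)` over distinct event times, with
#' the standard tie convention that events precede censoring at the same
#' time (subjects censored at `t` still count as at risk at `t`).
#' Right-continuous, non-increasing, `S(0) = 1`.
#'
#' @param time non-negative event/censoring times.
#' @param event logical or 0/1; `TRUE` when the event was observed.
#' @return data.frame with one row per distinct event time: `time`,
#'   `n_risk`, `n_event`, `surv`.
#' @export
kmEstimate <- function(time, event) {
  if (any(time < 0)) stop("negative survival time")
  stopifnot(length(time) == length(event))
  event <- as.logical(event)
  if (!length(time)) stop("need at least 1 subject")
  et <- sort(unique(time[event]))
  if (!length(et))
    return(data.frame(time = numeric(0), n_risk = integer(0),
                      n_event = integer(0), surv = numeric(0)))
  nRisk <- vapply(et, function(t) sum(time >= t), integer(1))
  nEvent <- vapply(et, function(t) sum(time == t & event), integer(1))
  surv <- cumprod(1 - nEvent / nRisk)
  data.frame(time = et, n_risk = nRisk, n_event = nEvent, surv = surv)
}

#' Evaluate a KM estimate at arbitrary times
#'
#' @param km data.frame from [kmEstimate()].
#' @param t times at which to evaluate the step function.
#' @return survival probabilities (1 before the first event).
#' @export
kmSurvivalAt <- function(km, t) {
  vapply(t, function(tt) {
    i <- which(km$time <= tt)
    if (!length(i)) 1 else km$surv[max(i)]
  }, numeric(1))
}

#' Two-group log-rank test
#'
#' Standard observed-minus-expected log-rank chi-square with 1 degree of
#' freedom over the pooled distinct event times, with the hypergeometric
#' variance; two-sided p value. Symmetric in group order.
#'
#' @param timeA,eventA times and event indicators for group A.
#' @param timeB,eventB times and event indicators for group B.
#' @return list with `chi2`, `p`, `observed` and `expected` (length-2, A
#'   then B).
#' @export
logrankTest <- function(timeA, eventA, timeB, eventB) {
  if (!length(timeA) || !length(timeB)) stop("both groups must be non-empty")
  eventA <- as.logical(eventA); eventB <- as.logical(eventB)
  if (!any(eventA) && !any(eventB)) stop("no events in either group")
  time <- c(timeA, timeB)
  event <- c(eventA, eventB)
  grp <- rep(c(1L, 2L), c(length(timeA), length(timeB)))
  et <- sort(unique(time[event]))
  oA <- eA <- v <- 0
  for (t in et) {
    atRisk <- time >= t
    n <- sum(atRisk)
    n1 <- sum(atRisk & grp == 1L)
    d <- sum(time == t & event)
    d1 <- sum(time == t & event & grp == 1L)
    oA <- oA + d1
    eA <- eA + d * n1 / n
    if (n > 1)
      v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chi2 <- if (v > 0) (oA - eA)^2 / v else 0
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  totE <- sum(event)
  list(chi2 = chi2, p = p,
       observed = c(oA, totE - oA),
       expected = c(eA, totE - eA))
}
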