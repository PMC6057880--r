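#' Tumor-doubling progression event for one growth curve
#'
#' Progression-free survival in a PDX trial is anchored on tumor doubling
#' time: the event occurs at the first measured day on which the volume
#' reaches at least twice the treatment-start baseline (the measurement
#' closest to day 0, ties toward the earlier day). Curves that never
#' double by the horizon are censored at the horizon.
#'
#' @param curve growth-curve data.frame with `day` and `volume_mm3`.
#' @param horizon_days observation horizon in days (default 18).
#' @return list with `time_days`, `event` (logical), `baseline_mm3`.
#' @examples
#' cv <- data.frame(day = c(0, 7, 14), volume_mm3 = c(100, 150, 210))
#' doubling_event(cv)  # event at day 14
#' @export
doubling_event <- function(curve, horizon_days = 18) {
  stop_if_not_scalar_number(horizon_days, "horizon_days")
  if (nrow(curve) < 1L) stop("empty growth curve: no baseline", call. = FALSE)
  o <- order(curve$day)
  d <- curve$day[o]
  v <- curve$volume_mm3[o]
  b <- order(abs(d), d)[1L]
  v0 <- v[b]
  hit <- which(d > d[b] & d <= horizon_days & v >= 2 * v0)
  if (length(hit)) {
    list(time_days = d[hit[1L]], event = TRUE, baseline_mm3 = v0)
  } else {
    list(time_days = horizon_days, event = FALSE, baseline_mm3 = v0)
  }
}

#' Doubling-time survival records for a cohort
#'
#' Applies [doubling_event()] to one arm of every model and attaches the
#' model's response group.
#'
#' @param curves curve table from [growth_curves()].
#' @param calls classified response calls ([response_calls()]); invalid
#'   calls are skipped.
#' @param arm which arm's curves define the event (default `"treated"`).
#' @param horizon_days observation horizon.
#' @return data.frame with columns `model_id`, `time_days`, `event`,
#'   `group`.
#' @export
doubling_events <- function(curves, calls, arm = "treated",
                            horizon_days = 18) {
  calls <- calls[calls$valid %in% TRUE, , drop = FALSE]
  rows <- lapply(seq_len(nrow(calls)), function(i) {
    m <- calls$model_id[i]
    cv <- curves[curves$model_id == m & curves$arm == arm, , drop = FALSE]
    ev <- doubling_event(cv, horizon_days)
    data.frame(model_id = m, time_days = ev$time_days, event = ev$event,
               group = calls$group[i], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Kaplan-Meier product-limit estimate
#'
#' Product-limit estimator \eqn{S(t) = \prod_{t_i \le t} (1 - d_i/n_i)}
#' over the pooled event times, with the standard convention that events
#' precede censoring at tied times. Computed with
#' [survival::survfit()].
#'
#' @param time_days non-negative event/censoring times.
#' @param event logical (or 0/1) event indicator; `FALSE` = censored.
#' @return data.frame with one row per distinct observed time: `time`,
#'   `n_risk`, `n_event`, `n_censor`, `surv`.
#' @export
km_fit <- function(time_days, event) {
  if (length(time_days) < 1L) stop("need at least one record", call. = FALSE)
  if (any(time_days < 0)) stop("negative survival times", call. = FALSE)
  event <- as.logical(event)
  if (anyNA(time_days) || anyNA(event)) {
    stop("missing values in survival records", call. = FALSE)
  }
  fit <- survival::survfit(survival::Surv(time_days, event) ~ 1)
  data.frame(
    time = fit$time,
    n_risk = fit$n.risk,
    n_event = fit$n.event,
    n_censor = fit$n.censor,
    surv = fit$surv
  )
}

#' Log-rank (Mantel-Cox) comparison of survival between groups
#'
#' k-sample log-rank test on doubling-time survival records, with
#' `df = k - 1` and the p-value from the upper chi-squared tail.
#' Computed with [survival::survdiff()].
#'
#' @param time_days,event as in [km_fit()].
#' @param group group label per record; at least two non-empty groups.
#' @return list with `chisq`, `df`, `p`, and the per-group record
#'   counts `n`.
#' @export
logrank_test <- function(time_days, event, group) {
  if (any(time_days < 0)) stop("negative survival times", call. = FALSE)
  group <- factor(group)
  group <- droplevels(group)
  if (nlevels(group) < 2L) {
    stop("log-rank test needs at least two non-empty groups", call. = FALSE)
  }
  fit <- survival::survdiff(
    survival::Surv(time_days, as.logical(event)) ~ group
  )
  df <- nlevels(group) - 1L
  list(
    chisq = unname(fit$chisq),
    df = df,
    p = pchisq(fit$chisq, df, lower.tail = FALSE),
    n = setNames(as.integer(fit$n), levels(group))
  )
}
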