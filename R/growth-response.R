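#' Caliper tumor volume
#'
#' Converts the two caliper diameters of a subcutaneous xenograft to a
#' volume using the standard ellipsoid approximation
#' \deqn{V = \mathrm{shorter}^2 \times \mathrm{longer} / 2}
#' with diameters in mm and the volume in mm^3.
#'
#' @param shorter_mm shorter tumor diameter in mm (> 0). Vectorized.
#' @param longer_mm longer tumor diameter in mm (>= `shorter_mm`).
#' @return Numeric vector of tumor volumes in mm^3.
#' @examples
#' tumor_volume(5, 10)  # 125
#' tumor_volume(6, 8)   # 144
#' @export
tumor_volume <- function(shorter_mm, longer_mm) {
  if (length(shorter_mm) != length(longer_mm)) {
    stop("`shorter_mm` and `longer_mm` must have the same length", call. = FALSE)
  }
  if (!is.numeric(shorter_mm) || !is.numeric(longer_mm) ||
      anyNA(shorter_mm) || anyNA(longer_mm)) {
    stop("diameters must be numeric and non-missing", call. = FALSE)
  }
  if (any(shorter_mm <= 0)) {
    stop("diameters must be positive", call. = FALSE)
  }
  if (any(longer_mm < shorter_mm)) {
    stop("`longer_mm` must be >= `shorter_mm` (diameter order violated)",
         call. = FALSE)
  }
  shorter_mm^2 * longer_mm / 2
}

#' Build growth curves from caliper measurements
#'
#' Converts a measurement table (one row per mouse per day, with the two
#' caliper diameters) into per-mouse growth curves of (day, volume).
#'
#' @param measurements data.frame with columns `model_id`, `mouse_id`,
#'   `arm` (`"treated"`, `"vehicle"` or `"excluded"`), `day`,
#'   `shorter_mm`, `longer_mm`.
#' @return data.frame with columns `model_id`, `mouse_id`, `arm`, `day`,
#'   `volume_mm3`, ordered by model, arm and day.
#' @export
growth_curves <- function(measurements) {
  required <- c("model_id", "mouse_id", "arm", "day", "shorter_mm", "longer_mm")
  missing <- setdiff(required, names(measurements))
  if (length(missing)) {
    stop("measurement table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bad_arm <- setdiff(unique(measurements$arm),
                     c("treated", "vehicle", "excluded"))
  if (length(bad_arm)) {
    stop("unknown arm label(s): ", paste(bad_arm, collapse = ", "),
         call. = FALSE)
  }
  out <- data.frame(
    model_id = as.character(measurements$model_id),
    mouse_id = as.character(measurements$mouse_id),
    arm = as.character(measurements$arm),
    day = as.numeric(measurements$day),
    volume_mm3 = tumor_volume(measurements$shorter_mm, measurements$longer_mm),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$model_id, out$arm, out$day), , drop = FALSE]
  dup <- duplicated(out[, c("model_id", "mouse_id", "day")])
  if (any(dup)) {
    stop("duplicate measurement for the same mouse and day", call. = FALSE)
  }
  rownames(out) <- NULL
  out
}

# Start/end volumes for one arm of one model: start = measurement closest
# to day 0 (ties broken toward the earlier day), end = last measurement
# with day <= horizon.
curve_endpoints <- function(curve, horizon) {
  if (nrow(curve) < 1L) stop("empty growth curve", call. = FALSE)
  d <- curve$day
  start_idx <- order(abs(d), d)[1L]
  in_window <- which(d <= horizon)
  if (!length(in_window)) {
    stop("no measurement at or before the horizon", call. = FALSE)
  }
  end_idx <- in_window[which.max(d[in_window])]
  list(
    v0 = curve$volume_mm3[start_idx], day0 = d[start_idx],
    vi = curve$volume_mm3[end_idx], dayi = d[end_idx]
  )
}

#' Treated-over-control growth ratio
#'
#' The T/C score of a 1x1x1 PDX model:
#' \deqn{T/C(\%) = 100 (T_i - T_0) / (C_i - C_0)}
#' where subscript 0 is the tumor volume at treatment start (measurement
#' closest to day 0) and subscript i at end of treatment (each arm's last
#' measurement at or before `horizon_days`). The score is unitless and
#' invariant to any common rescaling of volumes.
#'
#' A vehicle tumor that failed to grow (`C_i - C_0 <= 0`) makes the ratio
#' meaningless; such models are returned with `valid = FALSE` and no
#' score rather than a sign-flipped number.
#'
#' @param treated,control growth-curve data.frames for one model's
#'   treated and vehicle arms, with columns `day` and `volume_mm3`.
#' @param horizon_days end-of-treatment horizon in days (default 18).
#' @return list with `tc_percent` (numeric, `NA` when invalid) and
#'   `valid` (logical).
#' @export
tc_ratio <- function(treated, control, horizon_days = 18) {
  stop_if_not_scalar_number(horizon_days, "horizon_days")
  tr <- curve_endpoints(treated, horizon_days)
  ct <- curve_endpoints(control, horizon_days)
  denom <- ct$vi - ct$v0
  if (denom <= 0) {
    return(list(tc_percent = NA_real_, valid = FALSE))
  }
  list(tc_percent = 100 * (tr$vi - tr$v0) / denom, valid = TRUE)
}

#' Classify a T/C score into a response group
#'
#' The three response groups partition the real line with no gaps:
#' progression for T/C > 50, suppression for 0 <= T/C <= 50 (both
#' boundaries belong to suppression), regression for T/C < 0.
#'
#' @param tc_percent numeric vector of T/C scores in percent.
#' @return character vector with values `"progression"`, `"suppression"`
#'   or `"regression"`.
#' @examples
#' classify_response(c(120, 50, 0, -0.5))
#' @export
classify_response <- function(tc_percent) {
  if (!is.numeric(tc_percent) || any(!is.finite(tc_percent))) {
    stop("`tc_percent` must be finite numeric (no NA/NaN)", call. = FALSE)
  }
  ifelse(tc_percent > 50, "progression",
         ifelse(tc_percent >= 0, "suppression", "regression"))
}

#' Score and classify every model of a trial
#'
#' Runs [tc_ratio()] and [classify_response()] on each model's
#' treated/vehicle curve pair. Models whose vehicle tumor did not grow
#' get `valid = FALSE` and no group.
#'
#' @param measurements measurement table (see [growth_curves()]), or a
#'   curve table already carrying a `volume_mm3` column.
#' @param horizon_days end-of-treatment horizon in days.
#' @return data.frame with columns `model_id`, `tc_percent`, `group`,
#'   `valid`.
#' @export
response_calls <- function(measurements, horizon_days = 18) {
  curves <- if ("volume_mm3" %in% names(measurements)) measurements
            else growth_curves(measurements)
  models <- unique(curves$model_id)
  rows <- lapply(models, function(m) {
    tr <- curves[curves$model_id == m & curves$arm == "treated", , drop = FALSE]
    ct <- curves[curves$model_id == m & curves$arm == "vehicle", , drop = FALSE]
    if (!nrow(tr) || !nrow(ct)) {
      stop(sprintf("model %s lacks a treated or vehicle arm", m), call. = FALSE)
    }
    tc <- tc_ratio(tr, ct, horizon_days)
    data.frame(
      model_id = m,
      tc_percent = tc$tc_percent,
      group = if (tc$valid) classify_response(tc$tc_percent) else NA_character_,
      valid = tc$valid,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Average growth speed of a tumor
#'
#' Secant slope of the volume curve over the observation window,
#' `(V_end - V_start) / (day_end - day_start)`, in mm^3/day. With
#' `method = "regression"` an ordinary least-squares slope of volume on
#' day is returned instead.
#'
#' @param curve growth-curve data.frame with `day` and `volume_mm3`.
#' @param method `"secant"` (default) or `"regression"`.
#' @return growth speed in mm^3/day.
#' @export
growth_speed <- function(curve, method = c("secant", "regression")) {
  method <- match.arg(method)
  if (nrow(curve) < 2L) {
    stop("growth speed needs at least two measurements", call. = FALSE)
  }
  o <- order(curve$day)
  d <- curve$day[o]
  v <- curve$volume_mm3[o]
  if (method == "secant") {
    (v[length(v)] - v[1L]) / (d[length(d)] - d[1L])
  } else {
    unname(stats::coef(stats::lm(v ~ d))[2L])
  }
}

#' Waterfall table of response calls
#'
#' Valid calls sorted by descending T/C score, each tagged with its
#' response group — the tabular form of the trial's waterfall plot.
#' Invalid calls (undefined T/C) are dropped with a warning.
#'
#' @param calls data.frame from [response_calls()].
#' @return data.frame with columns `model_id`, `tc_percent`, `group`,
#'   ordered by descending `tc_percent`.
#' @export
waterfall <- function(calls) {
  keep <- calls[calls$valid %in% TRUE, , drop = FALSE]
  if (nrow(keep) < nrow(calls)) {
    warning(sprintf("%d model(s) with undefined T/C dropped from waterfall",
                    nrow(calls) - nrow(keep)), call. = FALSE)
  }
  keep <- keep[order(-keep$tc_percent), c("model_id", "tc_percent", "group")]
  rownames(keep) <- NULL
  keep
}

#' Response-group counts and percentages
#'
#' Tabulates group membership and reports percentages rounded half away
#' from zero to the nearest integer (the reporting convention under which
#' 8, 13 and 10 of 31 models read 26\%, 42\% and 32\%).
#'
#' @param groups character vector of response-group labels (e.g. the
#'   `group` column of [response_calls()] output, valid calls only).
#' @return data.frame with columns `group`, `n`, `percent`, ordered
#'   progression, suppression, regression.
#' @export
response_summary <- function(groups) {
  groups <- groups[!is.na(groups)]
  bad <- setdiff(unique(groups), RESPONSE_GROUPS)
  if (length(bad)) {
    stop("unknown response group(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  n <- vapply(RESPONSE_GROUPS, function(g) sum(groups == g), integer(1))
  data.frame(
    group = RESPONSE_GROUPS,
    n = as.integer(n),
    percent = round_half_up(100 * n / sum(n)),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Per-group growth-speed summary
#'
#' Mean and standard error of the mean (SEM) of growth speed per response
#' group and arm, as displayed in group growth comparisons. SEM is
#' reported as `NA` for groups with fewer than two models.
#'
#' @param calls classified response calls ([response_calls()]).
#' @param curves curve table from [growth_curves()].
#' @param horizon_days restrict curves to measurements at or before this
#'   day before computing speeds.
#' @return data.frame with columns `group`, `arm`, `n`, `mean_speed`,
#'   `sem_speed` (mm^3/day).
#' @export
summarize_groups <- function(calls, curves, horizon_days = 18) {
  calls <- calls[calls$valid %in% TRUE, , drop = FALSE]
  speeds <- group_speeds(calls, curves, horizon_days)
  rows <- list()
  for (g in intersect(RESPONSE_GROUPS, unique(speeds$group))) {
    for (a in c("treated", "vehicle")) {
      s <- speeds$speed[speeds$group == g & speeds$arm == a]
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, arm = a, n = length(s),
        mean_speed = mean(s),
        sem_speed = if (length(s) >= 2L) sd(s) / sqrt(length(s)) else NA_real_,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Per-model, per-arm growth speeds for classified models.
group_speeds <- function(calls, curves, horizon_days = 18) {
  rows <- list()
  for (i in seq_len(nrow(calls))) {
    m <- calls$model_id[i]
    for (a in c("treated", "vehicle")) {
      cv <- curves[curves$model_id == m & curves$arm == a &
                     curves$day <= horizon_days, , drop = FALSE]
      rows[[length(rows) + 1L]] <- data.frame(
        model_id = m, group = calls$group[i], arm = a,
        speed = growth_speed(cv), stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Compare vehicle-arm growth speeds of two response groups
#'
#' Two-sided two-sample Student's t-test of per-model growth speeds
#' between two response groups, by default on the vehicle arm (the
#' comparison asking whether intrinsically faster-growing tumors cluster
#' in a particular response group).
#'
#' @param calls,curves as in [summarize_groups()].
#' @param group_a,group_b the two response groups to compare.
#' @param arm `"vehicle"` (default) or `"treated"`.
#' @param horizon_days see [summarize_groups()].
#' @return list with `t`, `df`, `p`, and per-group `n`.
#' @export
compare_group_speeds <- function(calls, curves, group_a, group_b,
                                 arm = "vehicle", horizon_days = 18) {
  calls <- calls[calls$valid %in% TRUE, , drop = FALSE]
  speeds <- group_speeds(calls, curves, horizon_days)
  x <- speeds$speed[speeds$group == group_a & speeds$arm == arm]
  y <- speeds$speed[speeds$group == group_b & speeds$arm == arm]
  if (length(x) < 2L || length(y) < 2L) {
    stop("both groups need at least two models for a t-test", call. = FALSE)
  }
  fit <- t.test(x, y, var.equal = TRUE)
  list(t = unname(fit$statistic), df = unname(fit$parameter),
       p = fit$p.value, n_a = length(x), n_b = length(y))
}
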