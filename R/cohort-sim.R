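#' Specification of a synthetic PDX trial cohort
#'
#' Bundles the design constants of a 1x1x1 xenograft trial and the
#' distributions the growth simulator draws from. Defaults reproduce the
#' structure of a 31-model trial: inclusion at 50--100 mm^3, an 18-day
#' treatment horizon with thrice-weekly caliper readings, log-normal
#' exponential growth rates, and a three-component treatment-effect
#' mixture whose weights target 10 progression, 13 suppression and 8
#' regression models.
#'
#' Each mixture component is parameterised by the response it produces:
#' progression and suppression components draw a target analytic T/C
#' score (uniform on `tc_progression` / `tc_suppression`), the regression
#' component draws the treated tumor's end/start volume ratio (uniform on
#' `regression_shrink`, < 1 so the analytic T/C is negative). The treated
#' growth rate is then solved from the target, so a model's intended
#' class is consistent with its noiseless curves by construction; the
#' implied additive effect on the exponential rate is stored as ground
#' truth.
#'
#' @param n_models number of PDX models (patients).
#' @param seed integer seed; the generator is deterministic given it.
#' @param baseline_volume_range inclusion window in mm^3 (tumors enter
#'   the trial at the first measurement inside it).
#' @param growth_rate_meanlog,growth_rate_sdlog log-normal parameters of
#'   the per-model exponential growth rate g (per day). The default
#'   median 0.09/day corresponds to a vehicle doubling time of ~7.7 days.
#' @param mouse_rate_sdlog log-normal sd of the per-mouse jitter around
#'   the model growth rate.
#' @param mixture_weights named weights (progression, suppression,
#'   regression); must sum to 1. Models are allocated to components by
#'   largest remainder, so weights k/n yield exactly k models.
#' @param tc_progression,tc_suppression uniform ranges of the target
#'   analytic T/C (percent) for the two growing-response components.
#' @param regression_shrink uniform range of the treated end/start volume
#'   ratio for the regression component (must lie in (0, 1)).
#' @param measurement_days integer day offsets from treatment start
#'   (day 0) at which calipers are read; the horizon is their maximum.
#' @param noise_cv coefficient of variation of the multiplicative
#'   log-normal caliper noise applied to each diameter.
#' @param aspect_ratio longer/shorter diameter ratio used to invert a
#'   volume into the two diameters.
#' @return object of class `pdx_cohort_spec`.
#' @export
cohort_spec <- function(n_models = 31,
                        seed = 1,
                        baseline_volume_range = c(50, 100),
                        growth_rate_meanlog = log(0.09),
                        growth_rate_sdlog = 0.3,
                        mouse_rate_sdlog = 0.1,
                        mixture_weights = c(progression = 10, suppression = 13,
                                            regression = 8) / 31,
                        tc_progression = c(70, 140),
                        tc_suppression = c(15, 35),
                        regression_shrink = c(0.25, 0.55),
                        measurement_days = c(0, 2, 4, 7, 9, 11, 14, 16, 18),
                        noise_cv = 0.02,
                        aspect_ratio = 1.5) {
  if (n_models < 1 || n_models != round(n_models)) {
    stop("`n_models` must be a positive integer", call. = FALSE)
  }
  if (!setequal(names(mixture_weights), RESPONSE_GROUPS)) {
    stop("`mixture_weights` must be named progression/suppression/regression",
         call. = FALSE)
  }
  mixture_weights <- mixture_weights[RESPONSE_GROUPS]
  if (any(mixture_weights < 0) || abs(sum(mixture_weights) - 1) > 1e-8) {
    stop("mixture weights must be non-negative and sum to 1", call. = FALSE)
  }
  for (nm in c("growth_rate_meanlog", "growth_rate_sdlog", "mouse_rate_sdlog",
               "noise_cv", "aspect_ratio")) {
    stop_if_not_scalar_number(get(nm), nm)
  }
  if (exp(growth_rate_meanlog) <= 0 || growth_rate_sdlog < 0) {
    stop("growth-rate distribution parameters invalid", call. = FALSE)
  }
  if (noise_cv < 0) stop("`noise_cv` must be >= 0", call. = FALSE)
  if (aspect_ratio < 1) stop("`aspect_ratio` must be >= 1", call. = FALSE)
  if (length(baseline_volume_range) != 2L ||
      baseline_volume_range[1] <= 0 ||
      diff(baseline_volume_range) <= 0) {
    stop("`baseline_volume_range` must be an increasing positive pair",
         call. = FALSE)
  }
  if (any(measurement_days < 0) || measurement_days[1] != 0 ||
      is.unsorted(measurement_days, strictly = TRUE)) {
    stop("`measurement_days` must start at 0 and increase strictly",
         call. = FALSE)
  }
  if (tc_suppression[1] < 0 || tc_suppression[2] > 50 ||
      tc_progression[1] <= 50) {
    stop("T/C target ranges must lie inside their class", call. = FALSE)
  }
  if (regression_shrink[1] <= 0 || regression_shrink[2] >= 1) {
    stop("`regression_shrink` must lie in (0, 1)", call. = FALSE)
  }
  structure(
    list(
      n_models = as.integer(n_models), seed = as.integer(seed),
      baseline_volume_range = baseline_volume_range,
      growth_rate_meanlog = growth_rate_meanlog,
      growth_rate_sdlog = growth_rate_sdlog,
      mouse_rate_sdlog = mouse_rate_sdlog,
      mixture_weights = mixture_weights,
      tc_progression = tc_progression,
      tc_suppression = tc_suppression,
      regression_shrink = regression_shrink,
      measurement_days = as.integer(measurement_days),
      horizon = max(measurement_days),
      noise_cv = noise_cv,
      aspect_ratio = aspect_ratio
    ),
    class = "pdx_cohort_spec"
  )
}

# Largest-remainder allocation of n items to weights; exact when the
# weights are k/n.
allocate_classes <- function(weights, n) {
  raw <- weights * n
  base <- floor(raw + 1e-9)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  rep(names(weights), times = base)
}

# Invert a volume to the (shorter, longer) diameter pair at a fixed
# aspect ratio r: V = s^2 l / 2 with l = r s gives s = (2V/r)^(1/3).
volume_to_diameters <- function(volume, aspect_ratio) {
  shorter <- (2 * volume / aspect_ratio)^(1 / 3)
  list(shorter = shorter, longer = aspect_ratio * shorter)
}

#' Simulate a 1x1x1 PDX trial cohort
#'
#' For each model, three mice grow exponentially, `V(t) = V0 exp(g t)`,
#' from a seeded engraftment volume; mice are ranked by the calendar day
#' (on a 2-day pre-treatment caliper grid) at which they first reach the
#' inclusion window, and the first becomes the treated arm, the second
#' the vehicle arm, the third is excluded (ties go to the lower mouse
#' index). From its own day 0 the treated tumor grows at the rate solved
#' from the model's mixture component (see [cohort_spec()]); vehicle and
#' excluded tumors keep their intrinsic rates. Volumes on the measurement
#' grid are inverted to diameter pairs at the spec's aspect ratio and
#' corrupted with multiplicative log-normal caliper noise.
#'
#' With `noise_cv = 0` the emitted diameters invert exactly back to the
#' analytic volumes, and classifying the noiseless curves reproduces the
#' intended class of every model.
#'
#' @param spec a [cohort_spec()].
#' @return list with `measurements` (model_id, mouse_id, arm, day,
#'   shorter_mm, longer_mm) and `truth` (per-model ground truth:
#'   intended class, growth rates, effect on g, analytic T/C, baseline
#'   volumes).
#' @export
gen_growth_cohort <- function(spec) {
  stopifnot(inherits(spec, "pdx_cohort_spec"))
  with_seed(spec$seed, {
    classes <- allocate_classes(spec$mixture_weights, spec$n_models)
    classes <- sample(classes)
    horizon <- spec$horizon
    meas <- list()
    truth <- list()
    for (i in seq_len(spec$n_models)) {
      model_id <- sprintf("M%03d", i)
      g_model <- rlnorm(1, spec$growth_rate_meanlog, spec$growth_rate_sdlog)
      g_mouse <- g_model * rlnorm(3, 0, spec$mouse_rate_sdlog)
      v_engraft <- runif(3, 20, 45)
      # first pre-treatment caliper day (2-day grid) inside the window;
      # slow enough growth cannot overshoot 50 -> >100 in one step
      incl_day <- vapply(1:3, function(j) {
        t_cross <- log(spec$baseline_volume_range[1] / v_engraft[j]) / g_mouse[j]
        2 * ceiling(max(t_cross, 0) / 2)
      }, numeric(1))
      ord <- order(incl_day, seq_len(3))
      arms <- character(3)
      arms[ord] <- c("treated", "vehicle", "excluded")
      v0 <- v_engraft * exp(g_mouse * incl_day)

      j_t <- which(arms == "treated")
      j_c <- which(arms == "vehicle")
      g_c <- g_mouse[j_c]
      growth_c <- v0[j_c] * (exp(g_c * horizon) - 1)
      cls <- classes[i]
      if (cls == "regression") {
        shrink <- runif(1, spec$regression_shrink[1], spec$regression_shrink[2])
        g_t <- log(shrink) / horizon
        tc <- 100 * v0[j_t] * (shrink - 1) / growth_c
      } else {
        rng <- if (cls == "progression") spec$tc_progression else spec$tc_suppression
        tc <- runif(1, rng[1], rng[2])
        g_t <- log1p(tc / 100 * growth_c / v0[j_t]) / horizon
      }

      rate <- g_mouse
      rate[j_t] <- g_t
      sdlog <- sqrt(log(1 + spec$noise_cv^2))
      for (j in 1:3) {
        vols <- v0[j] * exp(rate[j] * spec$measurement_days)
        dd <- volume_to_diameters(vols, spec$aspect_ratio)
        if (spec$noise_cv > 0) {
          k <- length(vols)
          dd$shorter <- dd$shorter * rlnorm(k, -sdlog^2 / 2, sdlog)
          dd$longer <- dd$longer * rlnorm(k, -sdlog^2 / 2, sdlog)
          swap <- dd$longer < dd$shorter
          if (any(swap)) {
            tmp <- dd$shorter[swap]
            dd$shorter[swap] <- dd$longer[swap]
            dd$longer[swap] <- tmp
          }
        }
        meas[[length(meas) + 1L]] <- data.frame(
          model_id = model_id,
          mouse_id = sprintf("%s_m%d", model_id, j),
          arm = arms[j],
          day = spec$measurement_days,
          shorter_mm = dd$shorter,
          longer_mm = dd$longer,
          stringsAsFactors = FALSE
        )
      }
      truth[[i]] <- data.frame(
        model_id = model_id,
        class = cls,
        g_model = g_model,
        g_control = g_c,
        g_treated = g_t,
        effect = g_mouse[j_t] - g_t,
        tc_analytic = tc,
        v0_treated = v0[j_t],
        v0_control = v0[j_c],
        stringsAsFactors = FALSE
      )
    }
    list(
      measurements = do.call(rbind, meas),
      truth = do.call(rbind, truth)
    )
  })
}
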