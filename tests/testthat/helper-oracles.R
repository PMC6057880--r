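# Independent oracles and small fixture builders shared across tests.

# Growth curve from explicit day/volume pairs.
make_curve <- function(days, volumes) {
  data.frame(day = days, volume_mm3 = volumes)
}

# Brute-force product-limit estimator: walks the distinct times in
# order, applying S <- S * (1 - d/n) with events preceding censoring at
# ties. Independent of survival::survfit.
km_oracle <- function(time, event) {
  times <- sort(unique(time))
  n_at_risk <- length(time)
  out <- data.frame(time = times, n_risk = NA_real_, n_event = NA_real_,
                    surv = NA_real_)
  s <- 1
  for (i in seq_along(times)) {
    t <- times[i]
    d <- sum(time == t & event)
    c_ <- sum(time == t & !event)
    out$n_risk[i] <- n_at_risk
    out$n_event[i] <- d
    if (d > 0) s <- s * (1 - d / n_at_risk)
    out$surv[i] <- s
    n_at_risk <- n_at_risk - d - c_
  }
  out
}

# Brute-force two-group log-rank statistic: at each distinct event time,
# observed minus expected events in group 1 under the hypergeometric
# model, chi-square = (sum(O-E))^2 / sum(V).
logrank_oracle_2g <- function(time, event, group) {
  g1 <- group == unique(group)[1]
  times <- sort(unique(time[event]))
  o_minus_e <- 0
  v <- 0
  for (t in times) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & g1)
    d <- sum(time == t & event)
    d1 <- sum(time == t & event & g1)
    o_minus_e <- o_minus_e + (d1 - d * n1 / n)
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / v
}

# All multisets of (time, event) records with times from `times`,
# n records: returns list of data.frames.
survival_configurations <- function(n, times = 1:3) {
  pairs <- expand.grid(time = times, event = c(TRUE, FALSE))
  idx <- expand.grid(rep(list(seq_len(nrow(pairs))), n))
  keep <- apply(idx, 1, function(r) all(diff(r) >= 0))  # multisets only
  lapply(which(keep), function(r) pairs[unlist(idx[r, ]), , drop = FALSE])
}

# A small noiseless measurement table for two arms of one model growing
# exponentially at the given rates.
exp_measurements <- function(g_treated, g_control, v0 = 75,
                             days = c(0, 2, 4, 7, 9, 11, 14, 16, 18),
                             aspect = 1.5) {
  mk <- function(arm, g, mouse) {
    v <- v0 * exp(g * days)
    s <- (2 * v / aspect)^(1 / 3)
    data.frame(model_id = "M001", mouse_id = mouse, arm = arm, day = days,
               shorter_mm = s, longer_mm = aspect * s,
               stringsAsFactors = FALSE)
  }
  rbind(mk("treated", g_treated, "m1"), mk("vehicle", g_control, "m2"))
}
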