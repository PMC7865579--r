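# Brute-force survival oracles shared by the unit and acceptance tests.

# product-limit estimator computed by explicit tabulation
brute_km <- function(time, event) {
  ev_times <- sort(unique(time[event == 1]))
  s <- 1
  surv <- numeric(length(ev_times))
  for (i in seq_along(ev_times)) {
    t <- ev_times[i]
    d <- sum(time == t & event == 1)
    n <- sum(time >= t)
    s <- s * (1 - d / n)
    surv[i] <- s
  }
  med <- ev_times[which(surv <= 0.5 + 1e-12)[1]]
  list(time = ev_times, surv = surv,
       median = if (length(med) && !is.na(med)) med else NA_real_)
}

# two-group log-rank statistic via per-event-time 2x2 tabulation
brute_logrank <- function(time, event, grp) {
  ev_times <- sort(unique(time[event == 1]))
  U <- V <- 0
  for (t in ev_times) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & grp == 1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & grp == 1)
    U <- U + d1 - d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  U^2 / V
}

# Efron partial log-likelihood for a binary covariate, by explicit sums
efron_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (t in unique(time[event == 1])) {
    D <- which(time == t & event == 1)
    R <- which(time >= t)
    d <- length(D)
    s_eta <- sum(x[D]) * beta
    rs <- sum(exp(beta * x[R]))
    ds <- sum(exp(beta * x[D]))
    ll <- ll + s_eta
    for (l in seq_len(d) - 1) ll <- ll - log(rs - (l / d) * ds)
  }
  ll
}

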