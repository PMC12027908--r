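# Independent oracles used across the suite. These re-derive expected values
# from first principles and must never call the implementation they check.

# Cox log partial likelihood by direct evaluation of the formula (valid for
# untied event times, where Efron and Breslow coincide)
brute_force_cox_loglik <- function(beta, x, times, events) {
  x <- as.matrix(x)
  lp <- as.numeric(x %*% beta)
  stopifnot(!anyDuplicated(times[events == 1]))
  ll <- 0
  for (i in which(events == 1)) {
    risk_set <- times >= times[i]
    ll <- ll + lp[i] - log(sum(exp(lp[risk_set])))
  }
  ll
}

# hand product-limit estimator (no implementation shortcuts)
hand_km <- function(times, events) {
  ut <- sort(unique(times[events == 1]))
  s <- 1
  surv <- numeric(length(ut))
  for (k in seq_along(ut)) {
    at_risk <- sum(times >= ut[k])
    d <- sum(times == ut[k] & events == 1)
    s <- s * (1 - d / at_risk)
    surv[k] <- s
  }
  data.frame(time = ut, survival = surv)
}

# two-sided Fisher exact p by hypergeometric enumeration
enum_fisher_p <- function(tab) {
  a <- tab[1, 1]
  m <- sum(tab[1, ]); n2 <- sum(tab[2, ]); k <- sum(tab[, 1])
  supp <- max(0, k - n2):min(k, m)
  probs <- stats::dhyper(supp, m, n2, k)
  p_obs <- stats::dhyper(a, m, n2, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# exponential proportional-hazards survival data with one binary covariate
sim_exp_ph <- function(n, beta, base_rate = 0.05, cens = c(0.5, 3)) {
  x <- stats::rbinom(n, 1, 0.5)
  t <- stats::rexp(n, base_rate * exp(beta * x))
  cns <- stats::runif(n, cens[1], cens[2])
  list(x = x, times = pmin(t, cns), events = as.integer(t <= cns))
}

noiseless_params <- function(...) {
  waveform_params(noise_sd = 0, resp_amplitude = 0, ...)
}
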