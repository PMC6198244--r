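# shared fixtures and micro-oracles for the suite

fixture_trials <- function() read_trials_csv(alk_trials_fixture())

# published four-node PFS summaries (hazard ratios versus chemotherapy)
pfs_vs_chemo <- function() {
  tibble::tibble(
    treatment = c("alectinib", "ceritinib", "crizotinib"),
    hr = c(0.50, 0.75, 0.71),
    ci_low = c(0.43, 0.69, 0.66),
    ci_high = c(0.58, 0.83, 0.76)
  )
}

# independent inverse-variance oracle: plain arithmetic, no package code
oracle_fixed_pool <- function(y, se) {
  w <- 1 / se^2
  est <- sum(w * y) / sum(w)
  list(estimate = est, se = sqrt(1 / sum(w)),
       Q = sum(w * (y - est)^2))
}

# brute-force k=2 log-rank statistic from explicit risk tables
oracle_logrank_2g <- function(time, event, group) {
  stopifnot(length(unique(group)) == 2)
  g1 <- sort(unique(group))[1]
  ev_times <- sort(unique(time[event == 1]))
  O <- E <- V <- 0
  for (t in ev_times) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == g1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}
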