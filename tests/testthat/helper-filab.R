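# shared fixtures built in code

default_panel <- load_reference_panel()

# lab values at the midpoint of each normal range for one sex: codes to
# an all-zero deficit vector by construction
midpoint_labs <- function(sex, panel = default_panel) {
  vars <- panel_variables(panel)
  vals <- vapply(vars, function(v) {
    rg <- panel_range(panel, v, sex)
    switch(rg$bound_style,
           interval   = (rg$lower + rg$upper) / 2,
           upper_only = rg$upper / 2,
           lower_only = rg$lower + 1)
  }, numeric(1))
  vals
}

# tiny deterministic cohort for I/O and survival tests
make_toy_cohort <- function(n = 8, seed = 123) {
  cfg <- sim_config(n_subjects = n)
  generate_cohort(cfg, seed = seed)
}

# independent Breslow partial log-likelihood for a single binary covariate,
# written directly from the risk-set definition (oracle; no survival calls)
breslow_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    dead <- which(time == t & event == 1)
    risk <- which(time >= t)
    ll <- ll + beta * sum(x[dead]) -
      length(dead) * log(sum(exp(beta * x[risk])))
  }
  ll
}

# coarse-then-fine grid maximiser of the Breslow partial likelihood
grid_search_cox <- function(time, event, x, lo = -5, hi = 5) {
  for (step in c(0.01, 1e-4, 1e-6)) {
    grid <- seq(lo, hi, by = step)
    ll <- vapply(grid, breslow_loglik, numeric(1),
                 time = time, event = event, x = x)
    best <- grid[which.max(ll)]
    lo <- best - 2 * step
    hi <- best + 2 * step
  }
  best
}
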