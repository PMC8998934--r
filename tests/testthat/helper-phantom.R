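# Shared fixtures: small phantoms keep the suite fast while preserving the
# default acquisition's voxel anisotropy and tissue parameters.

default_te <- c(12.5, 29.2, 45.8, 62.5, 79.2, 95.8, 112.5, 129.2, 145.8, 162.5)

small_spec <- function(noise_sd = 0, ...) {
  phantom_spec(matrix_size = c(48, 48), n_slices = 6, noise_sd = noise_sd, ...)
}

# noiseless rendered session at a given week (memoized per call site)
small_session <- function(week = 3, noise_sd = 0, seed = 11, ...) {
  sp <- small_spec(noise_sd = noise_sd, ...)
  lm_ <- build_label_map(sp, week)
  list(spec = sp, label_map = lm_,
       stack = render_echo_stack(lm_, sp, seed = seed))
}

# two-point closed form for the decay time through points (te_i, s_i), (te_j, s_j)
t2_two_point <- function(te_i, te_j, s_i, s_j) (te_j - te_i) / log(s_i / s_j)

# Brute-force two-group log-rank: tally observed and expected events in A
# over the risk set at every distinct event time.
logrank_bruteforce <- function(time_a, event_a, time_b, event_b) {
  time <- c(time_a, time_b); event <- c(event_a, event_b)
  in_a <- rep(c(TRUE, FALSE), c(length(time_a), length(time_b)))
  o_minus_e <- 0; v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk); n_a <- sum(at_risk & in_a)
    d <- sum(event == 1 & time == t)
    d_a <- sum(event == 1 & time == t & in_a)
    o_minus_e <- o_minus_e + d_a - d * n_a / n
    if (n > 1) v <- v + d * (n_a / n) * (1 - n_a / n) * (n - d) / (n - 1)
  }
  chisq <- o_minus_e^2 / v
  list(chisq = chisq, p = pchisq(chisq, 1, lower.tail = FALSE))
}

# multiplicative volume jitter emulating animal-to-animal growth spread
with_seed_jitter <- function(seed, n = 74, sd = 0.15) {
  set.seed(seed)
  exp(rnorm(n, 0, sd))
}

# Exact two-sided Mann-Whitney p by full enumeration of group assignments.
mann_whitney_enum <- function(a, b) {
  pooled <- c(a, b)
  n_a <- length(a)
  u_of <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  u_obs <- u_of(a, b)
  combos <- combn(length(pooled), n_a)
  us <- apply(combos, 2, function(idx) u_of(pooled[idx], pooled[-idx]))
  mu <- n_a * (length(b)) / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}
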