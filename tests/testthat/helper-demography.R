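# Shared fixtures: synthetic demography at reduced population scale so the
# default test run stays fast; statistical checks state their own n.

small_demography <- function(base_count = 8000) {
  synth_demography(population = make_population(base_count = base_count))
}

# Life table with no tumor-independent mortality before the closing age.
zero_mortality_life_table <- function(min_age = 40L, max_age = 120L) {
  age <- min_age:max_age
  q <- rep(0, length(age))
  q[length(q)] <- 1
  structure(data.frame(age = age, q = q, e = life_expectancy_from_q(q)),
            class = c("life_table", "data.frame"))
}

# Two-sided binomial normal-approximation check: is p_hat consistent with p?
expect_within_binomial_ci <- function(p_hat, p, n, z = 3.5) {
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(p_hat - p), z * se + 1e-12)
}
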