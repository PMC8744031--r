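# Brute-force oracles, independent of the package's evaluation paths.

# AID by the literal double sum over all (x, y) pairs.
oracle_aid <- function(d, xbar) {
  s <- 0
  for (i in seq_along(d))
    for (j in seq_along(d))
      s <- s + d[i] * d[j] * abs(xbar[i] - xbar[j])
  s / 2
}

oracle_var <- function(d, xbar) {
  mu <- sum(d * xbar)
  sum(d * (xbar - mu)^2)
}

# Random discrete age-at-death distribution on integer ages in [0, top].
random_dist <- function(top = 110, max_support = 30) {
  n <- sample(2:max_support, 1)
  ages <- sort(sample(0:top, n))
  aad_from_counts(ages, stats::rgamma(n, shape = 0.7) + 1e-12,
                  point_mass = TRUE)
}

# A small HMD-style text fixture built in code: header plus rows.
hmd_text_fixture <- function() {
  lt <- fixtures()$worked_toy
  tf <- tempfile(fileext = ".txt")
  write_hmd_lifetable(lt, tf)
  tf
}
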