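# Small reusable fixtures, all generated in code.

expit <- function(z) 1 / (1 + exp(-z))

# Incomplete continuous sample with a known missingness pattern.
make_incomplete <- function(n = 40, n_miss = 15, seed = 42) {
  set.seed(seed)
  x <- rnorm(n)
  y <- 1 + 0.5 * x + rnorm(n, 0, 0.8)
  miss <- sample(n, n_miss)
  data.frame(x = x,
             y = replace(y, miss, NA_real_),
             r = as.integer(!seq_len(n) %in% miss))
}

# Incomplete binary sample; both classes guaranteed among the observed.
make_incomplete_binary <- function(n = 60, n_miss = 20, seed = 42) {
  set.seed(seed)
  x <- rnorm(n)
  y <- as.integer(runif(n) < expit(0.5 * x))
  obs <- setdiff(seq_len(n), sample(n, n_miss))
  while (length(unique(y[obs])) < 2) {
    y <- as.integer(runif(n) < expit(0.5 * x))
  }
  data.frame(x = x,
             y = replace(y, setdiff(seq_len(n), obs), NA_real_),
             r = as.integer(seq_len(n) %in% obs))
}
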