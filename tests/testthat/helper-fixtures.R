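# Shared fixtures and indexes, built once per test run.

.fixture_cache <- new.env(parent = emptyenv())

get_fixtures <- function() {
  if (is.null(.fixture_cache$fx)) .fixture_cache$fx <- standard_fixtures(seed = 1L)
  .fixture_cache$fx
}

get_index <- function(name) {
  key <- paste0("ix_", name)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- build_kmer_index(get_fixtures()[[name]]$promoters, k = 5L)
  }
  .fixture_cache[[key]]
}

# one seeded background model per fixture, shared by tests that only read it
get_model <- function(name, seed = 77L) {
  key <- paste0("bm_", name, "_", seed)
  if (is.null(.fixture_cache[[key]])) {
    fx <- get_fixtures()[[name]]
    set.seed(seed)
    .fixture_cache[[key]] <- build_background_model(
      fx$promoters, fx$catalog, index = get_index(name))
  }
  .fixture_cache[[key]]
}

# brute-force reference scanner, independent of the package matcher
brute_force_starts <- function(seq, variant) {
  w <- nchar(variant)
  starts <- integer(0)
  for (s in 0:(nchar(seq) - w)) {
    if (substr(seq, s + 1, s + w) == variant) starts <- c(starts, s)
  }
  starts
}

# exact enumeration oracle for the order test: P(#heads >= x or #heads <= n - x)
# over all 2^n equally likely outcomes, by exact binomial coefficient sums
# (integers below 2^53, so double arithmetic is exact)
order_test_oracle <- function(n, x) {
  counts <- choose(n, 0:n)
  hit <- sum(counts[(0:n) >= x | (0:n) <= (n - x)])
  hit / 2^n
}

# hand-rolled arithmetic reference for the forward pass
forward_oracle <- function(net, x) {
  out <- integer(nrow(x))
  for (i in seq_len(nrow(x))) {
    h <- numeric(nrow(net$w))
    for (j in seq_len(nrow(net$w))) {
      t <- net$b_h[j]
      for (k in 1:3) t <- t + net$w[j, k] * x[i, k]
      h[j] <- 1 / (1 + exp(-t))
    }
    z <- net$b_o
    for (j in seq_along(h)) z <- z + net$v[j] * h[j]
    out[i] <- as.integer(z >= 0)
  }
  out
}

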