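# Seeded substreams: each data type draws from its own seed derived from the
# root seed and a stream name, so adding or reordering streams never perturbs
# the others. All arithmetic stays below 2^53, result below 2^31 - 1.

stream_seed <- function(seed, stream) {
  m <- 2147483647
  h <- 0
  for (ch in utf8ToInt(stream)) h <- (h * 31 + ch) %% m
  base <- abs(as.numeric(seed)) %% m
  as.integer(((base * 2654435) %% m + h) %% m)
}

with_stream <- function(seed, stream, expr) {
  set.seed(stream_seed(seed, stream))
  force(expr)
}

# log-normal with the requested arithmetic mean and CV; cv = 0 degenerates to
# the constant mean so zero-noise configurations are exact.
rlnorm_mean_cv <- function(n, mean, cv) {
  if (cv <= 0) return(rep(mean, n))
  sdlog <- sqrt(log1p(cv^2))
  rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

# mean-one multiplicative noise
rnoise <- function(n, cv) rlnorm_mean_cv(n, 1, cv)

# normal truncated to (lower, upper]; rejection sampling (bounds are several
# SDs out for the defaults, so the loop rarely iterates twice)
rtrunc_norm <- function(n, mean, sd, lower = 0, upper = 1.2) {
  if (sd <= 0) return(rep(min(max(mean, lower + .Machine$double.eps), upper), n))
  out <- rnorm(n, mean, sd)
  for (i in 1:1000) {
    bad <- which(out <= lower | out > upper)
    if (!length(bad)) return(out)
    out[bad] <- rnorm(length(bad), mean, sd)
  }
  pmin(pmax(out, lower + 1e-9), upper)
}
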