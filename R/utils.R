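# Run an expression under a temporary RNG state so that seeded helpers do
# not disturb (and are not disturbed by) the caller's random stream.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

# Deterministic fan-out of one user-facing seed into independent child seeds
# (one per generator or per gene); kept below 2^31 for R's integer range.
child_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 48271 + as.double(stream) * 16807 + 17) %%
               2147483629)
}

log_skewness <- function(x) {
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  if (s == 0) return(0)
  mean(((x - m) / s)^3)
}
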