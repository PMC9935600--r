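# shared fixtures, built once per test session

# the desk-scale study cohort (50 subjects, 32^3, 8 views, 1 s/view fast),
# memoised because several test files exercise it
toy_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_cohort(n = 50L, seed = 7L)
    cache
  }
})

# a small uniform-disk phantom volume for reconstruction tests
disk_phantom <- function(n = 24L, radius_frac = 0.35) {
  ctr <- (n + 1) / 2
  co <- expand.grid(x = seq_len(n), y = seq_len(n), z = seq_len(n))
  act <- array(0, c(n, n, n))
  act[with(co, (x - ctr)^2 + (y - ctr)^2 <= (radius_frac * n)^2 &
             abs(z - ctr) <= n / 4)] <- 1
  act
}
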