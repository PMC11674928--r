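# Shared fixtures, built once per test run.
#
# The 20-node fixture emulates a coarse parcellation connectome normalized the
# way empirical whole-brain studies normalize theirs: weights rescaled to a
# mean node strength of 0.5, which places the hyperexcitation bifurcation of
# the linear-FIC model near G ~ 2-2.5 (alpha = 0.75), the documented working
# range. The 32-node "dense" fixture has 20 mm radius so inter-node spacing is
# comparable to the 1/lambda ~ 5.6 mm turbulence kernel range.

tiny20 <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- make_connectome(20, target_mean_strength = 0.5, seed = 1)
    cache
  }
})

dense32 <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- make_connectome(32, target_mean_strength = 0.5, seed = 5,
                                radius = 20)
    cache
  }
})

# independent brute-force two-sample K-S oracle: evaluate both ECDFs at every
# pooled breakpoint
ks_brute <- function(a, b) {
  u <- sort(c(a, b))
  max(abs(vapply(u, function(v) mean(a <= v) - mean(b <= v), numeric(1))))
}

# phase unwrapping for slope checks
unwrap_phase <- function(p) {
  d <- diff(p)
  d <- d - 2 * pi * round(d / (2 * pi))
  cumsum(c(p[1], d))
}
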