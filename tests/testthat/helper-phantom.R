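# Shared small-phantom fixtures, built once per test run.

small_truth <- function() phantom_truth(dim = c(24, 24, 7))

# Noiseless simulation + T1 map + concentration maps, cached.
fixture_noiseless <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      truth <- small_truth()
      sim <- simulate_study(truth, noise = noise_spec(sigma = 0))
      r1 <- fit_t1_vfa(sim$vfa)
      conc <- signal_to_concentration(sim$dce, r1)
      cache <<- list(truth = truth, sim = sim, r1 = r1, conc = conc)
    }
    cache
  }
})

# A flat-rim phantom: every enhancing voxel at the same (ktrans, ve), no
# muscle slab - used for Monte-Carlo recovery at a known operating point.
uniform_truth <- function(dim = c(48, 48, 9), ktrans = 0.25, ve = 0.4,
                          core_fraction = 0.3) {
  phantom_truth(dim = dim, core_fraction = core_fraction,
                ktrans_range = c(ktrans, ktrans), ve_range = c(ve, ve),
                muscle_box = list(x = integer(0), y = integer(0),
                                  z = integer(0)))
}
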