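# Shared fixtures built in code; no files on disk.

proto <- standard_protocol()
mean_feng <- feng_reference()$mean
sim_tcm <- tcm_params(0.075, 0.15, 0.03)

cardiac_idx <- select_window(proto$schedule, c(39, 48))
short_idx <- sort(c(select_window(proto$schedule, c(36, 39)),
                    select_window(proto$schedule, c(48, 60))))

# Single injection at time zero, full dose: reduces the multi-injection
# input to the plain Feng curve.
single_inj <- injection_schedule(0, 1)

# 27-combination kinetic simulation grid.
tcm_grid <- expand.grid(K1 = c(0.05, 0.075, 0.1),
                        k2 = c(0.05, 0.15, 0.25),
                        k3 = c(0.02, 0.03, 0.04))

# Numeric impulse-train convolution oracle for the multi-injection input:
# discretize the delta train as spikes on a fine grid and convolve with the
# sampled Feng curve by direct summation.
numeric_multi_injection <- function(params, injections, t_eval, h = 0.001) {
  tg <- seq(0, max(t_eval) + h, by = h)
  f <- feng_value(params, tg)
  sapply(t_eval, function(t) {
    out <- 0
    for (j in seq_len(nrow(injections))) {
      u <- t - injections$injection_time[j]
      if (u > 0) {
        # interpolate the sampled curve at the shifted time
        out <- out + injections$dose_fraction[j] * stats::approx(tg, f, u)$y
      }
    }
    out
  })
}

# A small noiseless phantom for fast imaging tests.
small_phantom <- function(noise_c = 0, seed = 1L, dim = c(16, 16, 8)) {
  geo <- brain_phantom_geometry(dim = dim, voxel_size = c(6, 6, 8))
  synth_phantom(geo$labels, geo$params, mean_feng, proto$injections,
                proto$schedule, noise = noise_config(noise_c, seed),
                voxel_size = c(6, 6, 8))
}
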