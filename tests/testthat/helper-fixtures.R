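# Shared fixtures: ideal electrode calibration, hand-built segments and
# small simulation scenarios.

ideal_cal <- function(slope = 58, intercept = 0) {
  # three exact points on the line V = intercept + slope*log10(c)
  conc <- c(0.1, 1, 10)
  fit_calibration(conc, intercept + slope * log10(conc))
}

# Build a position_segment directly (bypassing segmentation) from local
# times and voltages.
make_segment <- function(index, position_index, t_abs, v,
                         channel = "sise1", truncated = FALSE,
                         spans_reposition = FALSE) {
  s <- data.frame(time = t_abs, local_time = t_abs - t_abs[1])
  s[[channel]] <- v
  structure(list(index = index, position_index = position_index,
                 samples = s, truncated = truncated,
                 spans_reposition = spans_reposition),
            class = "position_segment")
}

# Alternating-position triple with shared linear drift d (mV/s) and a
# voltage step `step` (mV) at position 1 relative to position 0.
make_drift_triple <- function(base = 10, drift = 1 / 60, step = 2,
                              pos_first = 0) {
  t1 <- seq(0, 9.99, by = 0.01)
  line <- function(t) base + drift * t
  other <- 1 - pos_first
  sgn <- if (pos_first == 0) -step else step
  list(prev = make_segment(1, pos_first, t1, line(t1) +
                             if (pos_first == 1) -step else 0),
       mid = make_segment(2, other, t1 + 10, line(t1 + 10) +
                            if (other == 1) -step else 0),
       nxt = make_segment(3, pos_first, t1 + 20, line(t1 + 20) +
                            if (pos_first == 1) -step else 0))
}

# Noise-free scenario with a steady efflux producing about a 1% relative
# concentration difference between the positions.
recovery_scenario <- function(tau = 0.5, drift = 0, noise_sd = 0,
                              n_loops = 6, J_over_D = 100, seed = 1) {
  D <- diffusion_coefficient("K+")
  simulation_scenario(
    ion = "K+", bulk_conc = 0.5, true_flux = J_over_D * D,
    electrode = list(slope = 58, intercept = 0, tau = tau,
                     drift = drift, noise_sd = noise_sd),
    geometry = geometry_spec("flat", gap0 = 50e-6),
    n_loops = n_loops, seed = seed)
}
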